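#' End-to-end heart-rate estimation from a facial video
#'
#' Runs the full pipeline on a frame stack with a per-frame landmark track:
#' Delaunay patch tracking, naive-Bayes skin filtering (mean skin
#' probability >= `skin_threshold`), IQR stability selection (top
#' `keep_fraction` smallest IQR), green-trace extraction, and pairwise-ICA
#' majority voting. The skin filter runs before the stability ranking, so
#' "top 50%" is of the skin patches. Setting `use_skin_filter` /
#' `use_stability` to `FALSE` reproduces the ablated variants;
#' `patch_type = "grid"` replaces the landmark-driven triangles with static
#' grid cells over the whole frame.
#'
#' @param frames a [frame_stack()].
#' @param landmark_track K x 2 x T landmark array (ignored for grid
#'   patches).
#' @param skin_model a [train_skin_model()] fit, or `NULL` to skip skin
#'   filtering.
#' @param skin_threshold minimum mean skin probability for a patch.
#' @param keep_fraction fraction of patches kept by the IQR ranking.
#' @param use_skin_filter,use_stability ablation switches.
#' @param patch_type `"delaunay"` (landmark triangles) or `"grid"`.
#' @param grid_dim grid dimensions when `patch_type = "grid"`.
#' @param n_pairs,seed,min_peak_ratio forwarded to [estimate_hr()].
#' @return an `hr_estimate` with an additional `selection` element: a
#'   data.frame (`triangle_id`, `pixel_count`, `skin_score`, `iqr`, `kept`,
#'   `reason`) describing every patch's fate.
#' @export
estimate_hr_video <- function(frames, landmark_track = NULL, skin_model = NULL,
                              skin_threshold = 0.7, keep_fraction = 0.5,
                              use_skin_filter = TRUE, use_stability = TRUE,
                              patch_type = c("delaunay", "grid"),
                              grid_dim = c(6L, 6L), n_pairs = 100L,
                              seed = 1L, min_peak_ratio = 4.5) {
  patch_type <- match.arg(patch_type)
  stopifnot(inherits(frames, "frame_stack"))
  patches <- if (patch_type == "grid") {
    grid_patches(frames$size, n_frames(frames), grid_dim[1L], grid_dim[2L])
  } else {
    if (is.null(landmark_track)) stop("landmark_track is required for Delaunay patches")
    track_patches(landmark_track, frames$size)
  }
  m <- ncol(patches$counts)
  report <- data.frame(
    triangle_id = seq_len(m),
    pixel_count = round(colMeans(patches$counts)),
    skin_score = NA_real_, iqr = NA_real_,
    kept = FALSE, reason = "kept", stringsAsFactors = FALSE
  )

  alive <- which(colSums(patches$counts) > 0L)
  report$reason[setdiff(seq_len(m), alive)] <- "empty"

  if (use_skin_filter && !is.null(skin_model)) {
    sk <- suppressWarnings(
      filter_skin_patches(patches, frames, skin_model, skin_threshold)
    )
    report$skin_score <- sk$scores
    dropped <- setdiff(alive, sk$kept)
    report$reason[dropped] <- "non-skin"
    alive <- intersect(alive, sk$kept)
  }
  if (length(alive) < 2L) {
    stop("fewer than 2 patches survive skin filtering")
  }

  iqrs <- vapply(
    alive,
    function(i) change_series(patches$counts[, i])$iqr,
    numeric(1L)
  )
  report$iqr[alive] <- iqrs
  if (use_stability) {
    keep_idx <- select_stable(iqrs, keep_fraction)
    dropped <- alive[setdiff(seq_along(alive), keep_idx)]
    report$reason[dropped] <- "unstable"
    alive <- alive[keep_idx]
  }
  if (length(alive) < 2L) {
    stop("fewer than 2 patches survive stability selection")
  }
  report$kept[alive] <- TRUE

  traces <- extract_traces(frames, patches, kept = alive)
  est <- estimate_hr(traces,
    n_pairs = n_pairs, seed = seed,
    min_peak_ratio = min_peak_ratio
  )
  est$selection <- report
  est$patches <- patches
  est
}

#' Write an HR estimate (and its votes) as JSON
#'
#' @param est an `hr_estimate`.
#' @param path output path.
#' @export
write_hr_json <- function(est, path) {
  jsonlite::write_json(
    list(
      hr_bpm = est$hr_bpm, f_hr_hz = est$f_hr,
      n_pairs = est$n_pairs,
      vote_histogram = as.list(est$votes[est$votes > 0L]),
      hypotheses = est$hypotheses[, c("i", "j", "bin", "f_peak", "abstained")]
    ),
    path,
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' Export the patch-selection report as CSV
#'
#' @param est an `hr_estimate` from [estimate_hr_video()].
#' @param path output path.
#' @export
write_selection_csv <- function(est, path) {
  stopifnot(!is.null(est$selection))
  utils::write.csv(est$selection, path, row.names = FALSE)
  invisible(path)
}
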