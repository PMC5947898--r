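#' Track Delaunay patches across a landmark track
#'
#' The mesh topology is computed once, on the first frame with complete
#' landmarks, and the same vertex triples are rasterized on every frame, so
#' a patch keeps its identity (and covers the same skin region) while its
#' shape deforms with the landmarks. Frames with missing landmarks are
#' filled by per-coordinate linear interpolation across gaps of up to
#' `max_gap` frames; frames inside longer gaps are marked invalid and their
#' patches carry zero pixels with `valid = FALSE`.
#'
#' @param landmark_track K x 2 x T array (or list of K x 2 matrices) of
#'   landmark positions per frame; `NA` marks a missing frame.
#' @param frame_size `c(width, height)` in pixels.
#' @param max_gap longest run of missing frames bridged by interpolation.
#' @return An object of class `patch_track_set`: list with `mesh`,
#'   `counts` (T x n_triangles), `valid` (T x n_triangles logical),
#'   `pixels` (per frame, per triangle pixel-index vectors),
#'   `frame_size`, `n_frames`.
#' @export
track_patches <- function(landmark_track, frame_size, max_gap = 5L) {
  lm <- as_landmark_array(landmark_track)
  n_frames <- dim(lm)[3L]
  valid_frame <- apply(lm, 3L, function(m) all(is.finite(m)))
  if (mean(valid_frame) < 0.5) {
    stop("fewer than 50% of frames have landmarks; clip is untrackable")
  }
  lm <- interpolate_landmarks(lm, valid_frame, max_gap)
  usable <- apply(lm, 3L, function(m) all(is.finite(m)))
  first <- which(usable)[1L]
  mesh <- delaunay_triangulate(lm[, , first])
  m <- nrow(mesh$triangles)

  counts <- matrix(0L, nrow = n_frames, ncol = m)
  valid <- matrix(FALSE, nrow = n_frames, ncol = m)
  pixels <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    if (!usable[t]) {
      pixels[[t]] <- rep(list(integer(0L)), m)
      next
    }
    r <- rasterize_mesh(mesh, lm[, , t], frame_size)
    pixels[[t]] <- r$pixels
    counts[t, ] <- r$counts
    valid[t, ] <- r$counts > 0L
  }
  structure(
    list(
      mesh = mesh, counts = counts, valid = valid, pixels = pixels,
      frame_size = as.integer(frame_size), n_frames = n_frames,
      landmarks = lm
    ),
    class = "patch_track_set"
  )
}

as_landmark_array <- function(landmark_track) {
  if (is.list(landmark_track)) {
    k <- nrow(landmark_track[[1L]])
    lm <- array(NA_real_, dim = c(k, 2L, length(landmark_track)))
    for (t in seq_along(landmark_track)) {
      if (!is.null(landmark_track[[t]])) lm[, , t] <- as.matrix(landmark_track[[t]])
    }
    lm
  } else {
    arr <- landmark_track
    stopifnot(length(dim(arr)) == 3L, dim(arr)[2L] == 2L)
    arr
  }
}

interpolate_landmarks <- function(lm, valid_frame, max_gap) {
  if (all(valid_frame)) {
    return(lm)
  }
  n <- dim(lm)[3L]
  ok <- which(valid_frame)
  gap_ok <- logical(n)
  gap_ok[ok] <- TRUE
  miss <- rle(!valid_frame)
  pos <- cumsum(c(1L, miss$lengths))
  for (i in seq_along(miss$values)) {
    if (miss$values[i] && miss$lengths[i] <= max_gap) {
      run <- pos[i]:(pos[i + 1L] - 1L)
      # only bridge interior gaps
      if (pos[i] > 1L && pos[i + 1L] <= n) gap_ok[run] <- TRUE
    }
  }
  fill <- which(gap_ok & !valid_frame)
  if (length(fill)) {
    for (k in seq_len(dim(lm)[1L])) {
      for (d in 1:2) {
        lm[k, d, fill] <- stats::approx(ok, lm[k, d, ok], xout = fill)$y
      }
    }
  }
  lm
}

#' Patch pixel-count table
#'
#' @param x a `patch_track_set`.
#' @param row.names,optional,... passed through for S3 compatibility.
#' @return data.frame with columns `frame`, `triangle_id`, `pixel_count`.
#' @export
as.data.frame.patch_track_set <- function(x, row.names = NULL, optional = FALSE, ...) {
  m <- ncol(x$counts)
  data.frame(
    frame = rep(seq_len(x$n_frames), each = m),
    triangle_id = rep(seq_len(m), times = x$n_frames),
    pixel_count = as.integer(t(x$counts))
  )
}

#' @export
print.patch_track_set <- function(x, ...) {
  cat(
    "patch_track_set:", ncol(x$counts), "patches x", x$n_frames, "frames;",
    sum(!x$valid), "invalid patch-frames\n"
  )
  invisible(x)
}

#' Static rectangular grid patches over the full frame
#'
#' Baseline patch scheme used by the ablations: the frame is tiled by an
#' `nx` x `ny` grid of fixed cells that do not follow the landmarks, as in
#' grid-cell rPPG methods. Returns the same `patch_track_set` structure as
#' [track_patches()] so the downstream stages apply unchanged.
#'
#' @param frame_size `c(width, height)`.
#' @param n_frames number of frames in the clip.
#' @param nx,ny grid dimensions.
#' @export
grid_patches <- function(frame_size, n_frames, nx = 6L, ny = 6L) {
  w <- as.integer(frame_size[1L])
  h <- as.integer(frame_size[2L])
  xs <- round(seq(0L, w, length.out = nx + 1L))
  ys <- round(seq(0L, h, length.out = ny + 1L))
  cells <- list()
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      cx <- xs[i]:(xs[i + 1L] - 1L)
      cy <- ys[j]:(ys[j + 1L] - 1L)
      cells[[length(cells) + 1L]] <-
        as.integer(outer(cy, cx * h, `+`) + 1L)
    }
  }
  m <- length(cells)
  counts <- matrix(vapply(cells, length, integer(1L)),
    nrow = n_frames, ncol = m, byrow = TRUE
  )
  structure(
    list(
      mesh = NULL, counts = counts,
      valid = matrix(TRUE, n_frames, m),
      pixels = rep(list(cells), n_frames),
      frame_size = c(w, h), n_frames = n_frames, landmarks = NULL
    ),
    class = "patch_track_set"
  )
}
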