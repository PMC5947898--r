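#' Extract per-patch green-channel traces
#'
#' For every kept patch, averages the green-channel intensity over the
#' patch's member pixels on each frame. The green channel is used because
#' hemoglobin absorption peaks around 520-580 nm, inside the green
#' passband. Frames where a patch is empty or invalid are filled by linear
#' interpolation so every trace spans the full clip.
#'
#' @param frames a [frame_stack()].
#' @param patches a `patch_track_set`.
#' @param kept integer ids of the patches to extract (default all).
#' @return list of `raw_trace` objects (fields `patch_id`, `values`,
#'   `frame_rate`).
#' @export
extract_traces <- function(frames, patches, kept = NULL) {
  arr <- frame_array(frames)
  fr <- if (inherits(frames, "frame_stack")) frames$frame_rate else attr(frames, "frame_rate")
  stopifnot(!is.null(fr))
  if (is.null(kept)) kept <- seq_len(ncol(patches$counts))
  if (length(kept) < 2L) {
    stop("insufficient observations for ICA: need at least 2 patches")
  }
  n_t <- dim(arr)[4L]
  stopifnot(n_t == patches$n_frames)
  traces <- lapply(kept, function(i) rep(NA_real_, n_t))
  for (t in seq_len(n_t)) {
    g <- arr[, , 2L, t]
    for (j in seq_along(kept)) {
      px <- patches$pixels[[t]][[kept[j]]]
      if (length(px)) traces[[j]][t] <- mean(g[px])
    }
  }
  lapply(seq_along(kept), function(j) {
    v <- traces[[j]]
    if (anyNA(v)) {
      ok <- which(!is.na(v))
      if (length(ok) < 2L) stop("patch ", kept[j], " is empty on nearly all frames")
      v <- stats::approx(ok, v[ok], xout = seq_len(n_t), rule = 2)$y
    }
    structure(
      list(patch_id = kept[j], values = v, frame_rate = fr),
      class = "raw_trace"
    )
  })
}

#' Condition a raw trace for ICA
#'
#' Removes slow drift by subtracting a centered moving average (default
#' 10 s, shrinking at the edges) and standardizes to zero mean and unit
#' variance. FastICA requires centered inputs, and without detrending the
#' illumination drift dominates the variance.
#'
#' @param values numeric trace.
#' @param fs sampling rate (Hz).
#' @param ma_seconds moving-average window in seconds.
#' @return numeric vector, zero mean and unit variance (all-constant input
#'   comes back as zeros).
#' @export
preprocess_trace <- function(values, fs, ma_seconds = 10) {
  n <- length(values)
  w <- max(3L, min(n, round(ma_seconds * fs)))
  half <- w %/% 2L
  cs <- cumsum(c(0, values))
  lo <- pmax(0L, seq_len(n) - 1L - half)
  hi <- pmin(n, seq_len(n) + half)
  ma <- (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
  d <- values - ma
  s <- stats::sd(d)
  if (!is.finite(s) || s < 1e-12) {
    return(rep(0, n))
  }
  (d - mean(d)) / s
}

#' Pulse-frequency hypothesis from an unmixed patch pair
#'
#' Of the two ICA outputs, the pulse component is taken to be the one with
#' the larger in-band (0.7-4 Hz) peak-to-total-power ratio. The hypothesis
#' votes the frequency bin (width 1/30 Hz, tiling the band) containing the
#' highest in-band PSD peak. If the chosen component's peak does not stand
#' out from the in-band floor (peak-to-mean ratio below `min_peak_ratio`,
#' calibrated on white-noise draws), the hypothesis abstains.
#'
#' @param sources 2 x T matrix of ICA source estimates.
#' @param fs sampling rate (Hz).
#' @param band frequency search band in Hz.
#' @param bin_width voting bin width in Hz.
#' @param min_peak_ratio abstention floor for peak/mean in-band power.
#' @param seg_seconds Welch segment length passed to [welch_psd()].
#' @return object of class `hr_hypothesis`: list with `abstained`,
#'   `voted_bin`, `bin_center` (Hz), `f_peak`, `peak_power`, `psd`,
#'   `component`.
#' @export
hypothesis_from_pair <- function(sources, fs, band = c(0.7, 4),
                                 bin_width = 1 / 30, min_peak_ratio = 4.5,
                                 seg_seconds = 10) {
  stopifnot(is.matrix(sources), nrow(sources) == 2L)
  psds <- lapply(1:2, function(i) welch_psd(sources[i, ], fs, seg_seconds))
  scores <- vapply(psds, function(p) {
    ib <- p$freq >= band[1L] & p$freq <= band[2L]
    if (!any(ib) || sum(p$power) <= 0) {
      return(0)
    }
    max(p$power[ib]) / sum(p$power)
  }, numeric(1L))
  comp <- which.max(scores)
  psd <- psds[[comp]]
  ib <- psd$freq >= band[1L] & psd$freq <= band[2L]
  pin <- psd$power[ib]
  fin <- psd$freq[ib]
  peak <- which.max(pin)
  ratio <- if (mean(pin) > 0) pin[peak] / mean(pin) else 0
  if (!is.finite(ratio) || ratio < min_peak_ratio) {
    return(structure(
      list(
        abstained = TRUE, voted_bin = NA_integer_, bin_center = NA_real_,
        f_peak = NA_real_, peak_power = NA_real_, psd = psd, component = comp
      ),
      class = "hr_hypothesis"
    ))
  }
  f_peak <- fin[peak]
  bin <- min(
    as.integer(floor((f_peak - band[1L]) / bin_width)) + 1L,
    as.integer(ceiling((band[2L] - band[1L]) / bin_width))
  )
  structure(
    list(
      abstained = FALSE, voted_bin = bin,
      bin_center = band[1L] + (bin - 0.5) * bin_width,
      f_peak = f_peak, peak_power = pin[peak], psd = psd, component = comp
    ),
    class = "hr_hypothesis"
  )
}

#' Majority-vote heart-rate estimate from patch traces
#'
#' Samples up to `n_pairs` distinct patch pairs without replacement,
#' unmixes each with [ica_pair()], lets each pair's pulse hypothesis vote a
#' frequency bin via [hypothesis_from_pair()], and reports the bin with the
#' most votes: `HR = 60 * f_HR` with `f_HR` the winning bin's center. Vote
#' ties are broken by the larger summed peak power.
#'
#' @param traces list of `raw_trace` objects from [extract_traces()].
#' @param n_pairs maximum number of patch pairs to sample.
#' @param seed integer seed driving pair sampling and ICA initialization.
#' @param band,bin_width,min_peak_ratio forwarded to
#'   [hypothesis_from_pair()].
#' @param ma_seconds detrending window for [preprocess_trace()].
#' @return object of class `hr_estimate`: list with `hr_bpm`, `f_hr`,
#'   `votes` (per-bin counts), `n_pairs`, `hypotheses` (data.frame).
#' @export
estimate_hr <- function(traces, n_pairs = 100L, seed = 1L,
                        band = c(0.7, 4), bin_width = 1 / 30,
                        min_peak_ratio = 4.5, ma_seconds = 10) {
  n <- length(traces)
  if (n < 2L) {
    stop("insufficient observations for ICA: need at least 2 traces")
  }
  fs <- traces[[1L]]$frame_rate
  X <- vapply(traces, function(tr) preprocess_trace(tr$values, fs, ma_seconds),
    numeric(length(traces[[1L]]$values))
  )
  pairs <- t(utils::combn(n, 2L))
  if (nrow(pairs) > n_pairs) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    set.seed(seed)
    pairs <- pairs[sample.int(nrow(pairs), n_pairs), , drop = FALSE]
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }

  n_bins <- as.integer(ceiling((band[2L] - band[1L]) / bin_width))
  votes <- integer(n_bins)
  power_sum <- numeric(n_bins)
  rec <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]
    j <- pairs[k, 2L]
    un <- withCallingHandlers(
      ica_pair(X[, i], X[, j], seed = seed + 7L * k),
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (is.null(un) || !un$converged) {
      rec[[k]] <- data.frame(
        i = i, j = j, bin = NA_integer_, f_peak = NA_real_,
        peak_power = NA_real_, abstained = TRUE
      )
      next
    }
    hyp <- hypothesis_from_pair(un$S, fs,
      band = band, bin_width = bin_width,
      min_peak_ratio = min_peak_ratio
    )
    if (!hyp$abstained) {
      votes[hyp$voted_bin] <- votes[hyp$voted_bin] + 1L
      power_sum[hyp$voted_bin] <- power_sum[hyp$voted_bin] + hyp$peak_power
    }
    rec[[k]] <- data.frame(
      i = i, j = j, bin = hyp$voted_bin, f_peak = hyp$f_peak,
      peak_power = if (hyp$abstained) NA_real_ else hyp$peak_power,
      abstained = hyp$abstained
    )
  }
  if (sum(votes) == 0L) {
    stop("no pulse found: every patch-pair hypothesis abstained")
  }
  win <- tally_votes(votes, power_sum)
  f_hr <- band[1L] + (win - 0.5) * bin_width
  structure(
    list(
      hr_bpm = 60 * f_hr, f_hr = f_hr,
      votes = stats::setNames(votes, sprintf(
        "%.3f", band[1L] + (seq_len(n_bins) - 0.5) * bin_width
      )),
      n_pairs = nrow(pairs),
      hypotheses = do.call(rbind, rec)
    ),
    class = "hr_estimate"
  )
}

# winning bin of a vote histogram; ties go to the larger summed peak power
tally_votes <- function(votes, power_sum) {
  top <- which(votes == max(votes))
  top[which.max(power_sum[top])]
}

#' @export
print.hr_estimate <- function(x, ...) {
  cat(
    sprintf(
      "HR estimate: %.1f bpm (f_HR = %.3f Hz) from %d patch pairs, %d votes for winner\n",
      x$hr_bpm, x$f_hr, x$n_pairs, max(x$votes)
    )
  )
  invisible(x)
}
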