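#' Normalized pixel-count change series of a patch
#'
#' The raw change series of a patch with per-frame pixel counts
#' `N = (N_1, ..., N_K)` is the first difference
#' `(N_2 - N_1, ..., N_K - N_{K-1})`. To put every patch on the same scale
#' regardless of its size, each element is weighted by
#' `K / sqrt(sum(N))`. The interquartile range (Q3 - Q1, type-7 quartiles)
#' of the weighted series measures how stable the patch's visible area is
#' over the clip: self-occlusion and expression artifacts inflate it.
#'
#' @param N integer vector of per-frame pixel counts (length K >= 3).
#' @return object of class `change_series` with fields `raw`, `weighted`,
#'   `weight`, `iqr`.
#' @examples
#' change_series(c(4, 9, 4, 9, 4))
#' @export
change_series <- function(N) {
  N <- as.numeric(N)
  k <- length(N)
  if (k < 3L) {
    stop("need at least 3 frames to form a change series")
  }
  total <- sum(N)
  if (total <= 0) {
    stop("dead patch: zero pixels over the whole clip")
  }
  raw <- diff(N)
  weight <- k / sqrt(total)
  weighted <- weight * raw
  structure(
    list(
      raw = raw, weighted = weighted, weight = weight,
      iqr = unname(diff(stats::quantile(weighted, c(0.25, 0.75),
        type = 7, names = FALSE
      )))
    ),
    class = "change_series"
  )
}

#' Select the most size-stable patches by IQR
#'
#' Ranks patches by the IQR of their normalized change series (ascending)
#' and keeps the top `keep_fraction` (default 50%) with the smallest IQR.
#' Ties are broken by smaller patch id, so selection is deterministic.
#'
#' @param patches list of [change_series()] objects, or a bare numeric
#'   vector of IQR values.
#' @param keep_fraction fraction of patches to keep; `ceiling(f * n)` are
#'   kept.
#' @return integer vector of kept patch ids (indices into `patches`), in
#'   ascending id order.
#' @export
select_stable <- function(patches, keep_fraction = 0.5) {
  if (length(patches) == 0L) {
    stop("no patches to select from")
  }
  iqrs <- if (is.numeric(patches)) {
    as.numeric(patches)
  } else {
    vapply(patches, function(p) p$iqr, numeric(1L))
  }
  n <- length(iqrs)
  n_keep <- min(n, as.integer(ceiling(keep_fraction * n)))
  ord <- order(iqrs, seq_len(n))
  sort(ord[seq_len(n_keep)])
}
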