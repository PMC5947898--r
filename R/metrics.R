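#' Spectral signal-to-noise ratio around the ground-truth frequency
#'
#' `SNR = (E_gt + E_1st_harmonic) / E_remaining`: the energy within
#' `band_halfwidth` of the ground-truth frequency, plus the energy around
#' its first harmonic, divided by the remaining energy in the evaluated
#' span (0.7-4 Hz, matching the heart-rate search band). When no energy
#' remains outside the two bands the ratio is reported as `Inf` with
#' `infinite = TRUE`.
#'
#' @param psd data.frame with `freq` and `power` columns (e.g. from
#'   [welch_psd()]), or a numeric power vector with a `freq` vector given
#'   via `freq`.
#' @param f_gt ground-truth frequency in Hz.
#' @param band_halfwidth half-width of the signal bands in Hz (default
#'   0.1 Hz, about 6 bpm).
#' @param span frequency span over which energies are accumulated.
#' @param freq optional frequency vector when `psd` is a bare vector.
#' @return object of class `snr_report`: list with `snr`, `e_gt`,
#'   `e_first_harmonic`, `e_remaining`, `band_halfwidth`, `infinite`.
#' @export
snr_report <- function(psd, f_gt, band_halfwidth = 0.1, span = c(0.7, 4),
                       freq = NULL) {
  if (is.data.frame(psd)) {
    freq <- psd$freq
    power <- psd$power
  } else {
    power <- psd
    stopifnot(!is.null(freq), length(freq) == length(power))
  }
  stopifnot(f_gt > 0, all(power >= 0))
  if (f_gt > max(freq) || 2 * f_gt > max(freq)) {
    stop("f_gt and its first harmonic must lie inside the evaluated spectrum")
  }
  in_span <- freq >= span[1L] & freq <= span[2L]
  gt_band <- abs(freq - f_gt) <= band_halfwidth & in_span
  h_band <- abs(freq - 2 * f_gt) <= band_halfwidth & in_span & !gt_band
  e_gt <- sum(power[gt_band])
  e_h <- sum(power[h_band])
  e_rem <- sum(power[in_span & !gt_band & !h_band])
  structure(
    list(
      snr = if (e_rem > 0) (e_gt + e_h) / e_rem else Inf,
      e_gt = e_gt, e_first_harmonic = e_h, e_remaining = e_rem,
      band_halfwidth = band_halfwidth, infinite = e_rem <= 0
    ),
    class = "snr_report"
  )
}

#' Agreement metrics between predicted and reference heart rates
#'
#' Computes the standard evaluation arithmetic for HR estimators:
#' `HR_error = HR_pred - HR_GT`; `me` the mean error; `sde` its sample
#' (n-1) standard deviation; `rmse`; Bland-Altman 95% limits of agreement
#' `me +/- 1.96 * sde`; the Pearson correlation between prediction and
#' reference (flagged `NA` when either side is constant); and the
#' well-estimation rate, the fraction of clips with `|error|` strictly
#' less than 5 bpm.
#'
#' @param pred,truth numeric vectors of equal length (>= 2), in bpm.
#' @return object of class `agreement_report`.
#' @export
agreement_report <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("pred and truth must have equal length")
  }
  if (length(pred) < 2L) {
    stop("need at least 2 paired measurements")
  }
  err <- pred - truth
  me <- mean(err)
  sde <- stats::sd(err)
  pearson <- if (stats::sd(pred) > 0 && stats::sd(truth) > 0) {
    stats::cor(pred, truth)
  } else {
    NA_real_
  }
  structure(
    list(
      rmse = sqrt(mean(err^2)), me = me, sde = sde,
      loa_low = me - 1.96 * sde, loa_high = me + 1.96 * sde,
      pearson_r = pearson, constant_input = is.na(pearson),
      well_rate = mean(abs(err) < 5), n = length(err),
      errors = err
    ),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "RMSE %.2f bpm (Me %.2f +/- SDe %.2f); LoA [%.2f, %.2f]; r = %s; well rate %.1f%% (n = %d)\n",
    x$rmse, x$me, x$sde, x$loa_low, x$loa_high,
    ifelse(is.na(x$pearson_r), "NA", sprintf("%.3f", x$pearson_r)),
    100 * x$well_rate, x$n
  ))
  invisible(x)
}

#' Bland-Altman plot of two HR measurement methods
#'
#' Scatter of difference against the mean of the two measurements, with
#' the mean difference and the 95% limits of agreement.
#'
#' @param pred,truth numeric vectors in bpm.
#' @return a ggplot object.
#' @export
bland_altman_plot <- function(pred, truth) {
  rep_ <- agreement_report(pred, truth)
  df <- data.frame(avg = (pred + truth) / 2, diff = pred - truth)
  ggplot2::ggplot(df, ggplot2::aes(x = avg, y = diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = rep_$me, colour = "red") +
    ggplot2::geom_hline(
      yintercept = c(rep_$loa_low, rep_$loa_high),
      linetype = "dashed", colour = "blue"
    ) +
    ggplot2::labs(
      x = "Mean of methods (bpm)", y = "Difference (bpm)",
      title = sprintf(
        "Bland-Altman: Me = %.2f, LoA [%.2f, %.2f]",
        rep_$me, rep_$loa_low, rep_$loa_high
      )
    ) +
    ggplot2::theme_minimal()
}

#' Write an agreement report as JSON
#'
#' @param report an [agreement_report()].
#' @param path output path.
#' @export
write_agreement_json <- function(report, path) {
  jsonlite::write_json(
    report[c(
      "rmse", "me", "sde", "loa_low", "loa_high", "pearson_r",
      "well_rate", "n"
    )],
    path,
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}
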