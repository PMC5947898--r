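#' Welch power spectral density
#'
#' Averaged modified periodogram with a Hann window. Segments default to
#' 10 s with 50% overlap; each segment is mean-removed, windowed and
#' zero-padded so the frequency grid step is at most `freq_res`.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param seg_seconds segment length in seconds (clipped to the signal
#'   length).
#' @param overlap fractional overlap between segments.
#' @param freq_res desired frequency grid step in Hz (via zero padding).
#' @return data.frame with columns `freq` (Hz) and `power` (one-sided
#'   density).
#' @export
welch_psd <- function(x, fs, seg_seconds = 10, overlap = 0.5, freq_res = 0.01) {
  n <- length(x)
  stopifnot(n >= 8L, fs > 0)
  L <- min(n, max(8L, round(seg_seconds * fs)))
  step <- max(1L, floor(L * (1 - overlap)))
  starts <- seq(1L, n - L + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1L)) / (L - 1L))
  u <- sum(win^2)
  nfft <- max(L, ceiling(fs / freq_res))
  half <- floor(nfft / 2) + 1L
  acc <- numeric(half)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * win
    sp <- stats::fft(c(seg, numeric(nfft - L)))[seq_len(half)]
    acc <- acc + (Mod(sp)^2) / (fs * u)
  }
  p <- acc / length(starts)
  # fold two-sided density into one-sided
  inner <- 2:(half - 1L)
  p[inner] <- 2 * p[inner]
  data.frame(freq = (seq_len(half) - 1L) * fs / nfft, power = p)
}
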