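#' Welch power spectral density
#'
#' Welch's averaged-periodogram PSD estimate: the series is split into
#' Hann-windowed segments with 50% overlap (by default), each segment is
#' detrended by mean removal, and the squared FFT magnitudes are averaged
#' and normalized to a one-sided density (power per Hz).
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param seg_len segment length in samples; defaults to `length(x)/8`
#'   rounded to the nearest power of two (at least 256 when possible).
#' @param overlap fractional overlap between segments.
#' @return data frame with columns `freq` (Hz) and `power`.
#' @export
welch_psd <- function(x, fs, seg_len = NULL, overlap = 0.5) {
  n <- length(x)
  if (is.null(seg_len)) {
    seg_len <- 2^floor(log2(max(n %/% 8, 2)))
    seg_len <- min(max(seg_len, min(256, n)), n)
  }
  seg_len <- min(seg_len, n)
  step <- max(1, round(seg_len * (1 - overlap)))
  starts <- seq(1, n - seg_len + 1, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  u <- sum(win^2)
  acc <- numeric(seg_len %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)]
    seg <- (seg - mean(seg)) * win
    p <- abs(stats::fft(seg))^2
    acc <- acc + p[seq_len(seg_len %/% 2 + 1)]
  }
  psd <- acc / (length(starts) * fs * u)
  # double interior bins to fold negative frequencies into a one-sided PSD
  if (length(psd) > 2) psd[2:(length(psd) - 1)] <- 2 * psd[2:(length(psd) - 1)]
  freq <- seq(0, by = fs / seg_len, length.out = length(psd))
  data.frame(freq = freq, power = psd)
}

#' Log-log spectral slope over a frequency band
#'
#' Ordinary least-squares fit of `log10(power)` against `log10(freq)`
#' within `band`, the estimator behind the f^-beta scaling exponents of
#' stabilogram spectra.
#'
#' @param psd data frame from [welch_psd()].
#' @param band length-2 frequency interval (Hz), inclusive.
#' @return slope (dimensionless); `NA` with a warning if fewer than 3
#'   spectral points fall inside the band.
#' @export
loglog_slope <- function(psd, band) {
  sel <- psd$freq >= band[1] & psd$freq <= band[2] & psd$freq > 0 &
    psd$power > 0
  if (sum(sel) < 3) {
    warning("fewer than 3 spectral points in band; slope omitted")
    return(NA_real_)
  }
  unname(stats::coef(stats::lm(log10(power) ~ log10(freq),
                               data = psd[sel, ]))[2])
}
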