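#' Zero-lag Butterworth filtering
#'
#' Applies a Butterworth filter forward and backward
#' ([signal::filtfilt()]), yielding zero phase lag and a squared
#' magnitude response (two -3 dB passes at the cut-off, i.e. amplitude
#' about 0.5 at the nominal cut-off frequency).
#'
#' @param x numeric vector or matrix (columns filtered independently).
#' @param fs sampling rate (Hz).
#' @param cutoff cut-off frequency (Hz); length 2 for `type = "pass"`.
#' @param order filter order of each pass.
#' @param type `"low"`, `"high"` or `"pass"`.
#' @return filtered series, same shape as `x`.
#' @export
butter_zero_lag <- function(x, fs, cutoff, order = 4, type = "low") {
  w <- cutoff / (fs / 2)
  if (any(w <= 0) || any(w >= 1))
    stop("cutoff must lie strictly inside (0, fs/2)")
  flt <- signal::butter(order, w, type = switch(type, low = "low",
                                                high = "high", pass = "pass"))
  # odd-reflection padding suppresses the zero-initial-state edge
  # transients of the forward and backward passes
  f_lo <- min(cutoff)
  apply_flt <- function(v) {
    n <- length(v)
    pad <- min(n - 1, ceiling(10 * fs / f_lo))
    vp <- c(2 * v[1] - v[seq(pad + 1, 2)], v,
            2 * v[n] - v[seq(n - 1, n - pad)])
    y <- signal::filtfilt(flt, vp)
    y[(pad + 1):(pad + n)]
  }
  if (is.matrix(x)) apply(x, 2, apply_flt) else apply_flt(x)
}

#' Central-difference derivative
#'
#' Second-order accurate central differences on interior samples and
#' first-order one-sided differences at the two endpoints (exact on
#' affine signals everywhere). Endpoint samples are flagged by the
#' `"endpoint"` attribute so downstream peak detection can exclude them.
#'
#' @param x numeric vector.
#' @param dt sample interval (s), or use `fs`.
#' @param fs sampling rate (Hz), alternative to `dt`.
#' @return numeric vector of derivatives, same length as `x`.
#' @export
central_diff <- function(x, dt = NULL, fs = NULL) {
  if (is.null(dt)) dt <- 1 / fs
  n <- length(x)
  if (n < 2) stop("need at least 2 samples")
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  if (n > 2) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  attr(d, "endpoint") <- c(1L, n)
  d
}

#' Fourier-domain resampling
#'
#' Band-limited rate conversion: the series is reflection-padded (to
#' suppress edge ringing), transformed, its spectrum truncated or
#' zero-extended to the new rate, and transformed back. Frequency
#' content below the smaller Nyquist limit is preserved with unit gain;
#' content above it is removed.
#'
#' @param x numeric vector or matrix (columns resampled independently).
#' @param fs_in,fs_out input and output sampling rates (Hz).
#' @return resampled series of `round(n * fs_out / fs_in)` samples.
#' @export
resample_stream <- function(x, fs_in, fs_out) {
  if (fs_in == fs_out) return(x)
  rs <- function(v) {
    n <- length(v)
    pad <- min(n, max(16, ceiling(0.05 * n)))
    vp <- c(rev(v[seq_len(pad)]), v, rev(v[seq(n - pad + 1, n)]))
    np <- length(vp)
    mp <- round(np * fs_out / fs_in)
    sp <- stats::fft(vp)
    out_sp <- complex(real = numeric(mp))
    half <- min(np, mp) %/% 2
    out_sp[seq_len(half + 1)] <- sp[seq_len(half + 1)]
    if (half > 1)
      out_sp[seq(mp, mp - half + 2)] <- sp[seq(np, np - half + 2)]
    y <- Re(stats::fft(out_sp, inverse = TRUE)) / np
    i0 <- round(pad * fs_out / fs_in)
    m <- round(n * fs_out / fs_in)
    y[(i0 + 1):(i0 + m)]
  }
  if (is.matrix(x)) apply(x, 2, rs) else rs(x)
}
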