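#' Frequency band definitions
#'
#' The canonical EEG analysis bands: theta 4-7, alpha 8-12, low-beta
#' 13-20, high-beta 21-30 and gamma 40-60 Hz. All configurable.
#'
#' @param theta,alpha,low_beta,high_beta,gamma length-2 frequency
#'   intervals (Hz), inclusive.
#' @return named list of bands, class `band_set`.
#' @export
band_set <- function(theta = c(4, 7), alpha = c(8, 12),
                     low_beta = c(13, 20), high_beta = c(21, 30),
                     gamma = c(40, 60)) {
  b <- list(theta = theta, alpha = alpha, low_beta = low_beta,
            high_beta = high_beta, gamma = gamma)
  structure(b, class = "band_set")
}

#' EEG epoch container
#'
#' Event-locked EEG segments: an `epoch x channel x time` array with its
#' sampling rate, channel labels and epoch window.
#'
#' @param data numeric array `[epoch, channel, time]` (microvolts).
#' @param fs sampling rate (Hz).
#' @param channels channel labels (10/10 names).
#' @param window length-2 epoch window (s) relative to the event.
#' @return an object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, fs, channels = NULL, window = c(-5, 15)) {
  stopifnot(length(dim(data)) == 3)
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(data)[2]))
  if (length(channels) != dim(data)[2])
    stop("channel labels must match dim(data)[2]")
  n <- dim(data)[3]
  t <- seq(window[1], window[2], length.out = n)
  structure(list(data = data, fs = fs, channels = channels,
                 window = window, t = t), class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d epochs x %d channels x %d samples @ %g Hz, window [%g, %g] s\n",
              d[1], d[2], d[3], x$fs, x$window[1], x$window[2]))
  invisible(x)
}

#' Continuous EEG preprocessing
#'
#' The light preprocessing chain applied before epoching: polyphase
#' downsampling to the analysis rate, a zero-lag first-order Butterworth
#' high-pass at 1 Hz, and re-referencing to the average potential of all
#' electrodes (so the per-sample channel mean is zero).
#'
#' @param x numeric matrix `time x channel` (microvolts).
#' @param fs_in input sampling rate (Hz).
#' @param fs_out analysis rate (Hz).
#' @param hp_cutoff high-pass cut-off (Hz); `NULL` disables.
#' @param rereference average re-reference on/off.
#' @return numeric matrix `time x channel` at `fs_out`.
#' @export
preprocess_eeg <- function(x, fs_in, fs_out = 1000, hp_cutoff = 1,
                           rereference = TRUE) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 channels")
  if (fs_out > fs_in) stop("fs_out must not exceed fs_in")
  y <- resample_stream(x, fs_in, fs_out)
  if (!is.null(hp_cutoff))
    y <- butter_zero_lag(y, fs_out, hp_cutoff, order = 1, type = "high")
  if (rereference) y <- y - rowMeans(y)
  y
}

#' Epoch continuous EEG at event times
#'
#' @param x numeric matrix `time x channel`.
#' @param fs sampling rate (Hz).
#' @param events event times (s); sample 1 is `t = t0`.
#' @param window epoch window (s) relative to each event.
#' @param channels channel labels.
#' @param t0 time of the first sample (s).
#' @return an [eeg_epochs()] object; out-of-range events are dropped
#'   with a warning.
#' @export
epoch_eeg <- function(x, fs, events, window = c(-5, 15), channels = NULL,
                      t0 = 0) {
  x <- as.matrix(x)
  len <- round(diff(window) * fs) + 1
  i0 <- round((events + window[1] - t0) * fs) + 1
  keep <- i0 >= 1 & (i0 + len - 1) <= nrow(x)
  if (!all(keep)) warning(sum(!keep), " event(s) dropped (incomplete window)")
  i0 <- i0[keep]
  arr <- array(NA_real_, c(length(i0), ncol(x), len))
  for (e in seq_along(i0))
    arr[e, , ] <- t(x[i0[e]:(i0[e] + len - 1), , drop = FALSE])
  eeg_epochs(arr, fs, channels, window)
}

#' Event-related potential with peak detection
#'
#' Event-locked average over epochs per channel; the mean-subtracted
#' average is also returned for display. Use [erp_peaks()] to locate the
#' P1/N1/P2/N2 deflections.
#'
#' @param epochs an [eeg_epochs()] object with at least 2 epochs.
#' @return list with `t`, `erp` (`channel x time` matrix), `centered`,
#'   `channels`, `fs`.
#' @export
compute_erp <- function(epochs) {
  if (dim(epochs$data)[1] < 2) stop("need at least 2 epochs")
  erp <- apply(epochs$data, c(2, 3), mean)
  rownames(erp) <- epochs$channels
  list(t = epochs$t, erp = erp, centered = erp - rowMeans(erp),
       channels = epochs$channels, fs = epochs$fs)
}

#' Locate ERP component peaks
#'
#' Finds the perturbation-evoked deflections in polarity-specific search
#' windows: by default P1 as the positive maximum in [20, 90] ms, N1 the
#' negative minimum in [90, 200] ms, P2 the positive maximum in
#' [200, 400] ms and N2 the negative minimum in [400, 700] ms. A peak
#' whose amplitude does not have the requested polarity is flagged
#' absent.
#'
#' @param erp result of [compute_erp()].
#' @param channel channel label or index.
#' @param windows named list of `c(t_min, t_max)` search windows (s);
#'   names starting with `P` search for positive maxima, `N` for
#'   negative minima.
#' @param smooth_cutoff low-pass cut-off (Hz) applied to the average
#'   before peak picking (zero-lag Butterworth), the usual guard against
#'   residual-noise peak jitter; `NULL` disables.
#' @return data frame with columns `peak`, `latency` (s), `amplitude`
#'   (microvolts), `present`.
#' @export
erp_peaks <- function(erp, channel = 1,
                      windows = list(P1 = c(0.020, 0.090),
                                     N1 = c(0.090, 0.200),
                                     P2 = c(0.200, 0.400),
                                     N2 = c(0.400, 0.700)),
                      smooth_cutoff = 20) {
  if (is.character(channel)) channel <- match(channel, erp$channels)
  y <- erp$erp[channel, ]
  if (!is.null(smooth_cutoff) && smooth_cutoff < erp$fs / 2)
    y <- butter_zero_lag(y, erp$fs, smooth_cutoff, order = 4, type = "low")
  if (all(abs(y - mean(y)) < 1e-12)) {
    return(data.frame(peak = names(windows), latency = NA_real_,
                      amplitude = NA_real_, present = FALSE))
  }
  out <- lapply(names(windows), function(nm) {
    w <- windows[[nm]]
    sel <- which(erp$t >= w[1] & erp$t <= w[2])
    pos <- startsWith(nm, "P")
    i <- if (pos) sel[which.max(y[sel])] else sel[which.min(y[sel])]
    amp <- y[i]
    lat <- erp$t[i]
    # sub-sample refinement: parabola through the peak and its neighbours
    if (i > 1 && i < length(y)) {
      den <- y[i - 1] - 2 * y[i] + y[i + 1]
      if (abs(den) > .Machine$double.eps) {
        delta <- 0.5 * (y[i - 1] - y[i + 1]) / den
        if (abs(delta) <= 1) lat <- lat + delta / erp$fs
      }
    }
    data.frame(peak = nm, latency = lat, amplitude = amp,
               present = if (pos) amp > 0 else amp < 0)
  })
  do.call(rbind, out)
}

#' Morlet-wavelet time-frequency decomposition
#'
#' Complex Morlet wavelet transform of every epoch and channel on a
#' linear frequency grid (default 2-60 Hz in 0.5 Hz steps). The number
#' of cycles grows linearly with frequency from `cycles0` at the lowest
#' frequency, with slope set by `cycle_factor` (the wavelet length in
#' cycles at the highest frequency is
#' `cycles0 * ((1 - cycle_factor) + cycle_factor * f_max/f_min)`).
#' Samples closer to an epoch edge than `edge_sd` wavelet standard
#' deviations are flagged invalid in the `valid` matrix. Coefficients
#' may be decimated in time (`decim`) to bound memory.
#'
#' @param epochs an [eeg_epochs()] object.
#' @param freqs analysis frequencies (Hz), strictly increasing, below
#'   Nyquist.
#' @param n_cycles optional explicit per-frequency cycle counts
#'   (overrides `cycles0`/`cycle_factor`).
#' @param cycles0 cycles at the lowest frequency.
#' @param cycle_factor linear cycle-growth factor in (0, 1].
#' @param decim keep every `decim`-th time sample.
#' @param edge_sd edge-exclusion half-width in wavelet SDs.
#' @return an object of class `tfr_stack`: list with `coeffs` (complex
#'   array `[epoch, channel, freq, time]`), `times`, `freqs`, `valid`
#'   (`freq x time` logical), `fs`, `channels`.
#' @export
morlet_tfr <- function(epochs, freqs = seq(2, 60, by = 0.5),
                       n_cycles = NULL, cycles0 = 3, cycle_factor = 0.5,
                       decim = 1, edge_sd = 3) {
  fs <- epochs$fs
  if (any(diff(freqs) <= 0)) stop("freqs must be strictly increasing")
  if (max(freqs) > fs / 2) stop("frequencies above Nyquist requested")
  if (is.null(n_cycles)) {
    n_cycles <- cycles0 * ((1 - cycle_factor) +
                             cycle_factor * freqs / freqs[1])
  }
  d <- dim(epochs$data)
  n_ep <- d[1]; n_ch <- d[2]; n_t <- d[3]
  sigma_t <- n_cycles / (2 * pi * freqs)
  if (max(6 * sigma_t) * fs > n_t)
    stop("epoch shorter than the longest wavelet support")
  keep <- seq(1, n_t, by = decim)
  nfft <- 2^ceiling(log2(n_t + ceiling(max(6 * sigma_t) * fs)))
  # wavelet spectra (analytic: one-sided Gaussian in frequency)
  fgrid <- c(seq(0, nfft / 2), seq(-nfft / 2 + 1, -1)) * fs / nfft
  wav_f <- matrix(0, length(freqs), nfft)
  for (k in seq_along(freqs)) {
    wav_f[k, ] <- exp(-2 * pi^2 * sigma_t[k]^2 * (fgrid - freqs[k])^2)
  }
  coeffs <- array(complex(real = NA_real_), c(n_ep, n_ch, length(freqs),
                                              length(keep)))
  for (ch in seq_len(n_ch)) {
    for (e in seq_len(n_ep)) {
      xf <- stats::fft(c(epochs$data[e, ch, ], numeric(nfft - n_t)))
      for (k in seq_along(freqs)) {
        y <- stats::fft(xf * wav_f[k, ], inverse = TRUE) / nfft
        coeffs[e, ch, k, ] <- y[keep]
      }
    }
  }
  times <- epochs$t[keep]
  valid <- matrix(TRUE, length(freqs), length(keep))
  for (k in seq_along(freqs)) {
    h <- edge_sd * sigma_t[k]
    valid[k, ] <- times >= epochs$t[1] + h & times <= epochs$t[n_t] - h
  }
  structure(list(coeffs = coeffs, times = times, freqs = freqs,
                 valid = valid, fs = fs, channels = epochs$channels,
                 n_cycles = n_cycles),
            class = "tfr_stack")
}

#' @export
print.tfr_stack <- function(x, ...) {
  d <- dim(x$coeffs)
  cat(sprintf("<tfr_stack> %d epochs x %d channels x %d freqs (%g-%g Hz) x %d times\n",
              d[1], d[2], d[3], min(x$freqs), max(x$freqs), d[4]))
  invisible(x)
}

.baseline_idx <- function(tfr, baseline_window) {
  all_valid <- apply(tfr$valid, 2, all)
  idx <- which(tfr$times >= baseline_window[1] &
                 tfr$times <= baseline_window[2] & all_valid)
  # the lowest analysis frequencies carry the widest wavelet support, so
  # the usable baseline may start slightly inside the nominal window
  if (length(idx) < 2)
    stop("baseline window lies outside the epoch's edge-valid region")
  idx
}

#' Event-related spectral perturbation
#'
#' Baseline-normalized time-frequency power: per frequency, power is
#' averaged across epochs first, the baseline is the mean of that
#' average over the baseline time points, and
#' `ERSP = 10*log10(power / baseline)` (dB). By construction the
#' time-mean of the ERSP over the baseline window is close to 0 dB at
#' every frequency.
#'
#' @param tfr a `tfr_stack` from [morlet_tfr()].
#' @param baseline_window length-2 interval (s) before the event, inside
#'   the epoch and outside the edge-invalid zone.
#' @return an object of class `ersp_result`: list with `power_db`
#'   (`channel x freq x time`), `baseline_power` (`channel x freq`),
#'   `times`, `freqs`, `valid`, `channels`, `baseline_window`.
#' @export
ersp <- function(tfr, baseline_window = c(-5, -1)) {
  bidx <- .baseline_idx(tfr, baseline_window)
  p <- abs(tfr$coeffs)^2
  mean_p <- apply(p, c(2, 3, 4), mean)            # channel x freq x time
  base <- apply(mean_p[, , bidx, drop = FALSE], c(1, 2), mean)
  if (any(base <= 0)) stop("zero baseline power")
  db <- 10 * log10(sweep(mean_p, c(1, 2), base, "/"))
  structure(list(power_db = db, baseline_power = base, times = tfr$times,
                 freqs = tfr$freqs, valid = tfr$valid,
                 channels = tfr$channels, baseline_window = baseline_window),
            class = "ersp_result")
}

#' Bootstrap significance mask for ERSP
#'
#' Non-parametric baseline-resampling test: for each bootstrap
#' replicate, one baseline time point is drawn (with replacement) per
#' epoch, the surrogate "event" power is the across-epoch mean of those
#' draws, and the per-frequency null band is the two-tailed percentile
#' interval of the surrogate means. A time-frequency cell is significant
#' where the observed across-epoch mean power exits its frequency's null
#' band. Deterministic given `seed`.
#'
#' @param tfr a `tfr_stack` from [morlet_tfr()].
#' @param baseline_window baseline interval (s).
#' @param n_boot number of bootstrap replicates (>= 200).
#' @param alpha two-tailed significance level.
#' @param seed integer seed.
#' @return logical array `channel x freq x time`, `TRUE` where
#'   significant. Constant (degenerate) data yield an all-`FALSE` mask.
#' @export
bootstrap_mask <- function(tfr, baseline_window = c(-5, -1), n_boot = 500,
                           alpha = 0.05, seed = 1L) {
  if (n_boot < 200) stop("n_boot must be >= 200")
  bidx <- .baseline_idx(tfr, baseline_window)
  d <- dim(tfr$coeffs)
  n_ep <- d[1]; n_ch <- d[2]; n_f <- d[3]; n_t <- d[4]
  mask <- array(FALSE, c(n_ch, n_f, n_t))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  draws <- matrix(sample(bidx, n_boot * n_ep, replace = TRUE), n_boot, n_ep)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  for (ch in seq_len(n_ch)) {
    p <- abs(tfr$coeffs[, ch, , , drop = FALSE])^2
    dim(p) <- c(n_ep, n_f, n_t)
    obs <- apply(p, c(2, 3), mean)
    if (max(p) - min(p) < 1e-30) next      # degenerate: all non-significant
    surro <- matrix(NA_real_, n_boot, n_f)
    for (b in seq_len(n_boot)) {
      acc <- numeric(n_f)
      for (e in seq_len(n_ep)) acc <- acc + p[e, , draws[b, e]]
      surro[b, ] <- acc / n_ep
    }
    lo <- apply(surro, 2, stats::quantile, probs = alpha / 2, names = FALSE)
    hi <- apply(surro, 2, stats::quantile, probs = 1 - alpha / 2,
                names = FALSE)
    mask[ch, , ] <- obs < lo | obs > hi
  }
  mask
}

#' Apply a significance mask to an ERSP
#'
#' Masked-out (non-significant) cells are reported as 0 dB, the
#' convention used when plotting ERSP maps.
#'
#' @param ersp_result an `ersp_result`.
#' @param mask logical array from [bootstrap_mask()].
#' @return the `ersp_result` with an added `power_db_masked` array.
#' @export
apply_ersp_mask <- function(ersp_result, mask) {
  stopifnot(all(dim(mask) == dim(ersp_result$power_db)))
  ersp_result$power_db_masked <- ersp_result$power_db * mask
  ersp_result$mask <- mask
  ersp_result
}

#' Inter-trial coherence
#'
#' `ITC(f, t) = |mean over epochs of coeff/|coeff||`: the length of the
#' mean unit phase vector across epochs, in [0, 1]; 1 for perfectly
#' phase-locked activity, about `sqrt(pi)/2 * n^(-1/2)` for random
#' phases. Zero-magnitude coefficients are excluded cell-wise.
#' Significance defaults to the Rayleigh-test approximation
#' `p = exp(-n * ITC^2)`; a permutation test (circularly re-phased
#' epochs) is available behind `method = "permutation"`.
#'
#' @param tfr a `tfr_stack` from [morlet_tfr()].
#' @param method `"rayleigh"` or `"permutation"`.
#' @param alpha significance level.
#' @param n_perm permutation count (permutation method only).
#' @param seed seed for the permutation method.
#' @return list with `itc` (`channel x freq x time`), `p`, `sig`
#'   (logical), `n_epochs`.
#' @export
itc <- function(tfr, method = c("rayleigh", "permutation"), alpha = 0.05,
                n_perm = 200, seed = 1L) {
  method <- match.arg(method)
  if (dim(tfr$coeffs)[1] < 2) stop("need at least 2 epochs")
  mag <- abs(tfr$coeffs)
  unit <- tfr$coeffs / ifelse(mag > 0, mag, 1)
  unit[mag == 0] <- 0                 # excluded epochs contribute nothing
  n_eff <- apply(mag > 0, c(2, 3, 4), sum)
  itc_v <- abs(apply(unit, c(2, 3, 4), sum)) / pmax(n_eff, 1)
  if (method == "rayleigh") {
    p <- exp(-pmax(n_eff, 1) * itc_v^2)
  } else {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    d <- dim(tfr$coeffs)
    exceed <- array(0L, d[2:4])
    for (b in seq_len(n_perm)) {
      ph <- stats::runif(d[1], 0, 2 * pi)
      rot <- unit * array(rep(exp(1i * ph), prod(d[2:4])), d)
      itc_b <- abs(apply(rot, c(2, 3, 4), sum)) / pmax(n_eff, 1)
      exceed <- exceed + (itc_b >= itc_v)
    }
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    p <- (exceed + 1) / (n_perm + 1)
  }
  list(itc = itc_v, p = p, sig = p < alpha, n_epochs = dim(tfr$coeffs)[1])
}

.band_rows <- function(freqs, band) {
  rows <- which(freqs >= band[1] & freqs <= band[2])
  if (length(rows) == 0)
    stop(sprintf("band [%g, %g] Hz has no frequencies on the grid", band[1],
                 band[2]))
  rows
}

#' Band-averaged ERSP time courses
#'
#' Mean ERSP (dB) over each band's frequency rows, per time point.
#'
#' @param ersp_result an `ersp_result`.
#' @param bands a [band_set()] (or named list of intervals).
#' @param channel channel label or index.
#' @return data frame with columns `band`, `t`, `db`.
#' @export
band_timecourse <- function(ersp_result, bands = band_set(), channel = 1) {
  if (is.character(channel)) channel <- match(channel, ersp_result$channels)
  out <- lapply(names(bands), function(nm) {
    rows <- .band_rows(ersp_result$freqs, bands[[nm]])
    m <- ersp_result$power_db[channel, rows, , drop = FALSE]
    dim(m) <- dim(m)[2:3]
    data.frame(band = nm, t = ersp_result$times, db = colMeans(m))
  })
  do.call(rbind, out)
}

#' Peak latency of a band time course
#'
#' Signed peak within a query window: the maximum for ERS
#' (`sign = "ers"`), the minimum for ERD (`sign = "erd"`).
#'
#' @param band_tc data frame from [band_timecourse()].
#' @param band band name.
#' @param window query window (s).
#' @param sign `"ers"` or `"erd"`.
#' @return list with `latency` (s) and `db`.
#' @export
band_peak_latency <- function(band_tc, band, window = c(0, 15),
                              sign = c("ers", "erd")) {
  sign <- match.arg(sign)
  d <- band_tc[band_tc$band == band & band_tc$t >= window[1] &
                 band_tc$t <= window[2], ]
  if (nrow(d) == 0) stop("empty band/window selection")
  i <- if (sign == "ers") which.max(d$db) else which.min(d$db)
  list(latency = d$t[i], db = d$db[i])
}

#' Onset of a sustained band-limited ERS (or ERD)
#'
#' The earliest time at or after `t_min` at which the band-aggregated
#' significance holds continuously for at least `min_duration`. A time
#' point counts as "on" when at least `frac` of the band's frequency
#' bins are simultaneously significant with the requested sign of the
#' ERSP.
#'
#' @param ersp_result an `ersp_result`.
#' @param mask logical array from [bootstrap_mask()].
#' @param band length-2 frequency interval (Hz).
#' @param channel channel label or index.
#' @param t_min earliest admissible onset (s).
#' @param min_duration minimum sustained duration (s).
#' @param sign `"ers"` (positive dB) or `"erd"` (negative dB).
#' @param frac minimum fraction of band bins significant.
#' @return onset time (s), or `NA` if no sustained run exists.
#' @export
ers_onset <- function(ersp_result, mask, band, channel = 1, t_min = 0,
                      min_duration = 0.2, sign = c("ers", "erd"),
                      frac = 0.5) {
  sign <- match.arg(sign)
  if (is.character(channel)) channel <- match(channel, ersp_result$channels)
  rows <- .band_rows(ersp_result$freqs, band)
  db <- ersp_result$power_db[channel, rows, , drop = FALSE]
  mk <- mask[channel, rows, , drop = FALSE]
  good <- if (sign == "ers") mk & db > 0 else mk & db < 0
  dim(good) <- dim(good)[2:3]
  on <- colMeans(good) >= frac
  tt <- ersp_result$times
  dt <- stats::median(diff(tt))
  need <- max(1L, ceiling(min_duration / dt))
  cand <- which(on & tt >= t_min)
  for (i in cand) {
    if (i + need - 1 <= length(on) && all(on[i:(i + need - 1)]))
      return(tt[i])
  }
  NA_real_
}

#' Compare pre-perturbation baseline spectra with quiet stance
#'
#' Per-frequency-bin paired Wilcoxon signed-rank tests between the
#' perturbed-condition baseline powers and the quiet-stance powers
#' across participants, with Benjamini-Hochberg false-discovery-rate
#' correction across bins. Bins with all-tied pairs are flagged and
#' excluded from the adjustment.
#'
#' @param perturbed_baseline,quiet numeric matrices
#'   `participant x frequency bin` (paired rows), n >= 5 participants.
#' @param freqs optional bin frequencies (Hz).
#' @param alpha FDR level.
#' @return data frame with columns `freq`, `p`, `p_adj`, `significant`,
#'   `tied`.
#' @export
baseline_vs_quiet <- function(perturbed_baseline, quiet, freqs = NULL,
                              alpha = 0.05) {
  stopifnot(all(dim(perturbed_baseline) == dim(quiet)))
  if (nrow(perturbed_baseline) < 5) stop("need at least 5 paired participants")
  n_bin <- ncol(perturbed_baseline)
  if (is.null(freqs)) freqs <- seq_len(n_bin)
  p <- rep(NA_real_, n_bin)
  tied <- logical(n_bin)
  for (j in seq_len(n_bin)) {
    d <- perturbed_baseline[, j] - quiet[, j]
    if (all(d == 0)) { tied[j] <- TRUE; next }
    p[j] <- suppressWarnings(
      stats::wilcox.test(perturbed_baseline[, j], quiet[, j],
                         paired = TRUE, exact = FALSE)$p.value)
  }
  p_adj <- rep(NA_real_, n_bin)
  p_adj[!tied] <- stats::p.adjust(p[!tied], method = "BH")
  data.frame(freq = freqs, p = p, p_adj = p_adj,
             significant = !is.na(p_adj) & p_adj < alpha, tied = tied)
}
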