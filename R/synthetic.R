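#' Spectral-synthesis sway noise
#'
#' Generates a 1-D series with power spectral density proportional to
#' `f^-beta` by shaping white Gaussian noise in the frequency domain,
#' used as a fixture for validating the stabilogram slope estimators.
#'
#' @param beta spectral exponent (>= 0; 0 is white noise).
#' @param duration series duration (s).
#' @param fs sampling rate (Hz).
#' @param seed integer seed; identical seeds give identical series.
#' @return numeric vector of `duration * fs` samples, unit variance.
#' @export
synth_sway <- function(beta, duration, fs, seed = 1L) {
  if (beta < 0) stop("beta must be >= 0")
  n <- round(duration * fs)
  set.seed(seed)
  # Hermitian spectrum of white noise, shaped by f^(-beta/2)
  nf <- n %/% 2
  f <- seq_len(nf) * fs / n
  amp <- f^(-beta / 2)
  z <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) * amp
  spec <- complex(real = numeric(n))
  spec[2:(nf + 1)] <- z
  spec[seq(n, n - nf + 2)] <- Conj(z[seq_len(nf - 1)])
  if (n %% 2 == 0) spec[nf + 1] <- complex(real = Re(z[nf]) * sqrt(2))
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  as.numeric(scale(x))
}

#' Default planted ERP components
#'
#' Gaussian-windowed deflections emulating the perturbation-evoked
#' P1/N1/P2/N2 sequence, with latencies and amplitudes matching the
#' group means reported for perturbed stance (P1 41 ms / +5.1 uV, N1
#' 116 ms / -17.2 uV, P2 264 ms / +8.5 uV; N2 is placed at 450 ms with
#' a representative negative amplitude).
#'
#' @return data frame with columns `label`, `latency` (s), `amplitude`
#'   (microvolts), `width` (s, Gaussian SD).
#' @export
default_erp_components <- function() {
  data.frame(label = c("P1", "N1", "P2", "N2"),
             latency = c(0.041, 0.116, 0.264, 0.450),
             amplitude = c(5.1, -17.2, 8.5, -6.0),
             width = c(0.012, 0.020, 0.030, 0.050))
}

#' Default planted band modulations
#'
#' Non-phase-locked band-limited power modulations emulating the
#' perturbation response: a high-beta ERD peaking at 0.45 s, a
#' long-lasting high-beta ERS (beta rebound) over 1-4 s peaking at
#' 3.27 s, and a theta ERD over 1-4 s.
#'
#' @return data frame with columns `label`, `f_lo`, `f_hi` (Hz),
#'   `t_start`, `t_peak`, `t_end` (s), `gain_db` (peak power change in
#'   dB re baseline).
#' @export
default_band_modulations <- function() {
  data.frame(label = c("high_beta_erd", "high_beta_ers", "theta_erd"),
             f_lo = c(21, 21, 4), f_hi = c(30, 30, 7),
             t_start = c(0.25, 1.0, 1.0),
             t_peak = c(0.45, 3.27, 1.88),
             t_end = c(0.80, 4.0, 4.0),
             gain_db = c(-8, 8, -8))
}

# amplitude gain profile of a band modulation: raised-cosine edge ramps
# (spectral-splatter control) around a tilted plateau whose unique
# maximum-magnitude point is t_peak
.gain_profile <- function(t, t_start, t_peak, t_end, gain_db,
                          ramp = 0.1) {
  a_max <- 10^(gain_db / 20)
  shape <- numeric(length(t))
  up <- t >= t_start & t <= t_peak
  dn <- t > t_peak & t <= t_end
  shape[up] <- 0.6 + 0.4 * (t[up] - t_start) / max(t_peak - t_start, 1e-9)
  shape[dn] <- 0.6 + 0.4 * (t_end - t[dn]) / max(t_end - t_peak, 1e-9)
  edge <- rep(1, length(t))
  lo <- t >= t_start & t < t_start + ramp
  hi <- t > t_end - ramp & t <= t_end
  edge[lo] <- 0.5 - 0.5 * cos(pi * (t[lo] - t_start) / ramp)
  edge[hi] <- 0.5 - 0.5 * cos(pi * (t_end - t[hi]) / ramp)
  w <- shape * edge
  1 + (a_max - 1) * w
}

# band-pass an epoch via an FFT mask with raised-cosine spectral edges
.fft_bandpass <- function(x, fs, f_lo, f_hi, edge = 1) {
  n <- length(x)
  f <- abs(c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1))) * fs / n
  h <- numeric(n)
  h[f >= f_lo & f <= f_hi] <- 1
  lo <- f >= f_lo - edge & f < f_lo
  hi <- f > f_hi & f <= f_hi + edge
  h[lo] <- 0.5 - 0.5 * cos(pi * (f[lo] - (f_lo - edge)) / edge)
  h[hi] <- 0.5 + 0.5 * cos(pi * (f[hi] - f_hi) / edge)
  Re(stats::fft(stats::fft(x) * h, inverse = TRUE)) / n
}

#' Synthetic EEG epochs with planted ground truth
#'
#' Generates event-locked EEG epochs as 1/f background noise plus (i)
#' phase-locked ERP templates (identical Gaussian-windowed deflections
#' added to every epoch) and (ii) non-phase-locked band-limited power
#' modulations (the band component of the background is multiplied by a
#' smooth gain envelope, different noise per epoch). Inter-trial
#' coherence therefore separates the two classes exactly as intended:
#' the ERP is phase-locked, the ERD/ERS are not. Modulations and ERPs
#' are spatially weighted toward the first (designated "Cz") channel.
#'
#' @param n_epochs number of epochs.
#' @param fs sampling rate (Hz).
#' @param channels channel labels; the first carries full effect weight.
#' @param window epoch window (s) relative to the event.
#' @param erp_components data frame as [default_erp_components()]; use a
#'   zero-row or zero-amplitude frame for no ERP.
#' @param band_modulations data frame as [default_band_modulations()];
#'   zero rows (or `gain_db = 0`) for the null generator.
#' @param background_exponent spectral exponent of the 1/f background.
#' @param background_rms background RMS amplitude (microvolts).
#' @param focal_weight effect weight of non-focal channels (the focal
#'   channel has weight 1).
#' @param seed integer seed.
#' @return list with `epochs` (an [eeg_epochs()]) and `ground_truth`
#'   (planted parameters plus the seed; regeneration from the same
#'   configuration and seed is bit-identical).
#' @export
synth_eeg <- function(n_epochs = 40, fs = 250, channels = c("Cz", "C3", "C4"),
                      window = c(-5, 15),
                      erp_components = default_erp_components(),
                      band_modulations = default_band_modulations(),
                      background_exponent = 1, background_rms = 6,
                      focal_weight = 0.4, seed = 1L) {
  if (nrow(band_modulations) &&
      any(band_modulations$f_hi > fs / 2))
    stop("band modulation outside Nyquist range")
  n_ch <- length(channels)
  n_t <- round(diff(window) * fs) + 1
  t <- seq(window[1], window[2], length.out = n_t)
  erp <- numeric(n_t)
  if (nrow(erp_components)) {
    for (i in seq_len(nrow(erp_components))) {
      cm <- erp_components[i, ]
      erp <- erp + cm$amplitude * exp(-(t - cm$latency)^2 / (2 * cm$width^2))
    }
  }
  gains <- lapply(seq_len(nrow(band_modulations)), function(i) {
    bm <- band_modulations[i, ]
    .gain_profile(t, bm$t_start, bm$t_peak, bm$t_end, bm$gain_db)
  })
  w_ch <- c(1, rep(focal_weight, n_ch - 1))
  set.seed(seed)
  arr <- array(NA_real_, c(n_epochs, n_ch, n_t))
  for (e in seq_len(n_epochs)) {
    for (ch in seq_len(n_ch)) {
      bg <- synth_sway(background_exponent, diff(window) + 1 / fs, fs,
                       seed = stats::runif(1, 1, 2^30)) # per-epoch sub-seed
      bg <- bg[seq_len(n_t)] * background_rms
      x <- bg
      for (k in seq_along(gains)) {
        bm <- band_modulations[k, ]
        comp <- .fft_bandpass(bg, fs, bm$f_lo, bm$f_hi)
        x <- x + w_ch[ch] * (gains[[k]] - 1) * comp
      }
      arr[e, ch, ] <- x + w_ch[ch] * erp
    }
  }
  gt <- list(erp_components = erp_components,
             band_modulations = band_modulations,
             background_exponent = background_exponent,
             background_rms = background_rms,
             focal_weight = focal_weight, fs = fs, window = window,
             n_epochs = n_epochs, seed = as.integer(seed))
  list(epochs = eeg_epochs(arr, fs, channels, window), ground_truth = gt)
}

#' Synthetic perturbed-stance trial with ground truth
#'
#' Generates a complete multi-rate trial recording from one noisy run of
#' the stance model with repeated support-surface perturbations:
#' motion-capture markers by forward kinematics plus Gaussian jitter
#' (ankle markers ride on the belt), force-plate CoP/GRF from the model
#' CoP plus noise in the global (belt-shifted) frame, and surface EMG as
#' noise-carrier bursts whose envelopes peak about 150 ms (soleus and
#' medial gastrocnemius) and 200 ms (tibialis anterior) after each
#' perturbation onset, over a tonic background.
#'
#' @param n_events number of perturbations.
#' @param interval inter-perturbation interval (s); must exceed the
#'   epoch window span of downstream analyses.
#' @param body,passive,intermittent,reflex,perturbation,noise model
#'   parameter objects (see [simulate_stance()]); `noise` defaults to
#'   [noise_params()] with a seed derived from `seed`.
#' @param dt simulation step (s).
#' @param settle settling time simulated before the first event (s).
#' @param tail recording time after the last event (s).
#' @param fs_markers,fs_forceplate,fs_emg stream sampling rates (Hz).
#' @param marker_jitter_sd marker noise SD (m).
#' @param cop_noise_sd,grf_noise_sd force-plate noise SDs (m, N).
#' @param emg_burst_amp burst amplitude relative to the unit tonic
#'   background.
#' @param seed integer seed controlling all streams.
#' @return an object of class `trial_recording`: list with `markers`
#'   (list of n x 3 `(ap, ml, vert)` matrices at `fs_markers`), `grf`
#'   (data frame `t`, `fx`, `fy`, `cop` at `fs_forceplate`, global
#'   frame), `emg` (data frame at `fs_emg` with columns `so_l` ...
#'   `ta_r`), `events` (onset times, s), `belt` (data frame), `sim`
#'   (the `sim_trajectory`), `fs` (named rates) and `ground_truth`
#'   (planted EMG latencies, jitter levels, seed).
#' @export
synth_trial <- function(n_events = 20, interval = 20,
                        body = body_params(),
                        passive = passive_params(body),
                        intermittent = intermittent_params(body),
                        reflex = reflex_params(),
                        perturbation = perturbation_profile(),
                        noise = NULL, dt = 1e-3, settle = 30, tail = 17,
                        fs_markers = 300, fs_forceplate = 1200,
                        fs_emg = 1000, marker_jitter_sd = 5e-4,
                        cop_noise_sd = 5e-4, grf_noise_sd = 2,
                        emg_burst_amp = 8, seed = 1L) {
  if (interval <= 0 || n_events < 1) stop("invalid event configuration")
  events <- interval * (seq_len(n_events) - 1)
  if (is.null(noise)) noise <- noise_params(seed = seed + 1000L)
  t_end <- events[n_events] + tail
  traj <- simulate_stance(body, passive, intermittent, reflex, perturbation,
                          noise, dt = dt, t_start = -settle, t_end = t_end,
                          perturbation_time = events)
  if (attr(traj, "fallen")) stop("model fell during trial generation")
  fs_sim <- 1 / dt
  set.seed(seed)
  belt <- belt_kinematics(perturbation, traj$t, events)

  # markers at fs_markers (global frame: ankle rides on the belt)
  t_m <- seq(traj$t[1], traj$t[nrow(traj)], by = 1 / fs_markers)
  th_a <- stats::approx(traj$t, traj$theta_a, t_m)$y
  th_h <- stats::approx(traj$t, traj$theta_h, t_m)$y
  bx <- stats::approx(traj$t, belt$disp, t_m)$y
  ankle <- cbind(ap = bx, vert = 0)
  troch <- cbind(ap = bx + body$l_le * sin(th_a),
                 vert = body$l_le * cos(th_a))
  acrom <- cbind(ap = troch[, 1] + body$l_hat * sin(th_a + th_h),
                 vert = troch[, 2] + body$l_hat * cos(th_a + th_h))
  jit <- function(m) {
    n <- nrow(m)
    cbind(ap = m[, 1] + stats::rnorm(n, 0, marker_jitter_sd),
          ml = stats::rnorm(n, 0, marker_jitter_sd),
          vert = m[, 2] + stats::rnorm(n, 0, marker_jitter_sd))
  }
  markers <- list(ankle_l = jit(ankle), ankle_r = jit(ankle),
                  trochanter_l = jit(troch), trochanter_r = jit(troch),
                  acromion_l = jit(acrom), acromion_r = jit(acrom),
                  t = t_m, fs = fs_markers)

  # force plate at fs_forceplate (global CoP = belt-relative model CoP +
  # belt displacement)
  t_fp <- seq(traj$t[1], traj$t[nrow(traj)], by = 1 / fs_forceplate)
  cop_rel <- stats::approx(traj$t, traj$cop_x, t_fp)$y
  belt_fp <- stats::approx(traj$t, belt$disp, t_fp)$y
  m_tot <- body$m_foot + body$m_le + body$m_hat
  grf <- data.frame(t = t_fp,
                    fx = stats::rnorm(length(t_fp), 0, grf_noise_sd),
                    fy = m_tot * body$g +
                      stats::rnorm(length(t_fp), 0, grf_noise_sd),
                    cop = cop_rel + belt_fp +
                      stats::rnorm(length(t_fp), 0, cop_noise_sd))

  # EMG at fs_emg: tonic unit-variance carrier plus event-locked bursts
  t_emg <- seq(traj$t[1], traj$t[nrow(traj)], by = 1 / fs_emg)
  lat <- c(so = 0.15, mg = 0.15, ta = 0.20)
  burst_sd <- 0.04
  emg <- list(t = t_emg)
  gt_emg <- data.frame(muscle = names(lat), peak_latency = as.numeric(lat),
                       width = burst_sd, rel_amplitude = emg_burst_amp)
  for (mu in names(lat)) {
    envl <- rep(1, length(t_emg))
    for (ev in events) {
      envl <- envl + emg_burst_amp *
        exp(-(t_emg - ev - lat[[mu]])^2 / (2 * burst_sd^2))
    }
    for (side in c("l", "r"))
      emg[[paste0(mu, "_", side)]] <- stats::rnorm(length(t_emg)) * envl
  }
  structure(list(markers = markers, grf = grf, emg = as.data.frame(emg),
                 events = events, belt = belt, sim = traj,
                 fs = c(markers = markers$fs, forceplate = fs_forceplate,
                        emg = fs_emg, sim = fs_sim),
                 ground_truth = list(emg_bursts = gt_emg,
                                     marker_jitter_sd = marker_jitter_sd,
                                     cop_noise_sd = cop_noise_sd,
                                     seed = as.integer(seed),
                                     noise = noise)),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> %d perturbation events, %.0f s of data\n",
              length(x$events), diff(range(x$grf$t))))
  cat(sprintf("  streams: markers @ %g Hz, force plate @ %g Hz, EMG @ %g Hz\n",
              x$fs[["markers"]], x$fs[["forceplate"]], x$fs[["emg"]]))
  invisible(x)
}
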