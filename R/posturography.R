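#' Joint angles from motion-capture markers
#'
#' Estimates the ankle and hip joint angles of the sagittal double
#' inverted pendulum from ankle, greater-trochanter and acromion markers.
#' Left/right marker pairs are projected onto the sagittal plane
#' (anterior-posterior and vertical coordinates) and averaged; the ankle
#' angle is the forward tilt of the ankle-trochanter segment from
#' vertical, the hip angle the rotation of the trochanter-acromion
#' segment relative to it.
#'
#' @param markers named list of marker position matrices `ankle_l`,
#'   `ankle_r`, `trochanter_l`, `trochanter_r`, `acromion_l`,
#'   `acromion_r`, each n x 3 with columns `(ap, ml, vert)` in m (an
#'   n x 2 matrix `(ap, vert)` is also accepted).
#' @param convention `"forward"` (default): forward rotation positive for
#'   both joints, the convention of the simulation model; or
#'   `"anatomical"`: plantar flexion positive at the ankle and extension
#'   positive at the hip (both signs flipped).
#' @return data frame with columns `theta_a`, `theta_h` (rad).
#' @export
joint_angles_from_markers <- function(markers,
                                      convention = c("forward", "anatomical")) {
  convention <- match.arg(convention)
  need <- c("ankle_l", "ankle_r", "trochanter_l", "trochanter_r",
            "acromion_l", "acromion_r")
  missing <- setdiff(need, names(markers))
  if (length(missing))
    stop("missing marker stream(s): ", paste(missing, collapse = ", "))
  sagittal <- function(m) {
    m <- as.matrix(m)
    if (ncol(m) == 3) m[, c(1, 3), drop = FALSE] else m[, 1:2, drop = FALSE]
  }
  avg <- function(a, b) (sagittal(markers[[a]]) + sagittal(markers[[b]])) / 2
  ank <- avg("ankle_l", "ankle_r")
  tro <- avg("trochanter_l", "trochanter_r")
  acr <- avg("acromion_l", "acromion_r")
  theta_a <- atan2(tro[, 1] - ank[, 1], tro[, 2] - ank[, 2])
  phi2 <- atan2(acr[, 1] - tro[, 1], acr[, 2] - tro[, 2])
  theta_h <- phi2 - theta_a
  if (convention == "anatomical") {
    theta_a <- -theta_a
    theta_h <- -theta_h
  }
  data.frame(theta_a = theta_a, theta_h = theta_h)
}

#' CoM position and velocity from joint angles
#'
#' Mass-weighted combination of the LE and HAT link CoMs (HAT:LE mass
#' ratio 0.62:0.35 of the total body mass by default, link CoM at
#' mid-link), low-pass filtered with a zero-lag 4th-order Butterworth at
#' 10 Hz, with velocity by central differences of the filtered series.
#'
#' @param theta data frame or matrix with columns `theta_a`, `theta_h`
#'   (rad), forward-positive convention.
#' @param fs sampling rate (Hz).
#' @param body a [body_params()] object carrying the segment geometry and
#'   masses.
#' @param cutoff low-pass cut-off (Hz); `NULL` disables filtering.
#' @return data frame with columns `x_com` (m) and `v_com` (m/s).
#' @export
estimate_com <- function(theta, fs, body = body_params(), cutoff = 10) {
  theta <- as.matrix(as.data.frame(theta)[, c("theta_a", "theta_h")])
  x <- com_kinematics(theta, body)$x_com
  if (!is.null(cutoff)) x <- butter_zero_lag(x, fs, cutoff, order = 4, "low")
  data.frame(x_com = x, v_com = as.numeric(central_diff(x, fs = fs)))
}

#' Belt-relative CoP with filtering and velocity
#'
#' Subtracts the ankle position (which moves with the support-surface
#' belt) from the measured global CoP so the series expresses the actual
#' postural response, then applies the standard zero-lag 4th-order 10 Hz
#' Butterworth low-pass and central-difference velocity. Both inputs must
#' share a common time base (resample first, see [resample_stream()]).
#'
#' @param cop_global measured CoP series (m).
#' @param ankle_position ankle AP position series (m), same length.
#' @param fs sampling rate (Hz).
#' @param cutoff low-pass cut-off (Hz); `NULL` disables filtering.
#' @return data frame with columns `cop` (m) and `v_cop` (m/s).
#' @export
cop_relative <- function(cop_global, ankle_position, fs, cutoff = 10) {
  if (length(cop_global) != length(ankle_position))
    stop("cop_global and ankle_position must share a common time base")
  x <- cop_global - ankle_position
  if (!is.null(cutoff)) x <- butter_zero_lag(x, fs, cutoff, order = 4, "low")
  data.frame(cop = x, v_cop = as.numeric(central_diff(x, fs = fs)))
}

#' Quiet-stance sway metrics
#'
#' Standard deviation of the CoP per axis and the two-regime log-log
#' spectral slopes of the AP stabilogram: a Welch PSD (Hann window, 50%
#' overlap, segment length at least 100 s for the low regime) is fitted
#' by ordinary least squares on log10-log10 points within the low
#' (0.02-0.2 Hz) and high (1-8 Hz) frequency regimes. The low-regime
#' slope is the negated f^-beta scaling exponent (beta about 1.5 is the
#' intermittent-control hallmark).
#'
#' @param cop_ap AP CoP series (m or mm).
#' @param fs sampling rate (Hz).
#' @param cop_ml optional ML CoP series for `sd_ml`.
#' @param low_band,high_band frequency regimes (Hz).
#' @param min_low_duration minimum series duration (s) required to fit
#'   the low regime; shorter series get `slope_low = NA` with a warning.
#' @return list with `sd_ap`, `sd_ml`, `slope_low`, `slope_high` and the
#'   `psd` data frame. SDs are in the unit of the input series.
#' @export
sway_metrics <- function(cop_ap, fs, cop_ml = NULL,
                         low_band = c(0.02, 0.2), high_band = c(1, 8),
                         min_low_duration = 400) {
  dur <- length(cop_ap) / fs
  seg <- min(length(cop_ap), max(2^ceiling(log2(100 * fs)), 256))
  psd <- welch_psd(cop_ap, fs, seg_len = seg)
  slope_low <- if (dur >= min_low_duration) {
    loglog_slope(psd, low_band)
  } else {
    warning("series shorter than ", min_low_duration,
            " s; low-regime slope omitted")
    NA_real_
  }
  slope_high <- loglog_slope(psd, high_band)
  list(sd_ap = stats::sd(cop_ap),
       sd_ml = if (is.null(cop_ml)) NA_real_ else stats::sd(cop_ml),
       slope_low = slope_low, slope_high = slope_high, psd = psd)
}

#' Event-locked epoch extraction and averaging
#'
#' Segments a series into event-locked epochs over `window` (seconds
#' relative to each event) and returns the per-epoch stack and the
#' arithmetic mean epoch; the averaged profile is also returned
#' mean-subtracted for display. Events whose window falls outside the
#' recording are dropped with a warning.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param events event times (s) on the same clock as `x` (sample 1 is
#'   `t = t0`).
#' @param window length-2 window in s relative to each event.
#' @param t0 time of the first sample (s).
#' @return list with `t` (epoch time axis), `epochs` (epoch x time
#'   matrix), `mean` and `mean_centered`.
#' @export
event_locked_average <- function(x, fs, events, window = c(-5, 15), t0 = 0) {
  n <- length(x)
  i0 <- round((events + window[1] - t0) * fs) + 1
  i1 <- i0 + round(diff(window) * fs)
  keep <- i0 >= 1 & i1 <= n
  if (!all(keep))
    warning(sum(!keep), " event(s) with out-of-range windows dropped")
  if (!any(keep)) stop("no events with complete windows")
  idx0 <- i0[keep]
  len <- round(diff(window) * fs) + 1
  ep <- t(vapply(idx0, function(i) x[i:(i + len - 1)], numeric(len)))
  m <- colMeans(ep)
  list(t = seq(window[1], window[2], length.out = len),
       epochs = ep, mean = m, mean_centered = m - mean(m))
}

#' EMG envelope processing
#'
#' The standard surface-EMG chain: zero-lag 4th-order Butterworth
#' band-pass 20-450 Hz, full-wave rectification, zero-lag 2nd-order
#' 15 Hz low-pass, left/right averaging, event-locked averaging, and
#' normalization of the averaged envelope by its maximum (peak = 1); the
#' peak latency relative to the event is returned.
#'
#' @param emg_l,emg_r raw EMG series (microvolts); `emg_r = NULL` for a
#'   single channel.
#' @param fs sampling rate (Hz), at least 1000 for the standard band.
#' @param events optional event times (s) for event-locked averaging.
#' @param window epoch window (s) relative to each event.
#' @param band band-pass corner frequencies (Hz).
#' @param envelope_cutoff low-pass cut-off of the rectified signal (Hz).
#' @param t0 time of the first sample (s).
#' @return list with `envelope` (full-length processed envelope); and,
#'   when `events` are given, `t`, `mean` (normalized averaged
#'   envelope), `peak_latency` (s) and `peak_value` (pre-normalization
#'   units). If the averaged envelope is all zero, normalization is
#'   skipped and `normalized = FALSE` is flagged.
#' @export
process_emg <- function(emg_l, emg_r = NULL, fs, events = NULL,
                        window = c(-5, 15), band = c(20, 450),
                        envelope_cutoff = 15, t0 = 0) {
  if (fs < 2 * band[2]) stop("sampling rate too low for the band-pass")
  env1 <- function(x) {
    x <- butter_zero_lag(x, fs, band, order = 4, type = "pass")
    butter_zero_lag(abs(x), fs, envelope_cutoff, order = 2, type = "low")
  }
  env <- env1(emg_l)
  if (!is.null(emg_r)) env <- (env + env1(emg_r)) / 2
  out <- list(envelope = env)
  if (!is.null(events)) {
    ela <- event_locked_average(env, fs, events, window, t0 = t0)
    pk <- max(ela$mean)
    if (pk <= 0) {
      warning("all-zero envelope; normalization skipped")
      out <- c(out, list(t = ela$t, mean = ela$mean, normalized = FALSE,
                         peak_latency = NA_real_, peak_value = pk))
    } else {
      post <- ela$t >= 0
      out <- c(out, list(t = ela$t, mean = ela$mean / pk, normalized = TRUE,
                         peak_latency = ela$t[post][which.max(ela$mean[post])],
                         peak_value = pk))
    }
  }
  out
}

#' Inverse dynamics of perturbed stance
#'
#' Recovers the ankle and hip joint torques (the sum of passive, active
#' and reflexive components) from the joint-angle kinematics and the
#' support-surface acceleration, by inverting the same rigid-body
#' equations of motion used by the forward model in the accelerating
#' support frame: `tau = M(theta) acc + C + G - T_pert(alpha)`. With the
#' foot fixed to the support surface the chain torques follow from the
#' kinematics and the belt acceleration alone; optional GRF/CoP inputs
#' are used only for a quasi-static consistency diagnostic
#' (`cop_residual`), not for the solution. Angles are low-pass filtered
#' (zero-lag 4th-order Butterworth) before double central differencing.
#'
#' @param theta data frame or matrix with columns `theta_a`, `theta_h`
#'   (rad), forward-positive convention.
#' @param fs sampling rate (Hz).
#' @param belt_acc support-surface acceleration series (m/s^2), same
#'   length (scalar 0 for quiet stance).
#' @param body a [body_params()] object.
#' @param cutoff angle low-pass cut-off (Hz); `NULL` disables filtering
#'   (appropriate for noise-free simulated kinematics).
#' @param grf,cop optional vertical GRF (N) and belt-relative CoP (m)
#'   series for the consistency diagnostic.
#' @return data frame with columns `tau_a`, `tau_h` (N m), `transition`
#'   (`TRUE` for samples inside the finite-difference support of a
#'   support-acceleration discontinuity, where instantaneous torque
#'   steps cannot be resolved by differentiation) and, when `grf`/`cop`
#'   are supplied, `cop_residual` (m).
#' @export
inverse_dynamics <- function(theta, fs, belt_acc = 0, body = body_params(),
                             cutoff = 10, grf = NULL, cop = NULL) {
  theta <- as.matrix(as.data.frame(theta)[, c("theta_a", "theta_h")])
  n <- nrow(theta)
  if (length(belt_acc) == 1) belt_acc <- rep(belt_acc, n)
  if (!is.null(cutoff)) theta <- butter_zero_lag(theta, fs, cutoff, 4, "low")
  jump <- which(diff(belt_acc) != 0)
  transition <- rep(FALSE, n)
  for (j in jump) transition[max(1, j - 2):min(n, j + 3)] <- TRUE
  transition[c(1, 2, n - 1, n)] <- TRUE      # one-sided-difference endpoints
  om <- apply(theta, 2, central_diff, fs = fs)
  ac <- apply(om, 2, central_diff, fs = fs)
  tau <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    d <- derive_dynamics_terms(theta[i, ], om[i, ], body)
    tau[i, ] <- d$inertia %*% ac[i, ] + d$coriolis + d$gravity -
      perturbation_torque(theta[i, ], body, belt_acc[i])
  }
  out <- data.frame(tau_a = tau[, 1], tau_h = tau[, 2],
                    transition = transition)
  if (!is.null(grf) && !is.null(cop)) {
    m_tot <- body$m_foot + body$m_le + body$m_hat
    out$cop_residual <- cop - (-out$tau_a / (m_tot * body$g))
  }
  out
}
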