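#' Delay-free linearization of the control-OFF dynamics
#'
#' Linearizes the control-OFF stance dynamics about the upright
#' equilibrium, reduced to the single-link-equivalent CoM tilt
#' coordinate: `I_eq * acc = (K_load - k_a) * theta - b_a * omega`, with
#' `K_load` the gravitational load stiffness and `I_eq` the whole-body
#' moment of inertia about the ankle. When the passive ankle stiffness is
#' below the load stiffness the equilibrium is a saddle: one positive and
#' one negative eigenvalue, whose eigendirections are the unstable and
#' stable manifolds of the OFF dynamics.
#'
#' @param body a [body_params()] object.
#' @param passive a [passive_params()] object.
#' @return an object of class `saddle_analysis`: list with `jacobian`
#'   (2x2), `eigenvalues` (sorted decreasing), `stable_dir` and
#'   `unstable_dir` (unit vectors in the `(theta, omega)` plane;
#'   `stable_dir` has negative slope for the saddle case), `load_stiffness`
#'   and `inertia`.
#' @export
linearize_off <- function(body, passive) {
  k_load <- load_stiffness(body)
  i_eq <- ankle_inertia(body)
  jac <- matrix(c(0, (k_load - passive$k_a) / i_eq,
                  1, -passive$b_a / i_eq), 2, 2)
  e <- eigen(jac)
  if (any(abs(Im(e$values)) > 1e-12)) {
    # complex pair (heavily overdamped/stiff cases do not reach here)
    ord <- order(Re(e$values), decreasing = TRUE)
    vals <- e$values[ord]
    vecs <- e$vectors[, ord, drop = FALSE]
    stable_dir <- unstable_dir <- NULL
  } else {
    ord <- order(Re(e$values), decreasing = TRUE)
    vals <- Re(e$values[ord])
    vecs <- Re(e$vectors[, ord, drop = FALSE])
    norm1 <- function(v) {
      v <- v / sqrt(sum(v^2))
      if (v[1] < 0) -v else v
    }
    unstable_dir <- norm1(vecs[, 1])
    stable_dir <- norm1(vecs[, 2])
  }
  structure(list(jacobian = jac, eigenvalues = vals,
                 stable_dir = stable_dir, unstable_dir = unstable_dir,
                 load_stiffness = k_load, inertia = i_eq),
            class = "saddle_analysis")
}

#' Distance from the linear stable manifold
#'
#' Perpendicular distance of a phase-plane state from the stable
#' eigendirection of the control-OFF saddle, and a boolean classification
#' at tolerance `tol`. States initialized on the stable eigendirection
#' decay toward the origin (for small amplitudes, where the
#' linearization is valid); states on the unstable direction diverge.
#'
#' @param state length-2 `c(theta, omega)` or an n x 2 matrix.
#' @param saddle a `saddle_analysis` from [linearize_off()].
#' @param tol distance tolerance for the boolean classification.
#' @return list with `distance` and `on_manifold` (logical).
#' @export
on_stable_manifold <- function(state, saddle, tol = 1e-4) {
  if (is.null(saddle$stable_dir))
    stop("saddle has no real stable direction")
  if (!is.matrix(state)) state <- matrix(state, ncol = 2)
  d <- saddle$stable_dir
  dist <- abs(state[, 1] * d[2] - state[, 2] * d[1])
  list(distance = as.numeric(dist), on_manifold = as.numeric(dist) <= tol)
}

#' Detect ON/OFF/REFLEX switching events
#'
#' One event per control-mode change of a simulated trajectory,
#' timestamped at the first sample of the new mode.
#'
#' @param trajectory a `sim_trajectory` (or any data frame with columns
#'   `t` and `control_mode`).
#' @return data frame with columns `t`, `from_mode`, `to_mode`; zero rows
#'   for a constant mode.
#' @export
detect_switch_events <- function(trajectory) {
  m <- as.character(trajectory$control_mode)
  if (is.null(m)) stop("trajectory must carry a control_mode column")
  idx <- which(m[-1] != m[-length(m)]) + 1L
  data.frame(t = trajectory$t[idx],
             from_mode = m[idx - 1L], to_mode = m[idx],
             stringsAsFactors = FALSE)
}

#' CoM - CoP separation series
#'
#' The anterior-posterior difference `epsilon(t) = CoM(t) - CoP(t)` of a
#' simulated trajectory. Intervals where epsilon is small and alternates
#' in sign index the intermittent micro-dynamics (trembling) of quiet
#' stance; its upward zero crossings approximate switch-OFF events of
#' the intermittent controller.
#'
#' Both series are low-pass filtered (zero-lag 4th-order Butterworth)
#' before subtraction. The default cut-off of 2.5 Hz isolates the
#' trembling band around its ~1 Hz dominant component: the model's
#' instantaneous control-torque steps give the raw CoP a wide-band tail
#' that physical torque transmission (muscle activation dynamics) does
#' not have, and zero-crossing counts of a wide-band residual measure
#' filter bandwidth rather than trembling occurrence. Set
#' `cutoff = NULL` for the raw difference.
#'
#' @param trajectory a `sim_trajectory` from [simulate_stance()].
#' @param body a [body_params()] object (defaults to the stored one).
#' @param cutoff low-pass cut-off (Hz), or `NULL` for no filtering.
#' @return data frame with columns `t` (s) and `epsilon` (m).
#' @export
epsilon_series <- function(trajectory, body = attr(trajectory, "body"),
                           cutoff = 2.5) {
  com <- trajectory$com_x
  cop <- model_cop(trajectory, body)
  if (!is.null(cutoff)) {
    fs <- 1 / attr(trajectory, "dt")
    com <- butter_zero_lag(com, fs, cutoff, order = 4, type = "low")
    cop <- butter_zero_lag(cop, fs, cutoff, order = 4, type = "low")
  }
  data.frame(t = trajectory$t, epsilon = com - cop)
}

#' Sliding-window upward zero-crossing rate
#'
#' Counts, per sliding window, samples where the series crosses from
#' `<= 0` to `> 0` and divides by the window length. The series is used
#' with its physical zero (no mean removal); a run of exact zeros counts
#' as a crossing completed at the first strictly positive sample.
#'
#' @param t sample times (s), uniformly spaced.
#' @param x numeric series (e.g. `epsilon` from [epsilon_series()]).
#' @param window window length (s).
#' @param step window step (s).
#' @return data frame with columns `window_center` (s) and `rate` (Hz);
#'   attributes `window` and `step`.
#' @export
upward_zero_crossing_rate <- function(t, x, window = 2, step = 0.1) {
  if (window <= 0) stop("window must be > 0")
  n <- length(x)
  if (n != length(t)) stop("t and x must have the same length")
  span <- t[n] - t[1]
  if (span < window) stop("series shorter than one window")
  # a crossing is completed at the first > 0 sample following a <= 0 sample,
  # scanning past exact-zero runs
  nonpos <- x <= 0
  cross <- c(FALSE, !nonpos[-1] & nonpos[-n])
  # runs of zeros between a negative and a positive sample already satisfy
  # the rule above at the first positive sample
  ct <- t[cross]
  centers <- seq(t[1] + window / 2, t[n] - window / 2, by = step)
  lo <- centers - window / 2
  counts <- vapply(seq_along(centers), function(i) {
    sum(ct >= lo[i] & ct < lo[i] + window)
  }, integer(1))
  structure(data.frame(window_center = centers, rate = counts / window),
            window = window, step = step)
}

#' Post-perturbation OFF-onset time
#'
#' The onset of the OFF-period of the intermittent controller, defined as
#' the window center (strictly after the perturbation) at which the
#' upward zero-crossing rate of `epsilon(t)` reaches its minimum; ties
#' are broken by the earliest time.
#'
#' @param rates data frame from [upward_zero_crossing_rate()].
#' @param t_pert perturbation onset time (s).
#' @return onset time (s).
#' @export
off_onset_time <- function(rates, t_pert) {
  post <- rates[rates$window_center > t_pert, , drop = FALSE]
  if (nrow(post) == 0) stop("no windows after the perturbation")
  post$window_center[which.min(post$rate)]
}

#' Correlation between paired onset times
#'
#' Pearson correlation between per-individual OFF-onset times and
#' ERS-onset times (or any equal-length paired onset lists).
#'
#' @param off_onsets,ers_onsets equal-length numeric vectors, n >= 3.
#' @return Pearson correlation coefficient.
#' @export
onset_correlation <- function(off_onsets, ers_onsets) {
  if (length(off_onsets) != length(ers_onsets))
    stop("paired lists must have equal length")
  if (length(off_onsets) < 3) stop("need at least 3 pairs")
  if (stats::sd(off_onsets) == 0 || stats::sd(ers_onsets) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(off_onsets, ers_onsets)
}
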