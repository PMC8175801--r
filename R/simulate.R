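#' Delayed-state history accessor
#'
#' Wraps sampled CoM tilt state series into an accessor function used by
#' the controller torque operations: `h(tq)` returns `c(theta, omega)` at
#' query time `tq` by linear interpolation, clamped to the earliest
#' stored sample for queries before the history starts (constant
#' pre-history warm-up) and to the latest sample after it ends.
#'
#' @param t sample times (s), strictly increasing.
#' @param theta_com,omega_com CoM tilt (rad) and tilt velocity (rad/s).
#' @return function of one time argument returning `c(theta, omega)`.
#' @export
make_state_history <- function(t, theta_com, omega_com) {
  stopifnot(length(t) == length(theta_com), length(t) == length(omega_com))
  f_th <- stats::approxfun(t, theta_com, rule = 2)
  f_om <- stats::approxfun(t, omega_com, rule = 2)
  function(tq) c(f_th(tq), f_om(tq))
}

#' Intermittent ankle control torque
#'
#' The ON/OFF-switched delayed PD ankle torque: zero when the
#' delay-affected CoM state `(theta_CoM(t - delta), omega_CoM(t - delta))`
#' lies in the OFF region, and the restoring PD feedback
#' `-(P*theta + D*omega)` of the delayed state when it lies in the ON
#' region. The hip receives no active torque.
#'
#' @param state_history accessor from [make_state_history()].
#' @param t current time (s).
#' @param params an [intermittent_params()] object.
#' @return ankle torque in N m.
#' @export
intermittent_torque <- function(state_history, t, params) {
  s <- state_history(t - params$delta)
  if (in_off_region(s[1], s[2], params$region)) return(0)
  -(params$p_gain * s[1] + params$d_gain * s[2])
}

#' Transient reflexive ankle torque
#'
#' High-gain delayed PD ankle torque active only inside the window
#' `[perturbation_time + t_on, perturbation_time + t_off)`; zero outside.
#' While active it preempts the intermittent controller.
#'
#' @param state_history accessor from [make_state_history()].
#' @param t current time (s).
#' @param params a [reflex_params()] object.
#' @param perturbation_time perturbation onset time (s).
#' @return ankle torque in N m.
#' @export
reflex_torque <- function(state_history, t, params, perturbation_time = 0) {
  tr <- t - perturbation_time
  if (tr < params$t_on || tr >= params$t_off) return(0)
  s <- state_history(t - params$delta_reflex)
  -(params$p_reflex * s[1] + params$d_reflex * s[2])
}

#' Simulate the intermittent-control stance model
#'
#' Forward-Euler integration of the double inverted pendulum under
#' passive, intermittent, reflexive, perturbation and noise torques, with
#' ring-buffer delay lines for the two feedback delays. Delays are
#' rounded to integer multiples of `dt` (with a warning if the rounding
#' is not exact); for times earlier than the first stored sample plus the
#' delay, the earliest stored state is used (constant pre-history). The
#' simulation halts with a `fallen` flag if `|theta_CoM|` exceeds
#' `fall_limit`.
#'
#' @param body a [body_params()] object.
#' @param passive a [passive_params()] object.
#' @param intermittent an [intermittent_params()] object.
#' @param reflex a [reflex_params()] object, or `NULL` for no reflexive
#'   controller.
#' @param perturbation a [perturbation_profile()] object, or `NULL` for
#'   unperturbed stance.
#' @param noise a [noise_params()] object, or `NULL` for the noiseless
#'   model.
#' @param dt integration step (s).
#' @param t_start,t_end simulation window (s).
#' @param perturbation_time onset time(s) of the perturbation(s) (s); may
#'   be a vector for repeated perturbations.
#' @param initial_state `c(theta_a, theta_h, omega_a, omega_h)` at
#'   `t_start`.
#' @param fall_limit CoM tilt magnitude (rad) treated as a fall. The
#'   default (1.2 rad, ~69 degrees) lies safely below the folded-chain
#'   rest configuration (|theta_CoM| ~ 1.48 rad) that an uncontrolled
#'   fall of the two-link body ends in, so divergence always triggers.
#' @return a `sim_trajectory`: a data frame with one row per time step
#'   and columns `t`, `theta_a`, `theta_h`, `omega_a`, `omega_h`,
#'   `theta_com`, `omega_com`, `com_x`, `com_y`, per-component torques,
#'   `control_mode` (factor OFF/ON/REFLEX) and `cop_x` (quasi-static
#'   model CoP, see [model_cop()]), with the run configuration stored in
#'   attributes (`body`, `fallen`, `dt`, `perturbation_time`).
#' @examples
#' body <- body_params()
#' traj <- simulate_stance(body, passive_params(body),
#'                         intermittent_params(body),
#'                         dt = 2e-3, t_start = -30, t_end = 0)
#' max(abs(traj$theta_com[traj$t > -10]))
#' @export
simulate_stance <- function(body = body_params(),
                            passive = passive_params(body),
                            intermittent = intermittent_params(body),
                            reflex = NULL, perturbation = NULL,
                            noise = NULL, dt = 1e-3,
                            t_start = -50, t_end = 5,
                            perturbation_time = 0,
                            initial_state = c(0.01, 0, 0, 0),
                            fall_limit = 1.2) {
  if (dt <= 0) stop("dt must be > 0")
  if (t_end <= t_start) stop("t_end must be > t_start")
  round_delay <- function(delta, name) {
    nd <- round(delta / dt)
    if (abs(nd * dt - delta) > 1e-9)
      warning(sprintf("%s rounded to %d integration steps (%.6f s)",
                      name, nd, nd * dt))
    as.integer(nd)
  }
  nd <- round_delay(intermittent$delta, "feedback delay")
  ctrl <- c(intermittent$p_gain, intermittent$d_gain, nd)
  if (is.null(reflex)) {
    rfx <- c(0, 0, 0, 0, 0, 0)
  } else {
    ndr <- round_delay(reflex$delta_reflex, "reflex delay")
    rfx <- c(1, reflex$p_reflex, reflex$d_reflex, ndr,
             reflex$t_on, reflex$t_off)
  }
  if (is.null(perturbation) || length(perturbation_time) == 0) {
    segs <- matrix(numeric(0), ncol = 3)
    pt <- numeric(0)
  } else {
    segs <- perturbation$segments
    pt <- sort(perturbation_time)
  }
  n <- round((t_end - t_start) / dt) + 1
  if (is.null(noise) || (noise$sigma_ankle == 0 && noise$sigma_hip == 0)) {
    nz <- matrix(0, n, 2)
  } else {
    withr_seed <- noise$seed
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(withr_seed)
    nz <- matrix(stats::rnorm(2L * n), n, 2)
    nz[, 1] <- nz[, 1] * noise$sigma_ankle / sqrt(dt)
    nz[, 2] <- nz[, 2] * noise$sigma_hip / sqrt(dt)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  res <- .sim_core(unclass(body),
                   c(passive$k_a, passive$b_a, passive$k_h, passive$b_h),
                   ctrl, rfx, segs, pt, nz, dt, t_start, t_end,
                   initial_state, intermittent$region$boundary_slopes,
                   fall_limit)
  fallen <- res$fallen
  res$fallen <- NULL
  traj <- as.data.frame(res)
  traj$control_mode <- factor(c("OFF", "ON", "REFLEX")[traj$control_mode + 1L],
                              levels = c("OFF", "ON", "REFLEX"))
  traj$cop_x <- -(traj$tau_pass_a + traj$tau_act_a + traj$tau_reflex_a) /
    ((body$m_foot + body$m_le + body$m_hat) * body$g)
  structure(traj, class = c("sim_trajectory", "data.frame"),
            body = body, fallen = fallen, dt = dt,
            perturbation_time = if (length(pt)) pt else NULL)
}

#' Quasi-static model center of pressure
#'
#' Approximates the anterior-posterior CoP of the model from the net
#' deterministic actuated ankle torque (passive + active + reflexive):
#' `cop_x = -tau_a_net / (M_total * g)`. The sign follows the
#' forward-positive torque convention; at static equilibrium this reduces
#' exactly to the whole-body CoM projection
#' `x_com * (m_le + m_hat) / M_total`. Documented as a quasi-static
#' approximation: foot-inertia and load-transfer dynamics are neglected,
#' and the white torque-noise term is excluded because its step-scaled
#' (`1/sqrt(dt)`) sample values have no dt-convergent instantaneous
#' value — noise reaches the CoP only through its effect on the state.
#'
#' @param trajectory a `sim_trajectory` from [simulate_stance()].
#' @param body a [body_params()] object (defaults to the one stored in
#'   the trajectory).
#' @return numeric vector of CoP positions (m).
#' @export
model_cop <- function(trajectory, body = attr(trajectory, "body")) {
  tau_net <- trajectory$tau_pass_a + trajectory$tau_act_a +
    trajectory$tau_reflex_a
  if (any(!is.finite(tau_net))) stop("trajectory torques must be finite")
  -tau_net / ((body$m_foot + body$m_le + body$m_hat) * body$g)
}

#' @export
print.sim_trajectory <- function(x, ...) {
  cat(sprintf("<sim_trajectory> %d samples, t in [%.3f, %.3f] s, dt = %g s\n",
              nrow(x), x$t[1], x$t[nrow(x)], attr(x, "dt")))
  cat(sprintf("  fallen: %s; mode counts: %s\n",
              attr(x, "fallen"),
              paste(names(table(x$control_mode)), table(x$control_mode),
                    sep = "=", collapse = " ")))
  invisible(x)
}
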