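#' Anthropometric parameters of the stance model
#'
#' Builds the body-segment parameter set of the double inverted pendulum
#' (DIP) model of upright stance: a leg link (LE, both lower extremities
#' lumped) pivoting about the ankle and a head-arms-trunk link (HAT)
#' pivoting about the hip, with the foot fixed to the support surface.
#' Defaults follow the common anthropometric convention of splitting the
#' total body mass as HAT:LE = 0.62:0.35 (the remainder assigned to the
#' feet) and placing each link's center of mass at mid-link; link inertias
#' default to the uniform-rod value m*l^2/12 about the link CoM.
#'
#' @param total_mass total body mass in kg.
#' @param l_le,l_hat link lengths in m (ankle-hip and hip-top).
#' @param mass_ratio_le,mass_ratio_hat fractions of `total_mass` assigned
#'   to the LE and HAT links; the remainder goes to the feet.
#' @param c_le,c_hat distance from the proximal joint to the link CoM in m
#'   (default mid-link).
#' @param i_le,i_hat link moments of inertia about the link CoM in
#'   kg m^2 (default uniform rod).
#' @param g gravitational acceleration in m/s^2.
#' @return an object of class `body_params`.
#' @seealso [load_stiffness()], [passive_params()], [simulate_stance()]
#' @export
body_params <- function(total_mass = 60, l_le = 0.9, l_hat = 0.8,
                        mass_ratio_le = 0.35, mass_ratio_hat = 0.62,
                        c_le = l_le / 2, c_hat = l_hat / 2,
                        i_le = NULL, i_hat = NULL, g = 9.81) {
  m_le <- total_mass * mass_ratio_le
  m_hat <- total_mass * mass_ratio_hat
  m_foot <- total_mass - m_le - m_hat
  if (is.null(i_le)) i_le <- m_le * l_le^2 / 12
  if (is.null(i_hat)) i_hat <- m_hat * l_hat^2 / 12
  b <- list(m_foot = m_foot, m_le = m_le, m_hat = m_hat,
            l_le = l_le, l_hat = l_hat, c_le = c_le, c_hat = c_hat,
            i_le = i_le, i_hat = i_hat, g = g)
  vals <- unlist(b[c("m_le", "m_hat", "l_le", "l_hat", "c_le", "c_hat",
                     "i_le", "i_hat")])
  # g = 0 is admitted for gravity-free mechanics checks
  if (any(!is.finite(unlist(b))) || any(vals <= 0) || g < 0 || m_foot < 0)
    stop("body parameters must be finite and positive (masses, lengths, inertias)")
  if (c_le > l_le || c_hat > l_hat)
    stop("link CoM distance must satisfy 0 < c <= l")
  structure(b, class = "body_params")
}

#' Linearized gravitational load stiffness at the ankle
#'
#' The proportional constant of the linearized gravitational toppling
#' torque about the ankle for the rigid (hip locked) body:
#' `g * (m_le*c_le + m_hat*(l_le + c_hat))` in N m/rad. The intermittent
#' control model requires the passive ankle stiffness to be smaller than
#' this value.
#'
#' @param body a [body_params()] object.
#' @return load stiffness in N m/rad.
#' @export
load_stiffness <- function(body) {
  body$g * (body$m_le * body$c_le + body$m_hat * (body$l_le + body$c_hat))
}

#' Single-link-equivalent moment of inertia about the ankle
#'
#' Moment of inertia of the rigid (hip locked) two-link body about the
#' ankle pivot, used by the delay-free linearization.
#'
#' @inheritParams load_stiffness
#' @return moment of inertia in kg m^2.
#' @export
ankle_inertia <- function(body) {
  body$i_le + body$m_le * body$c_le^2 +
    body$i_hat + body$m_hat * (body$l_le + body$c_hat)^2
}

#' Passive (intrinsic) joint viscoelasticity
#'
#' Torsional stiffness and viscosity of the ankle and hip joints. The
#' passive torque is `-(K*theta + B*theta_dot)` per joint. By model
#' assumption the ankle stiffness alone cannot stabilize the upright
#' equilibrium, so the default `k_a` is 80% of the gravitational load
#' stiffness; the hip is rigidly stabilized by large `k_h`, `b_h`.
#'
#' @param body a [body_params()] object (used for the default `k_a`).
#' @param k_a,b_a ankle torsional stiffness (N m/rad) and viscosity
#'   (N m s/rad).
#' @param k_h,b_h hip torsional stiffness and viscosity.
#' @return an object of class `passive_params`; its
#'   `ankle_stiffness_deficient` field flags whether `k_a` is below the
#'   load stiffness (the saddle-generating regime the model requires).
#' @export
passive_params <- function(body = body_params(),
                           k_a = 0.8 * load_stiffness(body), b_a = 35,
                           k_h = 2000, b_h = 200) {
  if (any(c(k_a, b_a, k_h, b_h) < 0)) stop("viscoelastic parameters must be >= 0")
  structure(list(k_a = k_a, b_a = b_a, k_h = k_h, b_h = b_h,
                 ankle_stiffness_deficient = k_a < load_stiffness(body)),
            class = "passive_params")
}

#' ON/OFF switching region of the phase plane
#'
#' Partition of the CoM tilt phase plane (theta_CoM, theta_dot_CoM) into
#' the OFF region (active control switched off) and the ON region, by two
#' lines through the origin. With the default slopes `c(0, Inf)` the OFF
#' region is the union of the 2nd and 4th quadrants
#' (`theta * theta_dot <= 0`), which contains the stable manifold of the
#' control-OFF saddle; boundary points are assigned to OFF (the passive
#' default).
#'
#' @param boundary_slopes two slopes (rad/s per rad) of the boundary lines;
#'   `Inf` denotes the vertical axis.
#' @return an object of class `switch_region`.
#' @export
switch_region <- function(boundary_slopes = c(0, Inf)) {
  if (length(boundary_slopes) != 2) stop("boundary_slopes must have length 2")
  structure(list(boundary_slopes = boundary_slopes,
                 off_contains_stable_manifold = TRUE),
            class = "switch_region")
}

#' Classify phase-plane points into the OFF region
#'
#' @param theta,omega CoM tilt (rad) and tilt velocity (rad/s); vectorized.
#' @param region a [switch_region()].
#' @return logical vector, `TRUE` where the point lies in the OFF region
#'   (boundaries inclusive).
#' @export
in_off_region <- function(theta, omega, region = switch_region()) {
  s <- region$boundary_slopes
  g1 <- if (is.finite(s[1])) omega - s[1] * theta else theta
  g2 <- if (is.finite(s[2])) omega - s[2] * theta else theta
  g1 * g2 <= 0
}

#' Intermittent (delayed PD) controller parameters
#'
#' Gains and feedback delay of the intermittently switched delayed PD
#' controller acting at the ankle. The proportional gain is deliberately
#' small (default 25% of the load stiffness): the ankle stiffness plus
#' the active proportional feedback barely exceed the gravitational
#' load, so stability rests on exploiting the control-OFF saddle
#' dynamics rather than on stiff feedback. The feedback delay is 0.2 s.
#'
#' The default switching region is the sector of the 2nd/4th phase-plane
#' quadrants between a slightly tilted horizontal boundary (slope
#' -0.115) and a steep boundary at slope `-p_gain/d_gain`. The steep
#' boundary is *torque-continuous*: on the ray `omega = -(P/D) * theta`
#' the PD torque vanishes, so the frequent switch events that occur
#' while the state rides that boundary toward upright inject no torque
#' steps into the ankle (and hence none into the model CoP). The
#' default derivative gain (100 N m s/rad) places this silent boundary
#' just inside the stable eigendirection of the OFF saddle; the tilted
#' lower boundary is calibrated so the noiseless orbit through a 0.01
#' rad initial tilt is nearly neutral, giving the hallmark quiet-stance
#' statistics (tilt oscillation of about 0.01 rad, CoP spectral
#' exponent near 1.5, CoM-CoP upward-crossing rate near 1 Hz).
#'
#' @param body a [body_params()] object (used for the default `p_gain`).
#' @param p_gain,d_gain proportional (N m/rad) and derivative
#'   (N m s/rad) gains.
#' @param delta feedback delay in s.
#' @param region a [switch_region()]; the default couples the steep
#'   boundary to `-p_gain/d_gain`.
#' @return an object of class `intermittent_params`.
#' @export
intermittent_params <- function(body = body_params(),
                                p_gain = 0.25 * load_stiffness(body),
                                d_gain = 100, delta = 0.2,
                                region = switch_region(c(-0.115,
                                                         if (d_gain > 0 && p_gain > 0)
                                                           -p_gain / d_gain else Inf))) {
  if (delta < 0 || p_gain < 0 || d_gain < 0)
    stop("gains and delay must be >= 0")
  structure(list(p_gain = p_gain, d_gain = d_gain, delta = delta,
                 region = region), class = "intermittent_params")
}

#' Transient reflexive controller parameters
#'
#' A high-gain delayed PD controller that operates only inside a short
#' window after a perturbation, modeling the stereotyped reflexive phase
#' of the postural response. Its delay is shorter than the intermittent
#' controller's (reflex arcs are faster than supraspinal feedback). While
#' active it preempts the intermittent controller.
#'
#' @param p_reflex,d_reflex reflex gains in N m/rad and N m s/rad.
#' @param delta_reflex reflex feedback delay in s.
#' @param t_on,t_off activation window in s relative to perturbation onset.
#' @return an object of class `reflex_params`.
#' @export
reflex_params <- function(p_reflex = 327, d_reflex = 50,
                          delta_reflex = 0.05, t_on = 0.05, t_off = 0.25) {
  if (t_on >= t_off) stop("t_on must be < t_off")
  if (delta_reflex < 0) stop("delta_reflex must be >= 0")
  structure(list(p_reflex = p_reflex, d_reflex = d_reflex,
                 delta_reflex = delta_reflex, t_on = t_on, t_off = t_off),
            class = "reflex_params")
}

#' Support-surface perturbation profile
#'
#' Piecewise-constant horizontal acceleration of the support surface,
#' given as ordered, non-overlapping segments `(t_start, t_end, alpha)`
#' relative to the perturbation onset. The default is the standard
#' backward translation: -4 m/s^2 for 100 ms followed by +4 m/s^2 for
#' 100 ms (net velocity change zero).
#'
#' @param segments numeric matrix with columns `t_start`, `t_end` (s) and
#'   `alpha` (m/s^2).
#' @return an object of class `perturbation_profile`.
#' @export
perturbation_profile <- function(segments = rbind(c(0, 0.1, -4), c(0.1, 0.2, 4))) {
  segments <- matrix(as.numeric(segments), ncol = 3,
                     dimnames = list(NULL, c("t_start", "t_end", "alpha")))
  if (any(segments[, 2] <= segments[, 1]))
    stop("each segment must have t_end > t_start")
  if (nrow(segments) > 1) {
    o <- order(segments[, 1])
    segments <- segments[o, , drop = FALSE]
    if (any(segments[-1, 1] < segments[-nrow(segments), 2] - 1e-12))
      stop("segments must not overlap")
  }
  structure(list(segments = segments), class = "perturbation_profile")
}

#' Belt kinematics implied by a perturbation profile
#'
#' Integrates the piecewise-constant support-surface acceleration into
#' belt velocity and displacement sampled on a time grid, with repeated
#' applications at each event time.
#'
#' @param profile a [perturbation_profile()].
#' @param t time grid in s.
#' @param events perturbation onset times in s.
#' @return data frame with columns `t`, `acc`, `vel`, `disp`.
#' @export
belt_kinematics <- function(profile, t, events = 0) {
  acc <- numeric(length(t))
  for (ev in events) {
    tr <- t - ev
    for (s in seq_len(nrow(profile$segments))) {
      seg <- profile$segments[s, ]
      acc[tr >= seg[1] & tr < seg[2]] <- acc[tr >= seg[1] & tr < seg[2]] + seg[3]
    }
  }
  dt <- diff(t)
  vel <- c(0, cumsum(acc[-length(acc)] * dt))
  disp <- c(0, cumsum(vel[-length(vel)] * dt))
  data.frame(t = t, acc = acc, vel = vel, disp = disp)
}

#' Motor (torque) noise parameters
#'
#' Additive white Gaussian torque noise per joint. The per-step noise
#' torque is `sigma * rnorm(1) / sqrt(dt)` so that the integrated effect
#' is invariant to the integration step (Euler-Maruyama scaling); `sigma`
#' is therefore a noise intensity in N m sqrt(s).
#'
#' @param sigma_ankle,sigma_hip noise intensities (N m sqrt(s)).
#' @param seed integer seed; identical seeds give identical realizations.
#' @return an object of class `noise_params`.
#' @export
noise_params <- function(sigma_ankle = 0.1, sigma_hip = 0.1, seed = 1L) {
  if (sigma_ankle < 0 || sigma_hip < 0) stop("noise intensities must be >= 0")
  structure(list(sigma_ankle = sigma_ankle, sigma_hip = sigma_hip,
                 seed = as.integer(seed)), class = "noise_params")
}
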