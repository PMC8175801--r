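#' Rigid-body terms of the stance equations of motion
#'
#' Returns the inertia matrix `M(theta)`, the centrifugal/Coriolis vector
#' `C(theta, theta_dot)` and the gravitational vector `G(theta)` of the
#' planar two-link inverted pendulum with the ankle pivot fixed, in the
#' form `M %*% acc + C + G = T` with generalized coordinates
#' `(theta_a, theta_h)` (ankle tilt from vertical; hip rotation of the
#' HAT link relative to the LE link; forward positive). The convention
#' makes `G` negative for a forward tilt, i.e. gravity contributes a
#' forward toppling acceleration.
#'
#' @param theta numeric length-2, joint angles (rad).
#' @param omega numeric length-2, joint angular velocities (rad/s).
#' @param body a [body_params()] object.
#' @return list with `inertia` (2x2, symmetric positive definite),
#'   `coriolis` (length 2) and `gravity` (length 2).
#' @export
derive_dynamics_terms <- function(theta, omega, body) {
  if (!all(is.finite(theta)) || !all(is.finite(omega)))
    stop("theta and omega must be finite")
  m1 <- body$m_le; m2 <- body$m_hat; l1 <- body$l_le
  c1 <- body$c_le; c2 <- body$c_hat
  ch <- cos(theta[2]); sh <- sin(theta[2])
  M11 <- body$i_le + m1 * c1^2 + body$i_hat +
    m2 * (l1^2 + c2^2 + 2 * l1 * c2 * ch)
  M12 <- body$i_hat + m2 * (c2^2 + l1 * c2 * ch)
  M22 <- body$i_hat + m2 * c2^2
  C <- c(-m2 * l1 * c2 * sh * (2 * omega[1] * omega[2] + omega[2]^2),
         m2 * l1 * c2 * sh * omega[1]^2)
  s1 <- sin(theta[1]); s12 <- sin(theta[1] + theta[2])
  G <- c(-body$g * ((m1 * c1 + m2 * l1) * s1 + m2 * c2 * s12),
         -body$g * m2 * c2 * s12)
  list(inertia = matrix(c(M11, M12, M12, M22), 2, 2),
       coriolis = C, gravity = G)
}

#' Passive viscoelastic joint torque
#'
#' `-(K_a*theta_a + B_a*omega_a, K_h*theta_h + B_h*omega_h)`: linear
#' restoring springs and dampers at the ankle and hip.
#'
#' @inheritParams derive_dynamics_terms
#' @param passive a [passive_params()] object.
#' @return length-2 torque vector (ankle, hip) in N m. Vectorized: if
#'   `theta`/`omega` are n x 2 matrices an n x 2 matrix is returned.
#' @export
passive_torque <- function(theta, omega, passive) {
  if (is.matrix(theta)) {
    cbind(-(passive$k_a * theta[, 1] + passive$b_a * omega[, 1]),
          -(passive$k_h * theta[, 2] + passive$b_h * omega[, 2]))
  } else {
    c(-(passive$k_a * theta[1] + passive$b_a * omega[1]),
      -(passive$k_h * theta[2] + passive$b_h * omega[2]))
  }
}

#' Forward kinematics of the link and total centers of mass
#'
#' Planar forward kinematics with the ankle at the origin. The total CoM
#' is the mass-weighted mean of the LE and HAT link CoMs; the foot link
#' (resting on the ground) is excluded, matching the convention used for
#' marker-based CoM estimation.
#'
#' @param theta length-2 vector or n x 2 matrix of joint angles (rad).
#' @param body a [body_params()] object.
#' @return data frame with columns `x_le`, `y_le`, `x_hat`, `y_hat`,
#'   `x_com`, `y_com` (m).
#' @export
com_kinematics <- function(theta, body) {
  if (!is.matrix(theta)) theta <- matrix(theta, ncol = 2)
  phi2 <- theta[, 1] + theta[, 2]
  x_le <- body$c_le * sin(theta[, 1]); y_le <- body$c_le * cos(theta[, 1])
  x_hat <- body$l_le * sin(theta[, 1]) + body$c_hat * sin(phi2)
  y_hat <- body$l_le * cos(theta[, 1]) + body$c_hat * cos(phi2)
  mt <- body$m_le + body$m_hat
  data.frame(x_le = x_le, y_le = y_le, x_hat = x_hat, y_hat = y_hat,
             x_com = (body$m_le * x_le + body$m_hat * x_hat) / mt,
             y_com = (body$m_le * y_le + body$m_hat * y_hat) / mt)
}

#' CoM tilt angle
#'
#' `theta_CoM = atan(x_com / y_com)`: the tilt of the single-link
#' equivalent pendulum through the total CoM. For a tilt-velocity series
#' apply [central_diff()] to the returned angles, the same differencing
#' rule used throughout the package.
#'
#' @param x_com,y_com horizontal and vertical CoM positions (m);
#'   vectorized.
#' @return tilt angle(s) in rad.
#' @export
com_tilt <- function(x_com, y_com) {
  if (any(y_com <= 0)) stop("y_com must be > 0 (body above the ground)")
  atan(x_com / y_com)
}

#' Support-surface perturbation torque
#'
#' Generalized joint torques induced by a horizontal support-surface
#' acceleration `alpha`, modeled as d'Alembert pseudo-forces `-m_i*alpha`
#' applied horizontally at each link CoM and projected onto the joint
#' coordinates. Zero when `alpha = 0`, linear in `alpha`; a backward
#' surface acceleration (`alpha < 0`) yields forward-toppling torques at
#' the upright configuration.
#'
#' @inheritParams derive_dynamics_terms
#' @param alpha support-surface horizontal acceleration (m/s^2).
#' @return length-2 torque vector (ankle, hip) in N m.
#' @export
perturbation_torque <- function(theta, body, alpha) {
  c1 <- cos(theta[1]); c12 <- cos(theta[1] + theta[2])
  c(-alpha * (body$m_le * body$c_le * c1 +
                body$m_hat * (body$l_le * c1 + body$c_hat * c12)),
    -alpha * body$m_hat * body$c_hat * c12)
}

#' Total mechanical energy of the free pendulum
#'
#' Kinetic plus gravitational potential energy of the two-link pendulum,
#' used by the energy-conservation checks of the dynamics derivation.
#'
#' @inheritParams derive_dynamics_terms
#' @return energy in J.
#' @export
mechanical_energy <- function(theta, omega, body) {
  d <- derive_dynamics_terms(theta, omega, body)
  kin <- 0.5 * drop(t(omega) %*% d$inertia %*% omega)
  y1 <- body$c_le * cos(theta[1])
  y2 <- body$l_le * cos(theta[1]) + body$c_hat * cos(theta[1] + theta[2])
  kin + body$g * (body$m_le * y1 + body$m_hat * y2)
}
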