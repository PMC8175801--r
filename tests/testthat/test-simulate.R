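test_that("switching region classification is total, disjoint and boundary-OFF", {
  reg <- switch_region(c(0, Inf))     # quadrants 2 and 4
  th <- c(0.1, -0.1, 0.1, -0.1, 0, 0.1)
  om <- c(0.2, 0.2, -0.2, -0.2, 0.3, 0)
  off <- in_off_region(th, om, reg)
  expect_equal(off, c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE))
  # default region: steep boundary slope equals -P/D (torque-continuous)
  ctl <- intermittent_params(tk_body())
  s <- ctl$region$boundary_slopes
  expect_equal(s[2], -ctl$p_gain / ctl$d_gain)
  # every point is classified (total function), boundary points are OFF
  expect_true(in_off_region(0.1, s[1] * 0.1, ctl$region))
  expect_true(in_off_region(0.1, s[2] * 0.1, ctl$region))
})

test_that("intermittent torque applies delayed PD feedback only in the ON region", {
  ctl <- intermittent_params(tk_body(), p_gain = 1, d_gain = 0, delta = 0.2,
                             region = switch_region(c(0, Inf)))
  t <- seq(0, 5, by = 1e-3)
  # constant history: output independent of the delay
  h_const <- make_state_history(t, rep(0.1, length(t)), rep(0.2, length(t)))
  for (delta in c(0, 0.1, 0.4)) {
    ctl_d <- intermittent_params(tk_body(), p_gain = 1, d_gain = 0,
                                 delta = delta,
                                 region = switch_region(c(0, Inf)))
    expect_equal(intermittent_torque(h_const, 3, ctl_d), -0.1)
  }
  # delayed state in the OFF region -> zero torque
  h_off <- make_state_history(t, rep(0.1, length(t)), rep(-0.2, length(t)))
  expect_equal(intermittent_torque(h_off, 3, ctl), 0)
})

test_that("ON-phase torque matches the closed form for a sinusoidal history", {
  P <- 50; D <- 7; delta <- 0.2; w <- 2 * pi * 0.5; A <- 0.05
  ctl <- intermittent_params(tk_body(), p_gain = P, d_gain = D, delta = delta,
                             region = switch_region(c(0, Inf)))
  t <- seq(0, 10, by = 1e-4)
  h <- make_state_history(t, A * sin(w * t), A * w * cos(w * t))
  for (tq in c(3.1, 4.35, 6.2)) {
    td <- tq - delta
    expected <- -(P * A * sin(w * td) + D * A * w * cos(w * td))
    if (A * sin(w * td) * A * w * cos(w * td) > 0)   # delayed state in ON
      expect_equal(intermittent_torque(h, tq, ctl), expected,
                   tolerance = 1e-6)
  }
})

test_that("reflex torque is gated to its window and preempts the PD controller", {
  rfx <- reflex_params(p_reflex = 327, d_reflex = 0, delta_reflex = 0,
                       t_on = 0.05, t_off = 0.25)
  t <- seq(-1, 2, by = 1e-3)
  h <- make_state_history(t, rep(0.01, length(t)), rep(0, length(t)))
  expect_equal(reflex_torque(h, 0.02, rfx, 0), 0)       # before the window
  expect_equal(reflex_torque(h, 0.3, rfx, 0), 0)        # after the window
  expect_equal(reflex_torque(h, 0.1, rfx, 0), -3.27)    # paper-scale gain
  # inside the simulation, modes are mutually exclusive
  tr <- tk_perturbed()
  expect_true(all(tr$tau_act_a[tr$control_mode != "ON"] == 0))
  expect_true(all(tr$tau_reflex_a[tr$control_mode != "REFLEX"] == 0))
  in_window <- tr$t >= 0.05 & tr$t < 0.25
  expect_true(all(tr$control_mode[tr$control_mode == "REFLEX"] == "REFLEX"))
  expect_true(all(which(tr$control_mode == "REFLEX") %in% which(in_window)))
})

test_that("simulation is deterministic given a seed", {
  a <- simulate_stance(tk_body(), noise = noise_params(seed = 7L),
                       dt = 1e-3, t_start = 0, t_end = 5)
  b <- simulate_stance(tk_body(), noise = noise_params(seed = 7L),
                       dt = 1e-3, t_start = 0, t_end = 5)
  expect_identical(a$theta_com, b$theta_com)
  expect_identical(a$tau_noise_a, b$tau_noise_a)
})

test_that("noiseless quiet stance settles on a ~0.01 rad nearly periodic orbit", {
  tr <- tk_quiet()
  ss <- tr[tr$t > 20, ]
  amp <- max(abs(ss$theta_com))
  expect_gt(amp, 0.005)
  expect_lt(amp, 0.02)
  # successive cycle peaks differ by < 1% after transient removal
  x <- abs(ss$theta_com)
  pk <- which(diff(sign(diff(x))) == -2) + 1
  pk <- pk[x[pk] > 0.5 * amp]
  expect_gt(length(pk), 3)
  expect_lt(max(abs(diff(x[pk])) / x[pk][-1]), 0.01)
})

test_that("uncontrolled saddle falls from a tilted start", {
  ctl0 <- intermittent_params(tk_body(), p_gain = 0, d_gain = 0)
  tr <- simulate_stance(tk_body(), intermittent = ctl0, dt = 1e-3,
                        t_start = 0, t_end = 30,
                        initial_state = c(0.05, 0, 0, 0))
  expect_true(attr(tr, "fallen"))
})

test_that("halving the integration step changes the perturbed state by < 1%", {
  run <- function(dt) {
    tr <- simulate_stance(tk_body(), reflex = reflex_params(),
                          perturbation = perturbation_profile(),
                          dt = dt, t_start = -50, t_end = 5)
    tr$theta_com[nrow(tr)]
  }
  v1 <- run(5e-4); v2 <- run(2.5e-4)
  expect_lt(abs(v1 - v2) / abs(v2), 0.01)
})

test_that("model CoP reduces to the static moment balance at equilibrium", {
  body <- tk_body()
  # hold a static tilted pose: equilibrium torque balances gravity exactly
  th <- c(0.1, 0)
  d <- derive_dynamics_terms(th, c(0, 0), body)
  traj <- data.frame(tau_pass_a = d$gravity[1], tau_act_a = 0,
                     tau_reflex_a = 0, tau_noise_a = 0)
  cop <- model_cop(traj, body)
  x_com <- com_kinematics(th, body)$x_com
  m_links <- body$m_le + body$m_hat
  m_tot <- m_links + body$m_foot
  expect_equal(cop, x_com * m_links / m_tot, tolerance = 1e-9)
  # zero net torque -> CoP at the ankle; doubling g at fixed torque halves it
  traj0 <- data.frame(tau_pass_a = 0, tau_act_a = 0, tau_reflex_a = 0,
                      tau_noise_a = 0)
  expect_equal(model_cop(traj0, body), 0)
  tau <- data.frame(tau_pass_a = -10, tau_act_a = 0, tau_reflex_a = 0,
                    tau_noise_a = 0)
  b2 <- body_params(g = 2 * 9.81)
  expect_equal(model_cop(tau, b2), model_cop(tau, body_params()) / 2)
})
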