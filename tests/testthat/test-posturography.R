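test_that("joint angles from markers invert forward kinematics", {
  body <- tk_body()
  # vertically collinear markers -> zero angles
  n <- 5
  up <- function(x, y) cbind(ap = rep(x, n), ml = 0, vert = rep(y, n))
  mk0 <- list(ankle_l = up(0, 0), ankle_r = up(0, 0),
              trochanter_l = up(0, 0.9), trochanter_r = up(0, 0.9),
              acromion_l = up(0, 1.7), acromion_r = up(0, 1.7))
  a0 <- joint_angles_from_markers(mk0)
  expect_equal(a0$theta_a, rep(0, n))
  expect_equal(a0$theta_h, rep(0, n))
  # synthesized from known angles -> exact round trip
  th_a <- c(-0.2, 0, 0.15, 0.3)
  th_h <- c(0.1, -0.25, 0, 0.2)
  ank <- cbind(ap = 0 * th_a, vert = 0 * th_a)
  tro <- cbind(ap = body$l_le * sin(th_a), vert = body$l_le * cos(th_a))
  acr <- cbind(ap = tro[, 1] + body$l_hat * sin(th_a + th_h),
               vert = tro[, 2] + body$l_hat * cos(th_a + th_h))
  mk <- list(ankle_l = ank, ankle_r = ank, trochanter_l = tro,
             trochanter_r = tro, acromion_l = acr, acromion_r = acr)
  a <- joint_angles_from_markers(mk)
  expect_equal(a$theta_a, th_a, tolerance = 1e-9)
  expect_equal(a$theta_h, th_h, tolerance = 1e-9)
  # anatomical convention flips both signs
  an <- joint_angles_from_markers(mk, convention = "anatomical")
  expect_equal(an$theta_a, -th_a, tolerance = 1e-9)
  # left +delta / right -delta tilts average to zero
  d <- 0.05
  tro_l <- cbind(ap = body$l_le * sin(d), vert = body$l_le * cos(d))
  tro_r <- cbind(ap = body$l_le * sin(-d), vert = body$l_le * cos(-d))
  mk_lr <- list(ankle_l = ank[1, , drop = FALSE], ankle_r = ank[1, , drop = FALSE],
                trochanter_l = tro_l, trochanter_r = tro_r,
                acromion_l = tro_l * c(2, 2), acromion_r = tro_r * c(2, 2))
  expect_equal(joint_angles_from_markers(mk_lr)$theta_a, 0, tolerance = 1e-12)
  expect_error(joint_angles_from_markers(mk[-1]), "ankle_l")
})

test_that("CoM estimation filters and differentiates correctly", {
  body <- tk_body()
  fs <- 300
  # static posture -> zero velocity
  th <- data.frame(theta_a = rep(0.05, 3 * fs), theta_h = rep(-0.02, 3 * fs))
  com <- estimate_com(th, fs, body)
  expect_lt(max(abs(com$v_com)), 1e-10)
  # linear ramp -> constant interior velocity equal to the slope
  tt <- seq(0, 3, by = 1 / fs)
  thr <- data.frame(theta_a = 0.01 * tt, theta_h = 0)
  cr <- estimate_com(thr, fs, body, cutoff = NULL)
  slope <- diff(range(cr$x_com)) / diff(range(tt))
  mid <- 100:(length(tt) - 100)
  expect_equal(cr$v_com[mid], rep(slope, length(mid)), tolerance = 1e-3)
  # round trip against the simulator's own CoM
  tr <- tk_trial()
  ang <- joint_angles_from_markers(tr$markers)
  est <- estimate_com(ang, tr$markers$fs, attr(tr$sim, "body"))
  xc_true <- stats::approx(tr$sim$t, tr$sim$com_x, tr$markers$t)$y
  expect_lt(sqrt(mean((est$x_com - xc_true)^2, na.rm = TRUE)), 2e-3)
})

test_that("belt-relative CoP removes the support displacement and filters", {
  fs <- 300
  n <- 6 * fs
  belt <- cumsum(rep(c(0, 1e-3), each = n / 2))
  cop <- sin(2 * pi * 0.5 * seq_len(n) / fs) * 0.01
  rel1 <- cop_relative(cop + belt, belt, fs)
  rel2 <- cop_relative(cop, rep(0, n), fs)
  expect_equal(rel1$cop, rel2$cop, tolerance = 1e-9)
  # DC preserved by the low-pass
  relc <- cop_relative(rep(0.02, n), rep(0, n), fs)
  expect_equal(relc$cop, rep(0.02, n), tolerance = 1e-6)
  # ~0.5 amplitude at the cut-off (two -3 dB passes of the zero-lag filter)
  x10 <- sin(2 * pi * 10 * seq_len(10 * fs) / fs)
  y10 <- cop_relative(x10, numeric(10 * fs), fs)$cop
  core <- 1000:(10 * fs - 1000)
  expect_equal(max(abs(y10[core])), 0.5, tolerance = 0.05)
})

test_that("zero-lag filtering preserves phase of broadband signals", {
  set.seed(1)
  fs <- 200
  x <- rnorm(8 * fs)
  y <- butter_zero_lag(x, fs, 15, order = 4, type = "low")
  cc <- ccf(y, x, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("central differences are exact on affine signals and O(dt^2) on smooth ones", {
  t1 <- seq(0, 1, by = 0.01)
  d <- central_diff(3 + 2 * t1, dt = 0.01)
  expect_equal(as.numeric(d), rep(2, length(t1)), tolerance = 1e-10)
  err_at <- function(dt) {
    tt <- seq(0, 1, by = dt)
    est <- central_diff(sin(2 * pi * tt), dt = dt)
    max(abs(est - 2 * pi * cos(2 * pi * tt))[5:(length(tt) - 5)])
  }
  # quartering dt cuts the interior error by ~16 (second-order accuracy)
  ratio <- err_at(0.02) / err_at(0.005)
  expect_gt(ratio, 10)
})

test_that("stabilogram slope estimators recover planted spectral exponents", {
  for (beta in c(0, 1.5)) {
    slopes <- vapply(1:20, function(s) {
      sway_metrics(synth_sway(beta, 420, 100, seed = s), 100)$slope_low
    }, numeric(1))
    expect_equal(mean(slopes), -beta, tolerance = 0.15)
  }
  m <- suppressWarnings(sway_metrics(rep(1, 420 * 50), 50))
  expect_equal(m$sd_ap, 0)
  expect_warning(sway_metrics(rnorm(100 * 50), 50), "slope omitted")
})

test_that("event-locked averaging pools epochs and converges as 1/sqrt(n)", {
  fs <- 100
  x <- rep(0, 120 * fs)
  template <- sin(2 * pi * seq(0, 1, by = 1 / fs))
  events <- c(20, 40, 60, 80)
  for (ev in events) {
    i <- round(ev * fs)
    x[i:(i + length(template) - 1)] <- template
  }
  ela <- event_locked_average(x, fs, events, window = c(-5, 15))
  expect_equal(nrow(ela$epochs), 4)
  expect_equal(ela$mean, ela$epochs[1, ], tolerance = 1e-12)
  # two trials of 20 events pooled -> 40 epochs
  ev40 <- seq(10, 790, by = 20)
  x40 <- rnorm(810 * fs)
  ela40 <- event_locked_average(x40, fs, ev40, window = c(-5, 14))
  expect_equal(nrow(ela40$epochs), 40)
  # averaging noise shrinks as 1/sqrt(n)
  set.seed(3)
  rms_n <- function(n) {
    ep <- matrix(rnorm(n * 200), n)
    sqrt(mean(colMeans(ep)^2))
  }
  expect_equal(rms_n(100) / rms_n(400), 2, tolerance = 0.35)
  expect_warning(event_locked_average(x, fs, c(20, 119), window = c(-5, 15)),
                 "dropped")
})

test_that("EMG processing normalizes envelopes and recovers burst latency", {
  fs <- 1000
  t <- seq(0, 60, by = 1 / fs)
  # DC input is removed by the band-pass
  dc <- process_emg(rep(3, length(t)), fs = fs)
  expect_lt(max(abs(dc$envelope[1000:50000])), 1e-6)
  # synthetic 100 Hz-carrier burst centered 150 ms after each event
  events <- c(10, 25, 40)
  env_true <- rep(0.05, length(t))
  for (ev in events) env_true <- env_true + exp(-(t - ev - 0.15)^2 / (2 * 0.03^2))
  raw <- sin(2 * pi * 100 * t) * env_true
  out <- process_emg(raw, fs = fs, events = events, window = c(-2, 5))
  expect_equal(max(out$mean), 1)
  expect_true(out$normalized)
  expect_lt(abs(out$peak_latency - 0.15), 0.010)
  # trial-generator bursts recovered within the same tolerance
  tr <- tk_trial()
  so <- process_emg(tr$emg$so_l, tr$emg$so_r, fs, tr$events,
                    window = c(-5, 14), t0 = tr$emg$t[1])
  ta <- process_emg(tr$emg$ta_l, tr$emg$ta_r, fs, tr$events,
                    window = c(-5, 14), t0 = tr$emg$t[1])
  expect_lt(abs(so$peak_latency - 0.15), 0.010)
  expect_lt(abs(ta$peak_latency - 0.20), 0.010)
  z <- suppressWarnings(process_emg(rep(0, length(t)), fs = fs,
                                    events = events, window = c(-2, 5)))
  expect_false(z$normalized)
})

test_that("inverse dynamics recovers static gravity moments and simulator torques", {
  body <- tk_body()
  fs <- 1000
  # static pose: recovered ankle torque equals the gravitational moment
  th <- data.frame(theta_a = rep(0.1, 2 * fs), theta_h = rep(0, 2 * fs))
  id <- inverse_dynamics(th, fs, 0, body, cutoff = NULL)
  g1 <- derive_dynamics_terms(c(0.1, 0), c(0, 0), body)$gravity[1]
  expect_equal(median(id$tau_a), g1, tolerance = 1e-9)
  # zero gravity, zero motion -> zero torque
  b0 <- body_params(g = 1e-12)
  id0 <- inverse_dynamics(th, fs, 0, b0, cutoff = NULL)
  expect_lt(max(abs(c(id0$tau_a, id0$tau_h))), 1e-9)
  # forward/inverse round trip on the noiseless perturbed simulation
  tr <- tk_perturbed()
  seg <- tr[tr$t >= -1 & tr$t <= 5, ]
  belt <- belt_kinematics(perturbation_profile(), seg$t, 0)
  rec <- inverse_dynamics(seg[, c("theta_a", "theta_h")], fs, belt$acc,
                          attr(tr, "body"), cutoff = NULL)
  keep <- !rec$transition
  true_a <- seg$tau_pass_a + seg$tau_act_a + seg$tau_reflex_a
  true_h <- seg$tau_pass_h
  rel <- function(a, b) sqrt(mean((a - b)^2)) / sqrt(mean(b^2))
  expect_lt(rel(rec$tau_a[keep], true_a[keep]), 0.05)
  expect_lt(rel(rec$tau_h[keep], true_h[keep]), 0.05)
})
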