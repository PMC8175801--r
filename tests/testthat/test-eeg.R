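test_that("preprocessing removes offsets, re-references and resamples cleanly", {
  fs_in <- 1024
  t <- seq(0, 10, by = 1 / fs_in)
  x <- cbind(10 + sin(2 * pi * 10 * t), -5 + rnorm(length(t)),
             3 + cos(2 * pi * 4 * t))
  y <- preprocess_eeg(x, fs_in, fs_out = 256)
  expect_lt(max(abs(rowMeans(y))), 1e-9)       # average reference
  expect_lt(abs(mean(y[, 1])), 0.2)            # offsets removed
  # a pure sinusoid survives polyphase resampling with its amplitude
  xs <- cbind(sin(2 * pi * 10 * t), cos(2 * pi * 10 * t))
  ys <- preprocess_eeg(xs, fs_in, fs_out = 256, hp_cutoff = NULL,
                       rereference = FALSE)
  core <- 200:(nrow(ys) - 200)
  expect_equal(max(abs(ys[core, 1])), 1, tolerance = 0.01)
  expect_error(preprocess_eeg(x[, 1, drop = FALSE], fs_in), "2 channels")
})

test_that("ERP equals the epoch for identical epochs and shrinks for pure noise", {
  fs <- 200
  template <- sin(2 * pi * 3 * seq(0, 1, by = 1 / fs))
  arr <- array(rep(template, each = 6), c(6, 1, length(template)))
  ep <- eeg_epochs(arr, fs, "Cz", window = c(0, 1))
  erp <- compute_erp(ep)
  expect_equal(erp$erp[1, ], template)
  set.seed(4)
  rms_for <- function(n) {
    arr <- array(rnorm(n * 400), c(n, 1, 400))
    sqrt(mean(compute_erp(eeg_epochs(arr, fs, "Cz", c(0, 2)))$erp^2))
  }
  expect_equal(rms_for(50) / rms_for(200), 2, tolerance = 0.4)
  expect_error(compute_erp(eeg_epochs(array(0, c(1, 1, 10)), fs, "Cz")), "2 epochs")
})

test_that("planted ERP component latencies are recovered within 5 ms", {
  se <- tk_eeg()
  pk <- erp_peaks(compute_erp(se$epochs), channel = "Cz")
  planted <- se$ground_truth$erp_components
  for (nm in c("P1", "N1", "P2")) {
    expect_lt(abs(pk$latency[pk$peak == nm] -
                    planted$latency[planted$label == nm]), 0.005)
  }
  expect_true(all(pk$present))
  expect_true(pk$amplitude[pk$peak == "P1"] > 0)
  expect_true(pk$amplitude[pk$peak == "N1"] < 0)
  # flat input flags all peaks absent
  flat <- list(t = seq(0, 1, by = 0.005), fs = 200, channels = "Cz",
               erp = matrix(0, 1, 201))
  expect_false(any(erp_peaks(flat, 1)$present))
})

test_that("Morlet transform localizes frequency and scales quadratically", {
  fs <- 250
  t <- seq(-2, 6, by = 1 / fs)
  sine <- sin(2 * pi * 10 * t)
  arr <- array(rep(sine, each = 2), c(2, 1, length(t)))
  ep <- eeg_epochs(arr, fs, "Cz", window = c(-2, 6))
  tfr <- morlet_tfr(ep, freqs = seq(4, 30, by = 1))
  p <- abs(tfr$coeffs[1, 1, , ])^2
  interior <- which(tfr$valid[which(tfr$freqs == 10), ])
  ridge <- apply(p[, interior], 2, which.max)
  expect_true(all(tfr$freqs[ridge] == 10))
  # doubling the amplitude quadruples power everywhere
  ep2 <- eeg_epochs(2 * arr, fs, "Cz", window = c(-2, 6))
  tfr2 <- morlet_tfr(ep2, freqs = seq(4, 30, by = 1))
  expect_equal(abs(tfr2$coeffs)^2, 4 * abs(tfr$coeffs)^2, tolerance = 1e-10)
  expect_error(morlet_tfr(ep, freqs = c(10, 200)), "Nyquist")
})

test_that("Morlet ridge tracks a linear chirp within 1 Hz", {
  fs <- 250
  t <- seq(0, 12, by = 1 / fs)
  f0 <- 5; f1 <- 40
  finst <- f0 + (f1 - f0) * t / max(t)
  phase <- 2 * pi * cumsum(finst) / fs
  arr <- array(sin(phase), c(1, 1, length(t)))
  ep <- eeg_epochs(arr, fs, "Cz", window = c(0, 12))
  tfr <- morlet_tfr(ep, freqs = seq(3, 45, by = 0.5))
  p <- abs(tfr$coeffs[1, 1, , ])^2
  ok <- 0
  checked <- 0
  for (j in seq_along(tfr$times)) {
    fi <- f0 + (f1 - f0) * tfr$times[j] / max(t)
    if (fi < 6 || fi > 38) next
    if (!all(tfr$valid[tfr$freqs >= fi - 1 & tfr$freqs <= fi + 1, j])) next
    checked <- checked + 1
    if (abs(tfr$freqs[which.max(p[, j])] - fi) <= 1) ok <- ok + 1
  }
  expect_gt(checked, 50)
  expect_gt(ok / checked, 0.95)
})

test_that("ERSP is ~0 dB for stationary noise and reflects planted gain steps", {
  set.seed(11)
  fs <- 125
  n_t <- round(20 * fs) + 1
  arr <- array(rnorm(40 * n_t), c(40, 1, n_t))
  ep <- eeg_epochs(arr, fs, "Cz", window = c(-5, 15))
  tfr <- morlet_tfr(ep, freqs = seq(4, 40, by = 1), decim = 5)
  er <- ersp(tfr)
  expect_lt(abs(mean(er$power_db[1, , apply(tfr$valid, 2, all)])), 0.5)
  # time-mean of ERSP over the baseline window is ~0 dB per frequency
  bidx <- which(er$times >= -5 & er$times <= -1 & apply(tfr$valid, 2, all))
  expect_lt(max(abs(rowMeans(er$power_db[1, , bidx]))), 0.2)
  # doubling amplitude in a time window lifts that window by ~6.02 dB
  arr2 <- arr
  lift <- ep$t >= 5 & ep$t <= 10
  arr2[, , lift] <- 2 * arr2[, , lift]
  tfr2 <- morlet_tfr(eeg_epochs(arr2, fs, "Cz", c(-5, 15)),
                     freqs = seq(4, 40, by = 1), decim = 5)
  er2 <- ersp(tfr2)
  inwin <- er2$times >= 6 & er2$times <= 9
  expect_equal(mean(er2$power_db[1, , inwin]), 20 * log10(2), tolerance = 0.7)
})

test_that("bootstrap mask is deterministic and detects a planted rebound", {
  tfr <- tk_tfr()
  m1 <- bootstrap_mask(tfr, n_boot = 300, seed = 21L)
  m2 <- bootstrap_mask(tfr, n_boot = 300, seed = 21L)
  expect_identical(m1, m2)
  er <- ersp(tfr)
  # >= 90% of the planted high-beta rebound patch is significant positive
  rows <- which(tfr$freqs >= 21 & tfr$freqs <= 30)
  cols <- which(tfr$times >= 1.3 & tfr$times <= 4)
  patch_sig <- m1[1, rows, cols] & er$power_db[1, rows, cols] > 0
  expect_gt(mean(patch_sig), 0.9)
  # masked presentation sets non-significant cells to 0 dB
  ermask <- apply_ersp_mask(er, m1)
  expect_true(all(ermask$power_db_masked[!m1] == 0))
})

test_that("ITC is 1 for identical epochs, amplitude-invariant, ~0.14 for null phases", {
  fs <- 125
  t <- seq(-2, 6, by = 1 / fs)
  base <- sin(2 * pi * 10 * t)
  arr <- array(rep(base, each = 8), c(8, 1, length(t)))
  ep <- eeg_epochs(arr, fs, "Cz", c(-2, 6))
  tfr <- morlet_tfr(ep, freqs = seq(6, 14, by = 1))
  it <- itc(tfr)
  valid <- tfr$valid[5, ]
  expect_true(all(abs(it$itc[1, 5, valid] - 1) < 1e-6))
  # rescaling epochs leaves ITC unchanged
  scl <- array(rep(seq(0.5, 4, length.out = 8), times = length(t) * 1),
               c(8, 1, length(t)))
  tfr_s <- morlet_tfr(eeg_epochs(arr * scl, fs, "Cz", c(-2, 6)),
                      freqs = seq(6, 14, by = 1))
  expect_equal(itc(tfr_s)$itc, it$itc, tolerance = 1e-8)
  # null: independent phases at n = 40 give mean ITC ~ sqrt(pi)/2/sqrt(40)
  set.seed(2)
  arrn <- array(rnorm(40 * 1 * length(t)), c(40, 1, length(t)))
  tfrn <- morlet_tfr(eeg_epochs(arrn, fs, "Cz", c(-2, 6)),
                     freqs = seq(6, 14, by = 1))
  itn <- itc(tfrn)
  vals <- itn$itc[1, , ][tfrn$valid]
  expect_equal(mean(vals), sqrt(pi) / 2 / sqrt(40), tolerance = 0.15)
})

test_that("band time courses aggregate ERSP rows and locate modulation peaks", {
  tfr <- tk_tfr()
  er <- ersp(tfr)
  bt <- band_timecourse(er, bands = band_set(gamma = c(31, 40)), channel = "Cz")
  gt <- tk_eeg()$ground_truth$band_modulations
  pk_ers <- band_peak_latency(bt, "high_beta", window = c(1, 4.5), sign = "ers")
  expect_equal(pk_ers$latency, gt$t_peak[gt$label == "high_beta_ers"],
               tolerance = 0.25)
  pk_erd <- band_peak_latency(bt, "high_beta", window = c(0.1, 0.95),
                              sign = "erd")
  expect_equal(pk_erd$latency, gt$t_peak[gt$label == "high_beta_erd"],
               tolerance = 0.25)
  # constant ERSP gives a constant band series
  er3 <- er
  er3$power_db[] <- 3
  bt3 <- band_timecourse(er3, channel = 1)
  expect_true(all(bt3$db == 3))
  expect_error(band_timecourse(er, bands = list(x = c(100, 120))), "grid")
})

test_that("sustained-significance onset detection matches its definition", {
  # synthetic mask true on [1, 4] s
  er <- list(power_db = array(1, c(1, 4, 81)),
             freqs = c(21, 24, 27, 30), times = seq(-1, 7, by = 0.1),
             channels = "Cz")
  mask <- array(FALSE, c(1, 4, 81))
  mask[1, , er$times >= 1 & er$times <= 4] <- TRUE
  expect_equal(ers_onset(er, mask, c(21, 30), t_min = 0), 1.0)
  # no sustained run -> absent
  mask2 <- array(FALSE, c(1, 4, 81))
  mask2[1, , 30] <- TRUE
  expect_true(is.na(ers_onset(er, mask2, c(21, 30), t_min = 0,
                              min_duration = 0.5)))
  # full pipeline: planted rebound significant from ~1 s
  tfr <- tk_tfr()
  erp <- ersp(tfr)
  mk <- bootstrap_mask(tfr, n_boot = 300, seed = 31L)
  onset <- ers_onset(erp, mk, c(21, 30), channel = "Cz", t_min = 0.5)
  expect_gte(onset, 0.8)
  expect_lte(onset, 1.4)
})

test_that("baseline-vs-quiet comparison flags ties and localizes planted shifts", {
  freqs <- seq(2, 60, by = 0.5)
  nb <- length(freqs)
  base <- matrix(rep(10 + freqs * 0.1, each = 9), 9)
  # identical paired spectra -> every bin tied, nothing significant
  r0 <- baseline_vs_quiet(base, base, freqs)
  expect_true(all(r0$tied))
  expect_false(any(r0$significant))
  # a planted shift confined to 2-4.5 Hz keeps any significance confined
  # to that neighbourhood (with 9 paired samples the smallest attainable
  # signed-rank p-value caps the power of so narrow a band after FDR)
  set.seed(6)
  quiet <- base + matrix(rnorm(9 * nb, sd = 0.05), 9)
  pert <- base + matrix(rnorm(9 * nb, sd = 0.05), 9)
  pert[, freqs <= 4.5] <- pert[, freqs <= 4.5] + 1
  r <- baseline_vs_quiet(pert, quiet, freqs)
  expect_false(any(r$significant[freqs > 5]))
  expect_true(all(r$p[freqs <= 4.5] < 0.01))
  # a broad planted shift passes the FDR threshold across its whole band
  pert2 <- base + matrix(rnorm(9 * nb, sd = 0.05), 9)
  pert2[, freqs <= 20] <- pert2[, freqs <= 20] + 1
  r2 <- baseline_vs_quiet(pert2, quiet, freqs)
  expect_gt(mean(r2$significant[freqs <= 20]), 0.9)
  expect_false(any(r2$significant[freqs > 21]))
  expect_error(baseline_vs_quiet(base[1:3, ], base[1:3, ]), "5")
})
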