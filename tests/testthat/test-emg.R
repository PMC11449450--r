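test_that("envelope is the rectified low-passed signal", {
  fs <- 1000
  zero <- emg_envelope(mast_ts(rep(0, 600), fs))
  expect_equal(zero$envelope$x, rep(0, 600))

  # +-1 V square wave at 5 Hz: envelope ~ 1 V (the rectified mean)
  t <- seq(0, 2, by = 1 / fs)
  sq <- mast_ts(sign(sin(2 * pi * 5 * t)), fs)
  env <- emg_envelope(sq)
  mid <- 500:1500
  expect_true(all(abs(env$envelope$x[mid] - 1) < 0.02))

  # non-negative and invariant to sign flip of the raw signal
  set.seed(14)
  x <- rnorm(1500)
  e1 <- emg_envelope(mast_ts(x, fs))
  e2 <- emg_envelope(mast_ts(-x, fs))
  expect_true(all(e1$envelope$x >= 0))
  expect_equal(e1$envelope$x, e2$envelope$x, tolerance = 1e-12)

  expect_error(emg_envelope(mast_ts(rep(0, 100), fs = 50)), "60 Hz")
})

test_that("envelope tracks the generating activation on synthetic EMG", {
  fs <- 2000
  t <- seq(0, 3, by = 1 / fs)
  act <- mast_ts(pmax(0, sin(2 * pi * t))^2, fs)
  emg <- synthesize_emg(act, seed = 77)
  env <- emg_envelope(emg)
  expect_gt(stats::cor(env$envelope$x, act$x), 0.9)
})

test_that("synthetic EMG baseline has the requested noise floor", {
  fs <- 2000
  act <- mast_ts(rep(0, 4000), fs)
  emg <- synthesize_emg(act, noise_floor_sd = 0.01, seed = 3)
  expect_equal(stats::sd(emg$x), 0.01, tolerance = 0.05)
  expect_error(synthesize_emg(act, carrier_band = c(80, 1200)), "Nyquist")
})

test_that("burst detection finds sustained threshold crossings", {
  fs <- 1000
  n <- 3000
  env <- rep(0.005, n)
  env[1201:1800] <- 1
  env <- mast_ts(env, fs)
  b <- detect_bursts(env, baseline = c(1, 1000))
  expect_equal(nrow(b), 1)
  expect_equal(b$onset_frame, 1201)
  expect_equal(b$offset_frame, 1800)

  # always below threshold: no bursts
  flat <- mast_ts(rep(0.005, n), fs)
  expect_equal(nrow(detect_bursts(flat, baseline = c(1, 1000))), 0)

  # round trip through synthetic EMG: onset within the envelope smoothing
  set.seed(15)
  act <- rep(0, n)
  act[1501:2500] <- 1
  emg <- synthesize_emg(mast_ts(act, fs), seed = 16)
  env2 <- emg_envelope(emg)
  b2 <- major_bursts(detect_bursts(env2, baseline = c(1, 1200)))
  expect_equal(nrow(b2), 1)
  expect_lt(abs(b2$onset_frame - 1501) / fs, 0.025)
})

test_that("detected onset is non-decreasing in the threshold", {
  # deterministic unimodal envelope: the up-crossing of a rising front can
  # only move later as the threshold is raised
  fs <- 1000
  t <- (0:2999) / fs
  env <- mast_ts(exp(-((t - 1.5) / 0.3)^2), fs)
  last_onset <- -Inf
  for (thr in c(0.05, 0.1, 0.3, 0.5, 0.7)) {
    b <- detect_bursts(env, threshold = thr)
    expect_equal(nrow(b), 1)
    expect_gte(b$onset_frame, last_onset)
    last_onset <- b$onset_frame
  }
})

test_that("recruitment ratio integrates envelopes over matched bursts", {
  fs <- 1000
  n <- 3000
  base <- rep(0.001, n)
  ref <- base; ref[1001:2000] <- 1
  test <- base; test[1001:2000] <- 0.5
  ref_e <- mast_ts(ref, fs); test_e <- mast_ts(test, fs)
  b_ref <- detect_bursts(ref_e, baseline = c(1, 900))
  b_test <- detect_bursts(test_e, baseline = c(1, 900))
  expect_equal(recruitment_ratio(ref_e, ref_e, b_ref, b_ref), 1.0)
  expect_equal(recruitment_ratio(test_e, ref_e, b_test, b_ref), 0.5,
               tolerance = 1e-6)
  # scale consistency: scaling the test envelope scales the ratio
  test2 <- mast_ts(2 * test, fs)
  expect_equal(recruitment_ratio(test2, ref_e, b_test, b_ref), 1.0,
               tolerance = 1e-6)
  # zero test integral
  zero <- mast_ts(rep(0, n), fs)
  expect_equal(recruitment_ratio(zero, ref_e, b_test, b_ref), 0)
  expect_error(recruitment_ratio(ref_e, zero, b_ref, b_test), "zero")
})

test_that("balancing vs working synthetic envelopes recover 47% recruitment", {
  rep_w <- report_working()
  rep_b <- report_balancing()
  rr <- recruitment_ratio(rep_b$envelope, rep_w$envelope,
                          test_bursts = rep_b$bursts_major,
                          reference_bursts = rep_w$bursts_major)
  expect_equal(rr, 0.47, tolerance = 0.03 / 0.47)
})

test_that("logistic current-recruitment fit recovers exact parameters", {
  I <- seq(0, 10, by = 0.5)
  f_true <- 1 / (1 + exp(-(I - 4) / 0.8))
  curve <- fit_current_recruitment(I, 6 * f_true)
  expect_equal(curve$midpoint_ma, 4, tolerance = 1e-6)
  expect_equal(curve$slope_ma, 0.8, tolerance = 1e-6)
  # inverse at 0.5 is the midpoint
  expect_equal(recruitment_inverse(curve, 0.5), curve$midpoint_ma,
               tolerance = 1e-9)
  # degenerate inputs
  expect_error(fit_current_recruitment(I, rep(2, length(I))),
               "dynamic range")
  expect_error(fit_current_recruitment(1:4, 1:4), "at least 5")
  expect_error(fit_current_recruitment(I, 6 / (1 + exp((I - 15) / 2))),
               "fit-quality")
})

test_that("stimulation commands replay the envelope through the curve", {
  I <- seq(0, 10, by = 0.5)
  curve <- fit_current_recruitment(I, 1 / (1 + exp(-(I - 4) / 0.8)))
  fs <- 1000
  env <- mast_ts(c(rep(0, 100), seq(0, 1, length.out = 200), rep(0, 100)),
                 fs)
  cmd <- stimulation_command(env, curve, target_recruitment = 1)
  expect_equal(max(cmd$x), curve$ceiling_ma, tolerance = 1e-9)
  expect_equal(cmd$x[1], curve$floor_ma, tolerance = 1e-9)

  # command at envelope peak for a 47% target matches a numeric root-finder
  cmd47 <- stimulation_command(env, curve, target_recruitment = 0.47)
  f_of <- function(I) 1 / (1 + exp(-(I - 4) / 0.8))
  i_root <- stats::uniroot(function(I) f_of(I) - 0.47, c(0, 10),
                           tol = 1e-12)$root
  expect_equal(max(cmd47$x), i_root, tolerance = 1e-6)

  expect_error(stimulation_command(env, curve, target_recruitment = 1.2),
               "\\(0, 1\\]")
})

test_that("replayed commands preserve the working >= balancing work ordering", {
  # map working (100%) and balancing (47%) commands through the same
  # logistic back to recruitment, drive the muscle, and compare work
  I <- seq(0, 10, by = 0.5)
  curve <- fit_current_recruitment(I, 1 / (1 + exp(-(I - 4) / 0.8)))
  p <- hill_params()
  fs <- 500
  t <- seq(0, 1, by = 1 / fs)
  env <- mast_ts(pmax(0, sin(2 * pi * t))^2, fs)
  f_of <- function(I) 1 / (1 + exp(-(I - curve$midpoint_ma) /
                                     curve$slope_ma))
  work_for <- function(target) {
    cmd <- stimulation_command(env, curve, target)
    recr <- mast_ts(pmin(1, f_of(cmd$x)), fs)
    a <- simulate_activation(recr, p)
    L <- mast_ts(p$l0 * (1 - 0.15 * (1 - cos(2 * pi * t))), fs)
    f <- simulate_muscle_force(L, a, p)
    loop_work(f, L, muscle_mass_g = 0.691)$positive_work
  }
  expect_gte(work_for(1), work_for(0.47))
})
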