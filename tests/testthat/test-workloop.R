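test_that("twitch kinetics measure rise and half-relaxation geometrically", {
  fs <- 10000
  # triangular force: 30 ms linear rise, 60 ms linear fall
  t_rise <- seq(0, 0.03, by = 1 / fs)
  t_fall <- seq(1 / fs, 0.06, by = 1 / fs)
  force <- mast_ts(c(t_rise / 0.03, 1 - t_fall / 0.06), fs)
  k <- twitch_kinetics(force, stim_time_s = 0)
  expect_equal(k$rise_ms, 30, tolerance = 1e-6)
  expect_equal(k$half_relaxation_ms, 30, tolerance = 1e-3)

  expect_error(twitch_kinetics(mast_ts(rep(0, 100), fs), stim_time_s = 0))
})

test_that("isometric stress converts N/mm^2 to kN/m^2", {
  expect_equal(isometric_stress(1, 1), 1000)
  expect_equal(isometric_stress(7.39, 55.6), 132.9, tolerance = 1e-3)
  expect_error(isometric_stress(1, 0), "positive")
})

test_that("twitch to tetanus ratio is a guarded quotient", {
  expect_equal(twitch_tetanus_ratio(4.3, 10), 0.43)
  expect_equal(twitch_tetanus_ratio(5, 5), 1)
  expect_error(twitch_tetanus_ratio(1, 0), "positive")
})

test_that("loop work handles elementary cases exactly", {
  fs <- 100
  n <- 51
  # constant 1 N over 2 mm shortening, 1 g muscle
  f <- mast_ts(rep(1, n), fs)
  L <- mast_ts(seq(10, 8, length.out = n), fs)
  lw <- loop_work(f, L, muscle_mass_g = 1)
  expect_equal(lw$positive_work, 2000)
  expect_equal(lw$negative_work, 0)
  expect_equal(lw$net_work, 2000)

  # zero force over any closed loop
  Lc <- mast_ts(10 + sin(2 * pi * (0:(n - 1)) / (n - 1)), fs)
  lw0 <- loop_work(mast_ts(rep(0, n), fs), Lc, 1)
  expect_equal(c(lw0$positive_work, lw0$negative_work, lw0$net_work),
               c(0, 0, 0))

  expect_error(loop_work(f, mast_ts(rep(1, n + 1), fs), 1), "common time")
  expect_error(loop_work(f, L, 0), "positive")
})

test_that("spring loops match the analytic and dense-quadrature oracle", {
  k_spring <- 2; A <- 1; L0 <- 10
  for (N in c(512, 4096)) {
    t <- seq(0, 1, length.out = N + 1)
    L <- mast_ts(L0 + A * sin(2 * pi * t), N)
    f <- mast_ts(k_spring * A * sin(2 * pi * t), N)
    lw <- loop_work(f, L, muscle_mass_g = 1000)   # 1 kg: raw mJ
    expect_equal(lw$net_work, 0, tolerance = 1e-9)
    expect_equal(lw$positive_work, k_spring * A^2, tolerance = 1e-6)
    expect_equal(lw$negative_work, -k_spring * A^2, tolerance = 1e-6)
  }
})

test_that("trapezoidal work converges at second order on smooth loops", {
  # nonlinear force-length loop; reference from a very dense grid
  loop_err <- function(N) {
    t <- seq(0, 1, length.out = N + 1)
    L <- 10 + sin(2 * pi * t)
    f <- 2 + (L - 10)^3 + 0.5 * cos(2 * pi * t)
    lw <- loop_work(mast_ts(f, N), mast_ts(L, N), 1000)
    lw$net_work
  }
  ref <- loop_err(2^16)
  e1 <- abs(loop_err(256) - ref)
  e2 <- abs(loop_err(512) - ref)
  expect_gt(e1 / e2, 3)
  expect_lt(e1 / e2, 5)
})

test_that("net work equals positive plus negative for every cycle", {
  rep_w <- report_working()
  for (lw in rep_w$workloops) {
    expect_identical(lw$net_work, lw$positive_work + lw$negative_work)
    expect_gte(lw$positive_work, 0)
    expect_lte(lw$negative_work, 0)
  }
})

test_that("time reversal swaps positive and negative work magnitudes", {
  set.seed(25)
  N <- 400
  t <- seq(0, 1, length.out = N)
  f <- 1 + pmax(0, sin(2 * pi * t + 0.4))
  L <- 10 + sin(2 * pi * t)
  a <- loop_work(mast_ts(f, N), mast_ts(L, N), 1)
  b <- loop_work(mast_ts(f, N), mast_ts(rev(L), N), 1)
  expect_equal(a$positive_work, -b$negative_work, tolerance = 1e-9)
  expect_equal(a$negative_work, -b$positive_work, tolerance = 1e-9)
})

test_that("counter-clockwise force-length loops yield net positive work", {
  # force high while shortening, low while lengthening
  N <- 1000
  t <- seq(0, 1, length.out = N)
  L <- 10 + cos(2 * pi * t)
  f <- 1 + 0.8 * sin(2 * pi * t)   # leads length by a quarter cycle
  lw <- loop_work(mast_ts(f, N), mast_ts(L, N), 1)
  expect_gt(lw$net_work, 0)
})

test_that("power integrates to net work and matches constant-velocity case", {
  N <- 1000
  fs <- N
  t <- seq(0, 1, length.out = N + 1)
  # constant force, constant shortening velocity
  f <- mast_ts(rep(2, N + 1), fs)
  L <- mast_ts(seq(12, 10, length.out = N + 1), fs)
  P <- instantaneous_power(f, L, muscle_mass_g = 1000)
  # F = 2 N, v = 2 mm/s, m = 1 kg: P = 4 mW/kg = 0.004 W/kg
  expect_equal(P$x[2:(N - 1)], rep(0.004, N - 2), tolerance = 1e-9)

  # isometric segment: zero power
  Liso <- mast_ts(rep(10, N + 1), fs)
  expect_equal(instantaneous_power(f, Liso, 1000)$x, rep(0, N + 1))

  # integral of power equals net loop work (discrete identity)
  L2 <- mast_ts(10 + sin(2 * pi * t) + 0.3 * sin(4 * pi * t + 1), fs)
  f2 <- mast_ts(2 + 1.5 * sin(2 * pi * t + 0.7), fs)
  lw <- loop_work(f2, L2, 1000)
  ip <- 1000 * mastloop:::trapz_sum(instantaneous_power(f2, L2, 1000)$x,
                                    1 / fs)
  expect_equal(ip, lw$net_work, tolerance = 1e-9)
})

test_that("net cycle power is net work over duration", {
  N <- 76   # 0.3 s at 250 Hz
  f <- mast_ts(rep(0, N), 250)
  L <- mast_ts(rep(10, N), 250)
  lw <- loop_work(f, L, 1)
  lw$net_work <- -903
  lw$cycle_duration <- 0.3
  expect_equal(net_cycle_power(lw), -3.01, tolerance = 1e-9)
  lw$net_work <- 0
  expect_equal(net_cycle_power(lw), 0)
  lw$cycle_duration <- 0
  expect_error(net_cycle_power(lw), "positive")
})

test_that("per-phase work attribution covers the whole cycle", {
  tr <- trial_working()
  rep_w <- report_working()
  for (k in seq_along(rep_w$workloops)) {
    lw <- rep_w$workloops[[k]]
    expect_equal(sum(lw$phase_work), lw$net_work, tolerance = 1e-9)
  }
})
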