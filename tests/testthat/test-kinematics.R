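test_that("rigid pose estimation recovers constructed transforms", {
  # identity
  p <- estimate_rigid_pose(tpl4, tpl4)
  expect_equal(p$rotation, diag(3), tolerance = 1e-12)
  expect_equal(p$translation, c(0, 0, 0), tolerance = 1e-12)

  # 30 degrees about z then translate (1, 2, 3) mm
  R <- mastloop:::rot_z(30)
  obs <- sweep(tpl4 %*% t(R), 2, c(1, 2, 3), `+`)
  p <- estimate_rigid_pose(tpl4, obs)
  expect_lt(max(abs(p$rotation - R)), 1e-9)
  expect_lt(max(abs(p$translation - c(1, 2, 3))), 1e-9)
  expect_equal(det(p$rotation), 1, tolerance = 1e-9)

  # degenerate inputs
  expect_error(estimate_rigid_pose(tpl4[1:2, ], tpl4[1:2, ]), "3 paired")
  line <- cbind(1:4, 2 * (1:4), 3 * (1:4))
  expect_error(estimate_rigid_pose(line, line), "collinear")
})

test_that("pose estimation round trip is the identity on noiseless data", {
  set.seed(11)
  for (i in 1:10) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- runif(1, -60, 60)
    R <- mastloop:::rot_z(ang)  # arbitrary axis via composition
    R <- mastloop:::rot_x(runif(1, -40, 40)) %*%
      mastloop:::rot_y(runif(1, -40, 40)) %*% R
    tr <- rnorm(3, sd = 5)
    obs <- sweep(tpl4 %*% t(R), 2, tr, `+`)
    p <- estimate_rigid_pose(tpl4, obs)
    back <- apply_pose(p, tpl4)
    expect_lt(max(abs(back - obs)), 1e-9)
  }
})

test_that("noisy pose residuals scale with the marker noise", {
  set.seed(21)
  sd_noise <- 0.05
  rms <- replicate(100, {
    obs <- tpl4 + matrix(rnorm(12, 0, sd_noise), 4, 3)
    estimate_rigid_pose(tpl4, obs)$rmse
  })
  expect_true(all(rms <= 3 * sd_noise))
})

test_that("jaw rotations decompose the condylar hinge correctly", {
  jcs <- jcs_definition(c(0, 0, -6), c(0, 0, 6), occlusal_dir = c(1, 0, 0))
  mk_pose <- function(R) structure(list(rotation = R,
                                        translation = c(0, 0, 0), rmse = 0,
                                        frame_index = 1L),
                                   class = "rigid_pose")
  ident <- mk_pose(diag(3))
  # neutral posture maps to zero
  k <- jaw_rotations(list(ident), list(ident), jcs)
  expect_equal(c(k$pitch$x, k$yaw$x, k$roll$x), c(0, 0, 0),
               tolerance = 1e-9)
  # pure 12-degree rotation about the JCS z-axis is pure pitch
  k <- jaw_rotations(list(ident), list(mk_pose(mastloop:::rot_z(12))), jcs)
  expect_equal(k$pitch$x, 12, tolerance = 1e-9)
  expect_equal(k$yaw$x, 0, tolerance = 1e-9)
  expect_equal(k$roll$x, 0, tolerance = 1e-9)
  # composed pitch and yaw decompose exactly
  k <- jaw_rotations(list(ident),
                     list(mk_pose(mastloop:::rot_z(10) %*%
                                    mastloop:::rot_y(4))), jcs)
  expect_equal(k$pitch$x, 10, tolerance = 1e-9)
  expect_equal(k$yaw$x, 4, tolerance = 1e-9)
})

test_that("zero-phase Butterworth matches its analytic magnitude response", {
  # DC gain is one: a constant trace passes through unchanged
  const <- mast_ts(rep(3, 400), fs = 250)
  expect_equal(butterworth_lowpass(const)$x, rep(3, 400), tolerance = 1e-8)

  # sinusoid attenuation matches the squared (two-pass) response
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  for (f in c(40, 100)) {
    y <- butterworth_lowpass(mast_ts(sin(2 * pi * f * t), fs), 25, 4)
    mid <- 400:1600
    X <- cbind(sin(2 * pi * f * t[mid]), cos(2 * pi * f * t[mid]))
    amp <- sqrt(sum(stats::coef(stats::lm(y$x[mid] ~ X - 1))^2))
    expect_equal(amp, butter2_gain(f, 25, fs, 4), tolerance = 0.01)
  }

  expect_error(butterworth_lowpass(const, cutoff = 200), "Nyquist")
})

test_that("tracking precision matches the analytic inter-point distance sd", {
  # noiseless rigid markers give zero
  still <- mast_ts(rep(5, 300), fs = 250)
  expect_equal(tracking_precision(still)$precision, 0)

  # two noisy points: distance sd ~ sqrt(2) * coordinate sd
  set.seed(33)
  sd_c <- 0.03
  n <- 4000
  p1 <- matrix(rnorm(3 * n, 0, sd_c), n, 3)
  p2 <- matrix(rnorm(3 * n, 0, sd_c), n, 3)
  p2[, 1] <- p2[, 1] + 10
  d <- sqrt(rowSums((p1 - p2)^2))
  prec <- tracking_precision(mast_ts(d, 250))$precision
  expect_equal(prec, sqrt(2) * sd_c, tolerance = 0.1)

  # invariant to rigid motion of the whole body (distances unchanged)
  R <- mastloop:::rot_z(25)
  p1r <- p1 %*% t(R); p2r <- p2 %*% t(R)
  dr <- sqrt(rowSums((p1r - p2r)^2))
  expect_equal(tracking_precision(mast_ts(dr, 250))$precision, prec,
               tolerance = 1e-12)

  expect_error(tracking_precision(list()), "at least one")
})

test_that("cycle segmentation counts peak-to-peak oscillations", {
  # 4 Hz sinusoid over 2 s: 8 maxima, 7 full cycles
  t <- seq(0, 2, by = 1 / 250)
  cyc <- segment_cycles(mast_ts(sin(2 * pi * 4 * t), fs = 250))
  expect_length(cyc, 7)

  # constant trace: empty with a warning
  expect_warning(out <- segment_cycles(mast_ts(rep(1, 500), fs = 250)),
                 "no cycles")
  expect_length(out, 0)

  # synthetic trial recovers its designed cycle count
  tr <- trial_working()
  cyc <- segment_cycles(butterworth_lowpass(tr$gape))
  expect_length(cyc, tr$truth$n_cycles)
})

test_that("phase classification recovers constructed boundaries", {
  # symmetric cosine cycle with a 50% threshold: boundaries mirror
  g <- cos(2 * pi * seq(0, 100, 1) / 100)
  ph <- classify_phases(g, threshold = 0.5)
  expect_equal(ph$fc_end, 100 - ph$so_end, tolerance = 1.1)
  expect_equal(ph$sc_end, 50, tolerance = 1.1)
  expect_equal(sum(ph$durations), 100)

  # piecewise-linear chew cycle built from the knot construction
  ph <- classify_phases(gape_cycle_fixture(), threshold = 0.25)
  expect_equal(ph$fc_end, 18.66, tolerance = 2 / 18.66)
  expect_equal(ph$sc_end, 60.51, tolerance = 2 / 60.51)
  expect_equal(ph$so_end, 68.84, tolerance = 2 / 68.84)

  # monotonic gape has no occlusion
  expect_error(classify_phases(seq(1, 0, length.out = 101)), "monoton")
})

test_that("phase durations sum to 100% on every segmented synthetic cycle", {
  rep_w <- report_working()
  for (ph in rep_w$phases) {
    expect_equal(sum(ph$durations), 100, tolerance = 1e-12)
    expect_true(ph$fc_end <= ph$sc_end && ph$sc_end <= ph$so_end)
  }
})

test_that("filtering is order-stable with respect to segmentation", {
  set.seed(5)
  t <- seq(0, 2.5, by = 1 / 250)
  clean <- 7.5 * (1 + sin(2 * pi * 3 * t))
  n_ref <- length(segment_cycles(butterworth_lowpass(mast_ts(clean, 250))))
  for (i in 1:5) {
    noisy <- clean + rnorm(length(t), 0, 0.1 * 7.5)
    n <- length(segment_cycles(butterworth_lowpass(mast_ts(noisy, 250))))
    expect_equal(n, n_ref)
  }
})
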