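test_that("marker synthesis applies poses exactly when noiseless", {
  ident <- structure(list(rotation = diag(3), translation = c(0, 0, 0),
                          rmse = 0, frame_index = 1L), class = "rigid_pose")
  poses <- rep(list(ident), 5)
  tab <- synthesize_markers(poses, tpl4, noise_sd = 0)
  for (i in 1:4) {
    expect_equal(unname(as.matrix(
      tab[, paste0("m", i, c("_x", "_y", "_z"))])),
      matrix(rep(tpl4[i, ], each = 5), 5, 3), tolerance = 1e-12)
  }

  # known 10-degree pitch rotation reproduces the analytic positions
  R <- mastloop:::rot_z(10)
  rot_pose <- structure(list(rotation = R, translation = c(0, 0, 0),
                             rmse = 0, frame_index = 1L),
                        class = "rigid_pose")
  tab2 <- synthesize_markers(list(rot_pose), tpl4, noise_sd = 0)
  expected <- tpl4 %*% t(R)
  for (i in 1:4) {
    expect_equal(as.numeric(tab2[1, paste0("m", i, c("_x", "_y", "_z"))]),
                 unname(expected[i, ]), tolerance = 1e-12)
  }

  line <- cbind(1:4, 0, 0)
  expect_error(synthesize_markers(poses, line), "collinear")
})

test_that("noisy marker distances have the analytic variance", {
  ident <- structure(list(rotation = diag(3), translation = c(0, 0, 0),
                          rmse = 0, frame_index = 1L), class = "rigid_pose")
  poses <- rep(list(ident), 1000)
  tab <- synthesize_markers(poses, tpl4, noise_sd = 0.05, seed = 55)
  d <- sqrt((tab$m1_x - tab$m2_x)^2 + (tab$m1_y - tab$m2_y)^2 +
              (tab$m1_z - tab$m2_z)^2)
  expect_equal(stats::sd(d), sqrt(2) * 0.05, tolerance = 0.1)
})

test_that("trial generation is bit-identical under a fixed seed", {
  a <- synthesize_trial("working", n_cycles = 2, seed = 9)
  b <- synthesize_trial("working", n_cycles = 2, seed = 9)
  expect_identical(a, b)
  c2 <- synthesize_trial("working", n_cycles = 2, seed = 10)
  expect_false(identical(a$emg$x, c2$emg$x))
  expect_error(synthesize_trial("chewing"))
})

test_that("trial truth records the scenario design values", {
  tw <- trial_working()
  expect_equal(tw$truth$strain_ptp, 0.32)
  expect_equal(tw$truth$onset_pct, 61.09)
  expect_equal(tw$truth$offset_pct, 10.99)
  expect_equal(tw$truth$recruitment, 1)
  tb <- trial_balancing()
  expect_equal(tb$truth$strain_ptp, 0.23)
  expect_equal(tb$truth$offset_pct, 1.45)
  expect_equal(tb$truth$recruitment, 0.47)
  # net = positive + negative in the truth work table
  expect_equal(tw$truth$work[, "net"],
               tw$truth$work[, "positive"] + tw$truth$work[, "negative"],
               tolerance = 1e-12)
})

test_that("trial traces share the kinematic time base and bead geometry", {
  tr <- trial_working()
  expect_equal(length(tr$force$x), length(tr$strain$x))
  expect_equal(tr$force$fs, tr$fs_kin)
  # imposed length stays on the ascending limb and plateau
  expect_lte(max(tr$length_mm$x), tr$params$l0 + 1e-12)
  # bead separation encodes the strain trajectory
  m <- tr$marker_tables$digastric
  d <- sqrt((m$db1_x - m$db2_x)^2 + (m$db1_y - m$db2_y)^2 +
              (m$db1_z - m$db2_z)^2)
  d_true <- tr$truth$bead_rest_mm * (1 + tr$strain$x)
  expect_lt(max(abs(d - d_true)), 0.3)   # bounded by marker noise
})

test_that("trials round-trip through the CSV + JSON bundle format", {
  dir <- tempfile("trial")
  tr <- synthesize_trial("balancing", n_cycles = 2, seed = 12)
  write_trial(tr, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "markers_skull.csv", "markers_mandible.csv", "markers_digastric.csv",
    "emg.csv", "force_length.csv", "truth.json")))))
  emg <- read_emg_csv(file.path(dir, "emg.csv"))
  expect_equal(emg$x, tr$emg$x, tolerance = 1e-9)
  expect_equal(emg$fs, tr$fs_emg, tolerance = 1e-6)
  fl <- read_force_length_csv(file.path(dir, "force_length.csv"))
  expect_equal(fl$force$x, tr$force$x, tolerance = 1e-9)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$strain_ptp, 0.23)
  unlink(dir, recursive = TRUE)
})
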