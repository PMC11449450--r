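# shared fixtures, built in code

# non-collinear 4-marker template (mm)
tpl4 <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 8, 0), c(3, 2, 6))

# a sample with exactly the requested mean and sd (affine transform)
sample_with <- function(mean, sd, n = 4) {
  z <- seq_len(n)
  mean + sd * (z - base::mean(z)) / stats::sd(z)
}

# squared magnitude of the zero-phase digital Butterworth low-pass
# (bilinear design, hence the tangent prewarping)
butter2_gain <- function(f, fc, fs, order) {
  1 / (1 + (tan(pi * f / fs) / tan(pi * fc / fs))^(2 * order))
}

# piecewise-linear masticatory gape cycle on a normalized grid, built
# directly from knot values (independent of the package's generator)
gape_cycle_fixture <- function(n = 1001,
                               knots_phi = c(0, 18.66, 60.51, 68.84, 100),
                               knots_gape = c(15, 3, 0, 0.5, 15)) {
  grid <- seq(0, 100, length.out = n)
  stats::approx(knots_phi, knots_gape, xout = grid)$y
}

# one cached synthetic trial pair per test run
trial_working <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- synthesize_trial("working", seed = 101)
    val
  }
})
trial_balancing <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- synthesize_trial("balancing", seed = 102)
    val
  }
})
report_working <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- run_trial(trial_working())
    val
  }
})
report_balancing <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- run_trial(trial_balancing())
    val
  }
})
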