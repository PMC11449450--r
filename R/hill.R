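#' Hill-type muscle parameters
#'
#' Parameter set for the Hill-type surrogate muscle used by the trial
#' synthesizer: a first-order activation stage feeding a contractile element
#' with multiplicative force-length and force-velocity scaling and a passive
#' elastic element engaged beyond optimal length.
#'
#' The default time constants and active-state duration are calibrated (see
#' [calibrate_hill_params()]) so that a single supramaximal 0.2 ms pulse
#' produces an isometric twitch with a rise time of about 36.25 ms and a
#' half-relaxation time of about 31.0 ms, and so that the twitch:tetanus
#' ratio (single pulse vs fused 200 Hz tetanus) is about 0.43 -- the
#' isometric contractile profile of a fast jaw-opening muscle. The default
#' `f_max` of 7.39 N corresponds to an isometric stress of 132.9 kN m^-2
#' acting over a 55.6 mm^2 physiological cross-section.
#'
#' @param f_max Maximal isometric tetanic force P0 (N).
#' @param l0 Optimal fascicle length (mm), the length of maximal twitch force.
#' @param tau_act Activation time constant (ms).
#' @param tau_deact Deactivation time constant (ms).
#' @param excitation_ms Active-state duration triggered by one stimulus pulse
#'   (ms); successive pulses closer than this fuse into sustained excitation.
#' @param fl_width Width of the force-length ascending limb as a fraction of
#'   `l0`; force-length scaling is parabolic below `l0` and 1 on the plateau.
#' @param v_max Maximal shortening velocity (optimal lengths per second).
#' @param hill_curvature Hill hyperbola shape constant a/P0, in (0, 1).
#' @param passive_stiffness Passive force slope beyond `l0` (N per `l0` of
#'   stretch).
#' @param density Muscle density (g mm^-3), default 0.001056.
#' @return An object of class `hill_params`.
#' @seealso [simulate_activation()], [simulate_muscle_force()],
#'   [simulate_twitch()]
#' @export
hill_params <- function(f_max = 7.39,
                        l0 = 11.59,
                        tau_act = 64.60,
                        tau_deact = 44.73,
                        excitation_ms = 36.25,
                        fl_width = 0.5,
                        v_max = 10,
                        hill_curvature = 0.25,
                        passive_stiffness = 2,
                        density = 0.001056) {
  stopifnot(f_max > 0, l0 > 0, tau_act > 0, tau_deact > 0,
            excitation_ms > 0, fl_width > 0, v_max > 0,
            hill_curvature > 0, hill_curvature < 1,
            passive_stiffness >= 0, density > 0)
  structure(list(f_max = f_max, l0 = l0, tau_act = tau_act,
                 tau_deact = tau_deact, excitation_ms = excitation_ms,
                 fl_width = fl_width, v_max = v_max,
                 hill_curvature = hill_curvature,
                 passive_stiffness = passive_stiffness, density = density),
            class = "hill_params")
}

#' @export
print.hill_params <- function(x, ...) {
  cat("<hill_params>\n")
  cat(sprintf("  f_max %.3g N | l0 %.3g mm | tau_act %.3g ms | tau_deact %.3g ms\n",
              x$f_max, x$l0, x$tau_act, x$tau_deact))
  cat(sprintf("  excitation %.3g ms | fl_width %.2f | v_max %.3g l0/s | a/P0 %.2f\n",
              x$excitation_ms, x$fl_width, x$v_max, x$hill_curvature))
  invisible(x)
}

#' First-order activation dynamics
#'
#' Integrates `da/dt = (u - a) / tau`, with `tau = tau_act` while the
#' excitation `u` is at or above the current activation and `tau = tau_deact`
#' while it is below, using the exact exponential update per sample (the
#' solution is exact for a piecewise-constant excitation). Output is bounded
#' in \[0, 1\] for any admissible excitation.
#'
#' @param stim_envelope Excitation/stimulation envelope as a [mast_ts()],
#'   values in \[0, 1\].
#' @param params A [hill_params()] object.
#' @param a0 Initial activation (default 0).
#' @return Activation as a [mast_ts()] on the same time base.
#' @export
simulate_activation <- function(stim_envelope, params = hill_params(), a0 = 0) {
  stopifnot(inherits(stim_envelope, "mast_ts"), inherits(params, "hill_params"))
  u <- stim_envelope$x
  if (any(!is.finite(u)) || any(u < 0) || any(u > 1)) {
    stop("stimulation envelope values must lie in [0, 1]", call. = FALSE)
  }
  dt_ms <- 1000 / stim_envelope$fs
  k_act <- exp(-dt_ms / params$tau_act)
  k_deact <- exp(-dt_ms / params$tau_deact)
  a <- numeric(length(u))
  prev <- a0
  for (i in seq_along(u)) {
    k <- if (u[i] >= prev) k_act else k_deact
    prev <- u[i] + (prev - u[i]) * k
    a[i] <- prev
  }
  mast_ts(a, fs = stim_envelope$fs, t0 = stim_envelope$t0)
}

# force-length scaling: 1 on the plateau (L >= l0), parabolic ascending limb
fl_scale <- function(L, params) {
  rel <- (params$l0 - L) / (params$fl_width * params$l0)
  ifelse(L >= params$l0, 1, pmax(0, 1 - rel^2))
}

# force-velocity scaling; v in l0/s, positive = shortening.
# Hill hyperbola on the shortening branch, linear eccentric branch capped so
# that total active force never exceeds 1.5 * f_max.
fv_scale <- function(v, params) {
  k <- params$hill_curvature
  vm <- params$v_max
  conc <- pmax(0, (1 - v / vm) / (1 + v / (k * vm)))
  ecc <- pmin(1.5, 1 + 2 * (-v) / vm)
  ifelse(v >= 0, conc, ecc)
}

# passive force: zero at or below l0, linear beyond
fpas <- function(L, params) {
  pmax(0, (L - params$l0) / params$l0) * params$passive_stiffness
}

#' Simulate muscle force from a length trajectory and activation
#'
#' Hill-type force: `F = a * f_max * fL(L) * fV(v) + Fpas(L)`, with fL = 1 on
#' the plateau and a parabolic ascending limb of width `fl_width * l0`; fV is
#' the Hill hyperbola for shortening and a linear eccentric branch capped at
#' 1.5 `f_max`; the passive element is slack below `l0`. Velocity is obtained
#' from the length trajectory by central differences (one-sided at the ends).
#'
#' @param length_trajectory Muscle length over time (mm) as a [mast_ts()].
#'   Intended use keeps the maximum imposed length at or below `l0` so the
#'   muscle operates on the ascending limb and plateau.
#' @param activation Activation in \[0, 1\] as a [mast_ts()] on the same time
#'   base (typically from [simulate_activation()]).
#' @param params A [hill_params()] object.
#' @return Force (N) as a [mast_ts()] on the same time base.
#' @export
simulate_muscle_force <- function(length_trajectory, activation,
                                  params = hill_params()) {
  check_common_base(length_trajectory, activation, "length and activation")
  stopifnot(inherits(params, "hill_params"))
  a <- activation$x
  if (any(a < -1e-12) || any(a > 1 + 1e-12)) {
    stop("activation must lie in [0, 1]", call. = FALSE)
  }
  L <- length_trajectory$x
  v_mm_s <- -central_diff(L) * length_trajectory$fs   # shortening positive
  v <- v_mm_s / params$l0
  f <- a * params$f_max * fl_scale(L, params) * fv_scale(v, params) +
    fpas(L, params)
  mast_ts(f, fs = length_trajectory$fs, t0 = length_trajectory$t0)
}

# central differences, one-sided at the endpoints; returns per-sample delta
central_diff <- function(x) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  d <- numeric(n)
  d[1] <- x[2] - x[1]
  d[n] <- x[n] - x[n - 1]
  if (n > 2L) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  d
}

#' Excitation envelope of a stimulus pulse train
#'
#' Converts stimulus pulse times into the excitation input of
#' [simulate_activation()]: each pulse switches the active state fully on for
#' `params$excitation_ms`; pulses closer together than that (e.g. a 200 Hz
#' fusion-frequency train) merge into sustained excitation.
#'
#' @param pulse_times_s Stimulus pulse onset times (s).
#' @param duration_s Envelope duration (s).
#' @param fs Sample rate (Hz).
#' @param params A [hill_params()] object.
#' @return Excitation envelope in \[0, 1\] as a [mast_ts()].
#' @export
pulse_train_envelope <- function(pulse_times_s, duration_s, fs,
                                 params = hill_params()) {
  tt <- seq(0, duration_s, by = 1 / fs)
  u <- numeric(length(tt))
  w <- params$excitation_ms / 1000
  for (tp in pulse_times_s) u[tt >= tp & tt < tp + w] <- 1
  mast_ts(u, fs = fs, t0 = 0)
}

#' Simulate an isometric twitch or tetanus at optimal length
#'
#' Runs the activation dynamics and force model for an isometric contraction
#' at `l0` driven either by a single supramaximal pulse (`mode = "twitch"`)
#' or by a pulse train at `train_hz` (`mode = "tetanus"`, default 200 Hz, the
#' fusion frequency used experimentally).
#'
#' @param params A [hill_params()] object.
#' @param mode `"twitch"` or `"tetanus"`.
#' @param fs Simulation sample rate (Hz; default 10000).
#' @param duration_s Simulated duration (s).
#' @param stim_time_s Time of the first pulse (s).
#' @param train_hz Pulse rate for tetanus mode.
#' @return A list with `force` (a [mast_ts()], N), `stim_time_s`, and
#'   `peak` (N).
#' @export
simulate_twitch <- function(params = hill_params(),
                            mode = c("twitch", "tetanus"),
                            fs = 10000, duration_s = 0.5,
                            stim_time_s = 0.05, train_hz = 200) {
  mode <- match.arg(mode)
  pulses <- if (mode == "twitch") {
    stim_time_s
  } else {
    seq(stim_time_s, duration_s - 0.05, by = 1 / train_hz)
  }
  u <- pulse_train_envelope(pulses, duration_s, fs, params)
  a <- simulate_activation(u, params)
  L <- mast_ts(rep(params$l0, length(a)), fs = fs, t0 = 0)
  f <- simulate_muscle_force(L, a, params)
  list(force = f, stim_time_s = stim_time_s, peak = max(f$x))
}

#' Calibrate Hill activation constants against isometric twitch metrics
#'
#' Finds the deactivation time constant by bisection on the simulated twitch
#' half-relaxation time and the activation time constant by bisection on the
#' simulated twitch:tetanus ratio; the active-state duration is set to the
#' twitch rise-time target (on the force-length plateau the isometric force
#' peaks when the active state switches off, so rise time equals the
#' active-state duration). Targets default to a fast jaw-opening muscle:
#' rise 36.25 ms, half-relaxation 31.0 ms, twitch:tetanus 0.43.
#'
#' @param rise_ms Target twitch rise time (ms).
#' @param half_relax_ms Target half-relaxation time (ms).
#' @param twitch_tetanus Target twitch:tetanus ratio.
#' @param base Starting [hill_params()] whose non-calibrated fields are kept.
#' @param fs Simulation rate for the calibration runs (Hz).
#' @param tol Bisection tolerance on the simulated metric.
#' @return A calibrated [hill_params()] object.
#' @export
calibrate_hill_params <- function(rise_ms = 36.25, half_relax_ms = 31.0,
                                  twitch_tetanus = 0.43,
                                  base = hill_params(), fs = 10000,
                                  tol = 0.01) {
  p <- base
  p$excitation_ms <- rise_ms

  sim_half_relax <- function(tau_d) {
    p2 <- p; p2$tau_deact <- tau_d
    tw <- simulate_twitch(p2, "twitch", fs = fs)
    twitch_kinetics(tw$force, stim_time_s = tw$stim_time_s)$half_relaxation_ms
  }
  p$tau_deact <- bisect_monotone(sim_half_relax, half_relax_ms,
                                 lo = 5, hi = 200, tol = tol)

  sim_ratio <- function(tau_a) {
    p2 <- p; p2$tau_act <- tau_a
    tw <- simulate_twitch(p2, "twitch", fs = fs)
    te <- simulate_twitch(p2, "tetanus", fs = fs, duration_s = 0.6)
    tw$peak / te$peak
  }
  # ratio decreases as tau_act grows
  p$tau_act <- bisect_monotone(sim_ratio, twitch_tetanus,
                               lo = 5, hi = 400, tol = 1e-4,
                               increasing = FALSE)
  p
}

# bisection for a monotone scalar function f(x) = target on [lo, hi]
bisect_monotone <- function(f, target, lo, hi, tol, increasing = TRUE,
                            max_iter = 60L) {
  flo <- f(lo); fhi <- f(hi)
  sgn <- if (increasing) 1 else -1
  if (sgn * (flo - target) > 0 || sgn * (fhi - target) < 0) {
    stop("bisection bracket does not contain the target", call. = FALSE)
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm - target) < tol || (hi - lo) < 1e-6) return(mid)
    if (sgn * (fm - target) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
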