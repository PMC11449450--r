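#' Twitch kinetics of an isometric force trace
#'
#' Rise time is the interval from the stimulus to the force peak;
#' half-relaxation time is the interval from the peak to the decay through
#' 50% of peak force, located with linear sub-sample interpolation.
#'
#' @param force Isometric twitch force (N) as a [mast_ts()].
#' @param stim_time_s Stimulus time (s); defaults to the trace start.
#' @return A list with `rise_ms`, `half_relaxation_ms`, `peak` (N) and
#'   `peak_time_s`.
#' @export
twitch_kinetics <- function(force, stim_time_s = force$t0) {
  stopifnot(inherits(force, "mast_ts"))
  x <- force$x
  tt <- ts_time(force)
  pk <- max(x)
  noise <- stats::sd(x[tt < stim_time_s])
  if (!is.finite(noise)) noise <- 0
  if (pk <= 0 || pk <= mean(x[tt < stim_time_s], na.rm = TRUE) + 5 * noise &&
      pk <= 1e-12) {
    stop("no twitch peak detectable above noise", call. = FALSE)
  }
  ip <- which.max(x)
  if (tt[ip] < stim_time_s) {
    stop("force peak precedes the stimulus", call. = FALSE)
  }
  rise_ms <- (tt[ip] - stim_time_s) * 1000
  half <- pk / 2
  post <- x[ip:length(x)]
  below <- which(post <= half)
  if (!length(below)) {
    stop("force never decays below half of peak", call. = FALSE)
  }
  j <- below[1]
  if (j == 1L) {
    t_half <- tt[ip]
  } else {
    i1 <- ip + j - 2L
    frac <- (x[i1] - half) / (x[i1] - x[i1 + 1L])
    t_half <- tt[i1] + frac / force$fs
  }
  list(rise_ms = rise_ms,
       half_relaxation_ms = (t_half - tt[ip]) * 1000,
       peak = pk, peak_time_s = tt[ip])
}

#' Isometric muscle stress
#'
#' Maximal isometric force per physiological cross-sectional area, reported
#' in kN m^-2 (1 N mm^-2 = 1000 kN m^-2).
#'
#' @param p0 Maximal isometric tetanic force (N).
#' @param pcsa_mm2 Physiological cross-sectional area (mm^2, > 0).
#' @return Stress in kN m^-2.
#' @examples
#' isometric_stress(7.39, 55.6)  # ~132.9
#' @export
isometric_stress <- function(p0, pcsa_mm2) {
  if (!is.finite(pcsa_mm2) || pcsa_mm2 <= 0) {
    stop("PCSA must be positive", call. = FALSE)
  }
  1000 * p0 / pcsa_mm2
}

#' Twitch to tetanus ratio
#' @param twitch_peak Peak single-twitch force (N).
#' @param tetanus_peak Peak fused tetanic force (N, > 0).
#' @return The ratio (fraction).
#' @export
twitch_tetanus_ratio <- function(twitch_peak, tetanus_peak) {
  if (!is.finite(tetanus_peak) || tetanus_peak <= 0) {
    stop("tetanus peak must be positive", call. = FALSE)
  }
  twitch_peak / tetanus_peak
}

#' Work-loop analysis of one cycle
#'
#' Computes positive, negative and net mass-specific work over a cyclic
#' force-length record using the shortening-positive sign convention: the
#' work increment between samples is the trapezoidal force times the
#' length decrease, `w_i = 0.5 (F_i + F_(i+1)) * (-(L_(i+1) - L_i))`
#' (N mm = mJ). Positive work sums the positive increments (shortening
#' under force), negative work the negative increments (active
#' lengthening), and net work their total, so net = positive + negative by
#' construction; all are normalized by muscle mass to mJ kg^-1. When phase
#' boundaries are supplied each increment is attributed to the masticatory
#' phase containing its midpoint.
#'
#' @param force Force (N) as a [mast_ts()].
#' @param length_mm Muscle length (mm) as a [mast_ts()] on the same time
#'   base.
#' @param muscle_mass_g Muscle mass in grams (> 0).
#' @param cycle Optional integer frame range `c(start, end)` restricting the
#'   analysis (default: the whole record).
#' @param phases Optional [classify_phases()] result for per-phase work
#'   attribution.
#' @return An object of class `workloop_result` with `positive_work`,
#'   `negative_work`, `net_work` (mJ kg^-1), `net_power` (W kg^-1),
#'   `cycle_duration` (s), `phase_work` (named vector, mJ kg^-1, when
#'   `phases` given) and the loop polygon (`length`, `force`).
#' @export
loop_work <- function(force, length_mm, muscle_mass_g, cycle = NULL,
                      phases = NULL) {
  check_common_base(force, length_mm, "force and length")
  if (!is.finite(muscle_mass_g) || muscle_mass_g <= 0) {
    stop("muscle mass must be positive", call. = FALSE)
  }
  idx <- if (is.null(cycle)) {
    seq_along(force$x)
  } else {
    if (cycle[1] < 1L || cycle[2] > length(force$x) || cycle[1] >= cycle[2]) {
      stop("cycle frame range lies outside the traces", call. = FALSE)
    }
    seq(cycle[1], cycle[2])
  }
  f <- force$x[idx]
  L <- length_mm$x[idx]
  n <- length(f)
  mass_kg <- muscle_mass_g / 1000
  w <- 0.5 * (f[-n] + f[-1]) * (-(diff(L))) / mass_kg   # mJ/kg per step
  positive <- sum(pmax(w, 0))
  negative <- sum(pmin(w, 0))
  net <- positive + negative
  dur <- (n - 1) / force$fs
  phase_work <- NULL
  if (!is.null(phases)) {
    stopifnot(inherits(phases, "mast_phases"))
    pct_mid <- (seq_len(n - 1) - 0.5) / (n - 1) * 100
    lab <- cut(pct_mid,
               breaks = c(-Inf, phases$fc_end, phases$sc_end, phases$so_end,
                          Inf),
               labels = c("FC", "SC", "SO", "FO"))
    phase_work <- vapply(c("FC", "SC", "SO", "FO"),
                         function(p) sum(w[lab == p]), numeric(1))
  }
  structure(list(positive_work = positive, negative_work = negative,
                 net_work = net,
                 net_power = net / dur / 1000,
                 cycle_duration = dur,
                 phase_work = phase_work,
                 loop = data.frame(length = L, force = f)),
            class = "workloop_result")
}

#' @export
print.workloop_result <- function(x, ...) {
  cat(sprintf(paste0("<workloop_result> +%.0f / %.0f -> net %.0f mJ/kg ",
                     "(%.2f W/kg over %.3f s)\n"),
              x$positive_work, x$negative_work, x$net_work, x$net_power,
              x$cycle_duration))
  invisible(x)
}

#' @export
plot.workloop_result <- function(x, ...) {
  graphics::plot(x$loop$length, x$loop$force, type = "l",
                 xlab = "Length (mm)", ylab = "Force (N)", ...)
  invisible(x)
}

#' Instantaneous mass-specific muscle power
#'
#' `P(t) = F(t) * v(t) / mass` with shortening velocity `v = -dL/dt`
#' obtained by central differences (one-sided at the endpoints); reported in
#' W kg^-1. The time integral of the power trace over a cycle equals the
#' cycle's net work.
#'
#' @inheritParams loop_work
#' @return Power (W kg^-1) as a [mast_ts()].
#' @export
instantaneous_power <- function(force, length_mm, muscle_mass_g) {
  check_common_base(force, length_mm, "force and length")
  if (!is.finite(muscle_mass_g) || muscle_mass_g <= 0) {
    stop("muscle mass must be positive", call. = FALSE)
  }
  v <- -central_diff(length_mm$x) * force$fs      # mm/s, shortening +
  p_mw_kg <- force$x * v / (muscle_mass_g / 1000) # N*mm/s = mW, per kg
  mast_ts(p_mw_kg / 1000, fs = force$fs, t0 = force$t0)
}

#' Net cycle-average power of a work-loop result
#'
#' Net work divided by cycle duration (mJ kg^-1 / s = mW kg^-1, reported in
#' W kg^-1).
#'
#' @param result A [loop_work()] result.
#' @return Net power in W kg^-1.
#' @export
net_cycle_power <- function(result) {
  stopifnot(inherits(result, "workloop_result"))
  if (result$cycle_duration <= 0) {
    stop("cycle duration must be positive", call. = FALSE)
  }
  result$net_work / result$cycle_duration / 1000
}
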