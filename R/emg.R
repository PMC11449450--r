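#' Activity envelope of a raw EMG trace
#'
#' Full-wave rectification followed by zero-phase low-pass filtering
#' (default 30 Hz, order 4) to form an envelope of relative muscle
#' activity. Small negative filter undershoot is clipped so the envelope is
#' non-negative everywhere.
#'
#' @param raw Raw EMG (V) as a [mast_ts()]; the sample rate must exceed
#'   60 Hz so the default 30 Hz cutoff is below Nyquist.
#' @param cutoff Envelope low-pass cutoff (Hz, default 30).
#' @param order Filter order (default 4).
#' @return An object of class `emg_envelope`: a [mast_ts()] `envelope` plus
#'   the filter settings.
#' @export
emg_envelope <- function(raw, cutoff = 30, order = 4) {
  stopifnot(inherits(raw, "mast_ts"))
  if (raw$fs <= 60) {
    stop("EMG sample rate must exceed 60 Hz for a 30 Hz envelope",
         call. = FALSE)
  }
  rect <- mast_ts(abs(raw$x), fs = raw$fs, t0 = raw$t0)
  env <- butterworth_lowpass(rect, cutoff = cutoff, order = order)
  env$x <- pmax(0, env$x)
  structure(list(envelope = env, cutoff = cutoff, order = order),
            class = "emg_envelope")
}

# accept either an emg_envelope or a bare mast_ts
as_envelope_ts <- function(env) {
  if (inherits(env, "emg_envelope")) env$envelope
  else if (inherits(env, "mast_ts")) env
  else stop("expected an emg_envelope or mast_ts", call. = FALSE)
}

#' Quietest window of a trace
#'
#' Finds the contiguous window of the requested duration with the lowest
#' mean absolute value; used as the default EMG baseline and the default
#' EMG-silent occlusion reference.
#'
#' @param ts A [mast_ts()] (raw or envelope).
#' @param dur_s Window duration in seconds (default 0.2).
#' @return Integer vector `c(start_frame, end_frame)`.
#' @export
quiet_window <- function(ts, dur_s = 0.2) {
  ts <- as_envelope_ts(ts)
  w <- max(2L, round(dur_s * ts$fs))
  n <- length(ts$x)
  if (w >= n) return(c(1L, n))
  cs <- cumsum(c(0, abs(ts$x)))
  sums <- cs[(w + 1L):(n + 1L)] - cs[1:(n - w + 1L)]
  s <- which.min(sums)
  c(s, s + w - 1L)
}

#' Detect EMG bursts by a 2-SD baseline threshold
#'
#' Burst onsets and offsets are the crossings of a threshold set at the
#' baseline mean plus two baseline standard deviations. A crossing must be
#' sustained for at least `min_duration_s` (default 10 ms) to count, which
#' suppresses single-sample spikes, and sub-threshold dips shorter than the
#' same debounce interval do not split a burst.
#'
#' @param env An [emg_envelope()] (or a bare envelope [mast_ts()]).
#' @param baseline Integer frame range `c(start, end)` of a burst-free
#'   baseline; defaults to the quietest 200 ms window of the envelope.
#' @param min_duration_s Debounce duration in seconds (default 0.01).
#' @param threshold Optional explicit threshold (V), overriding the
#'   baseline-derived value.
#' @return A data frame with one row per burst: `onset_frame`,
#'   `offset_frame`, `onset_time`, `offset_time`; the threshold (V) is
#'   attached as attribute `threshold`. Zero rows when the threshold is
#'   never crossed.
#' @export
detect_bursts <- function(env, baseline = NULL, min_duration_s = 0.01,
                          threshold = NULL) {
  ts <- as_envelope_ts(env)
  n <- length(ts$x)
  if (is.null(threshold)) {
    if (is.null(baseline)) baseline <- quiet_window(ts, 0.2)
    base <- ts$x[baseline[1]:baseline[2]]
    thr <- mean(base) + 2 * stats::sd(base)
  } else {
    thr <- threshold
  }
  above <- ts$x > thr
  need <- max(1L, round(min_duration_s * ts$fs))

  runs <- rle(above)
  # debounce: absorb short sub-threshold gaps between bursts
  if (length(runs$lengths) > 2L) {
    interior <- 2:(length(runs$lengths) - 1L)
    flip <- interior[!runs$values[interior] & runs$lengths[interior] < need]
    if (length(flip)) {
      runs$values[flip] <- TRUE
      runs <- rle(inverse.rle(runs))
    }
  }
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values & runs$lengths >= need)
  tt <- ts_time(ts)
  out <- data.frame(onset_frame = starts[keep], offset_frame = ends[keep])
  out$onset_time <- tt[out$onset_frame]
  out$offset_time <- tt[out$offset_frame]
  out$area <- vapply(seq_len(nrow(out)), function(i) {
    trapz_sum(ts$x[out$onset_frame[i]:out$offset_frame[i]], 1 / ts$fs)
  }, numeric(1))
  attr(out, "threshold") <- thr
  out
}

#' Keep only the major bursts of a burst table
#'
#' The 2-SD threshold rule can mark brief low-amplitude envelope excursions
#' beside the main recruitment burst of each chew cycle. This helper keeps
#' the bursts that carry the activity: those whose integrated envelope is at
#' least `frac` (default 0.5) of the largest burst integral.
#'
#' @param bursts Data frame from [detect_bursts()] (with an `area` column).
#' @param frac Retention threshold as a fraction of the largest integral.
#' @return The filtered burst table.
#' @export
major_bursts <- function(bursts, frac = 0.5) {
  if (!nrow(bursts)) return(bursts)
  bursts[bursts$area >= frac * max(bursts$area), , drop = FALSE]
}

#' Express burst timings as percent of the containing gape cycle
#'
#' Onset percent is computed in the cycle containing the onset; offset
#' percent in the cycle containing the offset. A burst whose offset falls in
#' a later cycle than its onset (activity running through maximum gape into
#' the next cycle) is flagged `wrapped`, matching the convention of
#' reporting offsets as small percentages early in the next cycle.
#'
#' @param bursts Data frame from [detect_bursts()] (needs `onset_time`,
#'   `offset_time`).
#' @param cycles List of `mast_cycle` objects from [segment_cycles()].
#' @return Data frame with `onset_pct`, `offset_pct`, `onset_cycle`,
#'   `offset_cycle`, `wrapped`; bursts outside all cycles are dropped.
#' @export
burst_cycle_timing <- function(bursts, cycles) {
  if (!length(cycles)) return(data.frame())
  locate <- function(t) {
    for (k in seq_along(cycles)) {
      cy <- cycles[[k]]
      if (t >= cy$start_time && t < cy$end_time) {
        return(c(k, 100 * (t - cy$start_time) /
                   (cy$end_time - cy$start_time)))
      }
    }
    c(NA_real_, NA_real_)
  }
  res <- lapply(seq_len(nrow(bursts)), function(i) {
    on <- locate(bursts$onset_time[i])
    off <- locate(bursts$offset_time[i])
    data.frame(onset_cycle = on[1], onset_pct = on[2],
               offset_cycle = off[1], offset_pct = off[2],
               wrapped = !is.na(on[1]) && !is.na(off[1]) && off[1] > on[1])
  })
  res <- do.call(rbind, res)
  res[!is.na(res$onset_cycle) & !is.na(res$offset_cycle), , drop = FALSE]
}

#' Recruitment ratio of two EMG envelopes
#'
#' Ratio of the integrated EMG of a test envelope to that of a reference
#' envelope (by convention the working side, whose ratio is 1). Each
#' envelope is integrated over its own detected burst extents and the mean
#' per-burst integral is used, so differing numbers of detected bursts do
#' not bias the ratio.
#'
#' @param test_env,reference_env [emg_envelope()] objects (or envelope
#'   [mast_ts()]).
#' @param test_bursts,reference_bursts Optional burst tables from
#'   [detect_bursts()]; detected automatically (and reduced to the major
#'   bursts, see [major_bursts()]) when omitted.
#' @return The recruitment ratio (dimensionless fraction).
#' @export
recruitment_ratio <- function(test_env, reference_env,
                              test_bursts = NULL, reference_bursts = NULL) {
  te <- as_envelope_ts(test_env)
  re <- as_envelope_ts(reference_env)
  if (is.null(test_bursts)) test_bursts <- major_bursts(detect_bursts(te))
  if (is.null(reference_bursts)) {
    reference_bursts <- major_bursts(detect_bursts(re))
  }
  burst_integral <- function(ts, bursts) {
    if (!nrow(bursts)) return(0)
    mean(vapply(seq_len(nrow(bursts)), function(i) {
      seg <- ts$x[bursts$onset_frame[i]:bursts$offset_frame[i]]
      trapz_sum(seg, 1 / ts$fs)
    }, numeric(1)))
  }
  num <- burst_integral(te, test_bursts)
  den <- burst_integral(re, reference_bursts)
  if (den <= 0) stop("reference envelope integral is zero", call. = FALSE)
  num / den
}

#' Fit a sigmoidal current-recruitment curve
#'
#' Least-squares logistic fit of normalized isometric twitch force against
#' stimulation current: `f(I) = 1 / (1 + exp(-(I - midpoint) / slope))`.
#' The fitted curve provides the inverse mapping from a desired recruitment
#' fraction to the current that evokes it; the floor and ceiling currents
#' are the currents at 1% and 99% recruitment.
#'
#' @param currents Stimulation currents (mA), at least 5, spanning
#'   sub-threshold to plateau.
#' @param twitch_forces Evoked twitch forces (N), same length.
#' @return An object of class `recruitment_curve` with `midpoint_ma`,
#'   `slope_ma`, `floor_ma`, `ceiling_ma` and fitted values.
#' @export
fit_current_recruitment <- function(currents, twitch_forces) {
  stopifnot(length(currents) == length(twitch_forces))
  if (length(currents) < 5L) {
    stop("need at least 5 (current, force) pairs", call. = FALSE)
  }
  fmax <- max(twitch_forces)
  if (fmax <= 0 || (fmax - min(twitch_forces)) < 0.2 * fmax) {
    stop("fit-quality error: forces have no dynamic range", call. = FALSE)
  }
  f <- twitch_forces / fmax
  if (stats::cor(currents, f, method = "spearman") < 0.8) {
    stop("fit-quality error: force is not monotone in current beyond noise",
         call. = FALSE)
  }
  if (max(f[currents >= stats::quantile(currents, 0.8)]) < 0.9) {
    stop("fit-quality error: no plateau reached at high currents",
         call. = FALSE)
  }
  # free plateau amplitude A so exact logistic data is recovered exactly;
  # recruitment is force relative to the fitted plateau
  df <- data.frame(I = currents, F = twitch_forces)
  fit <- minpack.lm::nlsLM(
    F ~ A / (1 + exp(-(I - m) / s)),
    data = df,
    start = list(A = fmax, m = stats::median(currents),
                 s = diff(range(currents)) / 10),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  m <- unname(cf["m"]); s <- abs(unname(cf["s"]))
  inv <- function(p) m + s * log(p / (1 - p))
  structure(list(midpoint_ma = m, slope_ma = s,
                 plateau_force = unname(cf["A"]),
                 floor_ma = inv(0.01), ceiling_ma = inv(0.99),
                 fitted = stats::fitted(fit) / unname(cf["A"])),
            class = "recruitment_curve")
}

#' Inverse of a fitted current-recruitment curve
#'
#' Current (mA) required for a given recruitment fraction; fractions are
#' clipped to the fitted floor/ceiling (1%-99%) range.
#'
#' @param curve A [fit_current_recruitment()] result.
#' @param recruitment Recruitment fractions in \[0, 1\].
#' @return Currents (mA).
#' @export
recruitment_inverse <- function(curve, recruitment) {
  stopifnot(inherits(curve, "recruitment_curve"))
  p <- pmin(0.99, pmax(0.01, recruitment))
  curve$midpoint_ma + curve$slope_ma * log(p / (1 - p))
}

#' Recruitment-scaled stimulation command from an EMG envelope
#'
#' Converts an activity envelope into the time-varying current command that
#' replays the in vivo recruitment pattern through a stimulator: the
#' envelope is normalized to its own burst peak, scaled to the target
#' recruitment level (1 for the working side, e.g. 0.47 for the balancing
#' side), mapped through the inverse current-recruitment curve, and clipped
#' to the curve's floor/ceiling currents.
#'
#' @param env An [emg_envelope()] (or envelope [mast_ts()]).
#' @param curve A [fit_current_recruitment()] result.
#' @param target_recruitment Target recruitment fraction in (0, 1].
#' @return Current command (mA) as a [mast_ts()].
#' @export
stimulation_command <- function(env, curve, target_recruitment = 1) {
  ts <- as_envelope_ts(env)
  stopifnot(inherits(curve, "recruitment_curve"))
  if (!is.finite(target_recruitment) || target_recruitment <= 0 ||
      target_recruitment > 1) {
    stop("target recruitment must lie in (0, 1]", call. = FALSE)
  }
  pk <- max(ts$x)
  if (pk <= 0) stop("envelope has no activity to normalize", call. = FALSE)
  p <- target_recruitment * ts$x / pk
  cmd <- recruitment_inverse(curve, p)
  cmd <- pmin(curve$ceiling_ma, pmax(curve$floor_ma, cmd))
  mast_ts(cmd, fs = ts$fs, t0 = ts$t0)
}
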