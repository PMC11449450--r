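#' Resting inter-bead length from an EMG-silent occlusion window
#'
#' The strain reference length is the mean inter-bead distance over an
#' extended period of jaw occlusion during which the muscle is electrically
#' silent. Frames qualify when the occlusion mask is true and the EMG
#' envelope lies below the burst threshold (baseline mean + 2 sd, estimated
#' from the quietest stretch of the envelope when not supplied); the mean is
#' taken over the longest contiguous qualifying run, which must last at
#' least `min_s` seconds.
#'
#' @param distance Inter-bead distance (mm) as a [mast_ts()].
#' @param emg_envelope EMG envelope on the same time base (see
#'   [emg_envelope()]; resample with [ts_resample()] if needed).
#' @param occlusion_mask Logical vector, one element per frame, marking jaw
#'   occlusion.
#' @param threshold Envelope threshold (V); default baseline mean + 2 sd
#'   from the quietest 200 ms window.
#' @param min_s Minimum qualifying window duration in seconds (default 0.1).
#' @return Resting length (mm), with the qualifying frame range as
#'   attribute `window`.
#' @export
resting_length <- function(distance, emg_envelope, occlusion_mask,
                           threshold = NULL, min_s = 0.1) {
  check_common_base(distance, emg_envelope, "distance and envelope")
  if (length(occlusion_mask) != length(distance$x)) {
    stop("occlusion mask must have one element per frame", call. = FALSE)
  }
  if (is.null(threshold)) {
    qw <- quiet_window(emg_envelope, 0.2)
    base <- emg_envelope$x[qw[1]:qw[2]]
    threshold <- mean(base) + 2 * stats::sd(base)
  }
  ok <- occlusion_mask & (emg_envelope$x < threshold)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  good <- which(runs$values)
  need <- ceiling(min_s * distance$fs)
  good <- good[runs$lengths[good] >= need]
  if (!length(good)) {
    stop("no EMG-silent occlusion window of at least ", min_s * 1000,
         " ms found; select a resting window manually", call. = FALSE)
  }
  k <- good[which.max(runs$lengths[good])]
  win <- c(starts[k], ends[k])
  out <- mean(distance$x[win[1]:win[2]])
  attr(out, "window") <- win
  out
}

#' Fascicle strain from an inter-bead distance trace
#'
#' Strain is the inter-bead distance minus the resting length, divided by
#' the resting inter-bead length: `(d - L_rest) / L_rest`.
#'
#' @param distance Inter-bead distance (mm) as a [mast_ts()].
#' @param resting_length_mm Resting inter-bead length (mm, > 0), typically
#'   from [resting_length()].
#' @return A list of class `strain_trace` with `strain` (a dimensionless
#'   [mast_ts()]) and `resting_length` (mm).
#' @examples
#' d <- mast_ts(c(6, 6.3, 6.9, 6.3, 6), fs = 250)
#' compute_strain(d, 6)$strain$x   # 0 0.05 0.15 0.05 0
#' @export
compute_strain <- function(distance, resting_length_mm) {
  stopifnot(inherits(distance, "mast_ts"))
  lr <- as.numeric(resting_length_mm)
  if (!is.finite(lr) || lr <= 0) {
    stop("resting length must be positive", call. = FALSE)
  }
  structure(list(strain = mast_ts((distance$x - lr) / lr,
                                  fs = distance$fs, t0 = distance$t0),
                 resting_length = lr),
            class = "strain_trace")
}

#' Peak-to-peak strain amplitude per masticatory cycle
#'
#' @param strain A `strain_trace` (or a [mast_ts()] of strain values).
#' @param cycles A list of `mast_cycle` objects (or a single cycle).
#' @return Numeric vector of per-cycle peak-to-peak (max - min) strain.
#' @export
strain_amplitude <- function(strain, cycles) {
  ts <- if (inherits(strain, "strain_trace")) strain$strain else strain
  stopifnot(inherits(ts, "mast_ts"))
  if (inherits(cycles, "mast_cycle")) cycles <- list(cycles)
  vapply(cycles, function(cy) {
    seg <- cycle_resample(ts, cy)
    max(seg) - min(seg)
  }, numeric(1))
}
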