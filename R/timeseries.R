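#' Uniformly sampled time series
#'
#' Lightweight container used throughout the package for kinematic, EMG and
#' ergometer traces: a numeric vector plus a sample rate and a start time.
#'
#' @param x Numeric vector of samples.
#' @param fs Sample rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `mast_ts`.
#' @examples
#' ts <- mast_ts(sin(2 * pi * 4 * seq(0, 1, by = 1 / 250)), fs = 250)
#' ts_duration(ts)
#' @export
mast_ts <- function(x, fs, t0 = 0) {
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  structure(list(x = as.numeric(x), fs = fs, t0 = as.numeric(t0)),
            class = "mast_ts")
}

#' @export
print.mast_ts <- function(x, ...) {
  cat(sprintf("<mast_ts> %d samples @ %g Hz, t = [%.4f, %.4f] s\n",
              length(x$x), x$fs, x$t0, x$t0 + (length(x$x) - 1) / x$fs))
  invisible(x)
}

#' @export
length.mast_ts <- function(x) length(x$x)

#' Sample times of a time series
#' @param ts A [mast_ts()] object.
#' @return Numeric vector of sample times in seconds.
#' @export
ts_time <- function(ts) {
  stopifnot(inherits(ts, "mast_ts"))
  ts$t0 + (seq_along(ts$x) - 1) / ts$fs
}

#' Duration of a time series in seconds
#' @inheritParams ts_time
#' @export
ts_duration <- function(ts) (length(ts$x) - 1) / ts$fs

#' Resample a time series onto another time base
#'
#' Linear interpolation; values outside the source support are held at the
#' boundary samples (rule 2).
#'
#' @param ts A [mast_ts()] object.
#' @param fs Target sample rate (Hz).
#' @param t0,t1 Target start/end times; default to the source extent.
#' @export
ts_resample <- function(ts, fs, t0 = ts$t0, t1 = ts$t0 + ts_duration(ts)) {
  tt <- seq(t0, t1, by = 1 / fs)
  y <- stats::approx(ts_time(ts), ts$x, xout = tt, rule = 2)$y
  mast_ts(y, fs = fs, t0 = t0)
}

# internal: assert two traces share a time base
check_common_base <- function(a, b, what = "traces") {
  if (!inherits(a, "mast_ts") || !inherits(b, "mast_ts")) {
    stop(what, " must be mast_ts objects", call. = FALSE)
  }
  if (length(a$x) != length(b$x) || !isTRUE(all.equal(a$fs, b$fs)) ||
      !isTRUE(all.equal(a$t0, b$t0))) {
    stop(what, " must share a common time base (same length, fs and t0)",
         call. = FALSE)
  }
  invisible(TRUE)
}

# internal: trapezoidal integral of y over uniform spacing dx
trapz_sum <- function(y, dx) {
  n <- length(y)
  if (n < 2L) return(0)
  dx * sum((y[-1] + y[-n]) / 2)
}
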