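#' Least-squares rigid-body pose from paired markers
#'
#' Estimates the rotation and translation mapping a marker template onto an
#' observed marker set by the SVD (Kabsch) solution of the orthogonal
#' Procrustes problem, with reflections excluded, as in marker-based
#' rigid-body tracking of bones.
#'
#' @param template n x 3 matrix of template marker coordinates (mm).
#' @param observed n x 3 matrix of observed marker coordinates (mm), rows
#'   paired with `template`.
#' @param frame_index Optional integer recorded on the pose.
#' @return An object of class `rigid_pose` with fields `rotation` (3 x 3
#'   proper orthogonal), `translation` (length-3, mm), `rmse` (mm) and
#'   `frame_index`, such that `observed ~ template %*% t(rotation) + translation`.
#' @examples
#' tpl <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 8, 0), c(0, 0, 6))
#' p <- estimate_rigid_pose(tpl, tpl)
#' p$rotation  # identity
#' @export
estimate_rigid_pose <- function(template, observed, frame_index = NA_integer_) {
  template <- as.matrix(template)
  observed <- as.matrix(observed)
  if (nrow(template) < 3L || ncol(template) != 3L ||
      !all(dim(template) == dim(observed))) {
    stop("need >= 3 paired 3D markers", call. = FALSE)
  }
  ct <- colMeans(template)
  co <- colMeans(observed)
  X <- sweep(template, 2, ct)
  Y <- sweep(observed, 2, co)
  sv_t <- svd(X)
  if (sv_t$d[2] < 1e-9 * max(sv_t$d[1], 1e-12)) {
    stop("degenerate marker geometry: template markers are collinear",
         call. = FALSE)
  }
  H <- crossprod(X, Y)              # 3x3
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(co - R %*% ct)
  fit <- sweep(template %*% t(R), 2, tr, `+`)
  rmse <- sqrt(mean(rowSums((observed - fit)^2)))
  structure(list(rotation = R, translation = tr, rmse = rmse,
                 frame_index = frame_index),
            class = "rigid_pose")
}

#' Apply a rigid pose to points
#' @param pose A `rigid_pose`.
#' @param points n x 3 matrix of points.
#' @return n x 3 matrix of transformed points.
#' @export
apply_pose <- function(pose, points) {
  stopifnot(inherits(pose, "rigid_pose"))
  sweep(as.matrix(points) %*% t(pose$rotation), 2, pose$translation, `+`)
}

# elementary rotations (degrees), used for construction and decomposition
rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' Jaw joint coordinate system definition
#'
#' Builds an anatomical coordinate frame for the temporomandibular joint:
#' the z-axis passes through the left and right most-medial points of the
#' mandibular condyles, the x-axis lies parallel to the occlusal plane
#' (obtained by projecting `occlusal_dir` onto the plane normal to z), and
#' the y-axis completes the right-handed triad. Jaw pitch (the gape proxy)
#' is the rotation about the condylar z-axis.
#'
#' @param condyle_left,condyle_right 3-vectors, the condylar landmark pair (mm).
#' @param occlusal_dir 3-vector roughly parallel to the occlusal plane
#'   (e.g. posterior-to-anterior along the tooth row).
#' @return An object of class `jcs_definition` with fields `rotation`
#'   (columns = x, y, z axes in world coordinates) and `origin`.
#' @export
jcs_definition <- function(condyle_left, condyle_right,
                           occlusal_dir = c(1, 0, 0)) {
  z <- as.numeric(condyle_right) - as.numeric(condyle_left)
  nz <- sqrt(sum(z^2))
  if (nz < 1e-9) stop("condylar landmarks coincide", call. = FALSE)
  z <- z / nz
  x <- as.numeric(occlusal_dir)
  x <- x - sum(x * z) * z
  nx <- sqrt(sum(x^2))
  if (nx < 1e-9) stop("occlusal direction is parallel to the condylar axis",
                      call. = FALSE)
  x <- x / nx
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  structure(list(rotation = cbind(x = x, y = y, z = z),
                 origin = (as.numeric(condyle_left) +
                             as.numeric(condyle_right)) / 2),
            class = "jcs_definition")
}

#' Mandible-in-skull rotations in a jaw joint coordinate system
#'
#' Expresses the relative mandible-to-skull rotation in the joint coordinate
#' system and decomposes it with a body-fixed z-y'-x'' Euler sequence:
#' pitch about the condylar z-axis (the gape proxy), then yaw about the
#' intermediate y-axis (lateral deviation), then roll about x. The neutral
#' (occluded) posture in which the JCS was defined maps to (0, 0, 0). Angle
#' traces are unwrapped across frames; frames with |pitch| or |yaw| above 85
#' degrees are flagged for gimbal proximity.
#'
#' @param skull_poses,mandible_poses Lists of `rigid_pose` objects on a
#'   common frame base.
#' @param jcs A [jcs_definition()].
#' @param fs Sample rate of the pose sequence (Hz), stored on the output.
#' @return A list of class `jaw_kinematics` with [mast_ts()] fields `pitch`,
#'   `yaw`, `roll` (degrees), `gape` (alias of pitch) and logical
#'   `gimbal_warning`.
#' @export
jaw_rotations <- function(skull_poses, mandible_poses, jcs, fs = 250) {
  stopifnot(inherits(jcs, "jcs_definition"))
  if (length(skull_poses) != length(mandible_poses)) {
    stop("pose sequences must share a common time base", call. = FALSE)
  }
  n <- length(skull_poses)
  Rj <- jcs$rotation
  ang <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    Rrel <- t(skull_poses[[i]]$rotation) %*% mandible_poses[[i]]$rotation
    M <- t(Rj) %*% Rrel %*% Rj
    # M = Rz(pitch) %*% Ry(yaw) %*% Rx(roll)
    pitch <- atan2(M[2, 1], M[1, 1])
    yaw <- asin(max(-1, min(1, -M[3, 1])))
    roll <- atan2(M[3, 2], M[3, 3])
    ang[i, ] <- c(pitch, yaw, roll) * 180 / pi
  }
  ang <- apply(ang, 2, unwrap_deg)
  if (n == 1L) ang <- matrix(ang, 1, 3)
  gimbal <- abs(ang[, 1]) > 85 | abs(ang[, 2]) > 85
  structure(list(pitch = mast_ts(ang[, 1], fs),
                 yaw = mast_ts(ang[, 2], fs),
                 roll = mast_ts(ang[, 3], fs),
                 gape = mast_ts(ang[, 1], fs),
                 gimbal_warning = gimbal,
                 sample_rate = fs),
            class = "jaw_kinematics")
}

# unwrap a degree trace so frame-to-frame jumps never exceed 180
unwrap_deg <- function(x) {
  if (length(x) < 2L) return(x)
  d <- diff(x)
  jump <- round(d / 360)
  x - c(0, cumsum(jump) * 360)
}

#' Marker tracking precision
#'
#' Precision of rigid-body marker tracking, computed as the standard
#' deviation of the distance between a marker pair within one rigid body
#' (true distances are constant, so all variation is tracking noise); the
#' reported study precision is the mean of the per-pair standard deviations.
#'
#' @param distance_traces A list of [mast_ts()] inter-marker distance traces
#'   (or a single `mast_ts`).
#' @return A list with `per_pair_sd` (mm) and `precision` (mm, their mean).
#' @export
tracking_precision <- function(distance_traces) {
  if (inherits(distance_traces, "mast_ts")) {
    distance_traces <- list(distance_traces)
  }
  if (length(distance_traces) == 0L) {
    stop("at least one distance trace is required", call. = FALSE)
  }
  sds <- vapply(distance_traces, function(ts) {
    stopifnot(inherits(ts, "mast_ts"))
    stats::sd(ts$x)
  }, numeric(1))
  list(per_pair_sd = sds, precision = mean(sds))
}

#' Pairwise inter-marker distance traces of a rigid body
#'
#' @param markers Data frame of marker coordinates with columns
#'   `<name>_x`, `<name>_y`, `<name>_z` per marker (one row per frame).
#' @param fs Sample rate (Hz).
#' @return Named list of [mast_ts()] distance traces, one per marker pair.
#' @export
marker_pair_distances <- function(markers, fs = 250) {
  nm <- marker_names(markers)
  if (length(nm) < 2L) stop("need at least two markers", call. = FALSE)
  out <- list()
  for (i in seq_len(length(nm) - 1L)) {
    for (j in seq((i + 1L), length(nm))) {
      a <- marker_xyz(markers, nm[i])
      b <- marker_xyz(markers, nm[j])
      d <- sqrt(rowSums((a - b)^2))
      out[[paste(nm[i], nm[j], sep = "-")]] <- mast_ts(d, fs)
    }
  }
  out
}

# marker table helpers: columns named <marker>_x/_y/_z
marker_names <- function(markers) {
  cols <- names(markers)
  unique(sub("_[xyz]$", "", cols[grepl("_[xyz]$", cols)]))
}
marker_xyz <- function(markers, name) {
  as.matrix(markers[, paste0(name, c("_x", "_y", "_z")), drop = FALSE])
}

#' Segment a gape trace into masticatory cycles
#'
#' Delimits chew cycles at successive gape maxima using prominence-gated
#' peak detection (a local maximum qualifies if it stands above its
#' surrounding troughs by at least `min_prominence_frac` of the trace range;
#' ties at equal-height plateaus resolve to the earliest frame). Each cycle
#' runs from one maximum-gape frame to the next and carries a normalized
#' 0-100% grid (101 points by default, linear interpolation).
#'
#' @param gape A filtered gape (pitch) trace as a [mast_ts()].
#' @param min_prominence_frac Peak prominence gate as a fraction of the
#'   trace range (default 0.25).
#' @param npoints Normalized grid size (default 101: 0-100% in 1% steps).
#' @return A list of `mast_cycle` objects, each with `start_frame`,
#'   `end_frame`, `start_time`, `end_time`, `grid` (percent) and `gape`
#'   (gape resampled on the grid). Empty list (with a warning) when no
#'   peaks are found.
#' @export
segment_cycles <- function(gape, min_prominence_frac = 0.25, npoints = 101L) {
  stopifnot(inherits(gape, "mast_ts"))
  x <- gape$x
  rng <- diff(range(x))
  if (rng <= 0) {
    warning("gape trace is constant; no cycles detected")
    return(list())
  }
  peaks <- find_peaks(x, min_prominence = min_prominence_frac * rng)
  if (length(peaks) < 2L) {
    warning("fewer than two gape maxima; no full cycles detected")
    return(list())
  }
  tt <- ts_time(gape)
  lapply(seq_len(length(peaks) - 1L), function(k) {
    i0 <- peaks[k]; i1 <- peaks[k + 1L]
    grid <- seq(0, 100, length.out = npoints)
    seg <- stats::approx(seq(i0, i1), x[i0:i1],
                         xout = i0 + (i1 - i0) * grid / 100)$y
    structure(list(start_frame = i0, end_frame = i1,
                   start_time = tt[i0], end_time = tt[i1],
                   grid = grid, gape = seg),
              class = "mast_cycle")
  })
}

# interior local maxima with prominence gating; ties resolve to the earliest
# frame of a plateau
find_peaks <- function(x, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer())
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  # plateau handling: rising then flat then falling
  dx <- diff(x)
  starts <- which(dx > 0)
  for (s in starts) {
    i <- s + 1L
    if (i < n && dx[i] == 0) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) cand <- c(cand, i)
    }
  }
  cand <- sort(unique(cand))
  keep <- vapply(cand, function(p) {
    prominence(x, p) >= min_prominence
  }, logical(1))
  cand[keep]
}

prominence <- function(x, p) {
  n <- length(x)
  h <- x[p]
  # walk left/right to the nearest strictly higher sample (or the edge);
  # base on each side is the minimum along the walk
  left_min <- h
  i <- p
  while (i > 1L) {
    i <- i - 1L
    if (x[i] > h) break
    left_min <- min(left_min, x[i])
  }
  right_min <- h
  i <- p
  while (i < n) {
    i <- i + 1L
    if (x[i] > h) break
    right_min <- min(right_min, x[i])
  }
  h - max(left_min, right_min)
}

#' Resample a trace onto a cycle's normalized 0-100% grid
#'
#' @param ts A [mast_ts()] covering the cycle.
#' @param cycle A `mast_cycle` from [segment_cycles()].
#' @return Numeric vector on the cycle grid.
#' @export
cycle_resample <- function(ts, cycle) {
  stopifnot(inherits(ts, "mast_ts"), inherits(cycle, "mast_cycle"))
  tt <- ts_time(ts)
  if (cycle$start_time < tt[1] - 1e-9 ||
      cycle$end_time > tt[length(tt)] + 1e-9) {
    stop("cycle lies outside the trace", call. = FALSE)
  }
  xout <- cycle$start_time +
    (cycle$end_time - cycle$start_time) * cycle$grid / 100
  stats::approx(tt, ts$x, xout = xout, rule = 2)$y
}

#' Classify masticatory phases within one normalized cycle
#'
#' Splits a max-gape-to-max-gape cycle into fast closing (FC), slow closing
#' (SC, the power stroke), slow opening (SO) and fast opening (FO):
#' the FC/SC boundary is the first point after the peak closing speed at
#' which closing speed drops below `threshold` times that peak; the SC/SO
#' boundary is the end of minimum gape (occlusion); the SO/FO boundary is
#' the first point after occlusion at which opening speed rises above
#' `threshold` times the peak opening speed. Boundaries are reported as
#' percent of the cycle and the four phase durations sum to exactly 100.
#'
#' @param cycle A `mast_cycle` (from [segment_cycles()]), or a numeric gape
#'   vector on a uniform 0-100% grid.
#' @param threshold Velocity threshold as a fraction of the within-cycle
#'   peak closing/opening speed (default 0.25).
#' @return A list of class `mast_phases` with `fc_end`, `sc_end`, `so_end`
#'   (percent of cycle) and `durations` (named FC/SC/SO/FO, summing to 100).
#' @export
classify_phases <- function(cycle, threshold = 0.25) {
  g <- if (inherits(cycle, "mast_cycle")) cycle$gape else as.numeric(cycle)
  n <- length(g)
  if (n < 7L) stop("cycle grid too short", call. = FALSE)
  grid <- if (inherits(cycle, "mast_cycle")) {
    cycle$grid
  } else {
    seq(0, 100, length.out = n)
  }
  vel <- central_diff(g)                 # per grid step
  rng <- diff(range(g))
  if (rng <= 1e-12) stop("gape is constant within the cycle", call. = FALSE)
  tol <- 1e-6 * rng
  i_min <- which(g <= min(g) + tol)
  i_occ <- max(i_min)                    # end of occlusion
  if (i_occ <= 1L || i_occ >= n) {
    stop("no occlusion interior to the cycle: gape is monotonic",
         call. = FALSE)
  }
  closing <- pmax(0, -vel[1:i_occ])
  ip <- which.max(closing)
  pc <- closing[ip]
  if (pc <= 0) stop("no closing motion in cycle", call. = FALSE)
  after <- which(closing[ip:i_occ] < threshold * pc)
  i_fc <- if (length(after)) ip + after[1] - 1L else i_occ
  opening <- pmax(0, vel[i_occ:n])
  po <- max(opening)
  if (po <= 0) stop("no opening motion in cycle", call. = FALSE)
  rise <- which(opening > threshold * po)
  i_so <- if (length(rise)) i_occ + rise[1] - 1L else i_occ
  fc_end <- grid[i_fc]
  sc_end <- grid[i_occ]
  so_end <- grid[max(i_so, i_occ)]
  durations <- c(FC = fc_end, SC = sc_end - fc_end, SO = so_end - sc_end,
                 FO = 100 - so_end)
  structure(list(fc_end = fc_end, sc_end = sc_end, so_end = so_end,
                 durations = durations, threshold = threshold),
            class = "mast_phases")
}

#' @export
print.mast_phases <- function(x, ...) {
  cat(sprintf("<mast_phases> FC 0-%.2f%% | SC -%.2f%% | SO -%.2f%% | FO -100%%\n",
              x$fc_end, x$sc_end, x$so_end))
  invisible(x)
}
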