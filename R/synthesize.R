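#' Synthesize noisy marker trajectories for a rigid body
#'
#' Applies a pose sequence to a marker template and adds i.i.d. Gaussian
#' coordinate noise, emulating tracked radio-opaque beads.
#'
#' @param pose_sequence List of `rigid_pose` objects, one per frame.
#' @param marker_template n x 3 matrix of marker offsets (mm) in the body
#'   frame, with at least 3 non-collinear rows; row names become marker
#'   names (default `m1`, `m2`, ...).
#' @param noise_sd Coordinate noise standard deviation (mm).
#' @param seed Optional integer seed; when `NULL` the ambient RNG stream is
#'   used (as inside [synthesize_trial()], which seeds once per trial).
#' @param fs Sample rate (Hz) recorded in the `time_s` column.
#' @return Data frame with `frame`, `time_s` and `<marker>_x/_y/_z` columns.
#' @export
synthesize_markers <- function(pose_sequence, marker_template, noise_sd = 0,
                               seed = NULL, fs = 250) {
  tpl <- as.matrix(marker_template)
  if (nrow(tpl) < 3L || ncol(tpl) != 3L) {
    stop("marker template needs >= 3 markers in 3D", call. = FALSE)
  }
  sv <- svd(sweep(tpl, 2, colMeans(tpl)))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-12)) {
    stop("degenerate marker geometry: template markers are collinear",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  nm <- rownames(tpl)
  if (is.null(nm)) nm <- paste0("m", seq_len(nrow(tpl)))
  nf <- length(pose_sequence)
  out <- matrix(NA_real_, nf, 3L * nrow(tpl))
  for (i in seq_len(nf)) {
    p <- apply_pose(pose_sequence[[i]], tpl)
    if (noise_sd > 0) {
      p <- p + matrix(stats::rnorm(length(p), 0, noise_sd), nrow(p), 3L)
    }
    out[i, ] <- as.vector(t(p))
  }
  df <- as.data.frame(out)
  names(df) <- as.vector(t(outer(nm, c("_x", "_y", "_z"), paste0)))
  cbind(data.frame(frame = seq_len(nf),
                   time_s = (seq_len(nf) - 1) / fs), df)
}

#' Synthesize a raw EMG trace from an activation envelope
#'
#' Band-limited zero-mean Gaussian carrier noise, amplitude-modulated by the
#' activation envelope and superimposed on broadband baseline noise,
#' emulating a bipolar intramuscular EMG recording.
#'
#' @param activation Activation/recruitment envelope in \[0, 1\] (times the
#'   envelope amplitude) as a [mast_ts()] at the EMG sample rate.
#' @param carrier_band Carrier band in Hz, `c(low, high)`; must lie below
#'   Nyquist.
#' @param noise_floor_sd Baseline noise standard deviation (V).
#' @param gain Peak modulation amplitude (V per unit activation).
#' @param seed Optional integer seed (`NULL` = ambient RNG stream).
#' @return Raw EMG (V) as a [mast_ts()].
#' @export
synthesize_emg <- function(activation, carrier_band = c(80, 400),
                           noise_floor_sd = 0.01, gain = 1, seed = NULL) {
  stopifnot(inherits(activation, "mast_ts"))
  nyq <- activation$fs / 2
  if (carrier_band[2] >= nyq || carrier_band[1] <= 0 ||
      carrier_band[1] >= carrier_band[2]) {
    stop("carrier band must lie within (0, Nyquist)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(activation$x)
  bf <- signal::butter(2, carrier_band / nyq, type = "pass")
  carrier <- signal::filtfilt(bf, stats::rnorm(n + 400L))[201:(200L + n)]
  carrier <- carrier / stats::sd(carrier)
  x <- gain * activation$x * carrier + stats::rnorm(n, 0, noise_floor_sd)
  mast_ts(x, fs = activation$fs, t0 = activation$t0)
}

# masticatory gape waveform template: piecewise-linear gape (fraction of
# peak gape) against normalized cycle phase, with distinct speeds per phase
# so the velocity-threshold phase rule recovers the boundary positions.
gape_template <- function(phases = c(fc_end = 18.66, sc_end = 60.51,
                                     so_end = 68.84)) {
  list(phi = c(0, phases[["fc_end"]], phases[["sc_end"]],
               phases[["so_end"]], 100),
       frac = c(1, 0.2, 0, 1 / 30, 1))
}

gape_at_phase <- function(phi, tpl = gape_template()) {
  stats::approx(tpl$phi, tpl$frac, xout = phi, rule = 2)$y
}

#' Scenario design values for the synthetic trial generator
#'
#' Working- and balancing-side scenario parameters: peak-to-peak fascicle
#' strain (0.32 working, 0.23 balancing), EMG onset/offset as percent of the
#' gape cycle (onset 61.09 / 62.08%, offset 10.99 / 1.45%), and the
#' balancing-side envelope amplitude chosen so its integrated EMG is 47% of
#' the working side's.
#'
#' @param scenario `"working"` or `"balancing"`.
#' @return A list of scenario parameters.
#' @export
trial_scenario <- function(scenario = c("working", "balancing")) {
  scenario <- match.arg(scenario)
  on_w <- 61.09; off_w <- 10.99
  on_b <- 62.08; off_b <- 1.45
  dur_w <- 100 - on_w + off_w
  dur_b <- 100 - on_b + off_b
  if (scenario == "working") {
    list(scenario = "working", strain_ptp = 0.32,
         onset_pct = on_w, offset_pct = off_w,
         env_amp = 1, recruitment = 1)
  } else {
    list(scenario = "balancing", strain_ptp = 0.23,
         onset_pct = on_b, offset_pct = off_b,
         env_amp = 0.47 * dur_w / dur_b, recruitment = 0.47)
  }
}

# smooth boxcar with cosine ramps evaluated at times tt (s)
ramped_boxcar <- function(tt, t_on, t_off, ramp_s = 0.01) {
  up <- (tt - t_on) / ramp_s
  down <- (t_off - tt) / ramp_s
  v <- pmin(1, pmax(0, up)) * pmin(1, pmax(0, down))
  # cosine easing of the linear ramps
  0.5 - 0.5 * cos(pi * v)
}

#' Synthesize a ground-truthed masticatory trial
#'
#' Generates one complete synthetic feeding trial for a jaw-opening muscle
#' observed with marker-based kinematics, fluoromicrometry and EMG:
#'
#' * a cyclic gape (pitch) trajectory honouring the masticatory phase
#'   boundaries (fast closing to 18.66%, slow closing to 60.51%, slow
#'   opening to 68.84%, then fast opening), preceded by an EMG-silent
#'   occlusion rest that provides the resting-length and EMG-baseline
#'   windows;
#' * a fascicle strain trajectory proportional to gape (the muscle is
#'   shortest at maximum gape), with scenario peak-to-peak amplitude;
#' * noisy skull/mandible marker sets and an intramuscular bead pair whose
#'   separation follows the strain trajectory;
#' * a recruitment-scaled stimulation envelope gated between the scenario
#'   onset and (wrapped) offset percentages of each cycle;
#' * Hill-model activation and force in response to the imposed length
#'   trajectory (`L = l0 * (1 + strain)`, so the muscle stays on the
#'   ascending limb and plateau); and
#' * a raw synthetic EMG trace modulated by the stimulation envelope.
#'
#' A `truth` record stores every generating quantity (seed, strain
#' amplitude, burst timing, per-cycle work partitions from a direct
#' trapezoidal sum, cycle frames, phase boundaries) so downstream analyses
#' can be validated against ground truth; regeneration with the same seed is
#' bit-identical.
#'
#' @param scenario `"working"` or `"balancing"` (see [trial_scenario()]).
#' @param params A [hill_params()] object.
#' @param cycle_freq Chew cycle frequency (Hz, default 3.4).
#' @param n_cycles Number of chew cycles (>= 1, default 5).
#' @param seed Integer seed; all random draws come from one generator
#'   seeded here.
#' @param fs_kin Kinematic sample rate (Hz, default 250).
#' @param fs_emg EMG sample rate (Hz, default 2000).
#' @param rest_s Duration of the initial occlusion rest (s, default 1).
#' @param peak_gape_deg Peak gape (pitch) in degrees (default 15).
#' @param peak_yaw_deg Peak lateral (yaw) excursion during closing (deg).
#' @param bead_rest_mm Resting inter-bead distance (mm, default 6).
#' @param marker_noise_sd Marker coordinate noise sd (mm, default 0.036,
#'   which yields an inter-marker distance sd near 0.051 mm).
#' @param muscle_mass_g Muscle mass used for mass-specific truth work (g).
#' @param emg_gain,emg_noise_floor_sd See [synthesize_emg()].
#' @return An object of class `mast_trial`; see Details.
#' @export
synthesize_trial <- function(scenario = c("working", "balancing"),
                             params = hill_params(),
                             cycle_freq = 3.4, n_cycles = 5, seed = 1,
                             fs_kin = 250, fs_emg = 2000, rest_s = 1,
                             peak_gape_deg = 15, peak_yaw_deg = 3,
                             bead_rest_mm = 6, marker_noise_sd = 0.036,
                             muscle_mass_g = 0.691,
                             emg_gain = 1, emg_noise_floor_sd = 0.01) {
  sc <- trial_scenario(scenario)
  stopifnot(n_cycles >= 1, cycle_freq > 0, rest_s > 0)
  set.seed(seed)
  T_cyc <- 1 / cycle_freq
  ramp_s <- 0.12
  tail_s <- 0.2 * T_cyc
  t_cyc0 <- rest_s + ramp_s
  t_end <- t_cyc0 + n_cycles * T_cyc + tail_s
  tt <- seq(0, t_end, by = 1 / fs_kin)

  # normalized gape fraction over the whole trial
  gape_frac <- numeric(length(tt))
  in_ramp <- tt >= rest_s & tt < t_cyc0
  gape_frac[in_ramp] <- 0.5 - 0.5 * cos(pi * (tt[in_ramp] - rest_s) / ramp_s)
  in_cyc <- tt >= t_cyc0
  phi <- ((tt[in_cyc] - t_cyc0) / T_cyc * 100) %% 100
  # the tail after the final maximum-gape corner re-enters fast closing
  gape_frac[in_cyc] <- gape_at_phase(phi)
  gape_deg <- peak_gape_deg * gape_frac
  # lateral yaw excursion during jaw closing
  yaw_deg <- numeric(length(tt))
  yaw_deg[in_cyc][phi <= 60.51] <-
    peak_yaw_deg * sin(pi * phi[phi <= 60.51] / 60.51)

  # strain: muscle shortest at maximum gape, zero at occlusion/rest
  strain <- -sc$strain_ptp * gape_frac
  gape <- mast_ts(gape_deg, fs = fs_kin)
  strain_ts <- mast_ts(strain, fs = fs_kin)

  # stimulation envelope: active from onset% of each cycle through offset%
  # of the following cycle (wrapping through maximum gape)
  cyc_starts <- t_cyc0 + (seq_len(n_cycles) - 1) * T_cyc
  stim_at <- function(times) {
    v <- numeric(length(times))
    for (s0 in cyc_starts) {
      t_on <- s0 + sc$onset_pct / 100 * T_cyc
      t_off <- s0 + T_cyc + sc$offset_pct / 100 * T_cyc
      v <- pmax(v, ramped_boxcar(times, t_on, t_off))
    }
    sc$env_amp * v
  }
  stim_kin <- mast_ts(stim_at(tt), fs = fs_kin)

  # Hill-model force response to the imposed length trajectory
  activation <- simulate_activation(stim_kin, params)
  length_mm <- mast_ts(params$l0 * (1 + strain), fs = fs_kin)
  force <- simulate_muscle_force(length_mm, activation, params)

  # markers: static skull, mandible hinging about the condylar z-axis
  skull_tpl <- rbind(sk1 = c(0, 30, 10), sk2 = c(25, 35, 5),
                     sk3 = c(-10, 40, -8))
  mand_tpl <- rbind(md1 = c(20, -10, 4), md2 = c(35, -8, -5),
                    md3 = c(22, -20, 6))
  ident <- function(i) structure(list(rotation = diag(3),
                                      translation = c(0, 0, 0),
                                      rmse = 0, frame_index = i),
                                 class = "rigid_pose")
  skull_poses <- lapply(seq_along(tt), ident)
  mand_poses <- lapply(seq_along(tt), function(i) {
    structure(list(rotation = rot_z(gape_deg[i]) %*% rot_y(yaw_deg[i]),
                   translation = c(0, 0, 0), rmse = 0, frame_index = i),
              class = "rigid_pose")
  })
  skull_markers <- synthesize_markers(skull_poses, skull_tpl,
                                      noise_sd = marker_noise_sd, fs = fs_kin)
  mand_markers <- synthesize_markers(mand_poses, mand_tpl,
                                     noise_sd = marker_noise_sd, fs = fs_kin)
  # intramuscular bead pair: separation follows the strain trajectory
  bead_dir <- c(0.6, -0.8, 0)
  bead_base <- c(15, -5, 0)
  d_true <- bead_rest_mm * (1 + strain)
  nfr <- length(tt)
  b1 <- matrix(rep(bead_base, each = nfr), nfr, 3) +
    matrix(stats::rnorm(3 * nfr, 0, marker_noise_sd), nfr, 3)
  b2 <- matrix(rep(bead_base, each = nfr), nfr, 3) +
    outer(d_true, bead_dir) +
    matrix(stats::rnorm(3 * nfr, 0, marker_noise_sd), nfr, 3)
  muscle_markers <- data.frame(frame = seq_len(nfr), time_s = tt,
                               db1_x = b1[, 1], db1_y = b1[, 2],
                               db1_z = b1[, 3],
                               db2_x = b2[, 1], db2_y = b2[, 2],
                               db2_z = b2[, 3])

  # EMG at its own (higher) sample rate; the scenario amplitude scales the
  # modulation gain so the integrated-EMG recruitment ratio is by design
  tt_emg <- seq(0, t_end, by = 1 / fs_emg)
  emg <- synthesize_emg(mast_ts(stim_at(tt_emg) / sc$env_amp, fs = fs_emg),
                        gain = emg_gain * sc$env_amp,
                        noise_floor_sd = emg_noise_floor_sd)

  # truth work partitions: direct trapezoidal sum per cycle
  cyc_frames <- vapply(c(cyc_starts, t_cyc0 + n_cycles * T_cyc),
                       function(s) which.min(abs(tt - s)), integer(1))
  mass_kg <- muscle_mass_g / 1000
  truth_work <- t(vapply(seq_len(n_cycles), function(k) {
    i0 <- cyc_frames[k]; i1 <- cyc_frames[k + 1]
    f <- force$x[i0:i1]; L <- length_mm$x[i0:i1]
    m <- length(f)
    w <- 0.5 * (f[-m] + f[-1]) * (-(diff(L))) / mass_kg
    c(positive = sum(pmax(w, 0)), negative = sum(pmin(w, 0)), net = sum(w))
  }, numeric(3)))

  truth <- list(
    scenario = sc$scenario, seed = seed,
    strain_ptp = sc$strain_ptp,
    onset_pct = sc$onset_pct, offset_pct = sc$offset_pct,
    recruitment = sc$recruitment, env_amp = sc$env_amp,
    cycle_freq = cycle_freq, cycle_duration_s = T_cyc,
    n_cycles = n_cycles,
    cycle_frames = cyc_frames, cycle_start_times = c(cyc_starts,
                                                     t_cyc0 + n_cycles * T_cyc),
    phase_boundaries = c(fc_end = 18.66, sc_end = 60.51, so_end = 68.84),
    work = truth_work,
    net_power_w_kg = truth_work[, "net"] / T_cyc / 1000,
    bead_rest_mm = bead_rest_mm, marker_noise_sd = marker_noise_sd,
    peak_gape_deg = peak_gape_deg, muscle_mass_g = muscle_mass_g,
    rest_s = rest_s)

  structure(list(
    marker_tables = list(skull = skull_markers, mandible = mand_markers,
                         digastric = muscle_markers),
    templates = list(skull = skull_tpl, mandible = mand_tpl),
    condyles = list(left = c(0, 0, -6), right = c(0, 0, 6),
                    occlusal_dir = c(1, 0, 0)),
    emg = emg, force = force, length_mm = length_mm,
    stim_envelope = stim_kin, activation = activation,
    gape = gape, strain = strain_ts,
    params = params, fs_kin = fs_kin, fs_emg = fs_emg,
    truth = truth), class = "mast_trial")
}

#' @export
print.mast_trial <- function(x, ...) {
  cat(sprintf("<mast_trial> %s side, %d cycles @ %.2f Hz, seed %d\n",
              x$truth$scenario, x$truth$n_cycles, x$truth$cycle_freq,
              x$truth$seed))
  invisible(x)
}

#' Write a synthetic trial to disk as CSV + JSON
#'
#' Marker tables, EMG and the ergometer-style force/length record are
#' written as CSV (`time_s` first, then named channels); the truth record
#' as JSON.
#'
#' @param trial A [synthesize_trial()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "mast_trial"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (body in names(trial$marker_tables)) {
    utils::write.csv(trial$marker_tables[[body]],
                     file.path(dir, paste0("markers_", body, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(data.frame(time_s = ts_time(trial$emg),
                              volts = trial$emg$x),
                   file.path(dir, "emg.csv"), row.names = FALSE)
  utils::write.csv(data.frame(time_s = ts_time(trial$force),
                              force_n = trial$force$x,
                              length_mm = trial$length_mm$x),
                   file.path(dir, "force_length.csv"), row.names = FALSE)
  truth <- trial$truth
  truth$work <- as.data.frame(truth$work)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
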