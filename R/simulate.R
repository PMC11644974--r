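#' Simulation configuration
#'
#' Parameters of the synthetic infant-session generator. Positions follow a
#' Markov chain with log-normal dwell times separated by unlabelled transition
#' gaps; each (class, location) pair has a gravity orientation (unit vector in
#' the sensor frame) around which the accelerometer signal is built as
#' `g * orientation + band-limited movement noise`; the gyroscope reads the
#' angular velocity of the orientation path plus white noise; the magnetometer
#' reads a fixed world field rotated into the sensor frame plus noise.
#' Caregiver clap spikes, sampling dropouts, occasional 40 Hz recordings and
#' displaced-sensor (constant-acceleration) artefact spans emulate the rough
#' edges of real recordings.
#'
#' @param n_infants,sessions_per_infant,duration_s study size.
#' @param rate base sampling rate, Hz.
#' @param locations sensor locations to emit.
#' @param dwell_meanlog,dwell_sdlog named per-class log-normal dwell
#'   parameters (seconds).
#' @param transition_gap_s unlabelled gap between consecutive positions.
#' @param orientations list: class -> location -> unit 3-vector.
#' @param noise_sd named per-class movement-noise standard deviation (m/s^2).
#' @param noise_band movement-noise band, Hz.
#' @param jitter_sd orientation wander scale (dimensionless, small-angle).
#' @param mag_field world magnetic field vector (arbitrary units).
#' @param mag_noise_sd,gyro_noise_sd sensor noise levels.
#' @param dropout_per_min expected dropout events per minute per recording.
#' @param dropout_len_s dropout length range, seconds.
#' @param artifact_prob probability that a recording contains one
#'   displaced-sensor constant span.
#' @param artifact_len_s artefact span length range, seconds.
#' @param rate_switch_prob probability that a recording is delivered at 40 Hz.
#' @param clap_times_audio caregiver clap times on the audio track, seconds.
#' @param sync_delay_range true sensor-minus-audio delay range, seconds.
#' @param g gravity magnitude, m/s^2.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_infants = 20, sessions_per_infant = 3,
                              duration_s = 300, rate = 60,
                              locations = c("trunk_a", "leg_left", "leg_right"),
                              dwell_meanlog = NULL, dwell_sdlog = NULL,
                              transition_gap_s = 1,
                              orientations = default_orientations(),
                              noise_sd = c("Sitting" = 0.25, "Upright" = 0.3,
                                           "Supine" = 0.2, "Prone" = 0.25,
                                           "Hands and Knees" = 0.6),
                              noise_band = c(2, 15), jitter_sd = 0.03,
                              mag_field = c(0.4, 0.1, -0.3),
                              mag_noise_sd = 0.02, gyro_noise_sd = 0.05,
                              dropout_per_min = 1, dropout_len_s = c(0.05, 0.4),
                              artifact_prob = 0.1, artifact_len_s = c(2, 4),
                              rate_switch_prob = 0.05,
                              clap_times_audio = seq(2.5, by = 1.25, length.out = 5),
                              sync_delay_range = c(-2, 2), g = 9.81) {
  classes <- position_classes()
  if (is.null(dwell_meanlog)) {
    dwell_meanlog <- stats::setNames(c(log(18), log(18), log(18), log(18), log(7)),
                                     classes)
  }
  if (is.null(dwell_sdlog)) {
    dwell_sdlog <- stats::setNames(c(0.4, 0.4, 0.4, 0.4, 0.5), classes)
  }
  if (any(exp(dwell_meanlog) <= window_spec()$length_s)) {
    stop("dwell-time means must exceed the window length")
  }
  for (cl in classes) {
    for (loc in locations) {
      v <- orientations[[cl]][[loc]]
      if (is.null(v)) stop("no orientation for class ", cl, " at ", loc)
      if (abs(sqrt(sum(v^2)) - 1) > 1e-6) stop("orientation not unit-norm for ",
                                               cl, " at ", loc)
    }
  }
  structure(list(n_infants = n_infants, sessions_per_infant = sessions_per_infant,
                 duration_s = duration_s, rate = rate, locations = locations,
                 dwell_meanlog = dwell_meanlog, dwell_sdlog = dwell_sdlog,
                 transition_gap_s = transition_gap_s, orientations = orientations,
                 noise_sd = noise_sd, noise_band = noise_band,
                 jitter_sd = jitter_sd, mag_field = mag_field,
                 mag_noise_sd = mag_noise_sd, gyro_noise_sd = gyro_noise_sd,
                 dropout_per_min = dropout_per_min, dropout_len_s = dropout_len_s,
                 artifact_prob = artifact_prob, artifact_len_s = artifact_len_s,
                 rate_switch_prob = rate_switch_prob,
                 clap_times_audio = clap_times_audio,
                 sync_delay_range = sync_delay_range, g = g),
            class = "simulation_config")
}

#' Default per-class, per-location gravity orientations
#'
#' Distinct unit vectors for each of the five classes at each location,
#' loosely mimicking how a trunk, leg or arm sensor would be oriented in each
#' posture.
#'
#' @return Nested list: class -> location -> unit 3-vector.
#' @export
default_orientations <- function() {
  base <- list(
    "Sitting" = c(1, 0, 0),
    "Upright" = c(0, 1, 0),
    "Supine" = c(0, 0, 1),
    "Prone" = c(0, 0, -1),
    "Hands and Knees" = c(0.7, 0, -sqrt(1 - 0.49)))
  tweak <- list(trunk_a = diag(3),
                trunk_b = rot_z(0.15),
                leg_left = rot_z(0.6) %*% rot_x(0.5),
                leg_right = rot_z(-0.6) %*% rot_x(0.5),
                arm_left = rot_x(1.0) %*% rot_z(0.3),
                arm_right = rot_x(-1.0) %*% rot_z(0.3))
  lapply(base, function(v) {
    lapply(tweak, function(R) {
      u <- as.numeric(R %*% v)
      u / sqrt(sum(u^2))
    })
  })
}

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)

# Rotate the fixed world vector v into the sensor frame whose world-z maps to
# u(t) (rows of U). Rodrigues formula vectorised over time.
rotate_field <- function(U, v) {
  z <- c(0, 0, 1)
  ct <- U[, 3]                       # cos(theta) = u . z
  k <- cbind(-U[, 2], U[, 1], 0)     # z x u
  kn <- sqrt(rowSums(k^2))
  st <- kn
  safe <- kn > 1e-12
  k[safe, ] <- k[safe, ] / kn[safe]
  if (any(!safe)) k[!safe, ] <- matrix(c(1, 0, 0), sum(!safe), 3, byrow = TRUE)
  kv <- k[, 1] * v[1] + k[, 2] * v[2] + k[, 3] * v[3]
  kxv <- cbind(k[, 2] * v[3] - k[, 3] * v[2],
               k[, 3] * v[1] - k[, 1] * v[3],
               k[, 1] * v[2] - k[, 2] * v[1])
  out <- matrix(v, nrow(U), 3, byrow = TRUE) * ct + kxv * st +
    k * kv * (1 - ct)
  flip <- !safe & ct < 0             # u = -z: rotate by pi about x
  if (any(flip)) out[flip, ] <- matrix(c(v[1], -v[2], -v[3]), sum(flip), 3,
                                       byrow = TRUE)
  out
}

# Band-limited noise with (approximately) the requested per-sample sd profile.
bandlimited_noise <- function(n, rate, band, sd_profile) {
  if (n < 24) return(stats::rnorm(n, sd = sd_profile))
  bf <- signal::butter(2, band / (rate / 2), type = "pass")
  w <- stats::rnorm(n)
  x <- signal::filtfilt(bf, w)
  x <- x / stats::sd(x)
  x * sd_profile
}

smooth_noise <- function(n, rate, cutoff = 0.4) {
  if (n < 24) return(numeric(n))
  bf <- signal::butter(2, cutoff / (rate / 2), type = "low")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  x / max(stats::sd(x), 1e-12)
}

# Draw the position sequence: dwells separated by transition gaps.
draw_position_sequence <- function(cfg) {
  classes <- position_classes()
  t <- 0
  rows <- list()
  prev <- 0L
  while (t < cfg$duration_s) {
    nxt <- if (prev == 0L) sample.int(5L, 1) else
      sample(setdiff(seq_len(5L), prev), 1)
    dwell <- stats::rlnorm(1, cfg$dwell_meanlog[classes[nxt]],
                           cfg$dwell_sdlog[classes[nxt]])
    end <- min(t + dwell, cfg$duration_s)
    rows[[length(rows) + 1L]] <- data.frame(start = t, end = end,
                                            class = classes[nxt])
    t <- end + cfg$transition_gap_s
    prev <- nxt
  }
  do.call(rbind, rows)
}

raw_label_for_class <- function(class) {
  map <- position_class_map()
  cands <- names(map)[map == class]
  cands[sample.int(length(cands), 1)]
}

#' Simulate one session and write its files
#'
#' Draws the position sequence, synthesises all sensor channels, the
#' caregiver clap track and the annotation file (in audio time, i.e. shifted
#' by the true delay), applies dropouts, artefact spans and rate switches, and
#' writes the session directory: one CSV per sensor, `annotations.tsv`,
#' `caregiver.csv`, `manifest.yaml` and `truth.json`.
#'
#' @param cfg a [simulation_config()].
#' @param infant_id infant identifier.
#' @param session_idx session number for this infant.
#' @param dir output directory (the session directory is created inside).
#' @param seed integer seed; identical seeds reproduce identical files.
#' @return Invisibly, the manifest path (attribute `truth` carries the ground
#'   truth list).
#' @export
simulate_session <- function(cfg, infant_id, session_idx = 1L, dir, seed) {
  set.seed(seed)
  classes <- position_classes()
  session_id <- sprintf("%s_s%02d", infant_id, session_idx)
  sdir <- file.path(dir, session_id)
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  rate <- cfg$rate
  n <- as.integer(cfg$duration_s * rate)
  t <- (seq_len(n) - 1) / rate
  seq_pos <- draw_position_sequence(cfg)
  seq_pos$label <- vapply(seq_pos$class, raw_label_for_class, character(1))
  delay <- stats::runif(1, cfg$sync_delay_range[1], cfg$sync_delay_range[2])
  # per-sample class code (0 in transition gaps)
  code <- integer(n)
  for (i in seq_len(nrow(seq_pos))) {
    code[t >= seq_pos$start[i] & t < seq_pos$end[i]] <- match(seq_pos$class[i],
                                                              classes)
  }
  sd_prof <- ifelse(code == 0L, mean(cfg$noise_sd),
                    cfg$noise_sd[classes[pmax(code, 1L)]])
  truth_artifacts <- list()
  for (loc in cfg$locations) {
    # orientation path: class orientation, linearly bridged through gaps,
    # with slow small-angle wander
    base_u <- matrix(NA_real_, n, 3)
    for (i in seq_len(nrow(seq_pos))) {
      sel <- t >= seq_pos$start[i] & t < seq_pos$end[i]
      base_u[sel, ] <- matrix(cfg$orientations[[seq_pos$class[i]]][[loc]],
                              sum(sel), 3, byrow = TRUE)
    }
    for (j in 1:3) {  # bridge gaps
      base_u[, j] <- stats::approx(t[code > 0], base_u[code > 0, j], xout = t,
                                   rule = 2)$y
    }
    U <- base_u + cfg$jitter_sd *
      cbind(smooth_noise(n, rate), smooth_noise(n, rate), smooth_noise(n, rate))
    U <- U / sqrt(rowSums(U^2))
    acc <- cfg$g * U + cbind(bandlimited_noise(n, rate, cfg$noise_band, sd_prof),
                             bandlimited_noise(n, rate, cfg$noise_band, sd_prof),
                             bandlimited_noise(n, rate, cfg$noise_band, sd_prof))
    dU <- rbind(0, diff(U)) * rate
    gyro <- cbind(U[, 2] * dU[, 3] - U[, 3] * dU[, 2],
                  U[, 3] * dU[, 1] - U[, 1] * dU[, 3],
                  U[, 1] * dU[, 2] - U[, 2] * dU[, 1]) +
      matrix(stats::rnorm(3 * n, sd = cfg$gyro_noise_sd), n, 3)
    mag <- rotate_field(U, cfg$mag_field) +
      matrix(stats::rnorm(3 * n, sd = cfg$mag_noise_sd), n, 3)
    # displaced-sensor artefact: an exactly constant acceleration span
    if (stats::runif(1) < cfg$artifact_prob) {
      len <- stats::runif(1, cfg$artifact_len_s[1], cfg$artifact_len_s[2])
      a0 <- stats::runif(1, 15, max(16, cfg$duration_s - len - 1))
      sel <- t >= a0 & t < a0 + len
      acc[sel, ] <- matrix(acc[which(sel)[1], ], sum(sel), 3, byrow = TRUE)
      truth_artifacts[[length(truth_artifacts) + 1L]] <-
        list(location = loc, start = a0, end = a0 + len)
    }
    keep <- rep(TRUE, n)
    n_drop <- stats::rpois(1, cfg$dropout_per_min * cfg$duration_s / 60)
    if (n_drop > 0) {
      for (d in seq_len(n_drop)) {
        len <- stats::runif(1, cfg$dropout_len_s[1], cfg$dropout_len_s[2])
        d0 <- stats::runif(1, 1, cfg$duration_s - len - 1)
        keep[t >= d0 & t < d0 + len] <- FALSE
      }
    }
    if (stats::runif(1) < cfg$rate_switch_prob) {
      t40 <- seq(0, max(t), by = 1 / 40)
      interp <- function(m) vapply(1:3, function(j)
        stats::spline(t, m[, j], xout = t40)$y, numeric(length(t40)))
      rec <- sensor_recording(loc, t40, interp(acc), interp(gyro), interp(mag), 40)
    } else {
      rec <- sensor_recording(loc, t[keep], acc[keep, ], gyro[keep, ],
                              mag[keep, ], 60)
    }
    write_sensor_csv(rec, file.path(sdir, paste0(loc, ".csv")))
  }
  # caregiver arm norms with clap spikes at audio time + delay
  clap_imu <- cfg$clap_times_audio + delay
  clap_imu <- clap_imu[clap_imu > 0.5 & clap_imu < cfg$duration_s - 0.5]
  spike <- function() {
    x <- cfg$g + stats::rnorm(n, sd = 0.08)
    for (tc in clap_imu) x <- x + 30 * exp(-((t - round(tc * rate) / rate) / 0.02)^2)
    x
  }
  caregiver <- data.frame(t = t, left = spike(), right = spike())
  data.table::fwrite(caregiver, file.path(sdir, "caregiver.csv"))
  # annotations in audio time
  ann <- annotation_track(seq_pos$start - delay, seq_pos$end - delay,
                          seq_pos$label, source = "synthetic")
  write_annotations(ann, file.path(sdir, "annotations.tsv"))
  age <- sample(c(4, 6, 9, 12), 1)
  task <- sample(c("book_sharing", "manipulative", "rattles"), 1)
  man <- list(infant_id = infant_id, session_id = session_id,
              age_point = age, task = task,
              sensors = stats::setNames(as.list(paste0(cfg$locations, ".csv")),
                                        cfg$locations),
              annotations = "annotations.tsv", caregiver = "caregiver.csv",
              clap_times = as.numeric(cfg$clap_times_audio))
  man_path <- file.path(sdir, "manifest.yaml")
  yaml::write_yaml(man, man_path)
  truth <- list(session_id = session_id, sync_delay = delay,
                intervals = data.frame(start = seq_pos$start, end = seq_pos$end,
                                       class = seq_pos$class),
                artifacts = truth_artifacts)
  jsonlite::write_json(truth, file.path(sdir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(structure(man_path, truth = truth))
}

#' Generate a named benchmark dataset
#'
#' Three presets: `separable` (distinct orientations, low noise), `noisy`
#' (overlapping Prone / Hands-and-Knees orientations with higher movement
#' noise) and `ambiguous_hk` (short, transitional Hands-and-Knees dwells).
#'
#' @param preset preset name.
#' @param dir output directory.
#' @param seed base seed; per-session seeds are derived deterministically.
#' @param n_infants,sessions_per_infant,duration_s study size overrides.
#' @param locations sensor locations to emit.
#' @return Character vector of manifest paths (attribute `truth`: list of
#'   ground-truth records).
#' @export
make_benchmark_suite <- function(preset = c("separable", "noisy", "ambiguous_hk"),
                                 dir, seed = 1L, n_infants = 20,
                                 sessions_per_infant = 3, duration_s = 300,
                                 locations = c("trunk_a", "leg_left", "leg_right")) {
  preset <- match.arg(preset)
  cfg <- simulation_config(n_infants = n_infants,
                           sessions_per_infant = sessions_per_infant,
                           duration_s = duration_s, locations = locations)
  if (preset == "noisy") {
    ori <- cfg$orientations
    for (loc in names(ori[["Prone"]])) {
      u <- 0.85 * ori[["Prone"]][[loc]] + 0.15 * ori[["Hands and Knees"]][[loc]]
      ori[["Hands and Knees"]][[loc]] <- u / sqrt(sum(u^2))
    }
    cfg$orientations <- ori
    cfg$noise_sd[] <- cfg$noise_sd * 2.5
  } else if (preset == "ambiguous_hk") {
    cfg$dwell_meanlog["Hands and Knees"] <- log(3.5)
    cfg$dwell_sdlog["Hands and Knees"] <- 0.5
  }
  manifests <- character()
  truths <- list()
  for (i in seq_len(cfg$n_infants)) {
    infant <- sprintf("inf%02d", i)
    for (j in seq_len(cfg$sessions_per_infant)) {
      s <- as.integer(seed) + 977L * i + 13L * j
      mp <- simulate_session(cfg, infant, j, dir, seed = s)
      manifests <- c(manifests, as.character(mp))
      truths[[length(truths) + 1L]] <- attr(mp, "truth")
    }
  }
  structure(manifests, truth = truths)
}
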