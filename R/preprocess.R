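#' Preprocessing configuration
#'
#' @param target_rate output sampling rate in Hz.
#' @param lp_cutoff,hp_cutoff low/high-pass cutoff frequencies in Hz. The
#'   default 1 Hz for both gives a complementary gravity (DC) / movement (AC)
#'   split of the accelerometer signal.
#' @param filter_order Butterworth order (applied forward-backward, so the
#'   effective attenuation is doubled).
#' @param artifact_window_s block length for the low-variance artefact rule.
#' @param artifact_var_threshold variance threshold below which an
#'   acceleration-magnitude block is flagged as a displaced-sensor artefact.
#' @param max_gap_s longest gap that is spline-interpolated; longer gaps are
#'   filled numerically but masked as artefacts.
#' @param clap_count expected number of caregiver synchronisation claps.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(target_rate = 60, lp_cutoff = 1, hp_cutoff = 1,
                              filter_order = 4, artifact_window_s = 0.1,
                              artifact_var_threshold = 1e-6, max_gap_s = 1,
                              clap_count = 5) {
  if (lp_cutoff >= target_rate / 2 || hp_cutoff >= target_rate / 2) {
    stop("filter cutoffs must be below the Nyquist frequency ", target_rate / 2, " Hz")
  }
  if (artifact_window_s <= 0) stop("artifact_window_s must be positive")
  structure(list(target_rate = target_rate, lp_cutoff = lp_cutoff,
                 hp_cutoff = hp_cutoff, filter_order = filter_order,
                 artifact_window_s = artifact_window_s,
                 artifact_var_threshold = artifact_var_threshold,
                 max_gap_s = max_gap_s, clap_count = clap_count),
            class = "preprocess_config")
}

#' Fill sampling gaps by cubic-spline interpolation
#'
#' Rebuilds a uniform time base at the recording's nominal rate and fills
#' missing samples per channel with a cubic spline through the observed
#' samples. Observed samples are left untouched. Gaps longer than `max_gap_s`
#' are still filled numerically (the filters need a complete series) but are
#' flagged in the artefact mask.
#'
#' @param rec a [sensor_recording()].
#' @param max_gap_s longest gap to interpolate silently, in seconds.
#' @return A [sensor_recording()] on a uniform grid.
#' @export
fill_gaps <- function(rec, max_gap_s = 1) {
  dt <- 1 / rec$rate
  n_obs <- length(rec$t)
  if (n_obs < 4) stop("need at least 4 samples for cubic-spline gap filling")
  t0 <- rec$t[1]
  idx <- as.integer(round((rec$t - t0) / dt))
  if (anyDuplicated(idx)) stop("timestamps collapse onto duplicate grid points")
  n <- idx[n_obs] + 1L
  if (n == n_obs && all(idx == seq_len(n_obs) - 1L)) {
    rec$t <- t0 + (seq_len(n_obs) - 1) * dt  # regularise jitter only
    return(rec)
  }
  grid_t <- t0 + (seq_len(n) - 1) * dt
  obs <- rep(FALSE, n); obs[idx + 1L] <- TRUE
  mask <- rep(FALSE, n); mask[idx + 1L] <- rec$mask
  # flag gaps longer than max_gap_s
  gap_id <- cumsum(obs)[!obs]
  if (length(gap_id) > 0) {
    runs <- rle(gap_id)
    long <- runs$values[runs$lengths * dt > max_gap_s]
    mask[!obs][gap_id %in% long] <- TRUE
  }
  fill <- function(ch) {
    out <- matrix(NA_real_, n, 3)
    for (j in 1:3) {
      out[, j] <- stats::spline(x = grid_t[obs], y = ch[, j], xout = grid_t,
                                method = "fmm")$y
      out[obs, j] <- ch[, j]
    }
    out
  }
  sensor_recording(rec$location, grid_t, fill(rec$acc), fill(rec$gyro),
                   fill(rec$mag), rec$rate, mask)
}

# Polyphase rational resampler, up 3 / down 2 (40 -> 60 Hz). 72-tap fir1
# low-pass at the input Nyquist; polyphase branches renormalised so DC passes
# exactly; reflective edge padding suppresses boundary transients.
poly_resample_3_2 <- function(x) {
  n <- length(x)
  pad <- 36L
  if (n < pad + 2) stop("series too short to resample")
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  h <- 3 * signal::fir1(72, 1 / 3)
  L <- length(h)
  for (ph in 0:2) {
    sel <- seq(ph + 1, L, by = 3)
    h[sel] <- h[sel] / sum(h[sel])
  }
  up <- numeric(3 * length(xp))
  up[seq(1, length(up), by = 3)] <- xp
  y <- stats::filter(c(up, numeric(L)), h, sides = 1)
  d <- (L - 1) / 2
  y <- y[(d + 1):(d + length(up))]
  y <- y[seq(1, length(y), by = 2)]
  y[(round(pad * 3 / 2) + 1):(round(pad * 3 / 2) + ceiling(n * 3 / 2))]
}

#' Resample a recording to the target rate
#'
#' 60 Hz input is returned unchanged; 40 Hz input is polyphase-resampled
#' (up 3, down 2) with anti-alias filtering. The artefact mask is carried over
#' by nearest-sample lookup.
#'
#' @param rec a [sensor_recording()] on a uniform grid (see [fill_gaps()]).
#' @param cfg a [preprocess_config()].
#' @return A [sensor_recording()] at `cfg$target_rate`.
#' @export
resample_to_target <- function(rec, cfg = preprocess_config()) {
  if (cfg$target_rate != 60) stop("unsupported target rate ", cfg$target_rate)
  if (rec$rate == 60) return(rec)
  if (rec$rate != 40) stop("unsupported input rate ", rec$rate)
  n <- length(rec$t)
  m <- ceiling(n * 3 / 2)
  t_out <- rec$t[1] + (seq_len(m) - 1) / 60
  res <- function(ch) apply(ch, 2, poly_resample_3_2)
  src <- pmin(n, as.integer(round((t_out - rec$t[1]) * 40)) + 1L)
  sensor_recording(rec$location, t_out, res(rec$acc), res(rec$gyro),
                   res(rec$mag), 60, rec$mask[src])
}

acc_magnitude <- function(acc) sqrt(rowSums(acc^2))

#' Mask low-variance artefacts
#'
#' Flags spans where the sensor lay still after being displaced: the variance
#' of the acceleration magnitude is computed in non-overlapping blocks of
#' `artifact_window_s` seconds, and blocks with variance below
#' `artifact_var_threshold` are added to the artefact mask. The trailing
#' partial block is left untouched.
#'
#' @param rec a [sensor_recording()].
#' @param cfg a [preprocess_config()].
#' @return The recording with an updated mask.
#' @export
mask_artifacts <- function(rec, cfg = preprocess_config()) {
  n <- length(rec$t)
  w <- as.integer(round(cfg$artifact_window_s * rec$rate))
  if (n < w || w < 2) return(rec)
  nb <- n %/% w
  m <- acc_magnitude(rec$acc)[seq_len(nb * w)]
  blocks <- matrix(m, nrow = w)
  v <- colSums(blocks^2) / (w - 1) - colSums(blocks)^2 / (w * (w - 1))
  v <- pmax(v, 0)
  flag <- v < cfg$artifact_var_threshold
  rec$mask[seq_len(nb * w)] <- rec$mask[seq_len(nb * w)] | rep(flag, each = w)
  rec
}

# Zero-phase Butterworth low-pass (forward-backward), with mean removal and
# odd-reflection padding so that constants pass exactly and start-up
# transients stay outside the returned span.
lowpass <- function(x, cutoff, rate, order = 4) {
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  n <- length(x)
  mu <- mean(x)
  xc <- x - mu
  pad <- min(n - 1, ceiling(6 * rate / cutoff))
  xp <- c(2 * xc[1] - xc[(pad + 1):2], xc, 2 * xc[n] - xc[(n - 1):(n - pad)])
  y <- signal::filtfilt(bf, xp)
  y[(pad + 1):(pad + n)] + mu
}

#' Derive the preprocessed signal set for one recording
#'
#' Splits the accelerometer into low-pass (gravity, DC) and high-pass
#' (movement, AC) parts with zero-phase Butterworth filters, computes Euclidean
#' norms of the raw, LP and HP acceleration triples, and tilt angles (roll,
#' pitch) from the LP acceleration. The high-pass part is the complement
#' `acc - LP(acc at hp_cutoff)`, so `acc_lp + acc_hp == acc` exactly when both
#' cutoffs coincide.
#'
#' @param rec a 60 Hz [sensor_recording()] with gaps filled.
#' @param cfg a [preprocess_config()].
#' @return A list of class `derived_signals`: `channels` (T x 20 matrix with
#'   named columns), `location`, `t`, `mask`, `rate`.
#' @export
derive_signals <- function(rec, cfg = preprocess_config()) {
  if (cfg$lp_cutoff >= rec$rate / 2 || cfg$hp_cutoff >= rec$rate / 2) {
    stop("filter cutoff at or above Nyquist")
  }
  acc_lp <- apply(rec$acc, 2, lowpass, cutoff = cfg$lp_cutoff,
                  rate = rec$rate, order = cfg$filter_order)
  base_hp <- if (cfg$hp_cutoff == cfg$lp_cutoff) acc_lp else
    apply(rec$acc, 2, lowpass, cutoff = cfg$hp_cutoff,
          rate = rec$rate, order = cfg$filter_order)
  acc_hp <- rec$acc - base_hp
  rp <- roll_pitch(acc_lp)
  ch <- cbind(rec$acc, acc_lp, acc_hp,
              acc_magnitude(rec$acc), acc_magnitude(acc_lp),
              acc_magnitude(acc_hp),
              rec$gyro, rec$mag, rp$roll, rp$pitch)
  colnames(ch) <- c("acc_x", "acc_y", "acc_z",
                    "acc_lp_x", "acc_lp_y", "acc_lp_z",
                    "acc_hp_x", "acc_hp_y", "acc_hp_z",
                    "norm", "norm_lp", "norm_hp",
                    "gyro_x", "gyro_y", "gyro_z",
                    "mag_x", "mag_y", "mag_z",
                    "roll", "pitch")
  structure(list(channels = ch, location = rec$location, t = rec$t,
                 mask = rec$mask, rate = rec$rate),
            class = "derived_signals")
}

#' Tilt angles from low-pass acceleration
#'
#' Aerospace accelerometer-tilt convention:
#' `roll = atan2(a_y, a_z)`, `pitch = atan2(-a_x, sqrt(a_y^2 + a_z^2))`.
#' Samples with zero norm propagate as `NA` (the window containing them is
#' later rejected).
#'
#' @param acc_lp T x 3 low-pass acceleration matrix.
#' @return List with numeric vectors `roll` (radians, (-pi, pi]) and `pitch`
#'   (radians, \[-pi/2, pi/2\]).
#' @export
roll_pitch <- function(acc_lp) {
  nrm <- acc_magnitude(acc_lp)
  roll <- atan2(acc_lp[, 2], acc_lp[, 3])
  pitch <- atan2(-acc_lp[, 1], sqrt(acc_lp[, 2]^2 + acc_lp[, 3]^2))
  zero <- nrm == 0
  roll[zero] <- NA_real_
  pitch[zero] <- NA_real_
  list(roll = roll, pitch = pitch)
}

#' Full preprocessing of one recording
#'
#' Gap filling, resampling to the target rate and artefact masking, in that
#' order. Idempotent on clean 60 Hz input.
#'
#' @param rec a [sensor_recording()].
#' @param cfg a [preprocess_config()].
#' @return A clean 60 Hz [sensor_recording()].
#' @export
preprocess_recording <- function(rec, cfg = preprocess_config()) {
  rec <- fill_gaps(rec, max_gap_s = cfg$max_gap_s)
  rec <- resample_to_target(rec, cfg)
  mask_artifacts(rec, cfg)
}

# Local maxima above a prominence-style threshold (5 x MAD above the median),
# separated by at least min_sep seconds.
detect_claps <- function(t, x, min_sep = 0.25) {
  med <- stats::median(x)
  thr <- med + 5 * stats::mad(x)
  cand <- which(x > thr)
  cand <- cand[cand > 1 & cand < length(x)]
  cand <- cand[x[cand] >= x[cand - 1] & x[cand] >= x[cand + 1]]
  if (length(cand) == 0) return(numeric())
  # enforce separation, keeping the taller peak
  keep <- integer()
  for (i in cand[order(-x[cand])]) {
    if (all(abs(t[i] - t[keep]) >= min_sep)) keep <- c(keep, i)
  }
  sort(t[keep])
}

#' Estimate the annotation-to-sensor synchronisation delay
#'
#' Detects the caregiver's clap spikes in the average of the two arm
#' acceleration-norm series and matches them, in order, to the clap times
#' annotated on the audio track. The returned delay is the median of
#' `peak_time - audio_time`; adding it to annotation times aligns them with
#' sensor time. When detected and annotated counts differ, a best-effort
#' ordered matching (minimum spread of the pairwise differences) is used with
#' a warning.
#'
#' @param caregiver data frame with columns `t`, `left`, `right`: the two arm
#'   acceleration norms on a common time base.
#' @param clap_times_audio annotated clap times in audio time, seconds.
#' @param cfg a [preprocess_config()] (`clap_count` is the expected count).
#' @return Delay in seconds.
#' @export
estimate_sync_delay <- function(caregiver, clap_times_audio,
                                cfg = preprocess_config()) {
  if (length(clap_times_audio) < 1) stop("need at least one annotated clap time")
  stopifnot(all(c("t", "left", "right") %in% names(caregiver)))
  avg <- (caregiver$left + caregiver$right) / 2
  peaks <- detect_claps(caregiver$t, avg)
  a <- sort(clap_times_audio)
  if (length(peaks) == 0) stop("sync error: no clap peaks detected")
  if (length(peaks) != length(a)) {
    warning(sprintf("detected %d clap peak(s) but %d annotated; using best-effort ordered matching",
                    length(peaks), length(a)))
  }
  k <- min(length(peaks), length(a))
  pick_best <- function(long, short) {
    cmb <- utils::combn(length(long), length(short))
    if (ncol(cmb) > 5000) cmb <- cmb[, seq_len(5000), drop = FALSE]
    spread <- apply(cmb, 2, function(ix) {
      d <- long[ix] - short
      max(d) - min(d)
    })
    long[cmb[, which.min(spread)]]
  }
  if (length(peaks) == length(a)) {
    d <- peaks - a
  } else if (length(peaks) > length(a)) {
    d <- pick_best(peaks, a) - a
  } else {
    d <- peaks - pick_best(a, peaks)
  }
  stats::median(d)
}

#' Synchronise a session's annotations to sensor time
#'
#' Estimates the delay from the caregiver clap track (if present) and stores
#' it on the session. Sessions without a caregiver track keep a zero delay.
#'
#' @param session an [imu_session()].
#' @param cfg a [preprocess_config()].
#' @return The session with `sync_delay` set.
#' @export
sync_session <- function(session, cfg = preprocess_config()) {
  if (!is.null(session$caregiver) && length(session$clap_times_audio) > 0) {
    session$sync_delay <- estimate_sync_delay(session$caregiver,
                                              session$clap_times_audio, cfg)
  } else if (is.na(session$sync_delay)) {
    session$sync_delay <- 0
  }
  session
}

#' Preprocess every recording in a session
#'
#' @param session an [imu_session()].
#' @param cfg a [preprocess_config()].
#' @return The session with cleaned recordings and `sync_delay` estimated.
#' @export
preprocess_session <- function(session, cfg = preprocess_config()) {
  session$recordings <- lapply(session$recordings, preprocess_recording, cfg = cfg)
  sync_session(session, cfg)
}
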