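# In-code builders for small deterministic sessions and recordings.

make_recording <- function(location = "trunk_a", duration = 10, rate = 60,
                           acc_fun = NULL, seed = 1, noise = 0.1) {
  set.seed(seed)
  n <- as.integer(duration * rate)
  t <- (seq_len(n) - 1) / rate
  acc <- if (is.null(acc_fun)) {
    cbind(rnorm(n, 0, noise), rnorm(n, 0, noise), rnorm(n, 9.81, noise))
  } else acc_fun(t)
  sensor_recording(location, t, acc,
                   gyro = matrix(rnorm(3 * n, 0, noise), n, 3),
                   mag = matrix(rnorm(3 * n, 0.3, noise), n, 3),
                   rate = rate)
}

# A session whose per-class gravity orientation is piecewise constant, built
# entirely in memory. `segments` is a data.frame(start, end, label) with raw
# annotation labels.
make_session <- function(infant_id = "i01", segments = NULL, duration = 30,
                         locations = c("trunk_a", "leg_left"), seed = 1,
                         noise = 0.15, sync_delay = 0, session_id = infant_id) {
  set.seed(seed)
  if (is.null(segments)) {
    b1 <- duration / 3; b2 <- 2 * duration / 3
    segments <- data.frame(start = c(0, b1 + 0.5, b2 + 0.5),
                           end = c(b1, b2, duration),
                           label = c("supine", "independent sitting", "prone"))
  }
  ori <- list("Sitting" = c(1, 0, 0), "Upright" = c(0, 1, 0),
              "Supine" = c(0, 0, 1), "Prone" = c(0, 0, -1),
              "Hands and Knees" = c(0.7, 0, -sqrt(0.51)))
  rate <- 60
  n <- as.integer(duration * rate)
  t <- (seq_len(n) - 1) / rate
  cls <- map_to_static(segments$label)
  recs <- lapply(locations, function(loc) {
    base <- matrix(0.5, n, 3)  # transition filler orientation
    for (i in seq_len(nrow(segments))) {
      sel <- t >= segments$start[i] & t < segments$end[i]
      u <- ori[[cls[i]]]
      if (loc != "trunk_a") u <- rev(u)  # distinct orientation per location
      base[sel, ] <- matrix(u, sum(sel), 3, byrow = TRUE)
    }
    acc <- 9.81 * base + matrix(rnorm(3 * n, 0, noise), n, 3)
    sensor_recording(loc, t, acc,
                     gyro = matrix(rnorm(3 * n, 0, noise), n, 3),
                     mag = matrix(rnorm(3 * n, 0.3, noise / 2), n, 3),
                     rate = rate)
  })
  names(recs) <- locations
  ann <- annotation_track(segments$start - sync_delay, segments$end - sync_delay,
                          segments$label)
  imu_session(infant_id, 9, "rattles", recs, ann, sync_delay = sync_delay,
              session_id = session_id)
}

# A small multi-infant session list with separable class structure.
make_cohort <- function(n_infants = 6, duration = 30, seed = 1,
                        locations = c("trunk_a", "leg_left")) {
  labs <- c("supine", "independent sitting", "prone", "standing upright",
            "crawling")
  sessions <- lapply(seq_len(n_infants), function(i) {
    set.seed(seed + i)
    ord <- sample(labs)
    k <- length(ord)
    bounds <- seq(0, duration, length.out = k + 1)
    seg <- data.frame(start = bounds[-(k + 1)] + c(0, rep(0.5, k - 1)),
                      end = bounds[-1], label = ord)
    make_session(sprintf("i%02d", i), segments = seg, duration = duration,
                 locations = locations, seed = seed + 100 * i)
  })
  sessions
}

# A feature table built directly (no signal pipeline): class signal carried by
# designated (group, signal) columns, all other columns pure noise.
make_synthetic_table <- function(n_infants = 10, windows_per_infant = 40,
                                 seed = 1,
                                 signal_cells = list(c("statistical", "acc_lp"))) {
  set.seed(seed)
  classes <- position_classes()
  groups <- c("statistical", "frequency", "summary", "difference", "correlation")
  desc <- do.call(rbind, lapply(groups, function(g) {
    data.frame(location = "trunk_a", signal = rep(c("acc_lp", "gyro"), each = 6),
               group = g, name = paste0(g, ".f", 1:12),
               stringsAsFactors = FALSE)
  }))
  W <- n_infants * windows_per_infant
  y <- sample(classes, W, replace = TRUE)
  mu <- matrix(stats::rnorm(length(classes) * nrow(desc), sd = 0), length(classes))
  X <- matrix(stats::rnorm(W * nrow(desc)), W)
  is_signal <- rep(FALSE, nrow(desc))
  for (cell in signal_cells) {
    is_signal <- is_signal | (desc$group == cell[1] & desc$signal == cell[2])
  }
  # orthogonal class means: class c owns every 5th signal column at +10
  shift <- 10 * (matrix(seq_len(sum(is_signal)), length(classes),
                        sum(is_signal), byrow = TRUE) %% length(classes) ==
                   (seq_along(classes) - 1))
  X[, is_signal] <- X[, is_signal] + shift[match(y, classes), , drop = FALSE]
  windows <- data.frame(
    infant_id = rep(sprintf("i%02d", seq_len(n_infants)), each = windows_per_infant),
    session_id = rep(sprintf("i%02d_s1", seq_len(n_infants)), each = windows_per_infant),
    start = rep(seq_len(windows_per_infant) - 1, n_infants),
    end = rep(seq_len(windows_per_infant) + 1, n_infants),
    label = y, stringsAsFactors = FALSE)
  feature_table(X, desc, windows)
}
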