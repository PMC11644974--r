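#' Feature-extraction configuration
#'
#' @param quantiles probabilities of the "key quantiles" added to the
#'   statistical group (the median is always present).
#' @param sensor_set locations whose signals enter the table. The default is
#'   the trunk-and-legs configuration.
#' @param signals signal families to include, a subset of
#'   `acc, acc_lp, acc_hp, norm, norm_lp, norm_hp, gyro, mag, roll, pitch`.
#' @param cross_modal also compute correlations between different sensor
#'   modalities (acc/gyro/mag, same axis, same location). Off by default.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(quantiles = c(0.25, 0.75),
                           sensor_set = c("trunk_a", "leg_left", "leg_right"),
                           signals = c("acc", "acc_lp", "acc_hp",
                                       "norm", "norm_lp", "norm_hp",
                                       "gyro", "mag", "roll", "pitch"),
                           cross_modal = FALSE) {
  if (length(sensor_set) == 0) stop("sensor_set must be non-empty")
  if (any(quantiles <= 0 | quantiles >= 1)) stop("quantiles must lie in (0, 1)")
  sensor_set <- intersect(sensor_locations(), sensor_set)  # canonical order
  signals <- intersect(signal_families(), signals)
  structure(list(quantiles = quantiles, sensor_set = sensor_set,
                 signals = signals, cross_modal = cross_modal),
            class = "feature_config")
}

signal_families <- function() {
  c("acc", "acc_lp", "acc_hp", "norm", "norm_lp", "norm_hp",
    "gyro", "mag", "roll", "pitch")
}

family_channels <- function(fam) {
  if (fam %in% c("acc", "acc_lp", "acc_hp", "gyro", "mag")) {
    stats::setNames(paste0(fam, "_", c("x", "y", "z")), c("x", "y", "z"))
  } else {
    stats::setNames(fam, "")
  }
}

stat_feature_names <- function(quantiles) {
  c("mean", "sd", "median", "skew", "kurt",
    sprintf("q%02d", round(100 * quantiles)), "min", "max")
}

freq_feature_names <- function() {
  c("energy", "entropy", "centroid", "bandwidth", "fmax")
}

#' Statistical features of one window
#'
#' Mean, standard deviation (n-1 denominator), median, adjusted
#' Fisher-Pearson skewness, excess kurtosis, the configured quantiles
#' (type 7), minimum and maximum. Skewness and kurtosis of an exactly
#' constant window are 0 by convention.
#'
#' @param x numeric window samples (or a samples-by-windows matrix).
#' @param quantiles quantile probabilities.
#' @return Named vector (or matrix with one row per window).
#' @export
statistical_features <- function(x, quantiles = c(0.25, 0.75)) {
  X <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 samples")
  m <- colMeans(X)
  Xc <- X - rep(m, each = n)
  m2 <- colMeans(Xc^2)
  m3 <- colMeans(Xc^3)
  m4 <- colMeans(Xc^4)
  sdv <- sqrt(colSums(Xc^2) / (n - 1))
  const <- m2 == 0
  m2s <- ifelse(const, 1, m2)
  skew <- (m3 / m2s^1.5) * sqrt(n * (n - 1)) / (n - 2)
  kurt <- m4 / m2s^2 - 3
  skew[const] <- 0
  kurt[const] <- 0
  S <- matrix(X[order(col(X), X)], nrow = n)  # column-wise sort
  qs <- vapply(c(0.5, quantiles), function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    S[lo, ] * (1 - (h - lo)) + S[hi, ] * (h - lo)
  }, numeric(ncol(X)))
  qs <- matrix(qs, ncol = length(quantiles) + 1)
  out <- cbind(m, sdv, qs[, 1], skew, kurt,
               qs[, -1, drop = FALSE], S[1, ], S[n, ])
  colnames(out) <- stat_feature_names(quantiles)
  if (is.matrix(x)) out else out[1, ]
}

#' Frequency features of one window
#'
#' From the one-sided periodogram of the mean-removed window (rectangular
#' window): total energy, spectral entropy (natural log), spectral centroid,
#' spectral bandwidth and the frequency of maximum power. A zero-power
#' (constant) window returns all five as 0 by convention.
#'
#' @param x numeric window samples (or a samples-by-windows matrix).
#' @param rate sampling rate in Hz.
#' @return Named vector (or matrix with one row per window).
#' @export
frequency_features <- function(x, rate = 60) {
  X <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  n <- nrow(X)
  m <- colMeans(X)
  Xc <- X - rep(m, each = n)
  Fz <- stats::mvfft(Xc)
  half <- n %/% 2
  k <- seq_len(half)
  P <- 2 * abs(Fz[k + 1, , drop = FALSE])^2 / n
  if (n %% 2 == 0) P[half, ] <- P[half, ] / 2  # Nyquist bin is not doubled
  f <- k * rate / n
  tot <- colSums(P)
  zero <- tot <= 0
  tots <- ifelse(zero, 1, tot)
  p <- P / rep(tots, each = half)
  plogp <- p * log(p)
  plogp[p == 0] <- 0
  entropy <- -colSums(plogp)
  centroid <- colSums(f * p)
  bandwidth <- sqrt(colSums((outer(f, centroid, `-`))^2 * p))
  fmax <- f[max.col(t(P), ties.method = "first")]
  out <- cbind(colSums(P), entropy, centroid, bandwidth, fmax)
  out[zero, ] <- 0
  colnames(out) <- freq_feature_names()
  if (is.matrix(x)) out else out[1, ]
}

# Pearson correlation per window from per-window sums: r = cov / (sd_a sd_b),
# zero-variance pairs -> 0 by convention.
pair_correlation <- function(Xa, Xb) {
  n <- nrow(Xa)
  sa <- colSums(Xa); sb <- colSums(Xb)
  cab <- colSums(Xa * Xb) - sa * sb / n
  va <- colSums(Xa^2) - sa^2 / n
  vb <- colSums(Xb^2) - sb^2 / n
  bad <- va <= 0 | vb <= 0
  r <- cab / sqrt(ifelse(bad, 1, va * vb))
  r[bad] <- 0
  pmin(1, pmax(-1, r))
}

#' Enumerate the feature columns implied by a configuration
#'
#' The canonical column layout: statistical and frequency features per signal
#' channel and location; summary features (axis sums per location, location
#' sums across the sensor set); difference features (mean axis differences
#' within location, mean location differences per channel); correlation
#' features with the same pair structure. Column order is deterministic and
#' independent of input data.
#'
#' @param cfg a [feature_config()].
#' @return Data frame of descriptors: `location`, `signal`, `group`, `name`.
#' @export
enumerate_feature_descriptors <- function(cfg = feature_config()) {
  rows <- list()
  add <- function(location, signal, group, name) {
    rows[[length(rows) + 1L]] <<- data.frame(
      location = location, signal = signal, group = group, name = name,
      stringsAsFactors = FALSE)
  }
  axis_fams <- intersect(c("acc", "acc_lp", "acc_hp", "gyro", "mag"), cfg$signals)
  sname <- stat_feature_names(cfg$quantiles)
  for (group in c("statistical", "frequency")) {
    fname <- if (group == "statistical") sname else freq_feature_names()
    for (loc in cfg$sensor_set) {
      for (fam in cfg$signals) {
        chs <- family_channels(fam)
        for (ax in names(chs)) {
          pre <- if (nzchar(ax)) paste0(ax, ".") else ""
          add(loc, fam, group, paste0(pre, fname))
        }
      }
    }
  }
  # summary: axis sums per location, then location sums across the set
  for (loc in cfg$sensor_set) {
    for (fam in axis_fams) add(loc, fam, "summary", "axsum.mean")
  }
  for (fam in cfg$signals) {
    chs <- family_channels(fam)
    for (ax in names(chs)) {
      pre <- if (nzchar(ax)) paste0(ax, ".") else ""
      add("all", fam, "summary", paste0(pre, "locsum.mean"))
    }
  }
  axis_pairs <- list(c("x", "y"), c("x", "z"), c("y", "z"))
  loc_pairs <- if (length(cfg$sensor_set) > 1) {
    utils::combn(cfg$sensor_set, 2, simplify = FALSE)
  } else list()
  for (group in c("difference", "correlation")) {
    fn <- if (group == "difference") "mdiff" else "corr"
    for (loc in cfg$sensor_set) {
      for (fam in axis_fams) {
        for (pr in axis_pairs) {
          add(loc, fam, group, paste(fn, pr[1], pr[2], sep = "."))
        }
      }
    }
    for (fam in cfg$signals) {
      chs <- family_channels(fam)
      for (ax in names(chs)) {
        pre <- if (nzchar(ax)) paste0(ax, ".") else ""
        for (pr in loc_pairs) {
          add(paste(pr[1], pr[2], sep = "&"), fam, group, paste0(pre, fn))
        }
      }
    }
  }
  if (cfg$cross_modal) {
    mods <- intersect(c("acc", "gyro", "mag"), cfg$signals)
    if (length(mods) > 1) {
      for (loc in cfg$sensor_set) {
        for (pr in utils::combn(mods, 2, simplify = FALSE)) {
          for (ax in c("x", "y", "z")) {
            add(loc, paste(pr[1], pr[2], sep = "&"), "correlation",
                paste("corr", ax, sep = "."))
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Build the window-by-feature matrix for one session
#'
#' Derives the full signal set for every sensor in the configuration, extracts
#' every labelled window and computes all five feature groups. Windows whose
#' features contain missing values (e.g. zero-norm roll/pitch samples) are
#' dropped; the count is recorded in attribute `dropped`.
#'
#' @param session a preprocessed, synchronised [imu_session()].
#' @param windows a window set from [segment_session()].
#' @param cfg a [feature_config()].
#' @param prep_cfg a [preprocess_config()] (filter settings for
#'   [derive_signals()]).
#' @return A [feature_table()] with one row per labelled window.
#' @export
build_feature_matrix <- function(session, windows, cfg = feature_config(),
                                 prep_cfg = preprocess_config()) {
  desc <- enumerate_feature_descriptors(cfg)
  miss <- setdiff(cfg$sensor_set, names(session$recordings))
  if (length(miss) > 0) {
    stop("session ", session$session_id, " lacks sensor(s): ",
         paste(miss, collapse = ", "))
  }
  lab_rows <- which(windows$label != UNASSIGNED)
  meta <- data.frame(infant_id = rep(session$infant_id, length(lab_rows)),
                     session_id = rep(session$session_id, length(lab_rows)),
                     start = windows$start[lab_rows],
                     end = windows$end[lab_rows],
                     label = windows$label[lab_rows],
                     stringsAsFactors = FALSE)
  W <- length(lab_rows)
  if (W == 0) {
    tab <- feature_table(matrix(numeric(), 0, nrow(desc)), desc,
                         meta[0, , drop = FALSE])
    attr(tab, "dropped") <- 0L
    return(tab)
  }
  derived <- lapply(session$recordings[cfg$sensor_set], derive_signals,
                    cfg = prep_cfg)
  rate <- derived[[1]]$rate
  n_win <- as.integer(round((windows$end[1] - windows$start[1]) * rate))
  # per location, per channel: the samples-by-windows matrix
  winmat <- lapply(derived, function(d) {
    starts <- as.integer(round((windows$start[lab_rows] - d$t[1]) * rate)) + 1L
    idx <- outer(seq_len(n_win) - 1L, starts, `+`)
    idx <- pmin(pmax(idx, 1L), nrow(d$channels))
    ch <- colnames(d$channels)
    out <- lapply(ch, function(cn) matrix(d$channels[idx, cn], nrow = n_win))
    names(out) <- ch
    out
  })
  cols <- vector("list", 0)
  push <- function(m) cols[[length(cols) + 1L]] <<- m
  axis_fams <- intersect(c("acc", "acc_lp", "acc_hp", "gyro", "mag"), cfg$signals)
  chan_mean <- lapply(winmat, function(loc) {
    vapply(loc, colMeans, numeric(W))
  })
  for (group in c("statistical", "frequency")) {
    for (loc in cfg$sensor_set) {
      for (fam in cfg$signals) {
        for (chn in family_channels(fam)) {
          X <- winmat[[loc]][[chn]]
          push(if (group == "statistical") {
            statistical_features(X, cfg$quantiles)
          } else {
            frequency_features(X, rate)
          })
        }
      }
    }
  }
  cm <- function(loc, chn) {
    m <- chan_mean[[loc]]
    if (is.matrix(m)) m[, chn] else m[chn]
  }
  for (loc in cfg$sensor_set) {
    for (fam in axis_fams) {
      chs <- family_channels(fam)
      push(matrix(cm(loc, chs[1]) + cm(loc, chs[2]) + cm(loc, chs[3]), ncol = 1))
    }
  }
  for (fam in cfg$signals) {
    for (chn in family_channels(fam)) {
      push(matrix(Reduce(`+`, lapply(cfg$sensor_set, cm, chn = chn)), ncol = 1))
    }
  }
  axis_pairs <- list(c("x", "y"), c("x", "z"), c("y", "z"))
  loc_pairs <- if (length(cfg$sensor_set) > 1) {
    utils::combn(cfg$sensor_set, 2, simplify = FALSE)
  } else list()
  for (group in c("difference", "correlation")) {
    for (loc in cfg$sensor_set) {
      for (fam in axis_fams) {
        for (pr in axis_pairs) {
          a <- paste0(fam, "_", pr[1]); b <- paste0(fam, "_", pr[2])
          push(matrix(if (group == "difference") cm(loc, a) - cm(loc, b)
                      else pair_correlation(winmat[[loc]][[a]], winmat[[loc]][[b]]),
                      ncol = 1))
        }
      }
    }
    for (fam in cfg$signals) {
      for (chn in family_channels(fam)) {
        for (pr in loc_pairs) {
          push(matrix(if (group == "difference") cm(pr[1], chn) - cm(pr[2], chn)
                      else pair_correlation(winmat[[pr[1]]][[chn]],
                                            winmat[[pr[2]]][[chn]]),
                      ncol = 1))
        }
      }
    }
  }
  if (cfg$cross_modal) {
    mods <- intersect(c("acc", "gyro", "mag"), cfg$signals)
    if (length(mods) > 1) {
      for (loc in cfg$sensor_set) {
        for (pr in utils::combn(mods, 2, simplify = FALSE)) {
          for (ax in c("x", "y", "z")) {
            a <- paste0(pr[1], "_", ax); b <- paste0(pr[2], "_", ax)
            push(matrix(pair_correlation(winmat[[loc]][[a]], winmat[[loc]][[b]]),
                        ncol = 1))
          }
        }
      }
    }
  }
  values <- do.call(cbind, cols)
  stopifnot(ncol(values) == nrow(desc))
  ok <- rowSums(is.na(values) | is.nan(values)) == 0
  tab <- feature_table(values[ok, , drop = FALSE], desc,
                       meta[ok, , drop = FALSE])
  attr(tab, "dropped") <- sum(!ok)
  tab
}

#' Extract features for a whole set of sessions
#'
#' Preprocesses, synchronises, segments and featurises each session, then
#' binds the per-session tables.
#'
#' @param sessions list of [imu_session()]s.
#' @param cfg a [feature_config()].
#' @param prep_cfg a [preprocess_config()].
#' @param spec a [window_spec()].
#' @param preprocessed set `TRUE` if the sessions are already preprocessed.
#' @return A [feature_table()].
#' @export
featurize_sessions <- function(sessions, cfg = feature_config(),
                               prep_cfg = preprocess_config(),
                               spec = window_spec(), preprocessed = FALSE) {
  tabs <- lapply(sessions, function(s) {
    if (!preprocessed) s <- preprocess_session(s, prep_cfg)
    w <- segment_session(s, spec, sensor_set = cfg$sensor_set)
    build_feature_matrix(s, w, cfg, prep_cfg)
  })
  rbind_feature_tables(tabs)
}

# ---- standalone per-window feature-group operations ----------------------

#' Summary features of one window
#'
#' Aggregates by summation: per location and axis-signal family the window
#' mean of the axis-sum series (x+y+z), and per channel the window mean of
#' the location-sum series across the sensor set.
#'
#' @param window_channels nested list: location -> channel name -> numeric
#'   window samples (channel names as in [derive_signals()]).
#' @param cfg a [feature_config()].
#' @return Named numeric vector.
#' @export
summary_features <- function(window_channels, cfg = feature_config()) {
  miss <- setdiff(cfg$sensor_set, names(window_channels))
  if (length(miss) > 0) stop("missing location(s): ", paste(miss, collapse = ", "))
  axis_fams <- intersect(c("acc", "acc_lp", "acc_hp", "gyro", "mag"), cfg$signals)
  out <- c()
  for (loc in cfg$sensor_set) {
    for (fam in axis_fams) {
      chs <- family_channels(fam)
      v <- mean(window_channels[[loc]][[chs[1]]] +
                window_channels[[loc]][[chs[2]]] +
                window_channels[[loc]][[chs[3]]])
      out[paste(loc, fam, "axsum.mean", sep = "|")] <- v
    }
  }
  for (fam in cfg$signals) {
    chs <- family_channels(fam)
    for (ai in seq_along(chs)) {
      ax <- names(chs)[ai]
      pre <- if (nzchar(ax)) paste0(ax, ".") else ""
      s <- Reduce(`+`, lapply(cfg$sensor_set,
                              function(l) window_channels[[l]][[chs[[ai]]]]))
      out[paste("all", fam, paste0(pre, "locsum.mean"), sep = "|")] <- mean(s)
    }
  }
  out
}

#' Difference features of one window
#'
#' Window means of pairwise differences: between axes within a signal family
#' and location, and between locations within a channel; pairs are ordered
#' lexicographically.
#'
#' @inheritParams summary_features
#' @return Named numeric vector.
#' @export
difference_features <- function(window_channels, cfg = feature_config()) {
  pairwise_window_features(window_channels, cfg, function(a, b) mean(a - b),
                           "mdiff")
}

#' Correlation features of one window
#'
#' Pearson correlations between axes within a signal family and location, and
#' between locations within a channel; zero-variance pairs give 0 by
#' convention.
#'
#' @inheritParams summary_features
#' @return Named numeric vector.
#' @export
correlation_features <- function(window_channels, cfg = feature_config()) {
  r <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    pair_correlation(matrix(a, ncol = 1), matrix(b, ncol = 1))
  }
  pairwise_window_features(window_channels, cfg, r, "corr")
}

pairwise_window_features <- function(window_channels, cfg, f, tag) {
  miss <- setdiff(cfg$sensor_set, names(window_channels))
  if (length(miss) > 0) stop("missing location(s): ", paste(miss, collapse = ", "))
  axis_fams <- intersect(c("acc", "acc_lp", "acc_hp", "gyro", "mag"), cfg$signals)
  axis_pairs <- list(c("x", "y"), c("x", "z"), c("y", "z"))
  out <- c()
  for (loc in cfg$sensor_set) {
    for (fam in axis_fams) {
      for (pr in axis_pairs) {
        a <- window_channels[[loc]][[paste0(fam, "_", pr[1])]]
        b <- window_channels[[loc]][[paste0(fam, "_", pr[2])]]
        out[paste(loc, fam, paste(tag, pr[1], pr[2], sep = "."), sep = "|")] <-
          f(a, b)
      }
    }
  }
  if (length(cfg$sensor_set) > 1) {
    for (fam in cfg$signals) {
      chs <- family_channels(fam)
      for (ai in seq_along(chs)) {
        ax <- names(chs)[ai]
        pre <- if (nzchar(ax)) paste0(ax, ".") else ""
        for (pr in utils::combn(cfg$sensor_set, 2, simplify = FALSE)) {
          a <- window_channels[[pr[1]]][[chs[[ai]]]]
          b <- window_channels[[pr[2]]][[chs[[ai]]]]
          out[paste(paste(pr[1], pr[2], sep = "&"), fam,
                    paste0(pre, tag), sep = "|")] <- f(a, b)
        }
      }
    }
  }
  out
}
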