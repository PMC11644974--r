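# Independent brute-force oracle for every feature formula. Deliberately
# avoids the implementation's code paths: quantiles/order statistics by
# explicit sorting, spectra by direct trigonometric DFT sums (no fft),
# correlations via stats::cor.

oracle_quantile7 <- function(x, p) {
  s <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

oracle_statistical <- function(x, quantiles = c(0.25, 0.75)) {
  n <- length(x)
  m <- sum(x) / n
  d <- x - m
  m2 <- sum(d^2) / n
  out <- c(mean = m,
           sd = sqrt(sum(d^2) / (n - 1)),
           median = oracle_quantile7(x, 0.5))
  if (m2 == 0) {
    out["skew"] <- 0
    out["kurt"] <- 0
  } else {
    g1 <- (sum(d^3) / n) / m2^1.5
    out["skew"] <- g1 * sqrt(n * (n - 1)) / (n - 2)
    out["kurt"] <- (sum(d^4) / n) / m2^2 - 3
  }
  for (p in quantiles) out[sprintf("q%02d", round(100 * p))] <- oracle_quantile7(x, p)
  out["min"] <- min(x)
  out["max"] <- max(x)
  out
}

oracle_power_spectrum <- function(x, rate) {
  n <- length(x)
  xc <- x - mean(x)
  half <- n %/% 2
  j <- seq_len(n) - 1
  P <- numeric(half)
  for (k in seq_len(half)) {
    re <- sum(xc * cos(2 * pi * k * j / n))
    im <- sum(xc * sin(2 * pi * k * j / n))
    P[k] <- 2 * (re^2 + im^2) / n
  }
  if (n %% 2 == 0) P[half] <- P[half] / 2
  list(f = seq_len(half) * rate / n, P = P)
}

oracle_frequency <- function(x, rate = 60) {
  sp <- oracle_power_spectrum(x, rate)
  tot <- sum(sp$P)
  if (tot <= 0) {
    return(c(energy = 0, entropy = 0, centroid = 0, bandwidth = 0, fmax = 0))
  }
  p <- sp$P / tot
  ent <- -sum(ifelse(p > 0, p * log(p), 0))
  cen <- sum(sp$f * p)
  bw <- sqrt(sum((sp$f - cen)^2 * p))
  c(energy = tot, entropy = ent, centroid = cen, bandwidth = bw,
    fmax = sp$f[which.max(sp$P)])
}

oracle_pearson <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

# Recompute one feature value from the window's raw channel samples, driven
# only by the feature descriptor.
oracle_feature <- function(d, win, rate = 60, quantiles = c(0.25, 0.75)) {
  chan <- function(loc, sig, ax) {
    nm <- if (nzchar(ax)) paste0(sig, "_", ax) else sig
    win[[loc]][[nm]]
  }
  parts <- strsplit(d$name, ".", fixed = TRUE)[[1]]
  if (d$group %in% c("statistical", "frequency")) {
    ax <- if (length(parts) > 1) parts[1] else ""
    feat <- parts[length(parts)]
    x <- chan(d$location, d$signal, ax)
    v <- if (d$group == "statistical") oracle_statistical(x, quantiles)
         else oracle_frequency(x, rate)
    return(unname(v[feat]))
  }
  if (d$group == "summary") {
    if (identical(parts[length(parts) - 1], "axsum")) {
      s <- chan(d$location, d$signal, "x") + chan(d$location, d$signal, "y") +
        chan(d$location, d$signal, "z")
      return(mean(s))
    }
    ax <- if (length(parts) == 3) parts[1] else ""
    locs <- names(win)
    s <- Reduce(`+`, lapply(locs, chan, sig = d$signal, ax = ax))
    return(mean(s))
  }
  # difference / correlation
  f <- if (d$group == "difference") function(a, b) mean(a - b) else oracle_pearson
  if (grepl("&", d$location, fixed = TRUE)) {
    locs <- strsplit(d$location, "&", fixed = TRUE)[[1]]
    ax <- if (length(parts) == 2) parts[1] else ""
    return(f(chan(locs[1], d$signal, ax), chan(locs[2], d$signal, ax)))
  }
  ax1 <- parts[length(parts) - 1]; ax2 <- parts[length(parts)]
  f(chan(d$location, d$signal, ax1), chan(d$location, d$signal, ax2))
}

# Fast trig-DFT variant (matrix products, no fft) for bulk checking.
oracle_frequency_fast <- function(x, rate, Cm, Sm, f) {
  n <- length(x)
  xc <- x - sum(x) / n
  re <- as.numeric(Cm %*% xc)
  im <- as.numeric(Sm %*% xc)
  P <- 2 * (re^2 + im^2) / n
  if (n %% 2 == 0) P[length(P)] <- P[length(P)] / 2
  tot <- sum(P)
  if (tot <= 0) return(c(energy = 0, entropy = 0, centroid = 0,
                         bandwidth = 0, fmax = 0))
  p <- P / tot
  cen <- sum(f * p)
  c(energy = tot, entropy = -sum(ifelse(p > 0, p * log(p), 0)),
    centroid = cen, bandwidth = sqrt(sum((f - cen)^2 * p)),
    fmax = f[which.max(P)])
}

# Extract the raw per-channel window samples of labelled window index `w`
# (indexing the labelled subset) from pre-derived signals.
oracle_window_channels_from <- function(derived, windows_row, rate) {
  n_win <- as.integer(round((windows_row$end - windows_row$start) * rate))
  lapply(derived, function(d) {
    s <- as.integer(round((windows_row$start - d$t[1]) * rate)) + 1L
    idx <- s:(s + n_win - 1L)
    cols <- colnames(d$channels)
    out <- lapply(cols, function(cn) d$channels[idx, cn])
    names(out) <- cols
    out
  })
}

oracle_window_channels <- function(session, windows, w, cfg,
                                   prep_cfg = preprocess_config()) {
  derived <- lapply(session$recordings[cfg$sensor_set], derive_signals, prep_cfg)
  oracle_window_channels_from(derived, windows[w, ], derived[[1]]$rate)
}

# Recompute every feature of every labelled-window row of `tab` from scratch
# and return the maximum relative error against the table values.
oracle_check_table <- function(session, tab, cfg,
                               prep_cfg = preprocess_config(), rate = 60,
                               rows = seq_len(nrow(tab$values))) {
  derived <- lapply(session$recordings[cfg$sensor_set], derive_signals, prep_cfg)
  desc <- tab$descriptors
  parts_list <- strsplit(desc$name, ".", fixed = TRUE)
  n_win <- as.integer(round((tab$windows$end[1] - tab$windows$start[1]) * rate))
  half <- n_win %/% 2
  j <- seq_len(n_win) - 1
  ang <- outer(seq_len(half), j, function(k, j) 2 * pi * k * j / n_win)
  Cm <- cos(ang); Sm <- sin(ang)
  f <- seq_len(half) * rate / n_win
  max_err <- 0
  for (ri in rows) {
    win <- oracle_window_channels_from(derived, tab$windows[ri, ], rate)
    cache <- new.env()
    chanval <- function(loc, sig, ax) {
      nm <- if (nzchar(ax)) paste0(sig, "_", ax) else sig
      win[[loc]][[nm]]
    }
    getvec <- function(group, loc, sig, ax) {
      key <- paste(group, loc, sig, ax)
      v <- cache[[key]]
      if (is.null(v)) {
        x <- chanval(loc, sig, ax)
        v <- if (group == "statistical") oracle_statistical(x, cfg$quantiles)
             else oracle_frequency_fast(x, rate, Cm, Sm, f)
        cache[[key]] <- v
      }
      v
    }
    for (ci in seq_len(nrow(desc))) {
      parts <- parts_list[[ci]]
      g <- desc$group[ci]; loc <- desc$location[ci]; sig <- desc$signal[ci]
      expect <- if (g %in% c("statistical", "frequency")) {
        ax <- if (length(parts) > 1) parts[1] else ""
        unname(getvec(g, loc, sig, ax)[parts[length(parts)]])
      } else if (g == "summary") {
        if (identical(parts[length(parts) - 1], "axsum")) {
          mean(chanval(loc, sig, "x") + chanval(loc, sig, "y") +
                 chanval(loc, sig, "z"))
        } else {
          ax <- if (length(parts) == 3) parts[1] else ""
          mean(Reduce(`+`, lapply(names(win), chanval, sig = sig, ax = ax)))
        }
      } else {
        fn <- if (g == "difference") function(a, b) mean(a - b) else oracle_pearson
        if (grepl("&", loc, fixed = TRUE)) {
          locs <- strsplit(loc, "&", fixed = TRUE)[[1]]
          ax <- if (length(parts) == 2) parts[1] else ""
          fn(chanval(locs[1], sig, ax), chanval(locs[2], sig, ax))
        } else {
          fn(chanval(loc, sig, parts[length(parts) - 1]),
             chanval(loc, sig, parts[length(parts)]))
        }
      }
      err <- abs(tab$values[ri, ci] - expect) / max(1, abs(expect))
      max_err <- max(max_err, err)
    }
  }
  max_err
}
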