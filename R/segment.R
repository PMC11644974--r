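#' Sliding-window specification
#'
#' @param length_s window length in seconds (2 s).
#' @param step_s advance between consecutive windows (1 s, i.e. 1 s overlap).
#' @param consistency_threshold minimum fraction of a window's samples that
#'   must carry the same position label for the window to receive it.
#' @param max_artifact_frac windows with a larger fraction of artefact-masked
#'   samples stay unassigned.
#' @return A list of class `window_spec`.
#' @export
window_spec <- function(length_s = 2, step_s = 1, consistency_threshold = 0.75,
                        max_artifact_frac = 0.25) {
  if (step_s <= 0 || step_s > length_s) stop("need 0 < step_s <= length_s")
  if (consistency_threshold <= 0.5 || consistency_threshold > 1) {
    stop("consistency_threshold must lie in (0.5, 1]")
  }
  structure(list(length_s = length_s, step_s = step_s,
                 consistency_threshold = consistency_threshold,
                 max_artifact_frac = max_artifact_frac),
            class = "window_spec")
}

#' Enumerate sliding windows over a duration
#'
#' Windows start at 0 and advance by `step_s`; the count is
#' `floor((duration - length_s) / step_s) + 1`, or zero when the duration is
#' shorter than one window.
#'
#' @param duration total duration in seconds.
#' @param spec a [window_spec()].
#' @return Data frame with columns `start`, `end` (seconds).
#' @export
make_windows <- function(duration, spec = window_spec()) {
  if (duration < spec$length_s) {
    return(data.frame(start = numeric(), end = numeric()))
  }
  k <- floor((duration - spec$length_s) / spec$step_s) + 1
  start <- (seq_len(k) - 1) * spec$step_s
  data.frame(start = start, end = start + spec$length_s)
}

# Per-sample class codes for a uniform time base: 0 = unlabelled transition,
# 1..5 index into position_classes(). Annotations are shifted by the sync
# delay into sensor time before lookup.
sample_class_codes <- function(t, annotations, sync_delay = 0) {
  classes <- position_classes()
  code <- integer(length(t))
  cls <- map_to_static(annotations$label)
  for (i in seq_len(nrow(annotations))) {
    lo <- annotations$start[i] + sync_delay
    hi <- annotations$end[i] + sync_delay
    code[t >= lo & t < hi] <- match(cls[i], classes)
  }
  code
}

#' Assign labels to sliding windows
#'
#' A window receives the modal position class iff the fraction of its samples
#' carrying that class is at least the consistency threshold (inclusive).
#' The denominator is all samples in the window, so unlabelled transition
#' samples count against the majority. Artefact-masked samples never count
#' towards a class, and windows whose masked fraction exceeds
#' `max_artifact_frac` stay unassigned.
#'
#' @param codes integer per-sample class codes (0 = unlabelled), uniform grid.
#' @param mask logical per-sample artefact mask.
#' @param starts integer sample indices (1-based) of window starts.
#' @param n_win samples per window.
#' @param spec a [window_spec()].
#' @return List: `label` (character, `UNASSIGNED` where no class qualifies),
#'   `frac` (modal-class sample fraction), `artifact_frac`.
#' @export
assign_window_labels <- function(codes, mask, starts, n_win,
                                 spec = window_spec()) {
  classes <- position_classes()
  W <- length(starts)
  if (W == 0) {
    return(list(label = character(), frac = numeric(), artifact_frac = numeric()))
  }
  idx <- outer(seq_len(n_win) - 1L, as.integer(starts), `+`)
  C <- matrix(codes[idx], nrow = n_win)
  M <- matrix(mask[idx], nrow = n_win)
  C[M] <- 0L  # masked samples never count toward a class
  counts <- vapply(seq_along(classes), function(k) colSums(C == k),
                   numeric(W))
  counts <- matrix(counts, nrow = W)
  best <- max.col(counts, ties.method = "first")
  best_n <- counts[cbind(seq_len(W), best)]
  # modal ties below threshold are unassigned anyway; at >= 75% a tie is impossible
  frac <- best_n / n_win
  art <- colMeans(M)
  label <- ifelse(frac >= spec$consistency_threshold - 1e-12 &
                    art <= spec$max_artifact_frac + 1e-12,
                  classes[best], UNASSIGNED)
  list(label = label, frac = frac, artifact_frac = art)
}

#' Cut a session into labelled sliding windows
#'
#' Uses the shortest recording in `sensor_set` to bound the windowed span (no
#' window extends past any sensor's data), combines the sensors' artefact
#' masks by union, and applies the consistency rule.
#'
#' @param session a preprocessed, synchronised [imu_session()].
#' @param spec a [window_spec()].
#' @param sensor_set locations to use; defaults to all present.
#' @return Data frame of class `window_set`: `start`, `end`, `label`, `frac`,
#'   `artifact_frac`.
#' @export
segment_session <- function(session, spec = window_spec(), sensor_set = NULL) {
  recs <- session$recordings
  if (!is.null(sensor_set)) {
    miss <- setdiff(sensor_set, names(recs))
    if (length(miss) > 0) stop("session ", session$session_id,
                               " lacks sensor(s): ", paste(miss, collapse = ", "))
    recs <- recs[sensor_set]
  }
  rate <- recs[[1]]$rate
  t0 <- max(vapply(recs, function(r) r$t[1], numeric(1)))
  t1 <- min(vapply(recs, function(r) r$t[length(r$t)], numeric(1)))
  duration <- t1 - t0
  win <- make_windows(duration, spec)
  if (nrow(win) == 0) {
    out <- data.frame(start = numeric(), end = numeric(), label = character(),
                      frac = numeric(), artifact_frac = numeric())
    class(out) <- c("window_set", "data.frame")
    return(out)
  }
  n_win <- as.integer(round(spec$length_s * rate))
  grid_t <- t0 + seq(0, by = 1 / rate, length.out = floor(duration * rate) + 1)
  delay <- if (is.na(session$sync_delay)) 0 else session$sync_delay
  codes <- sample_class_codes(grid_t, session$annotations, delay)
  mask <- rep(FALSE, length(grid_t))
  for (r in recs) {
    src <- as.integer(round((grid_t - r$t[1]) * rate)) + 1L
    mask <- mask | r$mask[pmin(length(r$mask), pmax(1L, src))]
  }
  starts <- as.integer(round(win$start * rate)) + 1L
  keep <- starts + n_win - 1L <= length(grid_t)
  win <- win[keep, , drop = FALSE]
  starts <- starts[keep]
  lab <- assign_window_labels(codes, mask, starts, n_win, spec)
  out <- data.frame(start = win$start + t0, end = win$end + t0,
                    label = lab$label, frac = lab$frac,
                    artifact_frac = lab$artifact_frac,
                    stringsAsFactors = FALSE)
  class(out) <- c("window_set", "data.frame")
  out
}
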