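#' Construct a sensor recording
#'
#' One sensor location's 9-channel time series: tri-axial accelerometer
#' (m/s^2), gyroscope (rad/s) and magnetometer (arbitrary field units), with a
#' nominal sampling rate and a per-sample artefact mask.
#'
#' @param location one of [sensor_locations()].
#' @param t numeric timestamps in seconds, strictly increasing.
#' @param acc,gyro,mag numeric T x 3 matrices (columns x, y, z).
#' @param rate nominal sampling rate in Hz, 60 or 40.
#' @param mask logical vector of length T; `TRUE` marks excluded samples.
#' @return An object of class `sensor_recording`.
#' @export
sensor_recording <- function(location, t, acc, gyro, mag, rate,
                             mask = rep(FALSE, length(t))) {
  location <- match.arg(location, sensor_locations())
  acc <- as_xyz(acc); gyro <- as_xyz(gyro); mag <- as_xyz(mag)
  n <- length(t)
  if (nrow(acc) != n || nrow(gyro) != n || nrow(mag) != n || length(mask) != n) {
    stop("channel arrays and mask must all have length ", n)
  }
  if (n > 1) {
    bad <- which(diff(t) <= 0)
    if (length(bad) > 0) {
      stop("timestamps not strictly increasing at row ", bad[1] + 1L)
    }
  }
  if (!rate %in% c(40, 60)) stop("nominal_rate must be 40 or 60, got ", rate)
  structure(list(location = location, t = as.numeric(t), acc = acc,
                 gyro = gyro, mag = mag, rate = rate,
                 mask = as.logical(mask)),
            class = "sensor_recording")
}

as_xyz <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (ncol(m) != 3) stop("expected a 3-column (x, y, z) matrix")
  colnames(m) <- c("x", "y", "z")
  m
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("<sensor_recording> %s: %d samples at %g Hz (%.1f s), %d masked\n",
              x$location, length(x$t), x$rate,
              if (length(x$t) > 1) diff(range(x$t)) else 0, sum(x$mask)))
  invisible(x)
}

sensor_csv_header <- c("t", "acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y",
                       "gyro_z", "mag_x", "mag_y", "mag_z")

#' Read a sensor CSV file
#'
#' Reads the package's plain-CSV sensor dialect (header
#' `t,acc_x,...,mag_z`, UTF-8, '.' decimal) and infers the nominal sampling
#' rate from the median timestamp spacing, rounded to 60 or 40 Hz.
#'
#' @param path file path.
#' @param location sensor location, one of [sensor_locations()].
#' @return A [sensor_recording()] with an all-`FALSE` artefact mask.
#' @export
read_sensor_csv <- function(path, location) {
  dt <- data.table::fread(path, header = TRUE, sep = ",", encoding = "UTF-8")
  if (!identical(names(dt), sensor_csv_header)) {
    stop("malformed sensor CSV header in ", path, ": expected ",
         paste(sensor_csv_header, collapse = ","))
  }
  t <- dt$t
  if (length(t) > 1) {
    bad <- which(diff(t) <= 0)
    if (length(bad) > 0) {
      stop("non-monotone timestamps in ", path, " at row ", bad[1] + 1L)
    }
  }
  rate <- infer_rate(t)
  sensor_recording(location, t,
                   acc = cbind(dt$acc_x, dt$acc_y, dt$acc_z),
                   gyro = cbind(dt$gyro_x, dt$gyro_y, dt$gyro_z),
                   mag = cbind(dt$mag_x, dt$mag_y, dt$mag_z),
                   rate = rate)
}

infer_rate <- function(t) {
  if (length(t) < 2) stop("need at least 2 samples to infer the sampling rate")
  dt <- stats::median(diff(t))
  rate <- c(60, 40)[which.min(abs(dt - c(1 / 60, 1 / 40)))]
  if (abs(dt - 1 / rate) > 0.2 / rate) {
    stop("timestamp spacing ", signif(dt, 4),
         " s matches neither 60 Hz nor 40 Hz")
  }
  rate
}

#' Write a sensor recording to CSV
#'
#' @param rec a [sensor_recording()].
#' @param path output path.
#' @export
write_sensor_csv <- function(rec, path) {
  dt <- data.table::data.table(
    t = rec$t,
    acc_x = rec$acc[, 1], acc_y = rec$acc[, 2], acc_z = rec$acc[, 3],
    gyro_x = rec$gyro[, 1], gyro_y = rec$gyro[, 2], gyro_z = rec$gyro[, 3],
    mag_x = rec$mag[, 1], mag_y = rec$mag[, 2], mag_z = rec$mag[, 3])
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Construct an annotation track
#'
#' Labelled position intervals in annotation (audio/video) time. Gaps between
#' intervals are transition periods and stay unlabelled.
#'
#' @param start,end interval bounds in seconds.
#' @param label annotated position labels (the 14-label vocabulary).
#' @param source free-text provenance.
#' @return An object of class `annotation_track` (a data frame).
#' @export
annotation_track <- function(start, end, label, source = "") {
  if (length(start) != length(end) || length(start) != length(label)) {
    stop("start, end and label must have equal length")
  }
  map_to_static(label)  # vocabulary check
  if (any(end <= start)) {
    stop("annotation intervals must satisfy start < end")
  }
  o <- order(start)
  start <- start[o]; end <- end[o]; label <- label[o]
  if (length(start) > 1 && any(start[-1] < end[-length(end)] - 1e-9)) {
    i <- which(start[-1] < end[-length(end)] - 1e-9)[1]
    stop(sprintf("overlapping annotation intervals: [%g, %g] and [%g, %g]",
                 start[i], end[i], start[i + 1], end[i + 1]))
  }
  structure(data.frame(start = start, end = end, label = label,
                       stringsAsFactors = FALSE),
            class = c("annotation_track", "data.frame"), source = source)
}

#' Read an annotation TSV
#'
#' ELAN-export-style TSV with columns `start`, `end`, `label` (seconds,
#' annotated-position vocabulary).
#'
#' @param path file path.
#' @return An [annotation_track()].
#' @export
read_annotations <- function(path) {
  dt <- utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("start", "end", "label")
  if (!all(need %in% names(dt))) {
    stop("annotation file ", path, " must have columns start, end, label")
  }
  annotation_track(dt$start, dt$end, dt$label, source = path)
}

#' Write an annotation track to TSV
#' @param ann an [annotation_track()].
#' @param path output path.
#' @export
write_annotations <- function(ann, path) {
  utils::write.table(as.data.frame(ann)[, c("start", "end", "label")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a session
#'
#' One infant's recording session: per-location sensor recordings, the
#' annotation track (in audio/video time until synchronised), and metadata.
#'
#' @param infant_id non-empty identifier.
#' @param age_point age point in months (4, 6, 9 or 12).
#' @param task one of `book_sharing`, `manipulative`, `rattles`.
#' @param recordings named list of [sensor_recording()]s, names are locations.
#' @param annotations an [annotation_track()].
#' @param caregiver optional data frame `t, left, right` of caregiver arm
#'   acceleration norms, used for clap synchronisation.
#' @param clap_times_audio numeric clap times in audio time (seconds).
#' @param sync_delay seconds to add to annotation times to reach sensor time,
#'   or `NA` if not yet estimated.
#' @param session_id identifier; defaults to `infant_id`.
#' @return An object of class `imu_session`.
#' @export
imu_session <- function(infant_id, age_point, task, recordings, annotations,
                        caregiver = NULL, clap_times_audio = numeric(),
                        sync_delay = NA_real_, session_id = infant_id) {
  if (!nzchar(infant_id)) stop("infant_id must be non-empty")
  if (!age_point %in% c(4, 6, 9, 12)) stop("age_point must be 4, 6, 9 or 12")
  task <- match.arg(task, c("book_sharing", "manipulative", "rattles"))
  if (length(recordings) == 0) stop("at least one recording is required")
  locs <- vapply(recordings, function(r) r$location, character(1))
  names(recordings) <- locs
  structure(list(infant_id = infant_id, age_point = age_point, task = task,
                 recordings = recordings, annotations = annotations,
                 caregiver = caregiver, clap_times_audio = clap_times_audio,
                 sync_delay = sync_delay, session_id = session_id),
            class = "imu_session")
}

#' @export
print.imu_session <- function(x, ...) {
  cat(sprintf("<imu_session> %s (infant %s, %d months, %s): %d sensors, %d annotations\n",
              x$session_id, x$infant_id, x$age_point, x$task,
              length(x$recordings), nrow(x$annotations)))
  invisible(x)
}

#' Read a session from a manifest file
#'
#' The manifest is a flat YAML key-value file with keys `infant_id`,
#' `age_point`, `task`, `session_id`, `annotations`, optionally `caregiver`
#' and `clap_times`, and a `sensors` map of location to sensor CSV path.
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path manifest path.
#' @return An [imu_session()].
#' @export
read_session <- function(path) {
  man <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) {
    if (file.exists(p)) p else file.path(base, p)
  }
  need <- c("infant_id", "age_point", "task", "sensors", "annotations")
  miss <- setdiff(need, names(man))
  if (length(miss) > 0) {
    stop("manifest ", path, " missing key(s): ", paste(miss, collapse = ", "))
  }
  recs <- lapply(names(man$sensors), function(loc) {
    f <- resolve(man$sensors[[loc]])
    if (!file.exists(f)) stop("manifest ", path, " references missing sensor file ", f)
    read_sensor_csv(f, loc)
  })
  names(recs) <- names(man$sensors)
  annf <- resolve(man$annotations)
  if (!file.exists(annf)) stop("manifest ", path, " references missing annotation file ", annf)
  caregiver <- NULL
  if (!is.null(man$caregiver)) {
    cf <- resolve(man$caregiver)
    if (!file.exists(cf)) stop("manifest ", path, " references missing caregiver file ", cf)
    caregiver <- as.data.frame(data.table::fread(cf))
  }
  imu_session(infant_id = as.character(man$infant_id),
              age_point = as.numeric(man$age_point),
              task = man$task, recordings = recs,
              annotations = read_annotations(annf),
              caregiver = caregiver,
              clap_times_audio = as.numeric(unlist(man$clap_times)),
              session_id = if (is.null(man$session_id)) as.character(man$infant_id)
                           else as.character(man$session_id))
}

#' Construct a feature table
#'
#' Window-by-feature matrix with per-column descriptors (sensor location,
#' signal, feature group, feature name) and per-row window metadata.
#'
#' @param values numeric W x P matrix.
#' @param descriptors data frame with columns `location`, `signal`, `group`,
#'   `name`, one row per feature column.
#' @param windows data frame with columns `infant_id`, `session_id`, `start`,
#'   `end`, `label`, one row per window.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, descriptors, windows) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.data.frame(descriptors), is.data.frame(windows))
  need <- c("location", "signal", "group", "name")
  stopifnot(all(need %in% names(descriptors)))
  stopifnot(all(c("infant_id", "session_id", "start", "end", "label") %in% names(windows)))
  if (ncol(values) != nrow(descriptors)) {
    stop("descriptor count ", nrow(descriptors), " != feature column count ", ncol(values))
  }
  if (nrow(values) != nrow(windows)) {
    stop("window metadata rows != value rows")
  }
  bad <- setdiff(unique(descriptors$group),
                 c("statistical", "frequency", "summary", "difference", "correlation"))
  if (length(bad) > 0) stop("unknown feature group(s): ", paste(bad, collapse = ", "))
  ids <- feature_ids(descriptors)
  if (anyDuplicated(ids)) {
    stop("duplicate feature descriptors: ", ids[duplicated(ids)][1])
  }
  colnames(values) <- ids
  rownames(values) <- NULL
  rownames(descriptors) <- NULL
  rownames(windows) <- NULL
  structure(list(values = values, descriptors = descriptors, windows = windows),
            class = "feature_table")
}

feature_ids <- function(descriptors) {
  paste(descriptors$location, descriptors$signal, descriptors$group,
        descriptors$name, sep = "|")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d windows x %d features (%d infants)\n",
              nrow(x$values), ncol(x$values), length(unique(x$windows$infant_id))))
  tab <- table(x$descriptors$group)
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Bind feature tables row-wise
#'
#' Tables must share an identical feature-column layout.
#' @param ... feature tables.
#' @return A [feature_table()].
#' @export
rbind_feature_tables <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1 && is.list(tabs[[1]]) && !inherits(tabs[[1]], "feature_table")) {
    tabs <- tabs[[1]]
  }
  ref <- feature_ids(tabs[[1]]$descriptors)
  for (tb in tabs[-1]) {
    if (!identical(feature_ids(tb$descriptors), ref)) {
      stop("feature tables have differing column layouts")
    }
  }
  feature_table(do.call(rbind, lapply(tabs, `[[`, "values")),
                tabs[[1]]$descriptors,
                do.call(rbind, lapply(tabs, `[[`, "windows")))
}

#' Subset a feature table
#'
#' @param x a [feature_table()].
#' @param rows row indices (default all).
#' @param cols column indices or logical over features (default all).
#' @return A [feature_table()].
#' @export
subset_feature_table <- function(x, rows = seq_len(nrow(x$values)),
                                 cols = seq_len(ncol(x$values))) {
  feature_table(x$values[rows, cols, drop = FALSE],
                x$descriptors[cols, , drop = FALSE],
                x$windows[rows, , drop = FALSE])
}

#' Write a feature table to CSV
#'
#' The file carries a 4-line column-metadata block (`#location`, `#signal`,
#' `#group`, `#name`) above the data header. Values are written with 17
#' significant digits so that [read_feature_table()] round-trips bit-exactly.
#'
#' @param table a [feature_table()].
#' @param path output path.
#' @export
write_feature_table <- function(table, path) {
  meta_cols <- c("infant_id", "session_id", "start", "end", "label")
  P <- ncol(table$values)
  hdr <- vapply(c("location", "signal", "group", "name"), function(f) {
    paste(c(paste0("#", f), rep("", length(meta_cols) - 1),
            table$descriptors[[f]]), collapse = ",")
  }, character(1))
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con, useBytes = TRUE)
  writeLines(paste(c(meta_cols, colnames(table$values)), collapse = ","), con,
             useBytes = TRUE)
  if (nrow(table$values) > 0) {
    vals <- matrix(sprintf("%.17g", table$values), nrow = nrow(table$values))
    body <- do.call(paste, c(list(table$windows$infant_id,
                                  table$windows$session_id,
                                  sprintf("%.17g", table$windows$start),
                                  sprintf("%.17g", table$windows$end),
                                  table$windows$label),
                             asplit(vals, 2), list(sep = ",")))
    writeLines(body, con, useBytes = TRUE)
  }
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path file path.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path) {
  hdr <- readLines(path, n = 5, encoding = "UTF-8")
  if (length(hdr) < 5 || !startsWith(hdr[1], "#location")) {
    stop("not a feature-table file (missing metadata block): ", path)
  }
  meta <- lapply(hdr[1:4], function(l) strsplit(l, ",", fixed = TRUE)[[1]])
  n_meta <- 5L
  desc <- data.frame(
    location = meta[[1]][-seq_len(n_meta)],
    signal = meta[[2]][-seq_len(n_meta)],
    group = meta[[3]][-seq_len(n_meta)],
    name = meta[[4]][-seq_len(n_meta)],
    stringsAsFactors = FALSE)
  # degenerate: zero features
  if (length(meta[[1]]) <= n_meta) {
    desc <- data.frame(location = character(), signal = character(),
                       group = character(), name = character(),
                       stringsAsFactors = FALSE)
  }
  dt <- data.table::fread(path, skip = 4, header = TRUE, sep = ",",
                          encoding = "UTF-8",
                          colClasses = list(character = c(1, 2, 5)))
  windows <- data.frame(infant_id = as.character(dt[[1]]),
                        session_id = as.character(dt[[2]]),
                        start = as.numeric(dt[[3]]), end = as.numeric(dt[[4]]),
                        label = as.character(dt[[5]]),
                        stringsAsFactors = FALSE)
  if (nrow(dt) == 0) {
    windows <- data.frame(infant_id = character(), session_id = character(),
                          start = numeric(), end = numeric(),
                          label = character(), stringsAsFactors = FALSE)
  }
  vals <- as.matrix(dt[, -(1:5), drop = FALSE])
  if (nrow(dt) == 0) vals <- matrix(numeric(), 0, nrow(desc))
  storage.mode(vals) <- "double"
  feature_table(vals, desc, windows)
}
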