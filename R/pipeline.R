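#' Run configuration
#'
#' Bundles the stage configurations for an end-to-end run.
#'
#' @param seed integer seed recorded in every output and used for fold
#'   construction and model fitting.
#' @param sensor_set locations used for features.
#' @param families classifier families to train.
#' @param quantiles statistical-feature quantiles.
#' @param prep a [preprocess_config()].
#' @param window a [window_spec()].
#' @param model_params named list of per-family parameter overrides.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       sensor_set = c("trunk_a", "leg_left", "leg_right"),
                       families = "gradient_boosted_trees",
                       quantiles = c(0.25, 0.75),
                       prep = preprocess_config(), window = window_spec(),
                       model_params = list()) {
  structure(list(seed = as.integer(seed), sensor_set = sensor_set,
                 families = families, quantiles = quantiles, prep = prep,
                 window = window, model_params = model_params),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognised keys mirror the [run_config()] arguments; preprocessing and
#' windowing keys (`target_rate`, `lp_cutoff`, `hp_cutoff`, `filter_order`,
#' `artifact_window_s`, `artifact_var_threshold`, `max_gap_s`, `clap_count`,
#' `window_s`, `step_s`, `consistency_threshold`) are accepted at the top
#' level.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  prep_keys <- c("target_rate", "lp_cutoff", "hp_cutoff", "filter_order",
                 "artifact_window_s", "artifact_var_threshold", "max_gap_s",
                 "clap_count")
  prep <- do.call(preprocess_config, y[intersect(names(y), prep_keys)])
  win_map <- c(window_s = "length_s", step_s = "step_s",
               consistency_threshold = "consistency_threshold")
  win_args <- y[intersect(names(y), names(win_map))]
  names(win_args) <- win_map[names(win_args)]
  win <- do.call(window_spec, win_args)
  args <- y[intersect(names(y), c("seed", "sensor_set", "families",
                                  "quantiles", "model_params"))]
  do.call(run_config, c(args, list(prep = prep, window = win)))
}

#' Time-in-position shares and their annotation-prediction correlation
#'
#' For each session and class, the share of session time annotated as the
#' class and the share predicted as the class, each expressed as a percentage
#' of the session duration. Overlapping windows contribute their step length
#' (1 s) to the temporal sums, except the last window of a session, which
#' contributes its full length, so overlap seconds are not double-counted.
#' Predicted shares use cross-validated held-out predictions only. Per class,
#' the Pearson correlation over sessions between annotated and predicted
#' share is reported.
#'
#' @param windows window metadata with columns `session_id`, `start`, `end`,
#'   `label` (the labelled windows that entered the model).
#' @param predictions data frame with `session_id`, `start`, `pred` (held-out
#'   predictions, e.g. from [cv_predictions()]).
#' @param durations named numeric vector: session duration in seconds.
#' @return List of class `time_share_report`: `shares` (session x class
#'   annotated/predicted percentages, long format) and `correlations` (per
#'   class Pearson r and n).
#' @export
time_share <- function(windows, predictions, durations) {
  classes <- position_classes()
  key <- function(s, st) paste(s, sprintf("%.6f", st))
  pred_map <- stats::setNames(predictions$pred,
                              key(predictions$session_id, predictions$start))
  sessions <- unique(windows$session_id)
  rows <- list()
  for (sid in sessions) {
    dur <- durations[[sid]]
    if (is.null(dur) || is.na(dur) || dur <= 0) {
      warning("session ", sid, " has zero or unknown duration; skipped")
      next
    }
    w <- windows[windows$session_id == sid, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    contrib <- if (nrow(w) > 1) c(diff(w$start), w$end[nrow(w)] - w$start[nrow(w)])
               else if (nrow(w) == 1) w$end - w$start else numeric()
    pr <- pred_map[key(sid, w$start)]
    for (cl in classes) {
      rows[[length(rows) + 1L]] <- data.frame(
        session_id = sid, class = cl,
        annotated_pct = 100 * sum(contrib[w$label == cl]) / dur,
        predicted_pct = 100 * sum(contrib[!is.na(pr) & pr == cl]) / dur,
        stringsAsFactors = FALSE)
    }
  }
  shares <- do.call(rbind, rows)
  cors <- do.call(rbind, lapply(classes, function(cl) {
    s <- shares[shares$class == cl, , drop = FALSE]
    ok <- stats::complete.cases(s[, c("annotated_pct", "predicted_pct")])
    s <- s[ok, , drop = FALSE]
    r <- if (nrow(s) >= 2 && stats::sd(s$annotated_pct) > 0 &&
             stats::sd(s$predicted_pct) > 0) {
      stats::cor(s$annotated_pct, s$predicted_pct)
    } else NA_real_
    data.frame(class = cl, r = r, n = nrow(s), stringsAsFactors = FALSE)
  }))
  structure(list(shares = shares, correlations = cors),
            class = "time_share_report")
}

#' @export
print.time_share_report <- function(x, ...) {
  cat("<time_share_report> annotated vs predicted time-in-position\n")
  print(x$correlations, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Run the full pipeline on a set of session manifests
#'
#' Preprocess, synchronise, segment, featurise, cross-validate and report.
#' Every artefact is written under `out_dir` together with a config snapshot,
#' the seed and a log; a rerun with the same inputs and seed reproduces all
#' CSV outputs byte-identically. On a stage failure the partial outputs are
#' moved under `out_dir/failed/` and the error names the stage and session.
#'
#' @param manifests character vector of manifest paths.
#' @param config a [run_config()].
#' @param out_dir output directory (created).
#' @return Invisibly, a list with the feature table, per-family [posture_cv()]
#'   results and the [time_share()] report.
#' @export
run_pipeline <- function(manifests, config = run_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  fail <- function(stage, sid, e) {
    fdir <- file.path(out_dir, "failed")
    dir.create(fdir, showWarnings = FALSE)
    for (f in setdiff(list.files(out_dir, full.names = TRUE),
                      file.path(out_dir, "failed"))) {
      file.copy(f, fdir, overwrite = TRUE)
    }
    stop("pipeline stage '", stage, "' failed for session '", sid, "': ",
         conditionMessage(e), call. = FALSE)
  }
  feat_cfg <- feature_config(quantiles = config$quantiles,
                             sensor_set = config$sensor_set)
  logf("seed=%d sessions=%d sensors=%s", config$seed, length(manifests),
       paste(config$sensor_set, collapse = "+"))
  tabs <- list()
  durations <- c()
  for (mp in manifests) {
    sid <- basename(dirname(mp))
    sess <- tryCatch(read_session(mp), error = function(e) fail("read", sid, e))
    sid <- sess$session_id
    sess <- tryCatch(preprocess_session(sess, config$prep),
                     error = function(e) fail("preprocess", sid, e))
    win <- tryCatch(segment_session(sess, config$window,
                                    sensor_set = config$sensor_set),
                    error = function(e) fail("segmentation", sid, e))
    tab <- tryCatch(build_feature_matrix(sess, win, feat_cfg, config$prep),
                    error = function(e) fail("features", sid, e))
    if (attr(tab, "dropped") > 0) {
      logf("session %s: dropped %d window(s) with missing features", sid,
           attr(tab, "dropped"))
    }
    logf("session %s: delay=%.4f s, %d/%d windows labelled", sid,
         sess$sync_delay, nrow(tab$values), nrow(win))
    tabs[[sid]] <- tab
    recs <- sess$recordings[config$sensor_set]
    durations[sid] <- min(vapply(recs, function(r) r$t[length(r$t)] - r$t[1],
                                 numeric(1)))
  }
  table <- rbind_feature_tables(tabs)
  write_feature_table(table, file.path(out_dir, "features.csv"))
  folds <- tryCatch(make_group_folds(table$windows$infant_id, 5, config$seed),
                    error = function(e) fail("folds", "-", e))
  results <- list()
  ts_report <- NULL
  for (fam in config$families) {
    spec <- model_spec(fam, params = if (is.null(config$model_params[[fam]]))
      list() else config$model_params[[fam]], seed = config$seed)
    cv <- tryCatch(posture_cv(table, spec, folds = folds),
                   error = function(e) fail(paste0("model:", fam), "-", e))
    results[[fam]] <- cv
    tag <- if (fam == "random_forest") "rf" else "gbt"
    data.table::fwrite(cv$summary, file.path(out_dir, paste0("cv_f1_", tag, ".csv")))
    preds <- cv_predictions(cv)
    data.table::fwrite(preds, file.path(out_dir, paste0("predictions_", tag, ".csv")))
    cs <- confusion_summary(cv)
    conf <- data.frame(actual = rep(cv$classes, each = length(cv$classes)),
                       predicted = rep(cv$classes, length(cv$classes)),
                       mean_count = as.vector(t(cs$mean_count)),
                       se_count = as.vector(t(cs$se_count)),
                       row_pct = as.vector(t(cs$row_pct)))
    data.table::fwrite(conf, file.path(out_dir, paste0("confusion_", tag, ".csv")))
    ts <- time_share(table$windows, data.frame(session_id = preds$session_id,
                                               start = preds$start,
                                               pred = preds$pred),
                     durations)
    data.table::fwrite(ts$shares, file.path(out_dir, paste0("time_share_", tag, ".csv")))
    data.table::fwrite(ts$correlations,
                       file.path(out_dir, paste0("time_share_cor_", tag, ".csv")))
    ts_report <- ts
    logf("model %s: macro F1 %.4f", fam, mean(cv$summary$mean_f1, na.rm = TRUE))
  }
  snapshot <- list(seed = config$seed, sensor_set = config$sensor_set,
                   families = config$families, quantiles = config$quantiles,
                   prep = unclass(config$prep), window = unclass(config$window))
  yaml::write_yaml(snapshot, file.path(out_dir, "config.yaml"))
  invisible(list(features = table, cv = results, time_share = ts_report,
                 durations = durations, folds = folds))
}

#' Command-line entry point
#'
#' Thin wrapper over the package functions, installed as
#' `exec/imuposture`. Verbs: `simulate` (write a benchmark dataset),
#' `run-all` (full pipeline over a dataset directory), `train-eval`
#' (cross-validate a stored feature table).
#'
#' @param args character vector of command-line arguments.
#' @return Exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: imuposture <verb> [options]",
    "  simulate   --out DIR [--preset separable|noisy|ambiguous_hk]",
    "             [--infants N] [--sessions N] [--duration S] [--seed N]",
    "  run-all    --data DIR --out DIR [--seed N] [--model gbt|rf]",
    "             [--sensors loc1,loc2,...]",
    "  train-eval --features FILE --out DIR [--model gbt|rf] [--seed N]",
    sep = "\n")
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  verb <- args[1]
  opts <- list()
  i <- 2
  while (i <= length(args)) {
    if (!startsWith(args[i], "--") || i == length(args)) {
      stop("malformed option: ", args[i])
    }
    opts[[substring(args[i], 3)]] <- args[i + 1]
    i <- i + 2
  }
  get <- function(key, default = NULL) {
    if (!is.null(opts[[key]])) opts[[key]] else default
  }
  seed <- as.integer(get("seed", "1"))
  fam <- function() {
    switch(get("model", "gbt"), gbt = "gradient_boosted_trees",
           rf = "random_forest", stop("unknown model: ", get("model")))
  }
  if (verb == "simulate") {
    out <- get("out"); if (is.null(out)) stop("simulate needs --out")
    mp <- make_benchmark_suite(get("preset", "separable"), out, seed = seed,
                               n_infants = as.integer(get("infants", "20")),
                               sessions_per_infant = as.integer(get("sessions", "3")),
                               duration_s = as.numeric(get("duration", "300")))
    message(length(mp), " sessions written under ", out)
  } else if (verb == "run-all") {
    data_dir <- get("data"); out <- get("out")
    if (is.null(data_dir) || is.null(out)) stop("run-all needs --data and --out")
    manifests <- sort(list.files(data_dir, pattern = "^manifest\\.yaml$",
                                 recursive = TRUE, full.names = TRUE))
    if (length(manifests) == 0) stop("no manifests under ", data_dir)
    cfg <- run_config(seed = seed, families = fam())
    if (!is.null(opts$sensors)) {
      cfg$sensor_set <- strsplit(opts$sensors, ",")[[1]]
    }
    res <- run_pipeline(manifests, cfg, out)
    print(res$cv[[1]])
  } else if (verb == "train-eval") {
    f <- get("features"); out <- get("out")
    if (is.null(f) || is.null(out)) stop("train-eval needs --features and --out")
    table <- read_feature_table(f)
    cv <- posture_cv(table, model_spec(fam(), seed = seed), seed = seed)
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(cv$summary, file.path(out, "cv_f1.csv"))
    data.table::fwrite(cv_predictions(cv), file.path(out, "predictions.csv"))
    print(cv)
  } else {
    message(usage)
    return(invisible(1L))
  }
  invisible(0L)
}
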