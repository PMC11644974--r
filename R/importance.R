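#' Feature-group ablation
#'
#' Retrains the classifier with a feature group removed (`mode = "without"`)
#' or kept alone (`mode = "only"`), on exactly the same folds and seed as a
#' reference run on all groups, and reports the per-class relative F1 change
#' `100 * (F1_ablated - F1_all) / F1_all`.
#'
#' @param table a [feature_table()].
#' @param spec a [model_spec()].
#' @param folds fold assignment from [make_group_folds()].
#' @param mode `"only"` or `"without"`.
#' @param group one of the five feature groups.
#' @param reference optional precomputed all-groups [posture_cv()] on the same
#'   table/folds/spec (computed when missing).
#' @return Data frame of class `ablation_report`: `class`, `mode`, `group`,
#'   `delta_f1_pct`, `f1_ablated`, `f1_reference`, plus per-fold values in
#'   attribute `per_fold`.
#' @export
ablate <- function(table, spec, folds, mode = c("only", "without"), group,
                   reference = NULL) {
  mode <- match.arg(mode)
  groups <- c("statistical", "frequency", "summary", "difference", "correlation")
  if (!group %in% groups) stop("unknown feature group: ", group)
  keep <- if (mode == "only") table$descriptors$group == group
          else table$descriptors$group != group
  if (!any(keep)) {
    stop("ablation filter (", mode, " ", group, ") leaves zero feature columns")
  }
  if (is.null(reference)) {
    reference <- posture_cv(table, spec, folds = folds)
  }
  sub <- subset_feature_table(table, cols = which(keep))
  abl <- posture_cv(sub, spec, folds = folds)
  ref_f1 <- reference$summary$mean_f1
  abl_f1 <- abl$summary$mean_f1
  out <- data.frame(class = reference$classes, mode = mode, group = group,
                    delta_f1_pct = 100 * (abl_f1 - ref_f1) / ref_f1,
                    f1_ablated = abl_f1, f1_reference = ref_f1,
                    stringsAsFactors = FALSE)
  attr(out, "per_fold") <- list(reference = reference$f1, ablated = abl$f1)
  class(out) <- c("ablation_report", "data.frame")
  out
}

#' Per-row absolute SHAP attributions of a fitted model
#'
#' Exact TreeSHAP feature contributions for a gradient-boosted model; the
#' multiclass attributions are reduced by summing the absolute value over the
#' class outputs, preserving the partition property when grouped.
#'
#' @param model a fitted `posture_classifier` (gradient-boosted family).
#' @param x numeric matrix of evaluation rows.
#' @return Rows x features matrix of summed absolute SHAP values (the bias
#'   column is excluded).
#' @export
shap_values <- function(model, x) {
  if (model$family != "random_forest" && model$family != "gradient_boosted_trees") {
    stop("unsupported model family")
  }
  if (model$family == "random_forest") {
    stop("exact additive Shapley attribution is available for the ",
         "gradient-boosted family only")
  }
  contrib <- stats::predict(model$fit, xgboost::xgb.DMatrix(x),
                            predcontrib = TRUE)
  # rows x classes x (features + bias)
  absum <- apply(abs(contrib), c(1, 3), sum)
  absum[, -ncol(absum), drop = FALSE]
}

#' Group-wise |SHAP| importance
#'
#' Per-feature mean absolute SHAP values over each fold's held-out rows,
#' aggregated within each (signal, group) cell by sum and by mean, with the
#' across-fold mean and standard error. The cell sums exactly partition the
#' total per-feature |SHAP| sum.
#'
#' @param cv a [posture_cv()] run of the gradient-boosted family.
#' @param table the [feature_table()] the run was fitted on.
#' @return Data frame of class `shap_group_report`: `signal`, `group`,
#'   `n_features`, `shap_sum`, `shap_sum_se`, `shap_mean`, `shap_mean_se`.
#'   Attribute `per_feature` carries the fold-averaged per-feature values.
#' @export
shap_group_importance <- function(cv, table) {
  desc <- table$descriptors
  per_fold <- lapply(seq_along(cv$folds), function(i) {
    f <- cv$folds[[i]]
    if (is.null(f$model) || nrow(f$predictions) == 0) return(NULL)
    if (f$model$p != ncol(table$values)) {
      stop("descriptor mismatch: model has ", f$model$p, " features, table has ",
           ncol(table$values))
    }
    sv <- shap_values(f$model, table$values[f$predictions$row, , drop = FALSE])
    colMeans(sv)  # per-feature mean |SHAP| over evaluation rows
  })
  per_fold <- per_fold[!vapply(per_fold, is.null, logical(1))]
  if (length(per_fold) == 0) stop("no evaluable folds")
  M <- do.call(rbind, per_fold)  # folds x features
  cell <- paste(desc$signal, desc$group, sep = "|")
  cells <- unique(cell)
  agg <- lapply(cells, function(cl) {
    sel <- cell == cl
    sums <- rowSums(M[, sel, drop = FALSE])
    sum_mean <- mean(sums)
    sum_se <- stats::sd(sums) / sqrt(length(sums))
    data.frame(signal = desc$signal[sel][1], group = desc$group[sel][1],
               n_features = sum(sel),
               shap_sum = sum_mean, shap_sum_se = sum_se,
               shap_mean = sum_mean / sum(sel),  # exact sum/count identity
               shap_mean_se = sum_se / sum(sel),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(-out$shap_sum), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "per_feature") <- colMeans(M)
  attr(out, "per_fold_feature") <- M
  class(out) <- c("shap_group_report", "data.frame")
  out
}

#' Friedman tests with FDR correction over classes
#'
#' For each position class, a Friedman rank test across folds (blocks) of the
#' paired treatment scores, with Benjamini-Hochberg adjustment across the
#' family of classes.
#'
#' @param scores named list, one entry per class, each a folds x treatments
#'   matrix of F1 scores.
#' @return Data frame: `class`, `statistic`, `df`, `p`, `p_adj`.
#' @export
friedman_fdr <- function(scores) {
  res <- lapply(names(scores), function(cl) {
    m <- scores[[cl]]
    if (is.null(m) || nrow(m) < 3 || any(!is.finite(m))) {
      warning("class ", cl, ": fewer than 3 complete paired observations; test skipped")
      return(data.frame(class = cl, statistic = NA_real_, df = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    ft <- stats::friedman.test(as.matrix(m))
    st <- unname(ft$statistic); pv <- ft$p.value
    if (!is.finite(st)) {  # every block fully tied: no evidence of difference
      st <- 0; pv <- 1
    }
    data.frame(class = cl, statistic = st, df = unname(ft$parameter), p = pv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Compare nested sensor subsets
#'
#' Fits the classifier on features restricted to each of the nested sensor
#' sets (trunk; trunk + legs; trunk + legs + arms) with identical folds, and
#' tests the per-class F1 differences across the paired sets with a Friedman
#' test, FDR-adjusted over the five classes.
#'
#' @param sessions list of preprocessed [imu_session()]s.
#' @param spec a [model_spec()].
#' @param seed seed for fold construction.
#' @param prep_cfg,win_spec preprocessing and windowing settings.
#' @param sets named list of location vectors; the default nests trunk, legs
#'   and arms.
#' @param quantiles passed to [feature_config()].
#' @return List of class `sensor_set_comparison`: `mean_f1` (set x class),
#'   `tests` ([friedman_fdr()] output), `cv` (per-set [posture_cv()] runs).
#' @export
compare_sensor_sets <- function(sessions, spec = model_spec(), seed = 1L,
                                prep_cfg = preprocess_config(),
                                win_spec = window_spec(),
                                sets = list(
                                  trunk = c("trunk_a", "trunk_b"),
                                  trunk_legs = c("trunk_a", "trunk_b",
                                                 "leg_left", "leg_right"),
                                  trunk_legs_arms = c("trunk_a", "trunk_b",
                                                      "leg_left", "leg_right",
                                                      "arm_left", "arm_right")),
                                quantiles = c(0.25, 0.75)) {
  have <- names(sessions[[1]]$recordings)
  sets <- lapply(sets, intersect, x = have)
  sets <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    if (length(s) == 0) stop("sensor set ", nm, " has no available locations")
    s
  }) |> stats::setNames(names(sets))
  folds <- NULL
  runs <- list()
  for (nm in names(sets)) {
    cfg <- feature_config(quantiles = quantiles, sensor_set = sets[[nm]])
    tab <- featurize_sessions(sessions, cfg, prep_cfg, win_spec,
                              preprocessed = TRUE)
    if (is.null(folds)) folds <- make_group_folds(tab$windows$infant_id, 5, seed)
    runs[[nm]] <- posture_cv(tab, spec, folds = folds)
  }
  classes <- position_classes()
  scores <- lapply(classes, function(cl) {
    m <- vapply(runs, function(r) r$f1[, cl], numeric(nrow(runs[[1]]$f1)))
    matrix(m, ncol = length(runs), dimnames = list(NULL, names(runs)))
  })
  names(scores) <- classes
  mean_f1 <- t(vapply(runs, function(r) r$summary$mean_f1, numeric(length(classes))))
  colnames(mean_f1) <- classes
  structure(list(mean_f1 = mean_f1, tests = friedman_fdr(scores),
                 scores = scores, cv = runs, sets = sets),
            class = "sensor_set_comparison")
}

#' @export
print.sensor_set_comparison <- function(x, ...) {
  cat("<sensor_set_comparison> mean F1 by sensor set:\n")
  print(round(x$mean_f1, 3))
  cat("Friedman tests (BH-adjusted over classes):\n")
  print(x$tests, row.names = FALSE, digits = 3)
  invisible(x)
}
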