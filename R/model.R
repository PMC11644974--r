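#' Classifier specification
#'
#' Two tree-ensemble families are supported. The random forest uses the fixed
#' reference setting `n_estimators = 1000, max_depth = 6` with balanced class
#' weighting. The gradient-boosted model defaults to 150 boosting iterations
#' at learning rate 0.2, depth 6, with balanced per-row weights; these
#' defaults are this package's own choice and are fully configurable.
#'
#' @param family `"gradient_boosted_trees"` or `"random_forest"`.
#' @param params named list overriding the family defaults
#'   (`n_estimators`/`iterations`, `max_depth`, `learning_rate`,
#'   `class_weight`).
#' @param seed integer seed used for every stochastic step of fitting.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(family = c("gradient_boosted_trees", "random_forest"),
                       params = list(), seed = 1L) {
  family <- match.arg(family)
  defaults <- if (family == "random_forest") {
    list(n_estimators = 1000L, max_depth = 6L, class_weight = "balanced")
  } else {
    list(iterations = 150L, max_depth = 6L, learning_rate = 0.2,
         class_weight = "balanced")
  }
  defaults[names(params)] <- params
  structure(list(family = family, params = defaults, seed = as.integer(seed)),
            class = "model_spec")
}

balanced_weights <- function(y, classes) {
  counts <- table(factor(y, levels = classes))
  w <- length(y) / (sum(counts > 0) * pmax(counts, 1))
  as.numeric(w[as.character(y)])
}

#' Assign infants to cross-validation folds
#'
#' Infants are shuffled with the seed and dealt round-robin into `k` folds, so
#' the assignment is a function of the infant identifier only and every
#' infant's windows land in exactly one test fold.
#'
#' @param infant_ids character vector, one entry per row (or the unique ids).
#' @param k number of folds.
#' @param seed integer seed.
#' @return Named integer vector: fold per unique infant.
#' @export
make_group_folds <- function(infant_ids, k = 5, seed = 1L) {
  infants <- sort(unique(as.character(infant_ids)))
  if (length(infants) < k) {
    stop("need at least ", k, " distinct infants for ", k, "-fold CV, got ",
         length(infants))
  }
  rng <- local_rng(seed)
  perm <- infants[rng$sample_idx(length(infants))]
  stats::setNames(rep_len(seq_len(k), length(perm)), perm)
}

# Seeded RNG scoped away from the global stream.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    s
  }
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    f()
  }
  list(sample_idx = function(n) with_state(function() sample.int(n)),
       runif = function(n, ...) with_state(function() stats::runif(n, ...)),
       with_state = with_state)
}

fit_classifier <- function(x, y, spec, classes = position_classes()) {
  y <- factor(as.character(y), levels = classes)
  p <- spec$params
  if (spec$family == "random_forest") {
    cw <- if (identical(p$class_weight, "balanced")) {
      counts <- table(y)
      w <- length(y) / (sum(counts > 0) * pmax(counts, 1))
      w[counts == 0] <- 0
      as.numeric(w)
    } else rep(1, length(classes))
    df <- as.data.frame(x)
    names(df) <- paste0("f", seq_len(ncol(x)))
    fit <- ranger::ranger(y = droplevels(y), x = df[, , drop = FALSE],
                          num.trees = p$n_estimators, max.depth = p$max_depth,
                          class.weights = cw[levels(y) %in% levels(droplevels(y))],
                          seed = spec$seed, num.threads = 1,
                          probability = FALSE)
    structure(list(family = spec$family, fit = fit, classes = classes,
                   levels_used = levels(droplevels(y)), p = ncol(x)),
              class = "posture_classifier")
  } else {
    w <- if (identical(p$class_weight, "balanced")) balanced_weights(y, classes)
         else rep(1, length(y))
    lab <- as.integer(y) - 1L
    dtrain <- xgboost::xgb.DMatrix(x, label = lab, weight = w)
    fit <- xgboost::xgb.train(
      params = list(objective = "multi:softprob",
                    num_class = length(classes),
                    max_depth = p$max_depth, eta = p$learning_rate,
                    nthread = 1, tree_method = "hist",
                    subsample = 1, colsample_bytree = 1,
                    seed = spec$seed),
      data = dtrain, nrounds = p$iterations, verbose = 0)
    structure(list(family = spec$family, fit = fit, classes = classes,
                   levels_used = classes, p = ncol(x)),
              class = "posture_classifier")
  }
}

predict_classifier <- function(model, x) {
  if (model$family == "random_forest") {
    df <- as.data.frame(x)
    names(df) <- paste0("f", seq_len(ncol(x)))
    as.character(stats::predict(model$fit, data = df,
                                num.threads = 1)$predictions)
  } else {
    pr <- stats::predict(model$fit, xgboost::xgb.DMatrix(x))
    model$classes[max.col(pr, ties.method = "first")]
  }
}

#' One-vs-rest F1 scores
#'
#' `F1 = 2PR / (P + R)` per class against all others, with `F1 = 0` when both
#' precision and recall are zero, and `NA` for classes absent from both truth
#' and prediction.
#'
#' @param truth,pred character vectors of class labels.
#' @param classes class order for the result.
#' @return Named numeric vector.
#' @export
f1_scores <- function(truth, pred, classes = position_classes()) {
  vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (tp + fp + fn == 0) return(NA_real_)
    if (tp == 0) return(0)
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, numeric(1))
}

#' Infant-grouped cross-validated posture classification
#'
#' The package's central fitting routine: trains the requested classifier
#' family under k-fold cross-validation with all of an infant's windows
#' confined to a single fold, and collects per-fold held-out predictions,
#' per-class one-vs-rest F1 scores and confusion counts.
#'
#' @param table a [feature_table()].
#' @param spec a [model_spec()].
#' @param k number of folds.
#' @param seed seed for fold construction (and the model seed unless the spec
#'   sets its own).
#' @param folds optional precomputed fold assignment from
#'   [make_group_folds()]; must cover every infant in the table.
#' @return An object of class `posture_cv`: `folds` (per-fold test infants,
#'   F1, predictions, confusion, fitted model), `summary` (per-class mean F1
#'   and standard error over folds), `classes`, `spec`, `fold_assignment`.
#' @export
posture_cv <- function(table, spec = model_spec(), k = 5, seed = 1L,
                       folds = NULL) {
  classes <- position_classes()
  y <- table$windows$label
  if (length(unique(y)) < 2) stop("feature table must contain at least 2 classes")
  if (is.null(folds)) folds <- make_group_folds(table$windows$infant_id, k, seed)
  miss <- setdiff(unique(table$windows$infant_id), names(folds))
  if (length(miss) > 0) stop("fold assignment missing infant(s): ",
                             paste(miss, collapse = ", "))
  row_fold <- unname(folds[table$windows$infant_id])
  k <- max(folds)
  fold_res <- lapply(seq_len(k), function(i) {
    tr <- which(row_fold != i)
    te <- which(row_fold == i)
    if (length(te) == 0) {
      return(list(test_infants = character(), f1 = rep(NA_real_, length(classes)),
                  predictions = data.frame(), confusion = matrix(0, length(classes),
                                                                 length(classes)),
                  model = NULL))
    }
    absent <- setdiff(classes, unique(y[tr]))
    if (length(absent) > 0 && length(absent) < length(classes)) {
      warning("fold ", i, ": class(es) absent from training split: ",
              paste(absent, collapse = ", "))
    }
    model <- fit_classifier(table$values[tr, , drop = FALSE], y[tr], spec, classes)
    pred <- predict_classifier(model, table$values[te, , drop = FALSE])
    f1 <- f1_scores(y[te], pred, classes)
    f1[classes %in% absent] <- NA_real_
    conf <- table(factor(y[te], levels = classes),
                  factor(pred, levels = classes))
    list(test_infants = sort(unique(table$windows$infant_id[te])),
         f1 = f1,
         predictions = data.frame(row = te,
                                  infant_id = table$windows$infant_id[te],
                                  session_id = table$windows$session_id[te],
                                  start = table$windows$start[te],
                                  truth = y[te], pred = pred,
                                  stringsAsFactors = FALSE),
         confusion = unclass(conf), model = model)
  })
  f1_mat <- t(vapply(fold_res, `[[`, numeric(length(classes)), "f1"))
  colnames(f1_mat) <- classes
  n_ok <- colSums(!is.na(f1_mat))
  summ <- data.frame(class = classes,
                     mean_f1 = colMeans(f1_mat, na.rm = TRUE),
                     se_f1 = apply(f1_mat, 2, stats::sd, na.rm = TRUE) /
                       sqrt(pmax(n_ok, 1)),
                     folds = n_ok, stringsAsFactors = FALSE)
  structure(list(folds = fold_res, f1 = f1_mat, summary = summ,
                 classes = classes, spec = spec, fold_assignment = folds,
                 seed = seed),
            class = "posture_cv")
}

#' Held-out predictions of a cross-validation run
#'
#' @param cv a [posture_cv()] result.
#' @return Data frame of all folds' held-out predictions, in row order of the
#'   feature table.
#' @export
cv_predictions <- function(cv) {
  out <- do.call(rbind, lapply(cv$folds, `[[`, "predictions"))
  out[order(out$row), , drop = FALSE]
}

#' @export
print.posture_cv <- function(x, ...) {
  cat(sprintf("<posture_cv> %s, %d folds, %d windows\n", x$spec$family,
              length(x$folds), sum(vapply(x$folds, function(f) nrow(f$predictions), 0))))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
summary.posture_cv <- function(object, ...) {
  cs <- confusion_summary(object)
  out <- list(f1 = object$summary, confusion = cs,
              macro_f1 = mean(object$summary$mean_f1, na.rm = TRUE))
  class(out) <- "summary.posture_cv"
  out
}

#' @export
print.summary.posture_cv <- function(x, ...) {
  print(x$f1, row.names = FALSE, digits = 3)
  cat(sprintf("macro F1: %.3f\n", x$macro_f1))
  cat("row-normalised confusion (%):\n")
  print(round(x$confusion$row_pct, 1))
  invisible(x)
}

#' @export
predict.posture_cv <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_table")) newdata$values else as.matrix(newdata)
  votes <- vapply(object$folds, function(f) {
    if (is.null(f$model)) return(rep(NA_character_, nrow(x)))
    predict_classifier(f$model, x)
  }, character(nrow(x)))
  votes <- matrix(votes, nrow = nrow(x))
  apply(votes, 1, function(v) {
    v <- v[!is.na(v)]
    names(sort(table(factor(v, levels = object$classes)), decreasing = TRUE))[1]
  })
}

#' @export
plot.posture_cv <- function(x, ...) {
  cs <- confusion_summary(x)
  pct <- cs$row_pct
  k <- nrow(pct)
  graphics::image(seq_len(k), seq_len(k), t(pct[k:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(25, "Blues", rev = TRUE),
                  axes = FALSE, xlab = "predicted", ylab = "actual", ...)
  graphics::axis(1, at = seq_len(k), labels = colnames(pct), las = 2, cex.axis = 0.8)
  graphics::axis(2, at = seq_len(k), labels = rev(rownames(pct)), las = 1, cex.axis = 0.8)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    graphics::text(j, k + 1 - i, sprintf("%.0f%%", pct[i, j]), cex = 0.8)
  }
  invisible(x)
}

#' Confusion-matrix summary across folds
#'
#' Per cell: mean count across folds, its standard error, and the
#' row-normalised percentage of the true class (rows sum to 100 for classes
#' that occur).
#'
#' @param cv a [posture_cv()] result.
#' @return List with matrices `mean_count`, `se_count`, `row_pct`, and
#'   `undefined_rows` (classes with no test windows in any fold).
#' @export
confusion_summary <- function(cv) {
  stopifnot(length(cv$folds) >= 1)
  arr <- simplify2array(lapply(cv$folds, `[[`, "confusion"))
  mean_count <- apply(arr, c(1, 2), mean)
  se_count <- apply(arr, c(1, 2), stats::sd) / sqrt(dim(arr)[3])
  rs <- rowSums(mean_count)
  row_pct <- 100 * mean_count / ifelse(rs == 0, NA, rs)
  dimnames(mean_count) <- dimnames(se_count) <- dimnames(row_pct) <-
    list(cv$classes, cv$classes)
  list(mean_count = mean_count, se_count = se_count, row_pct = row_pct,
       undefined_rows = cv$classes[rs == 0])
}
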