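# Classifier evaluation: confusion-matrix metrics, threshold-sweep ROC
# curves (including the truncated sweep that arises when a fixed arm-distance
# filter caps the attainable sensitivity), boolean AND/OR combination of
# predictors, stratified splitting, and the two reference baselines fitted on
# the same two features the rule-based classifier uses: "Moon Rover"
# (logistic regression) and "Moon Walker" (gradient boosting with 10-fold CV
# grid search on CV AUC).

#' Confusion-matrix metrics for binary predictions
#'
#' @param truth,preds Logical vectors of equal, positive length (no `NA`).
#' @return A list of class `confusion_metrics` with integer counts `tp`,
#'   `fp`, `tn`, `fn` and fractions `sensitivity` (TP/(TP+FN)), `specificity`
#'   (TN/(TN+FP)) and `ppv` (TP/(TP+FP)); a 0/0 ratio is reported as `NA`
#'   (undefined), never 0.
#' @examples
#' confusion_metrics(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
confusion_metrics <- function(truth, preds) {
  stopifnot(is.logical(truth), is.logical(preds))
  if (length(truth) != length(preds)) {
    stop("`truth` and `preds` must have equal length", call. = FALSE)
  }
  if (length(truth) == 0L || anyNA(truth) || anyNA(preds)) {
    stop("`truth` and `preds` must be non-empty and free of NA", call. = FALSE)
  }
  tp <- sum(truth & preds); fp <- sum(!truth & preds)
  tn <- sum(!truth & !preds); fn <- sum(truth & !preds)
  ratio <- function(num, den) if (den == 0L) NA_real_ else num / den
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp)
  ), class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat("Confusion metrics\n")
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  pct <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", 100 * v)
  cat("  sensitivity: ", pct(x$sensitivity),
      "   specificity: ", pct(x$specificity),
      "   PPV: ", pct(x$ppv), "\n", sep = "")
  invisible(x)
}

#' ROC curve by threshold sweep
#'
#' Sweeps the classification threshold over every distinct score value plus
#' the two limit thresholds and records (1 - specificity, sensitivity) at
#' each. Two modes:
#' * `"probability_sweep"`: predictions are `score >= t`, `t` from above the
#'   maximum down to 0; the curve ends at (1, 1).
#' * `"menthu_score_sweep"`: predictions are `score >= t AND top_dist <=
#'   dist_threshold`, with the arm-distance filter held fixed while `t` runs
#'   from infinity down to 0. Because the distance filter censors part of the
#'   positives, the curve is truncated: its endpoint sensitivity
#'   (`max_sensitivity`) can be below 1 no matter the threshold.
#'
#' The AUC is the trapezoidal area over the attainable points (anchored at
#' (0,0); no extrapolation beyond the truncation endpoint).
#'
#' @param truth Logical ground-truth labels.
#' @param score Numeric sweep scores; `Inf` allowed (ranked above every
#'   finite score), `NA` treated as never-predicted (no candidate pattern).
#' @param top_dist Arm distances of the top pattern (MENTHU mode only).
#' @param mode `"probability_sweep"` or `"menthu_score_sweep"`.
#' @param dist_threshold Fixed arm-distance filter for MENTHU mode.
#' @return A list of class `roc_curve`: `points` (data frame `threshold`,
#'   `fpr`, `sensitivity`), `auc`, `max_sensitivity`, `truncated`, `mode`.
#' @export
roc_sweep <- function(truth, score, top_dist = NULL,
                      mode = c("probability_sweep", "menthu_score_sweep"),
                      dist_threshold = 5L) {
  mode <- match.arg(mode)
  stopifnot(is.logical(truth), length(truth) == length(score))
  if (all(truth) || !any(truth)) {
    stop("ROC undefined: truth labels contain a single class", call. = FALSE)
  }
  eligible <- if (mode == "menthu_score_sweep") {
    if (is.null(top_dist)) {
      stop("`top_dist` is required for the MENTHU score sweep", call. = FALSE)
    }
    !is.na(score) & !is.na(top_dist) & top_dist <= dist_threshold
  } else {
    !is.na(score)
  }
  ths <- c(Inf, sort(unique(score[eligible & is.finite(score)]),
                     decreasing = TRUE), 0)
  ths <- unique(ths)
  pts <- vapply(ths, function(t) {
    pred <- eligible & score >= t
    m <- confusion_metrics(truth, pred)
    c(fpr = 1 - m$specificity, sens = m$sensitivity)
  }, numeric(2))
  points <- data.frame(threshold = ths, fpr = pts["fpr", ],
                       sensitivity = pts["sens", ])
  points <- points[order(points$fpr, points$sensitivity), , drop = FALSE]
  points <- points[!duplicated(points[, c("fpr", "sensitivity")]), , drop = FALSE]
  rownames(points) <- NULL
  x <- c(0, points$fpr); y <- c(0, points$sensitivity)
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  max_sens <- max(points$sensitivity)
  structure(list(
    points = points, auc = auc, max_sensitivity = max_sens,
    truncated = mode == "menthu_score_sweep" && max_sens < 1,
    mode = mode, dist_threshold = as.integer(dist_threshold)
  ), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("ROC curve (", x$mode, "), ", nrow(x$points), " points\n", sep = "")
  cat(sprintf("  AUC (trapezoid, attainable range): %.4f\n", x$auc))
  cat(sprintf("  max sensitivity: %.4f%s\n", x$max_sensitivity,
              if (x$truncated) "  [curve truncated by the distance filter]" else ""))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, add = FALSE, col = "black", ...) {
  if (!add) {
    plot(NA, xlim = c(0, 1), ylim = c(0, 1),
         xlab = "1 - specificity", ylab = "sensitivity", ...)
    graphics::abline(0, 1, lty = 3, col = "grey60")
  }
  graphics::lines(c(0, x$points$fpr), c(0, x$points$sensitivity), col = col)
  graphics::points(x$points$fpr, x$points$sensitivity, pch = 20, col = col)
  invisible(x)
}

#' Combine two boolean predictors
#'
#' `OR` labels a site positive when either predictor does (union: sensitivity
#' never below either input); `AND` requires both (intersection: specificity
#' never below either input).
#'
#' @param a,b Logical vectors of equal length.
#' @param mode `"OR"` or `"AND"`.
#' @return Logical vector.
#' @export
combine_predictions <- function(a, b, mode = c("OR", "AND")) {
  mode <- match.arg(mode)
  stopifnot(is.logical(a), is.logical(b))
  if (length(a) != length(b)) {
    stop("prediction vectors must have equal length", call. = FALSE)
  }
  if (mode == "OR") a | b else a & b
}

#' Stratified train/test split
#'
#' Splits indices into train and test sets of sizes rounding to
#' `train_frac`, drawing within each class so the positive:negative ratio is
#' preserved up to rounding. Deterministic given `seed`; the caller's RNG
#' stream is untouched.
#'
#' @param labels Logical class labels; both classes must be present.
#' @param train_frac Training fraction (default 0.7).
#' @param seed Integer seed.
#' @return List with sorted integer index vectors `train` and `test`.
#' @examples
#' stratified_split(rep(c(TRUE, FALSE), c(10, 90)), 0.7, seed = 1)
#' @export
stratified_split <- function(labels, train_frac = 0.7, seed) {
  stopifnot(is.logical(labels), !anyNA(labels))
  if (all(labels) || !any(labels)) {
    stop("stratified split needs both classes present", call. = FALSE)
  }
  if (!is.numeric(train_frac) || train_frac <= 0 || train_frac >= 1) {
    stop("`train_frac` must be in (0, 1)", call. = FALSE)
  }
  .with_seed(seed, {
    train <- integer(0)
    for (cls in c(TRUE, FALSE)) {
      idx <- which(labels == cls)
      n_tr <- round(length(idx) * train_frac)
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

#' Default hyperparameter grid for the gradient-boosting baseline
#'
#' Trees x depth x min-node x shrinkage, spanning the region where boosted
#' models of this size typically land (450 trees / depth 6 / min node 10 /
#' shrinkage 0.01 is included).
#'
#' @return A list with components `trees`, `depth`, `min_node`, `shrinkage`.
#' @export
walker_default_grid <- function() {
  list(trees = c(50L, 150L, 300L, 450L, 600L),
       depth = c(2L, 4L, 6L),
       min_node = c(5L, 10L, 20L),
       shrinkage = c(0.01, 0.1))
}

#' Fit a two-feature PreMA baseline model
#'
#' Fits either "Moon Rover" (logistic regression, `stats::glm`) or "Moon
#' Walker" (gradient boosting) on the two features the rule-based classifier
#' uses: the MENTHU score and the top-pattern arm distance. Infinite scores
#' (single-pattern sites) are capped at `score_cap` before fitting. Moon
#' Walker selects, by `cv_folds`-fold cross-validated AUC, one point of a
#' grid over the number of boosting iterations, maximum tree depth, minimum
#' observations per node (xgboost's `min_child_weight`) and shrinkage; ties
#' are broken by first-in-grid order (trees varying fastest, then depth,
#' min-node, shrinkage).
#'
#' @param train Data frame with columns `score`, `dist` and logical `prema`;
#'   at least 50 rows and both classes required.
#' @param kind `"rover"` (logistic) or `"walker"` (gradient boosting).
#' @param cv_folds CV folds for the walker grid search (default 10).
#' @param grid Hyperparameter grid as from [walker_default_grid()].
#' @param seed Integer seed controlling CV folds and fitting.
#' @param score_cap Finite stand-in for infinite MENTHU scores (default 1e6).
#' @return A list of class `baseline_model` with the fitted model, the CV
#'   table (walker) and the selected hyperparameters.
#' @seealso [predict.baseline_model()]
#' @export
fit_baseline <- function(train, kind = c("rover", "walker"), cv_folds = 10L,
                         grid = walker_default_grid(), seed = 1L,
                         score_cap = 1e6) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(train),
            all(c("score", "dist", "prema") %in% names(train)))
  if (nrow(train) < 50L) {
    stop("need at least 50 training events", call. = FALSE)
  }
  y <- train$prema
  if (all(y) || !any(y)) {
    stop("degenerate training set: a single class present", call. = FALSE)
  }
  df <- data.frame(score = pmin(train$score, score_cap), dist = train$dist,
                   prema = y)
  if (kind == "rover") {
    fit <- stats::glm(prema ~ score + dist, family = stats::binomial(),
                      data = df)
    return(structure(list(kind = kind, fit = fit, cv = NULL, best = NULL,
                          score_cap = score_cap, seed = seed),
                     class = "baseline_model"))
  }
  grid_df <- expand.grid(trees = grid$trees, depth = grid$depth,
                         min_node = grid$min_node, shrinkage = grid$shrinkage,
                         KEEP.OUT.ATTRS = FALSE)
  grid_df$cv_auc <- NA_real_
  X <- as.matrix(df[, c("score", "dist")])
  dm <- xgboost::xgb.DMatrix(X, label = as.numeric(df$prema))
  combos <- unique(grid_df[, c("depth", "min_node", "shrinkage")])
  for (r in seq_len(nrow(combos))) {
    cb <- combos[r, ]
    params <- list(objective = "binary:logistic", eval_metric = "auc",
                   max_depth = cb$depth, min_child_weight = cb$min_node,
                   eta = cb$shrinkage, nthread = 1)
    log <- .with_seed(seed, {
      cv <- xgboost::xgb.cv(params = params, data = dm,
                            nrounds = max(grid$trees), nfold = cv_folds,
                            verbose = 0, stratified = TRUE)
      cv$evaluation_log
    })
    sel <- grid_df$depth == cb$depth & grid_df$min_node == cb$min_node &
      grid_df$shrinkage == cb$shrinkage
    grid_df$cv_auc[sel] <- log$test_auc_mean[grid_df$trees[sel]]
  }
  best <- grid_df[which.max(grid_df$cv_auc), , drop = FALSE]
  fit <- .with_seed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic", eval_metric = "auc",
                  max_depth = best$depth, min_child_weight = best$min_node,
                  eta = best$shrinkage, nthread = 1),
    data = dm, nrounds = best$trees, verbose = 0
  ))
  structure(list(kind = kind, fit = fit, cv = grid_df, best = best,
                 score_cap = score_cap, seed = seed),
            class = "baseline_model")
}

#' Predict from a fitted baseline model
#'
#' @param object A `baseline_model`.
#' @param newdata Data frame with columns `score` and `dist`.
#' @param type `"prob"` for PreMA probabilities, `"class"` for thresholded
#'   logical calls.
#' @param threshold Probability cutoff for `type = "class"` (default 0.5).
#' @param ... Unused.
#' @return Numeric probabilities or logical calls.
#' @export
predict.baseline_model <- function(object, newdata,
                                   type = c("prob", "class"),
                                   threshold = 0.5, ...) {
  type <- match.arg(type)
  stopifnot(all(c("score", "dist") %in% names(newdata)))
  nd <- data.frame(score = pmin(newdata$score, object$score_cap),
                   dist = newdata$dist)
  p <- if (object$kind == "rover") {
    as.numeric(stats::predict(object$fit, newdata = nd, type = "response"))
  } else {
    as.numeric(stats::predict(
      object$fit, xgboost::xgb.DMatrix(as.matrix(nd[, c("score", "dist")]))))
  }
  if (type == "prob") p else p >= threshold
}

#' @export
print.baseline_model <- function(x, ...) {
  cat("Baseline PreMA model: ",
      if (x$kind == "rover") "Moon Rover (logistic regression)"
      else "Moon Walker (gradient boosting)", "\n", sep = "")
  if (x$kind == "walker") {
    cat(sprintf("  selected: %d trees, depth %d, min node %d, shrinkage %g (CV AUC %.4f)\n",
                x$best$trees, x$best$depth, x$best$min_node, x$best$shrinkage,
                x$best$cv_auc))
  }
  invisible(x)
}
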