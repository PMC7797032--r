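test_that("confusion metrics reproduce hand-computed ratios", {
  # 614 positives, 282 found: the sensitivity that prints as 46%
  truth <- rep(c(TRUE, FALSE), c(614, 386))
  preds <- rep(c(TRUE, FALSE, FALSE), c(282, 332, 386))
  m <- confusion_metrics(truth, preds)
  expect_equal(m$sensitivity, 282 / 614)
  expect_equal(round(100 * m$sensitivity), 46)

  m2 <- confusion_metrics(rep(c(TRUE, FALSE), c(10, 90)),
                          rep(c(TRUE, FALSE, TRUE, FALSE), c(8, 2, 2, 88)))
  expect_equal(m2$sensitivity, 0.8)
  expect_equal(m2$specificity, 88 / 90)
  expect_equal(m2$ppv, 0.8)

  all_right <- confusion_metrics(truth, truth)
  expect_equal(all_right$sensitivity, 1)
  expect_equal(all_right$specificity, 1)
  expect_equal(all_right$ppv, 1)
})

test_that("0/0 ratios are undefined rather than zero", {
  m <- confusion_metrics(c(TRUE, TRUE, FALSE), c(FALSE, FALSE, FALSE))
  expect_true(is.na(m$ppv))
  expect_equal(m$sensitivity, 0)
  expect_error(confusion_metrics(c(TRUE), c(TRUE, FALSE)), "equal length")
})

test_that("ROC sweeps hit the analytic endpoints", {
  set.seed(61)
  n <- 400
  truth <- runif(n) < 0.3
  sep <- ifelse(truth, 2, 0) + runif(n)
  expect_equal(roc_sweep(truth, sep, mode = "probability_sweep")$auc, 1)
  expect_error(roc_sweep(rep(TRUE, 10), runif(10)), "single class")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(62)
  truth <- runif(300) < 0.25
  sc <- rexp(300) + truth * 0.7
  a1 <- roc_sweep(truth, sc, mode = "probability_sweep")$auc
  a2 <- roc_sweep(truth, log1p(sc), mode = "probability_sweep")$auc
  expect_equal(a1, a2)
})

test_that("trapezoidal AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(63)
  truth <- runif(500) < 0.3
  sc <- runif(500) + truth * 0.4
  ours <- roc_sweep(truth, sc, mode = "probability_sweep")$auc
  ref <- as.numeric(pROC::auc(pROC::roc(truth, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("the fixed distance filter truncates the attainable sensitivity", {
  # 20% of true positives carry an arm distance beyond the filter
  truth <- rep(c(TRUE, FALSE), c(500, 1500))
  dist <- c(rep(c(7L, 2L), c(100, 400)), rep(3L, 1500))
  score <- c(runif(500, 1, 3), runif(1500, 1, 3))
  r <- roc_sweep(truth, score, top_dist = dist, mode = "menthu_score_sweep")
  expect_equal(r$max_sensitivity, 0.8)
  expect_true(r$truncated)
  # infinite scores rank above every finite threshold
  score[1] <- Inf
  r2 <- roc_sweep(truth, score, top_dist = dist, mode = "menthu_score_sweep")
  expect_equal(max(r2$points$sensitivity), 0.8)
})

test_that("AND/OR combination obeys its set-algebra guarantees", {
  expect_true(combine_predictions(TRUE, FALSE, "OR"))
  expect_false(combine_predictions(TRUE, FALSE, "AND"))
  expect_error(combine_predictions(c(TRUE, FALSE), TRUE, "OR"), "equal length")
  set.seed(64)
  for (i in 1:10) {
    truth <- runif(300) < 0.3
    a <- runif(300) < 0.4
    b <- runif(300) < 0.4
    m_a <- confusion_metrics(truth, a); m_b <- confusion_metrics(truth, b)
    m_or <- confusion_metrics(truth, combine_predictions(a, b, "OR"))
    m_and <- confusion_metrics(truth, combine_predictions(a, b, "AND"))
    expect_gte(m_or$sensitivity, max(m_a$sensitivity, m_b$sensitivity))
    expect_gte(m_and$specificity, max(m_a$specificity, m_b$specificity))
  }
})

test_that("stratified splits keep sizes and class balance deterministically", {
  lab <- rep(c(TRUE, FALSE), c(10, 90))
  sp <- stratified_split(lab, 0.7, seed = 3)
  expect_length(sp$train, 70L)
  expect_length(sp$test, 30L)
  expect_equal(sum(lab[sp$train]), 7L)
  expect_equal(sum(lab[sp$test]), 3L)
  # partition
  expect_setequal(c(sp$train, sp$test), seq_along(lab))
  expect_length(intersect(sp$train, sp$test), 0L)
  # the published corpus size splits 70-30 into 4120 / 1765
  big <- rep(c(TRUE, FALSE), c(614, 5271))
  sp2 <- stratified_split(big, 0.7, seed = 1)
  expect_length(sp2$train, 4120L)
  expect_length(sp2$test, 1765L)
  # determinism and seed sensitivity
  expect_identical(sp, stratified_split(lab, 0.7, seed = 3))
  expect_false(identical(sp$train, stratified_split(lab, 0.7, seed = 4)$train))
  expect_error(stratified_split(rep(TRUE, 10), 0.7, seed = 1), "both classes")
})

test_that("baseline fitting validates its inputs and exposes the paper-scale grid point", {
  g <- walker_default_grid()
  gd <- expand.grid(trees = g$trees, depth = g$depth, min_node = g$min_node,
                    shrinkage = g$shrinkage)
  expect_true(any(gd$trees == 450 & gd$depth == 6 & gd$min_node == 10 &
                  gd$shrinkage == 0.01))
  df <- data.frame(score = runif(60, 1, 3), dist = sample(0:8, 60, TRUE))
  df$prema <- TRUE
  expect_error(fit_baseline(df, "rover"), "single class")
  expect_error(fit_baseline(df[1:20, ], "rover"), "50")
})

test_that("both baselines learn the two-threshold rule from its own features", {
  df <- make_rule_corpus(600, seed = 71)
  sp <- stratified_split(df$prema, 0.7, seed = 71)
  tr <- df[sp$train, ]; te <- df[sp$test, ]
  rover <- suppressWarnings(fit_baseline(tr, "rover", seed = 71))
  p_r <- predict(rover, te, type = "prob")
  expect_gt(roc_sweep(te$prema, p_r, mode = "probability_sweep")$auc, 0.9)
  grid <- list(trees = c(100L, 300L), depth = c(2L, 4L), min_node = 10L,
               shrinkage = 0.1)
  walker <- fit_baseline(tr, "walker", cv_folds = 5L, grid = grid, seed = 71)
  p_w <- predict(walker, te, type = "prob")
  expect_gt(roc_sweep(te$prema, p_w, mode = "probability_sweep")$auc, 0.95)
  # class predictions are the thresholded probabilities
  expect_identical(predict(walker, te, type = "class"), p_w >= 0.5)
  # deterministic given the seed
  walker2 <- fit_baseline(tr, "walker", cv_folds = 5L, grid = grid, seed = 71)
  expect_identical(walker$best$cv_auc, walker2$best$cv_auc)
  expect_identical(predict(walker2, te, type = "prob"), p_w)
})
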