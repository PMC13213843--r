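test_that("confusion counts follow the strict-threshold tie rule", {
  labels <- c(0, 0, 1, 1)
  cm <- confusion(labels, c(0.1, 0.2, 0.9, 0.8))
  expect_equal(unclass(cm), list(TN = 2L, FP = 0L, FN = 0L, TP = 2L),
               ignore_attr = TRUE)
  # all probabilities at exactly the threshold are predicted negative
  cm <- confusion(labels, rep(0.5, 4))
  expect_equal(cm$TN, 2L)
  expect_equal(cm$FN, 2L)
  expect_equal(cm$TP + cm$FP, 0L)
  expect_error(confusion(integer(0), numeric(0)), "empty")
})

test_that("a constructed 100-case set yields the reference confusion counts", {
  labels <- c(rep(0, 84), rep(1, 16))
  probs <- c(rep(0.1, 82), rep(0.9, 2),   # 82 TN, 2 FP
             rep(0.1, 2), rep(0.9, 14))   # 2 FN, 14 TP
  cm <- confusion(labels, probs)
  expect_equal(cm$TN, 82L)
  expect_equal(cm$FP, 2L)
  expect_equal(cm$FN, 2L)
  expect_equal(cm$TP, 14L)
})

test_that("metric arithmetic is exact and flags undefined denominators", {
  m <- metrics_from_confusion(list(TN = 82, FP = 2, FN = 2, TP = 14))
  expect_equal(m$accuracy, 0.960)
  expect_equal(m$sensitivity, 0.875)
  expect_equal(m$specificity, 82 / 84)
  expect_equal(m$precision, 0.875)
  expect_equal(m$f1, 0.875)
  expect_equal(m$false_negative_rate, 0.125)
  expect_equal(m$false_positive_rate, 2 / 84)

  perfect <- metrics_from_confusion(list(TN = 1, FP = 0, FN = 0, TP = 1))
  for (nm in setdiff(names(perfect), "auc")) expect_equal(perfect[[nm]],
    if (grepl("rate", nm)) 0 else 1)

  w <- capture_warnings(
    m0 <- metrics_from_confusion(list(TN = 5, FP = 0, FN = 0, TP = 0))
  )
  expect_match(w, "undefined", all = TRUE)
  expect_true(is.na(m0$sensitivity))
  expect_true(is.na(m0$precision))
  expect_false(is.na(m0$accuracy))
})

test_that("accuracy decomposes into prevalence-weighted sensitivity and specificity", {
  set.seed(12)
  for (rep in 1:10) {
    cm <- list(TN = sample(1:50, 1), FP = sample(1:20, 1),
               FN = sample(1:20, 1), TP = sample(1:50, 1))
    m <- metrics_from_confusion(cm)
    prev <- (cm$TP + cm$FN) / (cm$TN + cm$FP + cm$FN + cm$TP)
    expect_equal(m$accuracy,
                 m$sensitivity * prev + m$specificity * (1 - prev))
  }
})

test_that("AUC equals the exhaustive pairwise concordance oracle", {
  expect_equal(roc_auc(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1.0)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.4, 4)), 0.5)
  set.seed(14)
  for (rep in 1:15) {
    n <- sample(10:50, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), 2) # rounding forces ties
    expect_equal(roc_auc(labels, scores), auc_oracle(labels, scores),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(rep(1, 5), runif(5)), "both classes")
})

test_that("AUC agrees with pROC on a random instance", {
  set.seed(15)
  labels <- rbinom(200, 1, 0.3)
  scores <- runif(200) + 0.5 * labels
  expect_equal(roc_auc(labels, scores),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("cross-validation fold summaries use the sample mean, SD and normal CI", {
  acc <- c(91.5, 86.8, 89.0, 88.4, 90.3)
  s <- summarize_cv_metric(acc)
  expect_equal(s$mean, 89.2)
  expect_equal(s$sd, sd(acc))
  expect_equal(s$ci_upper - s$mean, 1.96 * sd(acc) / sqrt(5))
  sens <- c(86.1, 80.0, 85.2, 82.1, 88.0)
  expect_equal(round(summarize_cv_metric(sens)$mean, 1), 84.3)
  same <- summarize_cv_metric(rep(88, 5))
  expect_equal(same$sd, 0)
  expect_equal(same$ci_lower, 88)
})

test_that("stratified folds are disjoint, exhaustive, and class-balanced within one", {
  set.seed(16)
  y <- rbinom(233, 1, 0.2)
  fold <- stratified_folds(y, k = 5, seed = 16)
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(length(fold), 233)
  counts <- table(fold, y)
  for (cl in colnames(counts)) {
    expect_lte(diff(range(counts[, cl])), 1)
  }
  expect_error(stratified_folds(c(rep(0, 20), 1, 1), k = 5), "at least k")
})

test_that("cross-validation trains a fresh model per fold and aggregates metrics", {
  fx <- trained_fixture()
  X <- rbind(fx$X_train, fx$X_test)
  y <- c(fx$y_train, fx$y_test)
  cfg <- training_config(max_epochs = 6, seed = 19)
  # under-trained fold models may predict no positives; undefined precision
  # warnings are expected there
  cv <- suppressWarnings(
    cross_validate(X, y, k = 5, config = cfg, seed = 19, n_rules = 4)
  )
  expect_equal(nrow(cv$folds), 5)
  expect_equal(cv$summary$mean[cv$summary$metric == "accuracy"],
               mean(cv$folds$accuracy))
  expect_true(all(cv$folds$auc >= 0 & cv$folds$auc <= 1))
})

test_that("perturbation importance isolates a single-feature model exactly", {
  model <- single_feature_model()
  set.seed(22)
  X <- matrix(runif(60 * 11), 60, 11, dimnames = list(NULL, feature_names()))
  y <- as.integer(X[, 1] > 0.5)
  imp <- perturbation_importance(model, X, y)
  expect_equal(imp$feature[1], "cognitive")
  expect_equal(imp$rank[1], 1)
  expect_true(all(imp$importance[-1] == 0))
  expect_gt(imp$importance[1], 0)

  # duplicating the evaluation set leaves importances unchanged
  imp2 <- perturbation_importance(model, rbind(X, X), c(y, y))
  expect_equal(imp2$importance, imp$importance)

  expect_setequal(imp$feature, feature_names())
  expect_equal(sort(imp$rank), 1:11)
})

test_that("importance tiers follow the documented cutoffs", {
  expect_equal(importance_tier(c(0.0055, 0.0031, 0.0016, 0.0004)),
               c("Dominant", "High", "Moderate", "Low"))
  expect_equal(importance_tier(c(0.005, 0.0025, 0.001)),
               c("Dominant", "High", "Moderate"))
})
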