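#' Confusion counts at a decision threshold
#'
#' A case is predicted positive iff its probability is strictly greater than
#' the threshold; ties at exactly the threshold are predicted negative.
#'
#' @param labels 0/1 true labels.
#' @param probs Predicted probabilities (or scores), same length.
#' @param threshold Decision threshold (default 0.5).
#' @return An object of class \code{confusion_counts}: list with \code{TN},
#'   \code{FP}, \code{FN}, \code{TP}.
#' @export
confusion <- function(labels, probs, threshold = 0.5) {
  if (length(labels) == 0) stop("confusion: empty input")
  if (length(labels) != length(probs)) {
    stop("confusion: labels and probs must have equal length")
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("confusion: labels must be binary")
  pred <- as.integer(probs > threshold)
  structure(list(
    TN = sum(pred == 0L & labels == 0L),
    FP = sum(pred == 1L & labels == 0L),
    FN = sum(pred == 0L & labels == 1L),
    TP = sum(pred == 1L & labels == 1L)
  ), class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity (recall), specificity, precision (PPV), F1,
#' false-negative rate and false-positive rate. A metric whose denominator
#' is zero is returned as \code{NA} with a warning rather than silently 0.
#'
#' @param counts A \code{confusion_counts}, or a list with elements TN, FP,
#'   FN, TP.
#' @return An object of class \code{metric_set}: named list of proportions,
#'   with \code{auc} unset (\code{NA}) until filled by \code{\link{roc_auc}}.
#' @export
metrics_from_confusion <- function(counts) {
  TN <- counts$TN; FP <- counts$FP; FN <- counts$FN; TP <- counts$TP
  if (any(c(TN, FP, FN, TP) < 0) || TN + FP + FN + TP == 0) {
    stop("metrics_from_confusion: counts must be nonnegative with positive total")
  }
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning("metrics_from_confusion: ", what, " undefined (zero denominator)")
      return(NA_real_)
    }
    num / den
  }
  total <- TN + FP + FN + TP
  sens <- safe_div(TP, TP + FN, "sensitivity")
  spec <- safe_div(TN, TN + FP, "specificity")
  prec <- safe_div(TP, TP + FP, "precision")
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) {
    NA_real_
  } else {
    2 * prec * sens / (prec + sens)
  }
  structure(list(
    accuracy = (TN + TP) / total,
    sensitivity = sens,
    specificity = spec,
    precision = prec,
    f1 = f1,
    false_negative_rate = if (is.na(sens)) NA_real_ else 1 - sens,
    false_positive_rate = if (is.na(spec)) NA_real_ else 1 - spec,
    auc = NA_real_
  ), class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  for (nm in names(x)) {
    if (!is.na(x[[nm]])) cat(sprintf("  %-20s %.4f\n", nm, x[[nm]]))
  }
  invisible(x)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance probability using mid-ranks, so
#' tied scores between a positive and a negative case count one half. This
#' equals the trapezoidal area under the ROC curve traced over all distinct
#' score thresholds.
#'
#' @param labels 0/1 true labels.
#' @param scores Predicted scores; higher means more positive.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) {
    stop("roc_auc: undefined - both classes must be present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified k-fold assignment
#'
#' Assigns each case to one of k folds so that every fold's class counts are
#' within one of proportional.
#'
#' @param y 0/1 labels.
#' @param k Number of folds.
#' @param seed Seed for the within-class shuffle.
#' @return Integer fold index per case, in 1..k.
#' @export
stratified_folds <- function(y, k = 5, seed = 1L) {
  y <- as.integer(y)
  if (any(table(y) < k)) {
    stop("stratified_folds: each class needs at least k members")
  }
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Summary statistics of a cross-validated metric
#'
#' Mean, sample SD, and normal-approximation 95% confidence interval
#' (mean +/- 1.96 * SD / sqrt(k)) of per-fold metric values.
#'
#' @param values Numeric vector of per-fold values.
#' @return List with \code{mean}, \code{sd}, \code{ci_lower}, \code{ci_upper}.
#' @export
summarize_cv_metric <- function(values) {
  m <- mean(values)
  s <- stats::sd(values)
  half <- 1.96 * s / sqrt(length(values))
  list(mean = m, sd = s, ci_lower = m - half, ci_upper = m + half)
}

#' Stratified k-fold cross-validation of the ANFIS
#'
#' Each fold trains a fresh model on the other k-1 folds and is evaluated on
#' itself: confusion-matrix metrics at threshold 0.5 plus AUC. Fold summary
#' statistics use the sample SD over folds and the normal-approximation 95%
#' CI mean +/- 1.96 * SD / sqrt(k).
#'
#' @param X Normalized feature matrix.
#' @param y 0/1 labels.
#' @param k Number of folds (default 5).
#' @param config \code{\link{training_config}} used for every fold.
#' @param seed Seed for the fold assignment.
#' @param n_rules Rules per model.
#' @return An object of class \code{cv_result}: list with \code{folds}
#'   (data.frame, one row per fold) and \code{summary} (data.frame with
#'   mean/sd/ci per metric).
#' @export
cross_validate <- function(X, y, k = 5, config = training_config(),
                           seed = 1L, n_rules = 8) {
  X <- if (is.data.frame(X)) as.matrix(X) else X
  y <- as.integer(y)
  fold <- stratified_folds(y, k, seed)
  metric_names <- c("accuracy", "sensitivity", "specificity", "precision",
                    "f1", "auc")
  rows <- lapply(seq_len(k), function(i) {
    tr <- fold != i
    if (length(unique(y[!tr])) < 2) {
      stop("cross_validate: fold ", i, " contains a single class")
    }
    cfg <- config
    cfg$seed <- config$seed + i
    fit <- anfis_train(X[tr, , drop = FALSE], y[tr], cfg, n_rules = n_rules)
    p <- predict(fit$model, X[!tr, , drop = FALSE])
    m <- metrics_from_confusion(confusion(y[!tr], p))
    m$auc <- roc_auc(y[!tr], p)
    data.frame(fold = i, as.data.frame(m[metric_names]))
  })
  folds <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(metric_names, function(nm) {
    s <- summarize_cv_metric(folds[[nm]])
    data.frame(metric = nm, mean = s$mean, sd = s$sd,
               ci_lower = s$ci_lower, ci_upper = s$ci_upper,
               stringsAsFactors = FALSE)
  }))
  structure(list(folds = folds, summary = summ, k = k), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold stratified cross-validation\n", x$k))
  print(x$folds, digits = 4, row.names = FALSE)
  print(x$summary, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Importance tier from a contribution score
#' @param score Accuracy-difference contribution score.
#' @return "Dominant", "High", "Moderate" or "Low".
#' @export
importance_tier <- function(score) {
  ifelse(score >= 0.005, "Dominant",
         ifelse(score >= 0.0025, "High",
                ifelse(score >= 0.001, "Moderate", "Low")))
}

#' Perturbation-based feature importance
#'
#' For each feature, the column is set to zero on the normalized scale (the
#' observed minimum under min-max scaling), the evaluation accuracy is
#' recomputed with the model held fixed, and the importance is the drop from
#' baseline accuracy. Tiers: Dominant >= 0.005, High >= 0.0025,
#' Moderate >= 0.001, else Low.
#'
#' @param model A trained \code{anfis_model}.
#' @param X Normalized feature matrix of the evaluation set.
#' @param y 0/1 labels.
#' @param threshold Decision threshold (default 0.5).
#' @return An object of class \code{importance_table}: data.frame with
#'   \code{feature}, \code{importance}, \code{rank}, \code{tier}, ordered by
#'   rank; attribute \code{baseline_accuracy}.
#' @export
perturbation_importance <- function(model, X, y, threshold = 0.5) {
  stopifnot(inherits(model, "anfis_model"))
  X <- if (is.data.frame(X)) as.matrix(X) else X
  if (nrow(X) == 0) stop("perturbation_importance: empty evaluation set")
  y <- as.integer(y)
  acc <- function(M) mean((predict(model, M) > threshold) == (y == 1L))
  baseline <- acc(X)
  imp <- vapply(seq_len(ncol(X)), function(i) {
    Xp <- X
    Xp[, i] <- 0
    baseline - acc(Xp)
  }, numeric(1))
  nms <- colnames(X)
  if (is.null(nms)) nms <- paste0("feature_", seq_len(ncol(X)))
  out <- data.frame(feature = nms, importance = imp,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$tier <- importance_tier(out$importance)
  rownames(out) <- NULL
  attr(out, "baseline_accuracy") <- baseline
  class(out) <- c("importance_table", "data.frame")
  out
}
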