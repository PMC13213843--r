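#' Confidence of a prediction
#'
#' Distance of the predicted probability from the 0.5 decision threshold,
#' normalized to [0, 1]: \code{|p - 0.5| / 0.5}. A probability at the
#' threshold has confidence 0; probabilities of 0 or 1 have confidence 1.
#'
#' @param p Predicted probability in [0, 1].
#' @return Confidence in [0, 1].
#' @export
confidence <- function(p) {
  if (any(p < 0 | p > 1)) stop("confidence: probability must lie in [0, 1]")
  abs(p - 0.5) / 0.5
}

#' Confidence tier
#'
#' Stratifies a confidence value for clinician-facing reporting: Low for
#' confidence <= 0.5, Medium for (0.5, 0.8], High for > 0.8. The boundary
#' value 0.8 belongs to Medium.
#'
#' @param conf Confidence in [0, 1].
#' @return "Low", "Medium" or "High".
#' @export
confidence_tier <- function(conf) {
  if (any(conf < 0 | conf > 1)) stop("confidence_tier: confidence must lie in [0, 1]")
  ifelse(conf <= 0.5, "Low", ifelse(conf <= 0.8, "Medium", "High"))
}

#' Linguistic membership label of a raw domain score
#'
#' Normalizes the raw score with the fitted scaler, evaluates the three
#' Gaussian membership functions of the feature, and returns the label of
#' the largest membership. When the top two memberships are within
#' \code{blend_gap} of each other, a blended label joining the two in
#' ascending center order is returned (e.g. "Medium-High").
#'
#' @param raw_score Raw score on the 0-100 scale.
#' @param model A trained \code{anfis_model}.
#' @param feature Feature name or column index.
#' @param scaler Fitted \code{scaler_params} covering the feature.
#' @param blend_gap Membership gap below which the top two labels blend
#'   (default 0.15).
#' @return Character label.
#' @export
mf_label <- function(raw_score, model, feature, scaler, blend_gap = 0.15) {
  stopifnot(inherits(model, "anfis_model"))
  if (is.character(feature)) {
    i <- match(feature, model$feature_names)
    if (is.na(i)) stop("mf_label: unknown feature: ", feature)
  } else {
    i <- feature
  }
  nm <- if (is.character(feature)) feature else model$feature_names[i]
  x <- (raw_score - scaler$min[nm]) / (scaler$max[nm] - scaler$min[nm])
  x <- min(max(x, 0), 1)
  mu <- gaussian_membership(x, model$centers[, i], model$widths[, i])
  labels <- c("Low", "Medium", "High")
  ord <- order(-mu)
  if (mu[ord[1]] - mu[ord[2]] < blend_gap) {
    pair <- sort(ord[1:2])
    paste(labels[pair], collapse = "-")
  } else {
    labels[ord[1]]
  }
}

recommendation_templates <- function() {
  list(
    "No diagnosis" = c(
      High = "Continue routine monitoring",
      Medium = "Continue routine monitoring; re-assess at the next scheduled visit",
      Low = "Refer for clinical review; prediction lies near the decision threshold"
    ),
    "Diagnosis" = c(
      High = "Refer for comprehensive multidisciplinary developmental evaluation",
      Medium = "Refer for comprehensive evaluation; corroborate with clinical judgement",
      Low = "Refer for clinical review; prediction lies near the decision threshold"
    )
  )
}

#' Generate an interpretable clinical report for one child
#'
#' Builds the engineered feature vector for the record, runs the model, and
#' assembles the clinician-facing output: prediction (probability strictly
#' above 0.5 means diagnosis), confidence and tier, per-domain linguistic
#' membership labels, the top contributing features for this case (each of
#' the 11 normalized features zeroed in turn, ranked by absolute change in
#' the output probability), and a recommendation drawn from a fixed template
#' table keyed on (prediction, tier).
#'
#' @param record One-row cohort data.frame (raw scores).
#' @param model Trained \code{anfis_model}.
#' @param scaler \code{scaler_params} fitted on the training feature matrix.
#' @param weights Composite-risk weights used in feature construction.
#' @param n_top Number of contributing features to list (default 3).
#' @return An object of class \code{clinical_report}.
#' @export
generate_report <- function(record, model, scaler,
                            weights = composite_risk_weights(), n_top = 3) {
  if (nrow(record) != 1) stop("generate_report: exactly one record expected")
  raw <- build_feature_matrix(record, weights = weights)
  X <- build_feature_matrix(record, weights = weights, scaler = scaler)
  p <- as.numeric(predict(model, X))
  pred <- if (p > 0.5) "Diagnosis" else "No diagnosis"
  conf <- confidence(p)
  tier <- confidence_tier(conf)

  # per-case contribution: zero each normalized feature, rank by |delta p|
  deltas <- vapply(seq_len(ncol(X)), function(i) {
    Xp <- X
    Xp[, i] <- 0
    abs(p - as.numeric(predict(model, Xp)))
  }, numeric(1))
  ord <- order(-deltas)
  top <- data.frame(feature = colnames(X)[ord[seq_len(n_top)]],
                    delta_probability = deltas[ord[seq_len(n_top)]],
                    stringsAsFactors = FALSE)

  domain_features <- c(cognitive = "cognitive", behavioral = "behavioral",
                       motor = "motor", social = "social")
  domain_cols <- c(cognitive = "cognitive_score", behavioral = "behavioral_score",
                   motor = "motor_skills", social = "social_interaction")
  domain_labels <- vapply(names(domain_features), function(d) {
    mf_label(record[[domain_cols[[d]]]], model, domain_features[[d]], scaler)
  }, character(1))

  rec_text <- recommendation_templates()[[pred]][[tier]]
  structure(list(
    prediction = pred,
    probability = p,
    confidence = conf,
    confidence_tier = tier,
    domain_labels = domain_labels,
    top_features = top,
    features_raw = raw[1, ],
    recommendation = rec_text
  ), class = "clinical_report")
}

#' @export
print.clinical_report <- function(x, ...) {
  cat("Clinical screening report\n")
  cat(sprintf("  Prediction:  %s (p = %.3f)\n", x$prediction, x$probability))
  cat(sprintf("  Confidence:  %.1f%% (%s)\n", 100 * x$confidence, x$confidence_tier))
  cat("  Domain membership:\n")
  for (d in names(x$domain_labels)) {
    cat(sprintf("    %-12s %s\n", d, x$domain_labels[[d]]))
  }
  cat(sprintf("  Cognitive-social ratio: %.2f; composite risk: %.2f\n",
              x$features_raw[["cognitive_social_ratio"]],
              x$features_raw[["composite_risk"]]))
  cat("  Top contributing features:\n")
  for (i in seq_len(nrow(x$top_features))) {
    cat(sprintf("    %d. %s (|delta p| = %.4f)\n", i,
                x$top_features$feature[i], x$top_features$delta_probability[i]))
  }
  cat(sprintf("  Recommendation: %s\n", x$recommendation))
  invisible(x)
}
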