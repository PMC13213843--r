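#' Names and order of the 11 engineered model features
#'
#' The feature order is fixed and versioned: perturbation-importance indices
#' and serialized models reference it. Four raw domain scores, four
#' age-adjusted ratios, two cross-domain ratios, and the weighted composite
#' risk score.
#'
#' @return Character vector of length 11.
#' @export
feature_names <- function() {
  c("cognitive", "behavioral", "motor", "social",
    "cognitive_age_ratio", "behavioral_age_ratio",
    "motor_age_ratio", "social_age_ratio",
    "cognitive_social_ratio", "motor_behavioral_ratio",
    "composite_risk")
}

#' Age-adjusted domain ratio
#'
#' Divides a domain score by chronological age, giving a crude normalization
#' of the score relative to an age-expected trajectory.
#'
#' @param score Domain score (0-100 scale).
#' @param age Age in years; must be >= 1 (cohort ages start at 1, and the
#'   guard keeps the ratio bounded).
#' @return Score per year.
#' @export
age_adjusted_ratio <- function(score, age) {
  if (any(age < 1)) stop("age_adjusted_ratio: age must be >= 1")
  score / age
}

#' Cognitive-to-social cross-domain ratio
#'
#' Cognitive score divided by (social score + 1); the +1 keeps the ratio
#' finite when the social score is 0. A value near 1 indicates balanced
#' cognitive-social development.
#'
#' @param cognitive,social Domain scores, >= 0.
#' @return Dimensionless ratio.
#' @export
cognitive_social_ratio <- function(cognitive, social) {
  if (any(cognitive < 0) || any(social < 0)) {
    stop("cognitive_social_ratio: scores must be >= 0")
  }
  cognitive / (social + 1)
}

#' Motor-to-behavioral cross-domain ratio
#'
#' Motor skills score divided by (behavioral score + 1).
#'
#' @param motor,behavioral Domain scores, >= 0.
#' @return Dimensionless ratio.
#' @export
motor_behavioral_ratio <- function(motor, behavioral) {
  if (any(motor < 0) || any(behavioral < 0)) {
    stop("motor_behavioral_ratio: scores must be >= 0")
  }
  motor / (behavioral + 1)
}

#' Composite risk weights
#'
#' Domain weights for the composite risk score (cognitive and social 0.3
#' each, behavioral and motor 0.2 each; they sum to 1) and the multiplicative
#' family-history factor applied when history is positive.
#'
#' @param w_cognitive,w_behavioral,w_motor,w_social Domain weights.
#' @param fh_multiplier_positive Multiplier applied for a positive family
#'   history (>= 1); negative history multiplies by 1.
#' @return An object of class \code{composite_risk_weights}.
#' @export
composite_risk_weights <- function(w_cognitive = 0.3, w_behavioral = 0.2,
                                   w_motor = 0.2, w_social = 0.3,
                                   fh_multiplier_positive = 1.25) {
  w <- c(w_cognitive, w_behavioral, w_motor, w_social)
  if (abs(sum(w) - 1) > 1e-9) {
    stop("composite_risk_weights: domain weights must sum to 1")
  }
  if (fh_multiplier_positive < 1) {
    stop("composite_risk_weights: positive-history multiplier must be >= 1")
  }
  structure(list(w_cognitive = w_cognitive, w_behavioral = w_behavioral,
                 w_motor = w_motor, w_social = w_social,
                 fh_multiplier_positive = fh_multiplier_positive,
                 fh_multiplier_negative = 1.0),
            class = "composite_risk_weights")
}

#' Weighted composite risk score
#'
#' Combines inverted domain scores (100 - score, so higher means greater
#' risk) with weights 0.3/0.2/0.2/0.3 for cognitive/behavioral/motor/social,
#' then multiplies by the family-history factor when history is positive.
#' With multiplier 1 the score lies in [0, 100] and decreases strictly in
#' every domain score.
#'
#' @param cognitive,behavioral,motor,social Domain scores in [0, 100].
#' @param family_history 0/1 indicator.
#' @param weights A \code{\link{composite_risk_weights}}.
#' @return Risk score (0-100 scale before the family-history multiplier).
#' @export
composite_risk <- function(cognitive, behavioral, motor, social,
                           family_history = 0,
                           weights = composite_risk_weights()) {
  scores <- c(cognitive, behavioral, motor, social)
  if (any(scores < 0 | scores > 100)) {
    stop("composite_risk: scores must lie in [0, 100]")
  }
  base <- weights$w_cognitive * (100 - cognitive) +
    weights$w_behavioral * (100 - behavioral) +
    weights$w_motor * (100 - motor) +
    weights$w_social * (100 - social)
  mult <- ifelse(family_history > 0, weights$fh_multiplier_positive,
                 weights$fh_multiplier_negative)
  base * mult
}

#' Build the 11-column engineered feature matrix
#'
#' Computes, on the raw 0-100 score scale, the four domain columns, the four
#' age-adjusted ratios, the two cross-domain ratios, and the composite risk
#' score, in the fixed order of \code{\link{feature_names}}. If a fitted
#' scaler is supplied the 11 columns are min-max normalized with it (fit the
#' scaler on the training rows only); with \code{scaler = NULL} the raw
#' matrix is returned, e.g. to fit a scaler on it.
#'
#' @param records Cohort data.frame (complete, after preprocessing).
#' @param weights Composite-risk weights.
#' @param scaler Optional \code{scaler_params} fitted on a feature matrix.
#' @return Numeric matrix, one row per record, 11 named columns.
#' @export
build_feature_matrix <- function(records, weights = composite_risk_weights(),
                                 scaler = NULL) {
  needed <- c("age", "cognitive_score", "behavioral_score", "motor_skills",
              "social_interaction", "family_history")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stop("build_feature_matrix: missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  cg <- records$cognitive_score
  bh <- records$behavioral_score
  mt <- records$motor_skills
  sc <- records$social_interaction
  X <- cbind(
    cognitive = cg,
    behavioral = bh,
    motor = mt,
    social = sc,
    cognitive_age_ratio = age_adjusted_ratio(cg, records$age),
    behavioral_age_ratio = age_adjusted_ratio(bh, records$age),
    motor_age_ratio = age_adjusted_ratio(mt, records$age),
    social_age_ratio = age_adjusted_ratio(sc, records$age),
    cognitive_social_ratio = cognitive_social_ratio(cg, sc),
    motor_behavioral_ratio = motor_behavioral_ratio(mt, bh),
    composite_risk = composite_risk(cg, bh, mt, sc,
                                    records$family_history, weights)
  )
  if (anyNA(X)) stop("build_feature_matrix: missing values in engineered features")
  if (!is.null(scaler)) {
    df <- scaler_transform(as.data.frame(X), scaler)
    X <- as.matrix(df)
  }
  X
}

#' Mutual-information screening of features against a binary label
#'
#' Estimates the mutual information (in nats) between each feature and the
#' binary label by discretizing the feature into equal-width bins over its
#' observed range and applying the plug-in estimator. Features scoring above
#' the threshold are flagged as retained. Screening is advisory: the model
#' consumes all 11 features by default, and low-MI features are reported for
#' post-hoc simplification.
#'
#' @param X Feature matrix (columns named).
#' @param labels Binary labels.
#' @param threshold Retention threshold in nats (default 0.01).
#' @param bins Number of equal-width bins (default 10).
#' @return Data.frame with \code{feature}, \code{mi}, \code{retained},
#'   ordered by decreasing MI.
#' @export
mutual_information_screen <- function(X, labels, threshold = 0.01, bins = 10) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("mutual_information_screen: undefined - labels contain a single class")
  }
  mi_one <- function(v) {
    rng <- range(v)
    if (rng[1] == rng[2]) return(0) # constant feature carries no information
    brk <- seq(rng[1], rng[2], length.out = bins + 1)
    b <- cut(v, breaks = brk, include.lowest = TRUE, labels = FALSE)
    joint <- table(b, labels) / length(v)
    px <- rowSums(joint)
    py <- colSums(joint)
    nz <- joint > 0
    sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
  }
  mi <- apply(X, 2, mi_one)
  out <- data.frame(feature = colnames(X), mi = unname(mi),
                    retained = unname(mi > threshold),
                    stringsAsFactors = FALSE)
  out[order(-out$mi), , drop = FALSE]
}
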