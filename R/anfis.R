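#' Gaussian membership function
#'
#' Degree of membership of a normalized input value in a fuzzy set with
#' Gaussian shape: \code{exp(-(x - center)^2 / (2 * width^2))}. Equals 1 at
#' the center and is symmetric about it.
#'
#' @param x Normalized input value(s).
#' @param center Membership-function center.
#' @param width Membership-function width; must be > 0.
#' @return Membership degree(s) in (0, 1].
#' @export
gaussian_membership <- function(x, center, width) {
  if (any(width <= 0) || any(!is.finite(c(center, width)))) {
    stop("gaussian_membership: width must be finite and > 0")
  }
  exp(-(x - center)^2 / (2 * width^2))
}

#' Construct a Sugeno ANFIS model
#'
#' A five-layer first-order Sugeno ANFIS: Gaussian fuzzification with three
#' membership functions (Low/Medium/High) per feature, product T-norm rule
#' firing computed in log-space with an underflow floor, firing-strength
#' normalization, linear rule consequents, and a sigmoid output mapping the
#' aggregated consequent to a probability.
#'
#' Defaults give the untrained state: membership centers evenly spaced at
#' 0, 0.5, 1 on the normalized input range with width 0.25 (substantial
#' overlap), zero consequent slopes, and intercepts drawn from N(0, 0.1^2)
#' so rules do not start identical. Rule antecedents must be supplied (see
#' \code{\link{init_rules_kmeans}} and \code{\link{init_rules_random}}).
#'
#' @param n_features Number of inputs (11 for the screening feature set).
#' @param rules Integer matrix, \code{n_rules x n_features}, entries in 1:3
#'   selecting the Low/Medium/High membership function per feature.
#' @param centers,widths Optional 3 x n_features matrices of MF parameters
#'   (rows = Low/Medium/High).
#' @param coef Optional \code{n_rules x n_features} consequent slope matrix.
#' @param intercept Optional length-\code{n_rules} consequent intercepts.
#' @param feature_names Optional column names the model expects.
#' @param eps Underflow floor applied to per-feature memberships before the
#'   product (default 1e-12).
#' @param sigma_min Lower bound kept on widths during training.
#' @param init_seed Seed for the random intercept draw when \code{intercept}
#'   is not given.
#' @return An object of class \code{anfis_model}.
#' @export
anfis_model <- function(n_features, rules, centers = NULL, widths = NULL,
                        coef = NULL, intercept = NULL, feature_names = NULL,
                        eps = 1e-12, sigma_min = 0.01, init_seed = 1L) {
  rules <- as.matrix(rules)
  storage.mode(rules) <- "integer"
  n_rules <- nrow(rules)
  if (ncol(rules) != n_features || any(rules < 1L | rules > 3L)) {
    stop("anfis_model: rules must be n_rules x n_features with entries in 1:3")
  }
  if (is.null(centers)) {
    centers <- matrix(rep(c(0, 0.5, 1), n_features), nrow = 3,
                      dimnames = list(c("Low", "Medium", "High"), feature_names))
  }
  if (is.null(widths)) {
    widths <- matrix(0.25, nrow = 3, ncol = n_features,
                     dimnames = dimnames(centers))
  }
  if (is.null(coef)) coef <- matrix(0, n_rules, n_features)
  if (is.null(intercept)) {
    set.seed(init_seed)
    intercept <- stats::rnorm(n_rules, 0, 0.1)
  }
  stopifnot(nrow(centers) == 3, ncol(centers) == n_features,
            identical(dim(centers), dim(widths)),
            nrow(coef) == n_rules, ncol(coef) == n_features,
            length(intercept) == n_rules)
  if (any(widths <= 0)) stop("anfis_model: widths must be > 0")
  pars <- c(centers, widths, coef, intercept)
  if (any(!is.finite(pars))) stop("anfis_model: parameters must be finite")
  structure(list(
    centers = centers, widths = widths, rules = rules,
    coef = coef, intercept = as.numeric(intercept),
    eps = eps, sigma_min = sigma_min,
    feature_names = feature_names
  ), class = "anfis_model")
}

#' @export
print.anfis_model <- function(x, ...) {
  cat(sprintf("Sugeno ANFIS: %d features, 3 Gaussian MFs/feature, %d rules\n",
              ncol(x$centers), nrow(x$rules)))
  if (!is.null(x$feature_names)) {
    cat("  features:", paste(x$feature_names, collapse = ", "), "\n")
  }
  invisible(x)
}

# log-memberships per MF level: list of 3 (n x d) matrices, floored at log(eps)
anfis_log_memberships <- function(model, X) {
  lapply(1:3, function(j) {
    z <- sweep(X, 2, model$centers[j, ], "-")
    lm <- -sweep(z^2, 2, 2 * model$widths[j, ]^2, "/")
    pmax(lm, log(model$eps))
  })
}

#' Rule firing strengths
#'
#' Product T-norm firing strength of every rule for every input row: the
#' product over features of the membership of the input under the rule's
#' selected membership function. Computed in log-space with per-feature
#' memberships floored at the model's underflow floor \code{eps}, so an
#' 11-way product of small memberships does not underflow to zero.
#'
#' @param model An \code{anfis_model}.
#' @param X Numeric matrix of normalized inputs (rows = cases).
#' @return Matrix \code{nrow(X) x n_rules} of positive firing strengths.
#' @export
rule_firing <- function(model, X) {
  X <- as_input_matrix(model, X)
  logM <- anfis_log_memberships(model, X)
  K <- nrow(model$rules)
  d <- ncol(X)
  logW <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    s <- 0
    for (i in seq_len(d)) s <- s + logM[[model$rules[k, i]]][, i]
    logW[, k] <- s
  }
  exp(logW)
}

#' Normalize firing strengths
#'
#' Scales each rule's firing strength by the sum over rules, so the
#' normalized strengths of each case sum to 1.
#'
#' @param w Matrix (or vector) of nonnegative firing strengths, rows = cases.
#' @return Normalized firing strengths of the same shape.
#' @export
normalize_firing <- function(w) {
  if (is.vector(w)) w <- matrix(w, nrow = 1)
  if (any(w < 0)) stop("normalize_firing: firing strengths must be >= 0")
  S <- rowSums(w)
  if (any(S == 0)) {
    stop("normalize_firing: degenerate all-zero firing (underflow floor inactive?)")
  }
  w / S
}

as_input_matrix <- function(model, X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  d <- ncol(model$centers)
  if (ncol(X) != d) {
    stop("anfis: input has ", ncol(X), " columns, model expects ", d)
  }
  if (!is.null(model$feature_names) && !is.null(colnames(X))) {
    if (!identical(colnames(X), model$feature_names)) {
      X <- X[, model$feature_names, drop = FALSE]
    }
  }
  X
}

#' Forward pass through the five ANFIS layers
#'
#' Fuzzification, rule firing, normalization, linear consequents, and sigmoid
#' output. Returns the full layer trace; \code{\link{predict.anfis_model}} is
#' the plain prediction interface.
#'
#' @param model An \code{anfis_model}.
#' @param X Matrix of normalized inputs.
#' @return List with \code{prob} (output probabilities), \code{logit}
#'   (pre-sigmoid aggregate), \code{norm_firing}, \code{firing}, and
#'   \code{consequent} (per-rule linear outputs).
#' @export
anfis_forward <- function(model, X) {
  X <- as_input_matrix(model, X)
  w <- rule_firing(model, X)
  wn <- normalize_firing(w)
  f <- X %*% t(model$coef) + matrix(model$intercept, nrow(X),
                                    nrow(model$rules), byrow = TRUE)
  z <- rowSums(wn * f)
  list(prob = stats::plogis(z), logit = z, norm_firing = wn,
       firing = w, consequent = f)
}

#' Predict from a fitted ANFIS model
#'
#' @param object An \code{anfis_model}.
#' @param newdata Matrix or data.frame of normalized features.
#' @param type \code{"prob"} for probabilities (default) or \code{"class"}
#'   for 0/1 labels at the 0.5 threshold (probability strictly greater than
#'   0.5 predicts positive).
#' @param ... Unused.
#' @return Numeric vector of probabilities or integer class labels.
#' @export
predict.anfis_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- anfis_forward(object, newdata)$prob
  if (type == "class") as.integer(p > 0.5) else p
}

#' Initialize rule antecedents by k-means clustering
#'
#' Clusters the normalized training features into \code{n_rules} groups and
#' maps each centroid coordinate to the nearest initial membership-function
#' center per feature, yielding data-driven antecedents. Duplicate
#' antecedents are perturbed to the second-nearest membership function on
#' the highest-variance feature still available.
#'
#' @param X Normalized training feature matrix.
#' @param n_rules Number of rules (8 in the screening configuration).
#' @param centers 3 x n_features matrix of initial MF centers.
#' @param seed Seed for k-means.
#' @return Integer \code{n_rules x n_features} antecedent matrix.
#' @export
init_rules_kmeans <- function(X, n_rules = 8,
                              centers = matrix(rep(c(0, 0.5, 1), ncol(X)), nrow = 3),
                              seed = 1L) {
  X <- as.matrix(X)
  if (nrow(unique(X)) < n_rules) {
    stop("init_rules_kmeans: need at least n_rules distinct rows")
  }
  set.seed(seed)
  km <- stats::kmeans(X, centers = n_rules, nstart = 5, iter.max = 100)
  d <- ncol(X)
  rules <- matrix(0L, n_rules, d)
  for (i in seq_len(d)) {
    rules[, i] <- apply(abs(outer(km$centers[, i], centers[, i], "-")), 1, which.min)
  }
  # break up duplicate antecedents on high-variance features
  var_order <- order(-apply(X, 2, stats::var))
  for (k in seq_len(n_rules)) {
    tries <- 0
    while (anyDuplicated(rules)[1] == k && tries < d) {
      tries <- tries + 1
      i <- var_order[tries]
      alt <- order(abs(centers[, i] - km$centers[k, i]))[2]
      rules[k, i] <- alt
    }
  }
  if (anyDuplicated(rules) > 0) {
    rules <- dedup_rules_random(rules)
  }
  rules
}

#' Initialize rule antecedents at random
#'
#' Seeded uniform draw of membership-function indices, with duplicate rules
#' re-drawn. Fallback when too few distinct data rows exist for k-means.
#'
#' @param n_features,n_rules Dimensions of the antecedent matrix.
#' @param seed Seed.
#' @return Integer \code{n_rules x n_features} antecedent matrix.
#' @export
init_rules_random <- function(n_features, n_rules = 8, seed = 1L) {
  set.seed(seed)
  rules <- matrix(sample.int(3, n_rules * n_features, replace = TRUE),
                  n_rules, n_features)
  dedup_rules_random(rules)
}

dedup_rules_random <- function(rules) {
  for (attempt in 1:100) {
    dup <- duplicated(rules)
    if (!any(dup)) break
    rules[dup, ] <- sample.int(3, sum(dup) * ncol(rules), replace = TRUE)
  }
  rules
}
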