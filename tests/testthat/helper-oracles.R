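# Independent oracles used to freeze expected values. Each is deliberately
# naive (numerical integration, per-pair enumeration, scalar loops) and shares
# no code with the implementation under test.

# mean of normal(mean, sd) conditioned on [low, high], by numerical integration
truncnorm_mean_numeric <- function(mean, sd, low, high) {
  Z <- stats::pnorm(high, mean, sd) - stats::pnorm(low, mean, sd)
  stats::integrate(function(x) x * stats::dnorm(x, mean, sd), low, high,
                   rel.tol = 1e-10)$value / Z
}

# scalar, layer-by-layer Sugeno forward pass for one input vector
anfis_forward_oracle <- function(model, x) {
  d <- length(x)
  K <- nrow(model$rules)
  w <- numeric(K)
  for (k in seq_len(K)) {
    prodv <- 1
    for (i in seq_len(d)) {
      j <- model$rules[k, i]
      mu <- exp(-(x[i] - model$centers[j, i])^2 / (2 * model$widths[j, i]^2))
      prodv <- prodv * max(mu, model$eps)
    }
    w[k] <- prodv
  }
  wn <- w / sum(w)
  f <- as.numeric(model$coef %*% x) + model$intercept
  1 / (1 + exp(-sum(wn * f)))
}

# exhaustive pairwise Mann-Whitney concordance (ties count one half)
auc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (sp in pos) {
    for (sn in neg) {
      total <- total + (sp > sn) + 0.5 * (sp == sn)
    }
  }
  total / (length(pos) * length(neg))
}

binary_entropy_nats <- function(p) {
  -p * log(p) - (1 - p) * log(1 - p)
}

# small ANFIS with randomly perturbed parameters, for oracle comparisons
random_small_model <- function(d = 2, K = 2, seed = 1) {
  set.seed(seed)
  rules <- matrix(sample.int(3, d * K, replace = TRUE), K, d)
  m <- anfis_model(d, rules, init_seed = seed)
  m$centers <- m$centers + matrix(stats::rnorm(3 * d, 0, 0.1), 3, d)
  m$widths <- m$widths + matrix(stats::runif(3 * d, -0.05, 0.1), 3, d)
  m$coef <- matrix(stats::rnorm(K * d, 0, 0.5), K, d)
  m$intercept <- stats::rnorm(K, 0, 0.5)
  m
}

# an 11-feature model whose output depends on exactly one feature: both rules
# carry the same consequent (5 * cognitive - 2.5), so firing strengths cancel
single_feature_model <- function() {
  d <- 11
  rules <- rbind(rep(1L, d), rep(3L, d))
  coef <- matrix(0, 2, d)
  coef[, 1] <- 5
  anfis_model(d, rules, coef = coef, intercept = c(-2.5, -2.5),
              feature_names = feature_names())
}

# small trained pipeline fixture, built once per test run and cached
.fixture_env <- new.env(parent = emptyenv())
trained_fixture <- function() {
  if (is.null(.fixture_env$fit)) {
    cc <- cohort_config(n_group0 = 520, n_group1 = 120, seed = 11)
    records <- encode_sex(generate_cohort(cc))
    parts <- stratified_split(records, 0.2, seed = 11)
    w <- composite_risk_weights()
    raw <- build_feature_matrix(parts$train, w)
    scaler <- fit_scaler(as.data.frame(raw))
    X_train <- build_feature_matrix(parts$train, w, scaler)
    X_test <- build_feature_matrix(parts$test, w, scaler)
    fit <- anfis_train(X_train, parts$train$diagnosis,
                       training_config(max_epochs = 15, seed = 11))
    .fixture_env$fit <- list(
      fit = fit, model = fit$model, scaler = scaler, weights = w,
      X_train = X_train, X_test = X_test,
      y_train = parts$train$diagnosis, y_test = parts$test$diagnosis,
      train = parts$train, test = parts$test
    )
  }
  .fixture_env$fit
}

# raw assessment profile of the worked clinical case
clinical_case_record <- function(age = 4L, family_history = 0L) {
  data.frame(
    child_id = "CASE1", age = age, sex = "female",
    cognitive_score = 64.45, behavioral_score = 74.14,
    motor_skills = 68.35, social_interaction = 61.20,
    family_history = family_history, diagnosis = 0L,
    stringsAsFactors = FALSE
  )
}
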