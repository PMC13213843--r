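#' Default run configuration
#'
#' A single nested configuration driving all pipeline stages: cohort
#' generation, split, training, evaluation options, and composite-risk
#' weights. Values may be overridden by a YAML config file
#' (\code{\link{load_run_config}}) and, at the command line, by per-command
#' flags (flags take precedence over file keys).
#'
#' @param seed Master seed applied to every stage.
#' @return Nested list of stage configurations.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    cohort = list(
      n_group0 = 4311L, n_group1 = 689L,
      age_min = 1L, age_max = 6L,
      missing_rate = 0,
      group0 = unclass(default_group0()),
      group1 = unclass(default_group1())
    ),
    split = list(test_fraction = 0.20, stratify_on = "diagnosis"),
    training = list(learning_rate = 0.01, max_epochs = 100L, batch_size = 32L,
                    early_stopping_patience = 10L, validation_fraction = 0.20,
                    n_rules = 8L),
    evaluation = list(cv_folds = 5L, test_subsample = NA_integer_),
    risk_weights = list(w_cognitive = 0.3, w_behavioral = 0.2,
                        w_motor = 0.2, w_social = 0.3,
                        fh_multiplier_positive = 1.25)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file of (possibly partial) configuration keys and merges it
#' over \code{\link{default_run_config}}.
#'
#' @param path YAML file, or NULL for pure defaults.
#' @param seed Master seed (overrides any seed in the file).
#' @return Nested configuration list.
#' @export
load_run_config <- function(path = NULL, seed = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

config_cohort <- function(cfg) {
  cohort_config(
    n_group0 = cfg$cohort$n_group0, n_group1 = cfg$cohort$n_group1,
    age_min = cfg$cohort$age_min, age_max = cfg$cohort$age_max,
    group0 = do.call(group_params, cfg$cohort$group0),
    group1 = do.call(group_params, cfg$cohort$group1),
    missing_rate = cfg$cohort$missing_rate,
    seed = cfg$seed
  )
}

config_training <- function(cfg) {
  training_config(
    learning_rate = cfg$training$learning_rate,
    max_epochs = cfg$training$max_epochs,
    batch_size = cfg$training$batch_size,
    early_stopping_patience = cfg$training$early_stopping_patience,
    validation_fraction = cfg$training$validation_fraction,
    seed = cfg$seed
  )
}

config_weights <- function(cfg) {
  do.call(composite_risk_weights, cfg$risk_weights)
}

pipeline_log <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), sprintf(...))
}

#' Simulate a cohort and write it to disk
#'
#' @param cfg Run configuration (\code{\link{default_run_config}}).
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, paths of the cohort CSV and summary CSV.
#' @export
pipeline_simulate <- function(cfg = default_run_config(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- generate_cohort(config_cohort(cfg))
  cohort_path <- file.path(out_dir, "cohort.csv")
  write_cohort(records, cohort_path)
  s <- summarize_cohort(records)
  summary_path <- file.path(out_dir, "cohort_summary.csv")
  utils::write.csv(s$domains, summary_path, row.names = FALSE)
  pipeline_log("simulate: wrote %d records (prevalence %.4f) to %s",
               nrow(records), s$proportions$prevalence, cohort_path)
  invisible(list(cohort = cohort_path, summary = summary_path))
}

# shared front half of train/evaluate/crossval/importance: preprocessing +
# features + split on a cohort file
prepare_data <- function(cohort_path, cfg) {
  records <- read_cohort(cohort_path)
  records <- encode_sex(records)
  cleaned <- apply_missing_policy(records)$records
  parts <- stratified_split(cleaned, cfg$split$test_fraction,
                            cfg$split$stratify_on, seed = cfg$seed)
  weights <- config_weights(cfg)
  raw_train <- build_feature_matrix(parts$train, weights = weights)
  scaler <- fit_scaler(as.data.frame(raw_train))
  list(
    train = parts$train, test = parts$test, scaler = scaler, weights = weights,
    X_train = build_feature_matrix(parts$train, weights, scaler),
    X_test = build_feature_matrix(parts$test, weights, scaler),
    y_train = parts$train$diagnosis,
    y_test = parts$test$diagnosis
  )
}

#' Train the ANFIS on a cohort file
#'
#' Preprocesses, engineers features, fits the scaler on the training
#' partition, trains the model, and writes the model JSON and the per-epoch
#' history CSV.
#'
#' @param cohort_path Cohort CSV from \code{\link{pipeline_simulate}}.
#' @param cfg Run configuration.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the fitted model, scaler, data splits, and
#'   artifact paths.
#' @export
pipeline_train <- function(cohort_path, cfg = default_run_config(),
                           out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prep <- prepare_data(cohort_path, cfg)
  fit <- anfis_train(prep$X_train, prep$y_train, config_training(cfg),
                     n_rules = cfg$training$n_rules)
  model_path <- file.path(out_dir, "model.json")
  write_anfis(fit$model, model_path, scaler = prep$scaler)
  history_path <- file.path(out_dir, "history.csv")
  utils::write.csv(fit$history, history_path, row.names = FALSE)
  pipeline_log("train: %d epochs (best %d), model -> %s",
               nrow(fit$history), fit$best_epoch, model_path)
  invisible(c(prep, list(fit = fit, model_path = model_path,
                         history_path = history_path)))
}

#' Evaluate a trained model on the held-out test partition
#'
#' @param cohort_path Cohort CSV.
#' @param model_path Model JSON from \code{\link{pipeline_train}}.
#' @param cfg Run configuration; \code{cfg$evaluation$test_subsample}, if not
#'   NA, evaluates on a seeded stratified subsample of the test partition of
#'   that size (the study protocol used 100 held-out cases).
#' @param out_dir Output directory for \code{metrics.csv}.
#' @return Invisibly, the \code{metric_set}.
#' @export
pipeline_evaluate <- function(cohort_path, model_path,
                              cfg = default_run_config(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prep <- prepare_data(cohort_path, cfg)
  loaded <- read_anfis(model_path)
  X <- prep$X_test
  y <- prep$y_test
  nsub <- cfg$evaluation$test_subsample
  if (!is.null(nsub) && !is.na(nsub) && nsub < length(y)) {
    df <- data.frame(idx = seq_along(y), diagnosis = y)
    sub <- stratified_split(df, test_fraction = nsub / length(y),
                            seed = cfg$seed)$test
    X <- X[sub$idx, , drop = FALSE]
    y <- y[sub$idx]
  }
  p <- predict(loaded$model, X)
  m <- metrics_from_confusion(confusion(y, p))
  m$auc <- roc_auc(y, p)
  out <- data.frame(metric = names(m), value = unlist(m, use.names = FALSE))
  utils::write.csv(out, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  pipeline_log("evaluate: n = %d, accuracy %.3f, AUC %.3f",
               length(y), m$accuracy, m$auc)
  print(m)
  invisible(m)
}

#' Cross-validate the ANFIS on a cohort file
#'
#' @param cohort_path Cohort CSV.
#' @param cfg Run configuration (\code{cfg$evaluation$cv_folds} folds).
#' @param out_dir Output directory for fold and summary CSVs.
#' @return Invisibly, the \code{cv_result}.
#' @export
pipeline_crossval <- function(cohort_path, cfg = default_run_config(),
                              out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prep <- prepare_data(cohort_path, cfg)
  X <- rbind(prep$X_train, prep$X_test)
  y <- c(prep$y_train, prep$y_test)
  cv <- cross_validate(X, y, k = cfg$evaluation$cv_folds,
                       config = config_training(cfg), seed = cfg$seed,
                       n_rules = cfg$training$n_rules)
  utils::write.csv(cv$folds, file.path(out_dir, "cv_folds.csv"), row.names = FALSE)
  utils::write.csv(cv$summary, file.path(out_dir, "cv_summary.csv"), row.names = FALSE)
  pipeline_log("crossval: mean accuracy %.3f",
               cv$summary$mean[cv$summary$metric == "accuracy"])
  print(cv)
  invisible(cv)
}

#' Perturbation importance of a trained model on the test partition
#'
#' @param cohort_path Cohort CSV.
#' @param model_path Model JSON.
#' @param cfg Run configuration.
#' @param out_dir Output directory for \code{importance.csv}.
#' @return Invisibly, the \code{importance_table}.
#' @export
pipeline_importance <- function(cohort_path, model_path,
                                cfg = default_run_config(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prep <- prepare_data(cohort_path, cfg)
  loaded <- read_anfis(model_path)
  imp <- perturbation_importance(loaded$model, prep$X_test, prep$y_test)
  utils::write.csv(imp, file.path(out_dir, "importance.csv"), row.names = FALSE)
  pipeline_log("importance: top feature %s (%.4f)",
               imp$feature[1], imp$importance[1])
  invisible(imp)
}

#' Clinical report for one child record
#'
#' @param record One-row data.frame with the raw assessment columns, or a
#'   cohort CSV path plus a \code{child_id}.
#' @param model_path Model JSON (must embed the scaler).
#' @param cfg Run configuration (composite-risk weights).
#' @param out_path Optional path for a JSON copy of the report.
#' @return The \code{clinical_report}, invisibly.
#' @export
pipeline_report <- function(record, model_path, cfg = default_run_config(),
                            out_path = NULL) {
  loaded <- read_anfis(model_path)
  if (is.null(loaded$scaler)) {
    stop("pipeline_report: model artifact does not embed a scaler")
  }
  rep <- generate_report(record, loaded$model, loaded$scaler,
                         weights = config_weights(cfg))
  print(rep)
  if (!is.null(out_path)) {
    jsonlite::write_json(list(
      prediction = rep$prediction, probability = rep$probability,
      confidence = rep$confidence, confidence_tier = rep$confidence_tier,
      domain_labels = as.list(rep$domain_labels),
      top_features = rep$top_features,
      features_raw = as.list(rep$features_raw),
      recommendation = rep$recommendation
    ), out_path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(rep)
}
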