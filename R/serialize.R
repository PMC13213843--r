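#' Save an ANFIS model to a JSON artifact
#'
#' Writes a single self-describing JSON file holding the membership bank,
#' rule antecedents, consequent parameters, feature order, and (optionally)
#' the fitted scaler, sufficient to reload the model and reproduce its
#' predictions exactly.
#'
#' @param model An \code{anfis_model}.
#' @param path Output file path.
#' @param scaler Optional \code{scaler_params} stored alongside the model.
#' @return \code{path}, invisibly.
#' @export
write_anfis <- function(model, path, scaler = NULL) {
  stopifnot(inherits(model, "anfis_model"))
  obj <- list(
    format = "anfisdd-model",
    version = 1L,
    n_features = ncol(model$centers),
    n_rules = nrow(model$rules),
    feature_names = model$feature_names,
    centers = model$centers,
    widths = model$widths,
    rules = model$rules,
    coef = model$coef,
    intercept = model$intercept,
    eps = model$eps,
    sigma_min = model$sigma_min
  )
  if (!is.null(scaler)) {
    obj$scaler <- list(min = as.list(scaler$min), max = as.list(scaler$max))
  }
  # digits = I(17): significant-digit encoding that round-trips doubles exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load an ANFIS model from a JSON artifact
#'
#' @param path File written by \code{\link{write_anfis}}.
#' @return A list with \code{model} (\code{anfis_model}) and \code{scaler}
#'   (\code{scaler_params} or NULL).
#' @export
read_anfis <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "anfisdd-model") {
    stop("read_anfis: not an anfisdd model artifact: ", path)
  }
  fn <- obj$feature_names
  model <- anfis_model(
    n_features = obj$n_features,
    rules = matrix(as.integer(obj$rules), obj$n_rules, obj$n_features),
    centers = matrix(as.numeric(obj$centers), 3, obj$n_features,
                     dimnames = list(c("Low", "Medium", "High"), fn)),
    widths = matrix(as.numeric(obj$widths), 3, obj$n_features,
                    dimnames = list(c("Low", "Medium", "High"), fn)),
    coef = matrix(as.numeric(obj$coef), obj$n_rules, obj$n_features),
    intercept = as.numeric(obj$intercept),
    feature_names = fn,
    eps = obj$eps, sigma_min = obj$sigma_min
  )
  scaler <- NULL
  if (!is.null(obj$scaler)) {
    scaler <- structure(list(min = unlist(obj$scaler$min),
                             max = unlist(obj$scaler$max)),
                        class = "scaler_params")
  }
  list(model = model, scaler = scaler)
}
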