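#' Training configuration
#'
#' Hyperparameters of the gradient-descent training protocol: Adam with
#' learning rate 0.01, up to 100 epochs at batch size 32, a 20% validation
#' hold-out monitored for early stopping with patience 10, and the best
#' validation-loss weights restored at the end.
#'
#' @param learning_rate Adam step size.
#' @param max_epochs Maximum epochs.
#' @param batch_size Minibatch size.
#' @param early_stopping_patience Epochs without validation-loss improvement
#'   tolerated before stopping.
#' @param validation_fraction Fraction of the training data held out for
#'   validation (stratified); 0 disables validation and early stopping.
#' @param seed Seed covering the validation split, rule initialization,
#'   intercept draw, and minibatch shuffling.
#' @return An object of class \code{training_config}.
#' @export
training_config <- function(learning_rate = 0.01, max_epochs = 100,
                            batch_size = 32, early_stopping_patience = 10,
                            validation_fraction = 0.20, seed = 1L) {
  if (learning_rate <= 0 || max_epochs < 1 || batch_size < 1 ||
      early_stopping_patience < 1) {
    stop("training_config: learning_rate, max_epochs, batch_size and patience must be positive")
  }
  if (validation_fraction < 0 || validation_fraction >= 1) {
    stop("training_config: validation_fraction must lie in [0, 1)")
  }
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "training_config")
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Loss and analytic gradients of the ANFIS on a batch
#'
#' Mean binary cross-entropy and its gradients with respect to every
#' adaptive parameter: membership-function centers and widths, consequent
#' slopes, and intercepts. Gradients through a membership that sits at the
#' underflow floor are zero (the floored value is constant there), matching
#' the forward computation exactly.
#'
#' @param model An \code{anfis_model}.
#' @param X Batch feature matrix (normalized).
#' @param y Batch 0/1 labels.
#' @return List with \code{loss} and \code{grads} (list of \code{centers},
#'   \code{widths}, \code{coef}, \code{intercept}).
#' @export
anfis_gradients <- function(model, X, y) {
  X <- as_input_matrix(model, X)
  n <- nrow(X)
  d <- ncol(X)
  K <- nrow(model$rules)
  logM <- anfis_log_memberships(model, X)
  log_eps <- log(model$eps)

  logW <- matrix(0, n, K)
  for (k in seq_len(K)) {
    s <- 0
    for (i in seq_len(d)) s <- s + logM[[model$rules[k, i]]][, i]
    logW[, k] <- s
  }
  w <- exp(logW)
  S <- rowSums(w)
  wn <- w / S
  f <- X %*% t(model$coef) + matrix(model$intercept, n, K, byrow = TRUE)
  z <- rowSums(wn * f)
  p <- stats::plogis(z)
  loss <- bce_loss(p, y)
  if (!is.finite(loss)) stop("anfis_gradients: non-finite loss")

  delta <- p - y                       # dL/dz for sigmoid + BCE
  dwn <- delta * wn                    # n x K
  grad_intercept <- colSums(dwn) / n
  grad_coef <- t(crossprod(X, dwn)) / n
  A <- dwn * (f - z)                   # dL/dlog(w_k), n x K

  grad_centers <- matrix(0, 3, d)
  grad_widths <- matrix(0, 3, d)
  for (j in 1:3) {
    dx <- sweep(X, 2, model$centers[j, ], "-")
    active <- logM[[j]] > log_eps      # floored memberships carry no gradient
    gc <- sweep(dx, 2, model$widths[j, ]^2, "/") * active
    gs <- sweep(dx^2, 2, model$widths[j, ]^3, "/") * active
    for (i in seq_len(d)) {
      ks <- which(model$rules[, i] == j)
      if (length(ks) == 0) next
      B <- if (length(ks) == 1) A[, ks] else rowSums(A[, ks, drop = FALSE])
      grad_centers[j, i] <- sum(B * gc[, i]) / n
      grad_widths[j, i] <- sum(B * gs[, i]) / n
    }
  }
  list(loss = loss,
       grads = list(centers = grad_centers, widths = grad_widths,
                    coef = grad_coef, intercept = grad_intercept))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

get_params <- function(model) {
  model[c("centers", "widths", "coef", "intercept")]
}

set_params <- function(model, params) {
  model$centers <- params$centers
  model$widths <- pmax(params$widths, model$sigma_min)
  model$coef <- params$coef
  model$intercept <- params$intercept
  model
}

stratified_holdout_idx <- function(y, fraction) {
  idx <- integer(0)
  for (cl in unique(y)) {
    cl_idx <- which(y == cl)
    n_val <- round(fraction * length(cl_idx))
    if (n_val >= 1 && n_val < length(cl_idx)) {
      idx <- c(idx, sample(cl_idx, n_val))
    }
  }
  idx
}

#' Train a Sugeno ANFIS by gradient descent
#'
#' Minimizes mean binary cross-entropy over all adaptive parameters
#' (membership centers and widths, consequent slopes and intercepts) with
#' Adam. A stratified validation fraction of the training data is held out
#' and monitored; training stops once the validation loss has not improved
#' for the configured patience, and the best-epoch weights are restored.
#' Widths are kept above \code{sigma_min} after every update.
#'
#' @param X Normalized feature matrix (training partition).
#' @param y 0/1 labels.
#' @param config A \code{\link{training_config}}.
#' @param n_rules Number of fuzzy rules (default 8).
#' @param rule_init \code{"kmeans"} (data-driven antecedents, default) or
#'   \code{"random"}.
#' @param model Optional pre-built \code{anfis_model} to continue training.
#' @param verbose Print per-epoch losses.
#' @return An object of class \code{anfis_fit}: list with \code{model} (best
#'   weights), \code{history} (per-epoch data.frame of train/validation loss
#'   and accuracy), and \code{best_epoch}.
#' @export
anfis_train <- function(X, y, config = training_config(), n_rules = 8,
                        rule_init = c("kmeans", "random"), model = NULL,
                        verbose = FALSE) {
  rule_init <- match.arg(rule_init)
  X <- if (is.data.frame(X)) as.matrix(X) else X
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("anfis_train: both classes must be present")
  if (any(X < -1e-9 | X > 1 + 1e-9)) {
    stop("anfis_train: features must be min-max normalized to [0, 1]")
  }
  set.seed(config$seed)
  val_idx <- if (config$validation_fraction > 0) {
    stratified_holdout_idx(y, config$validation_fraction)
  } else integer(0)
  has_val <- length(val_idx) > 0
  X_val <- X[val_idx, , drop = FALSE]
  y_val <- y[val_idx]
  X_tr <- if (has_val) X[-val_idx, , drop = FALSE] else X
  y_tr <- if (has_val) y[-val_idx] else y

  if (is.null(model)) {
    rules <- if (rule_init == "kmeans" && nrow(unique(X_tr)) >= n_rules) {
      init_rules_kmeans(X_tr, n_rules, seed = config$seed)
    } else {
      init_rules_random(ncol(X), n_rules, seed = config$seed)
    }
    model <- anfis_model(ncol(X), rules, feature_names = colnames(X),
                         init_seed = config$seed)
  }
  set.seed(config$seed + 1L) # minibatch shuffling stream

  params <- get_params(model)
  state <- adam_init(params)
  n <- nrow(X_tr)
  bs <- min(config$batch_size, n)

  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), train_acc = numeric(0),
                     val_acc = numeric(0))
  best_val <- Inf
  best_params <- params
  best_epoch <- 0L
  stall <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = bs)) {
      batch <- ord[start:min(start + bs - 1, n)]
      g <- anfis_gradients(model, X_tr[batch, , drop = FALSE], y_tr[batch])
      upd <- adam_step(params, g$grads, state, config$learning_rate)
      params <- upd$params
      state <- upd$state
      model <- set_params(model, params)
      params <- get_params(model) # widths after the sigma_min clamp
    }
    p_tr <- predict(model, X_tr)
    tr_loss <- bce_loss(p_tr, y_tr)
    tr_acc <- mean((p_tr > 0.5) == (y_tr == 1))
    if (!is.finite(tr_loss)) {
      stop("anfis_train: training diverged (non-finite loss) at epoch ", epoch)
    }
    if (has_val) {
      p_val <- predict(model, X_val)
      val_loss <- bce_loss(p_val, y_val)
      val_acc <- mean((p_val > 0.5) == (y_val == 1))
    } else {
      val_loss <- NA_real_
      val_acc <- NA_real_
    }
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tr_loss,
                                   val_loss = val_loss, train_acc = tr_acc,
                                   val_acc = val_acc))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %s", epoch, tr_loss,
                      if (has_val) sprintf("%.4f", val_loss) else "-"))
    }
    monitor <- if (has_val) val_loss else tr_loss
    if (monitor < best_val - 1e-12) {
      best_val <- monitor
      best_params <- params
      best_epoch <- epoch
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$early_stopping_patience) break
    }
  }
  model <- set_params(model, best_params)
  structure(list(model = model, history = hist, best_epoch = best_epoch),
            class = "anfis_fit")
}

#' @export
print.anfis_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("ANFIS fit: %d epochs (best epoch %d)\n", nrow(h), x$best_epoch))
  last <- h[nrow(h), ]
  cat(sprintf("  final train loss %.4f acc %.3f", last$train_loss, last$train_acc))
  if (is.finite(last$val_loss)) {
    cat(sprintf("; val loss %.4f acc %.3f", last$val_loss, last$val_acc))
  }
  cat("\n")
  invisible(x)
}
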