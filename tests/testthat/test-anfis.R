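test_that("Gaussian membership peaks at the center, is symmetric, and matches closed form", {
  expect_equal(gaussian_membership(0.5, 0.5, 0.25), 1.0)
  expect_equal(gaussian_membership(0.0, 0.5, 0.25), exp(-2))
  for (d in c(0.05, 0.2, 0.7)) {
    expect_equal(gaussian_membership(0.5 + d, 0.5, 0.25),
                 gaussian_membership(0.5 - d, 0.5, 0.25))
  }
  expect_error(gaussian_membership(0.5, 0.5, 0), "width")
})

test_that("rule firing is the product of selected memberships, computed without underflow", {
  d <- 11
  model <- anfis_model(d, rules = matrix(1L, 1, d)) # one all-Low rule
  # every coordinate at the rule's MF centers -> firing 1
  expect_equal(rule_firing(model, rep(0, d))[1, 1], 1.0)
  # one coordinate at membership 0.5, rest at centers -> firing 0.5
  x <- rep(0, d)
  x[4] <- sqrt(2 * 0.25^2 * log(2)) # mu = 0.5 for center 0, width 0.25
  expect_equal(rule_firing(model, x)[1, 1], 0.5)
  # 11 coordinates each at membership exp(-2): product exp(-22) ~ 2.7e-10
  w <- rule_firing(model, rep(0.5, d))[1, 1]
  expect_equal(w, exp(-22))
  expect_gt(w, 0)
})

test_that("normalized firing strengths are proportional and sum to one", {
  expect_equal(normalize_firing(c(2, 2, 0, 0, 0, 0, 0, 0))[1, 1:2], c(0.5, 0.5),
               ignore_attr = TRUE)
  expect_equal(normalize_firing(rep(3, 8))[1, ], rep(0.125, 8))
  w <- runif(8)
  expect_equal(normalize_firing(w), normalize_firing(17.3 * w))
  expect_error(normalize_firing(rep(0, 8)), "degenerate")
  set.seed(30)
  W <- matrix(rexp(40), 5, 8)
  expect_equal(rowSums(normalize_firing(W)), rep(1, 5))
})

test_that("forward pass reduces to the sigmoid of a constant when consequents agree", {
  d <- 3
  model <- anfis_model(d, rules = rbind(c(1L, 2L, 3L), c(2L, 2L, 1L)),
                       intercept = c(0, 0))
  set.seed(31)
  X <- matrix(runif(5 * d), 5, d)
  expect_equal(anfis_forward(model, X)$prob, rep(0.5, 5)) # all-zero consequents
  model$intercept <- c(1.7, 1.7)
  expect_equal(anfis_forward(model, X)$prob, rep(plogis(1.7), 5))
})

test_that("forward pass agrees with a hand-unrolled layer-by-layer oracle", {
  for (seed in 1:20) {
    m <- random_small_model(d = 2 + seed %% 3, K = 2 + seed %% 4, seed = seed)
    set.seed(100 + seed)
    x <- runif(ncol(m$centers))
    expect_equal(anfis_forward(m, x)$prob, anfis_forward_oracle(m, x),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("layer contracts hold on random inputs", {
  m <- random_small_model(d = 6, K = 8, seed = 77)
  set.seed(78)
  X <- matrix(runif(300), 50, 6)
  out <- anfis_forward(m, X)
  expect_true(all(out$firing > 0 & out$firing <= 1 + 1e-12))
  expect_equal(rowSums(out$norm_firing), rep(1, 50))
  expect_true(all(out$prob > 0 & out$prob < 1))
})

test_that("forward output is invariant to permuting rules with their consequents", {
  m <- random_small_model(d = 4, K = 6, seed = 55)
  set.seed(56)
  X <- matrix(runif(40), 10, 4)
  p0 <- anfis_forward(m, X)$prob
  perm <- sample(6)
  m2 <- m
  m2$rules <- m$rules[perm, , drop = FALSE]
  m2$coef <- m$coef[perm, , drop = FALSE]
  m2$intercept <- m$intercept[perm]
  expect_equal(anfis_forward(m2, X)$prob, p0, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences for every parameter", {
  m <- random_small_model(d = 3, K = 3, seed = 91)
  set.seed(92)
  X <- matrix(runif(24), 8, 3)
  y <- rbinom(8, 1, 0.5)
  g <- anfis_gradients(m, X, y)
  h <- 1e-6
  for (field in c("centers", "widths", "coef", "intercept")) {
    analytic <- as.numeric(g$grads[[field]])
    numeric_grad <- vapply(seq_along(analytic), function(i) {
      mp <- m; mp[[field]][i] <- mp[[field]][i] + h
      mm <- m; mm[[field]][i] <- mm[[field]][i] - h
      (anfis_gradients(mp, X, y)$loss - anfis_gradients(mm, X, y)$loss) / (2 * h)
    }, numeric(1))
    denom <- pmax(abs(numeric_grad), 1e-6)
    expect_lt(max(abs(analytic - numeric_grad) / denom), 1e-4)
  }
})

test_that("training reaches perfect accuracy on a linearly separable toy set", {
  set.seed(1)
  n <- 120
  y <- rep(0:1, each = n / 2)
  X <- cbind(f1 = ifelse(y == 1, runif(n, 0.6, 1), runif(n, 0, 0.4)),
             f2 = runif(n))
  fit <- anfis_train(X, y, training_config(max_epochs = 100, seed = 3),
                     n_rules = 4)
  expect_lte(nrow(fit$history), 100)
  acc <- mean((predict(fit$model, X) > 0.5) == (y == 1))
  expect_equal(acc, 1.0)
})

test_that("training on label-independent features stays near the majority rate", {
  set.seed(2)
  n <- 400
  X <- matrix(runif(n * 3), n, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- rbinom(n, 1, 0.25) # labels carry no feature signal
  fit <- anfis_train(X, y, training_config(max_epochs = 30, seed = 4),
                     n_rules = 4)
  h <- fit$history
  final_val_acc <- h$val_acc[nrow(h)]
  expect_lt(abs(final_val_acc - max(mean(y == 0), mean(y == 1))), 0.12)
})

test_that("training is deterministic and early stopping restores the best epoch", {
  set.seed(5)
  n <- 200
  y <- rbinom(n, 1, 0.3)
  X <- matrix(pmin(pmax(y * 0.4 + runif(n * 2, 0, 0.6), 0), 1), n, 2)
  cfg <- training_config(max_epochs = 25, seed = 6)
  fit1 <- anfis_train(X, y, cfg, n_rules = 3)
  fit2 <- anfis_train(X, y, cfg, n_rules = 3)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$model, fit2$model)
  # best epoch minimizes validation loss over all recorded epochs
  expect_equal(fit1$best_epoch, which.min(fit1$history$val_loss))
  expect_lte(fit1$history$val_loss[fit1$best_epoch], min(fit1$history$val_loss))
})

test_that("trained widths respect the sigma_min bound and rules stay unique", {
  fx <- trained_fixture()
  expect_true(all(fx$model$widths >= fx$model$sigma_min))
  expect_equal(anyDuplicated(fx$model$rules), 0)
  expect_equal(nrow(fx$model$rules), 8)
  expect_equal(ncol(fx$model$centers), 11)
})

test_that("model JSON artifact reloads to identical predictions", {
  fx <- trained_fixture()
  path <- tempfile(fileext = ".json")
  write_anfis(fx$model, path, scaler = fx$scaler)
  loaded <- read_anfis(path)
  expect_identical(predict(loaded$model, fx$X_test), predict(fx$model, fx$X_test))
  expect_equal(loaded$scaler$min, fx$scaler$min)
  bad <- tempfile(fileext = ".json")
  writeLines('{"format": "something-else"}', bad)
  expect_error(read_anfis(bad), "not an anfisdd model")
})

test_that("rule initialization produces valid, distinct antecedents", {
  set.seed(41)
  X <- matrix(runif(200 * 4), 200, 4)
  rules <- init_rules_kmeans(X, 8, seed = 41)
  expect_equal(dim(rules), c(8, 4))
  expect_true(all(rules %in% 1:3))
  expect_equal(anyDuplicated(rules), 0)
  rnd <- init_rules_random(11, 8, seed = 41)
  expect_equal(anyDuplicated(rnd), 0)
  expect_error(init_rules_kmeans(X[1:4, ], 8), "distinct")
})
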