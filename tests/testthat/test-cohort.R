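test_that("truncated-normal sampler respects bounds and collapses with vanishing variance", {
  set.seed(1)
  expect_equal(sample_truncated_normal(5, 50, 1e-9, 0, 100), rep(50, 5),
               tolerance = 1e-6)
  x <- sample_truncated_normal(2000, -50, 10, 0, 100)
  expect_true(all(x >= 0 & x <= 100))
  expect_error(sample_truncated_normal(1, NaN, 1, 0, 100), "finite")
  expect_error(sample_truncated_normal(1, 50, -1, 0, 100), "sd")
  expect_error(sample_truncated_normal(1, 50, 1, 10, 10), "low < high")
})

test_that("truncated-normal sample mean matches numerically integrated moments", {
  cases <- list(c(51.58, 17.09), c(60.86, 14.51), c(-20, 30), c(95, 10))
  set.seed(42)
  for (cs in cases) {
    x <- sample_truncated_normal(1e5, cs[1], cs[2], 0, 100)
    expect_equal(mean(x), truncnorm_mean_numeric(cs[1], cs[2], 0, 100),
                 tolerance = 0.5, ignore_attr = TRUE)
  }
})

test_that("cohort config resolves group sizes by deterministic rounding of prevalence", {
  cc <- cohort_config(n_total = 5000, prevalence = 0.138,
                      n_group0 = NULL, n_group1 = NULL)
  expect_equal(cc$n_group1, 690L)  # round(0.138 * 5000)
  expect_equal(cc$n_group0, 4310L)
  expect_equal(cohort_config()$n_group1, 689L) # explicit study counts
  expect_error(cohort_config(n_total = 10, prevalence = 0.01,
                             n_group0 = NULL, n_group1 = NULL), "degenerate")
})

test_that("generated cohorts satisfy type invariants and are seed-deterministic", {
  cc <- cohort_config(n_group0 = 300, n_group1 = 60, seed = 7)
  co <- generate_cohort(cc)
  expect_equal(nrow(co), 360)
  scores <- unlist(co[, c("cognitive_score", "behavioral_score",
                          "motor_skills", "social_interaction")])
  expect_true(all(scores >= 0 & scores <= 100))
  expect_true(all(co$family_history %in% 0:1))
  expect_true(all(co$diagnosis %in% 0:1))
  expect_true(all(co$age %in% 1:6))
  expect_true(all(co$sex %in% c("male", "female")))
  expect_equal(sum(co$diagnosis), 60)

  # byte-for-byte reproducibility after serialization
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(generate_cohort(cc), f1)
  write_cohort(generate_cohort(cc), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("group moments are recovered within sampling error plus truncation bias", {
  co <- generate_cohort(cohort_config(seed = 3))
  params <- list(`0` = default_group0(), `1` = default_group1())
  doms <- c(cognitive_score = "cognitive", behavioral_score = "behavioral",
            motor_skills = "motor", social_interaction = "social")
  for (g in names(params)) {
    gp <- params[[g]]
    sub <- co[co$diagnosis == as.integer(g), ]
    for (col in names(doms)) {
      mu <- gp[[paste0("mean_", doms[[col]])]]
      sd_ <- gp[[paste0("sd_", doms[[col]])]]
      mu_trunc <- truncnorm_mean_numeric(mu, sd_, 0, 100)
      expect_lt(abs(mu_trunc - mu), 0.3)  # truncation bias negligible here
      se <- sd_ / sqrt(nrow(sub))
      expect_lt(abs(mean(sub[[col]]) - mu_trunc), 4 * se)
    }
  }
  # group-1 cognitive mean within 3 standard errors of 51.58
  g1 <- co$cognitive_score[co$diagnosis == 1]
  expect_lt(abs(mean(g1) - 51.58), 3 * 17.09 / sqrt(689))
})

test_that("domains are sampled independently within group", {
  co <- generate_cohort(cohort_config(seed = 5))
  doms <- c("cognitive_score", "behavioral_score", "motor_skills",
            "social_interaction")
  cors <- stats::cor(co[co$diagnosis == 0, doms])
  off_diag <- cors[upper.tri(cors)]
  expect_true(all(abs(off_diag) < 0.05))
})

test_that("point-biserial equals the Pearson correlation and handles edge cases", {
  set.seed(8)
  v <- rnorm(200)
  l <- rbinom(200, 1, 0.3)
  expect_equal(point_biserial(v, l), stats::cor(v, l), tolerance = 1e-12)
  expect_equal(point_biserial(c(0, 1, 0, 1, 1), c(0, 1, 0, 1, 1)), 1.0)
  expect_error(point_biserial(rep(3, 5), c(0, 1, 0, 1, 1)), "zero variance")
  expect_error(point_biserial(rnorm(5), rep(1, 5)), "single class")
  # closed form: class means 51.58 / 60.86, total SD 15.23, p = 0.138
  closed_form <- (51.58 - 60.86) * sqrt(0.138 * 0.862) / 15.23
  expect_equal(closed_form, -0.21, tolerance = 0.005)
})

test_that("phi coefficient equals the Pearson correlation of binaries", {
  set.seed(9)
  a <- rbinom(300, 1, 0.5); b <- rbinom(300, 1, 0.5)
  expect_equal(phi_coefficient(a, b), stats::cor(a, b))
  expect_error(phi_coefficient(rep(1, 5), c(0, 1, 1, 0, 1)), "constant")
  expect_error(phi_coefficient(c(0, 2, 1), c(0, 1, 1)), "binary")
})

test_that("cohort summary reproduces hand-computed statistics on a 4-record cohort", {
  co <- data.frame(
    child_id = paste0("C", 1:4), age = c(2, 3, 4, 5),
    sex = c("female", "male", "female", "male"),
    cognitive_score = c(70, 60, 40, 50), behavioral_score = c(60, 50, 45, 55),
    motor_skills = c(55, 45, 40, 50), social_interaction = c(65, 55, 35, 45),
    family_history = c(0, 1, 1, 0), diagnosis = c(0, 0, 1, 1)
  )
  s <- summarize_cohort(co)
  cog <- s$domains[s$domains$domain == "cognitive", ]
  expect_equal(cog$mean_group0, 65)
  expect_equal(cog$mean_group1, 45)
  expect_equal(cog$mean_overall, 55)
  # overall mean is the group-size-weighted mean of group means
  expect_equal(cog$mean_overall, (2 * 65 + 2 * 45) / 4)
  expect_equal(s$proportions$prevalence, 0.5)
  expect_equal(s$proportions$p_female, 0.5)
  expect_equal(s$proportions$fh_group0, 0.5)
  expect_error(summarize_cohort(co[, -4]), "missing required columns")
  expect_error(summarize_cohort(co[co$diagnosis == 1, ]), "both diagnostic groups")
})

test_that("missingness hook emits NAs at the configured rate only in score cells", {
  cc <- cohort_config(n_group0 = 400, n_group1 = 100, missing_rate = 0.05,
                      seed = 13)
  co <- generate_cohort(cc)
  score_na <- sum(is.na(co[, c("cognitive_score", "behavioral_score",
                               "motor_skills", "social_interaction")]))
  expect_gt(score_na, 0)
  expect_lt(score_na / (4 * 500), 0.10)
  expect_false(anyNA(co[, c("age", "sex", "family_history", "diagnosis")]))
})

test_that("cohort CSV round-trips with the fixed schema", {
  co <- generate_cohort(cohort_config(n_group0 = 30, n_group1 = 10, seed = 2))
  path <- tempfile(fileext = ".csv")
  write_cohort(co, path)
  header <- readLines(path, n = 1)
  expect_identical(header,
    "child_id,age,sex,cognitive_score,behavioral_score,motor_skills,social_interaction,family_history,diagnosis")
  back <- read_cohort(path)
  expect_equal(back$cognitive_score, co$cognitive_score)
  expect_identical(back$sex, co$sex)
})
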