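#' Group-conditional distribution parameters for one diagnostic group
#'
#' Holds the marginal parameters of one diagnostic group: mean and SD of the
#' four developmental domain scores (0-100 scale), the probability of a
#' positive family history, and the probability of female sex.
#'
#' @param mean_cognitive,sd_cognitive Cognitive score mean and SD.
#' @param mean_behavioral,sd_behavioral Behavioral score mean and SD.
#' @param mean_motor,sd_motor Motor skills mean and SD.
#' @param mean_social,sd_social Social interaction mean and SD.
#' @param p_family_history Probability of positive family history.
#' @param p_female Probability of female sex.
#' @return An object of class \code{group_params}.
#' @export
group_params <- function(mean_cognitive, sd_cognitive,
                         mean_behavioral, sd_behavioral,
                         mean_motor, sd_motor,
                         mean_social, sd_social,
                         p_family_history, p_female) {
  gp <- list(
    mean_cognitive = mean_cognitive, sd_cognitive = sd_cognitive,
    mean_behavioral = mean_behavioral, sd_behavioral = sd_behavioral,
    mean_motor = mean_motor, sd_motor = sd_motor,
    mean_social = mean_social, sd_social = sd_social,
    p_family_history = p_family_history, p_female = p_female
  )
  vals <- unlist(gp)
  if (any(!is.finite(vals))) {
    stop("group_params: all parameters must be finite")
  }
  sds <- vals[grepl("^sd_", names(vals))]
  if (any(sds <= 0)) stop("group_params: all SDs must be > 0")
  means <- vals[grepl("^mean_", names(vals))]
  if (any(means < 0 | means > 100)) {
    stop("group_params: means must lie in [0, 100]")
  }
  props <- c(p_family_history, p_female)
  if (any(props < 0 | props > 1)) {
    stop("group_params: proportions must lie in [0, 1]")
  }
  structure(gp, class = "group_params")
}

#' Default group parameters for the typically developing group
#'
#' Marginal parameters of the typically developing (diagnosis = 0) group:
#' cognitive 60.86 +/- 14.51, behavioral 55.82 +/- 9.38, motor 51.08 +/- 7.79,
#' social 51.20 +/- 11.66, family history 45.0%, female 51.7%.
#'
#' @return A \code{group_params} object.
#' @export
default_group0 <- function() {
  group_params(60.86, 14.51, 55.82, 9.38, 51.08, 7.79, 51.20, 11.66,
               p_family_history = 0.450, p_female = 0.517)
}

#' Default group parameters for the developmental disability group
#'
#' Marginal parameters of the diagnosed (diagnosis = 1) group: cognitive
#' 51.58 +/- 17.09, behavioral 49.64 +/- 11.21, motor 45.08 +/- 8.00, social
#' 42.13 +/- 11.19, family history 85.6%, female 48.9%.
#'
#' @return A \code{group_params} object.
#' @export
default_group1 <- function() {
  group_params(51.58, 17.09, 49.64, 11.21, 45.08, 8.00, 42.13, 11.19,
               p_family_history = 0.856, p_female = 0.489)
}

#' Cohort simulation configuration
#'
#' Configuration of the synthetic cohort generator. Group sizes may be given
#' either as explicit counts (\code{n_group0}, \code{n_group1}) or as a total
#' and a prevalence; explicit counts take precedence. With a total and a
#' prevalence the diagnosed count is the nearest integer to
#' \code{prevalence * n_total} (deterministic, not Bernoulli), so realized
#' prevalence is exact by construction. Defaults reproduce the study cohort:
#' 4,311 typically developing and 689 diagnosed children (prevalence 13.8%),
#' ages discrete-uniform on 1-6 years.
#'
#' @param n_total Total number of children (used with \code{prevalence}).
#' @param prevalence Proportion diagnosed (used with \code{n_total}).
#' @param n_group0,n_group1 Explicit group sizes; override
#'   \code{n_total}/\code{prevalence} when both are supplied.
#' @param age_min,age_max Integer age range in years (inclusive).
#' @param group0,group1 \code{\link{group_params}} for each diagnostic group.
#' @param score_floor,score_ceiling Truncation bounds of the score scale.
#' @param missing_rate Optional probability that any one domain-score cell is
#'   set missing (uniformly at random); 0 emits complete data.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return An object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_total = 5000, prevalence = 0.138,
                          n_group0 = 4311, n_group1 = 689,
                          age_min = 1L, age_max = 6L,
                          group0 = default_group0(),
                          group1 = default_group1(),
                          score_floor = 0, score_ceiling = 100,
                          missing_rate = 0, seed = 1L) {
  if (is.null(n_group0) || is.null(n_group1)) {
    if (n_total < 2) stop("cohort_config: n_total must be >= 2")
    if (prevalence <= 0 || prevalence >= 1) {
      stop("cohort_config: prevalence must lie in (0, 1)")
    }
    n_group1 <- round(prevalence * n_total)
    n_group0 <- n_total - n_group1
  }
  if (n_group0 < 1 || n_group1 < 1) {
    stop("cohort_config: degenerate cohort - a diagnostic group has 0 members")
  }
  if (age_min < 1 || age_max < age_min) {
    stop("cohort_config: need age_min >= 1 and age_max >= age_min")
  }
  if (score_floor >= score_ceiling) {
    stop("cohort_config: score_floor must be < score_ceiling")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("cohort_config: missing_rate must lie in [0, 1)")
  }
  stopifnot(inherits(group0, "group_params"), inherits(group1, "group_params"))
  structure(list(
    n_group0 = as.integer(n_group0), n_group1 = as.integer(n_group1),
    age_min = as.integer(age_min), age_max = as.integer(age_max),
    group0 = group0, group1 = group1,
    score_floor = score_floor, score_ceiling = score_ceiling,
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Sample from a truncated normal distribution
#'
#' Draws from a normal(mean, sd) conditioned on \code{[low, high]} by
#' inverse-CDF sampling: a uniform draw on
#' \code{[pnorm(low), pnorm(high)]} is passed through \code{qnorm}. This is
#' genuine conditioning, not clipping, so no point mass accumulates at the
#' bounds, and each variate consumes exactly one uniform from the RNG stream.
#'
#' @param n Number of draws.
#' @param mean,sd Parameters of the parent normal; \code{sd > 0}.
#' @param low,high Truncation bounds, \code{low < high}.
#' @return Numeric vector of length \code{n}, all values in
#'   \code{[low, high]}.
#' @export
sample_truncated_normal <- function(n, mean, sd, low = 0, high = 100) {
  if (!all(is.finite(c(mean, sd, low, high)))) {
    stop("sample_truncated_normal: parameters must be finite")
  }
  if (sd <= 0) stop("sample_truncated_normal: sd must be > 0")
  if (low >= high) stop("sample_truncated_normal: need low < high")
  p_lo <- stats::pnorm(low, mean, sd)
  p_hi <- stats::pnorm(high, mean, sd)
  if (p_hi - p_lo < .Machine$double.eps) {
    # the parent normal puts essentially no mass in [low, high]; fall back to
    # the bound nearer the mean
    return(rep(if (mean < low) low else high, n))
  }
  u <- stats::runif(n, p_lo, p_hi)
  x <- stats::qnorm(u, mean, sd)
  pmin(pmax(x, low), high) # guard float round-off at the extreme quantiles
}

sample_group <- function(n, gp, diagnosis, cfg) {
  lo <- cfg$score_floor
  hi <- cfg$score_ceiling
  data.frame(
    age = sample(seq.int(cfg$age_min, cfg$age_max), n, replace = TRUE),
    sex = ifelse(stats::runif(n) < gp$p_female, "female", "male"),
    cognitive_score = sample_truncated_normal(n, gp$mean_cognitive, gp$sd_cognitive, lo, hi),
    behavioral_score = sample_truncated_normal(n, gp$mean_behavioral, gp$sd_behavioral, lo, hi),
    motor_skills = sample_truncated_normal(n, gp$mean_motor, gp$sd_motor, lo, hi),
    social_interaction = sample_truncated_normal(n, gp$mean_social, gp$sd_social, lo, hi),
    family_history = as.integer(stats::runif(n) < gp$p_family_history),
    diagnosis = diagnosis,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic child-assessment cohort
#'
#' Generates a seeded cohort of child records with the group-conditional
#' structure the screening analysis assumes: within each diagnostic group the
#' four domain scores are independent truncated normals with that group's
#' parameters, family history and sex are group-conditional Bernoulli, and
#' age is discrete-uniform on the configured range. Group sizes are exact
#' counts, so prevalence carries no sampling noise.
#'
#' @param config A \code{\link{cohort_config}}.
#' @return A \code{data.frame} with columns \code{child_id}, \code{age},
#'   \code{sex} ("male"/"female"), \code{cognitive_score},
#'   \code{behavioral_score}, \code{motor_skills}, \code{social_interaction},
#'   \code{family_history} (0/1), \code{diagnosis} (0/1).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_group0 = 80, n_group1 = 20, seed = 7))
#' table(cohort$diagnosis)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  g0 <- sample_group(config$n_group0, config$group0, 0L, config)
  g1 <- sample_group(config$n_group1, config$group1, 1L, config)
  records <- rbind(g0, g1)
  n <- nrow(records)
  # shuffle so record order carries no group information
  records <- records[sample.int(n), , drop = FALSE]
  if (config$missing_rate > 0) {
    score_cols <- c("cognitive_score", "behavioral_score",
                    "motor_skills", "social_interaction")
    for (col in score_cols) {
      miss <- stats::runif(n) < config$missing_rate
      records[[col]][miss] <- NA_real_
    }
  }
  records <- cbind(child_id = sprintf("C%05d", seq_len(n)), records,
                   stringsAsFactors = FALSE)
  rownames(records) <- NULL
  records
}

#' Point-biserial correlation of a continuous variable with a binary label
#'
#' Computes \code{(M1 - M0) * sqrt(p * (1 - p)) / SD} where \code{M1},
#' \code{M0} are the class means, \code{p} the positive-label proportion, and
#' \code{SD} the population (divide-by-n) standard deviation of all values.
#' This equals the Pearson correlation between the values and the 0/1 labels.
#'
#' @param values Numeric vector, all finite.
#' @param labels Binary (0/1 or logical) vector of the same length.
#' @return The correlation, in [-1, 1].
#' @export
point_biserial <- function(values, labels) {
  labels <- as.integer(labels)
  if (length(values) != length(labels)) {
    stop("point_biserial: values and labels must have equal length")
  }
  if (any(!is.finite(values))) stop("point_biserial: values must be finite")
  if (!all(labels %in% c(0L, 1L))) stop("point_biserial: labels must be binary")
  if (length(unique(labels)) < 2) {
    stop("point_biserial: undefined - labels contain a single class")
  }
  n <- length(values)
  sd_total <- sqrt(sum((values - mean(values))^2) / n)
  if (sd_total == 0) {
    stop("point_biserial: undefined - values have zero variance")
  }
  p <- mean(labels)
  (mean(values[labels == 1L]) - mean(values[labels == 0L])) *
    sqrt(p * (1 - p)) / sd_total
}

#' Phi coefficient between two binary variables
#'
#' The Pearson correlation of two 0/1 variables.
#'
#' @param x,y Binary vectors of equal length.
#' @return The phi coefficient, in [-1, 1].
#' @export
phi_coefficient <- function(x, y) {
  x <- as.integer(x)
  y <- as.integer(y)
  if (!all(x %in% c(0L, 1L)) || !all(y %in% c(0L, 1L))) {
    stop("phi_coefficient: inputs must be binary")
  }
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("phi_coefficient: undefined - a variable is constant")
  }
  stats::cor(x, y)
}

cohort_domains <- c(cognitive = "cognitive_score", behavioral = "behavioral_score",
                    motor = "motor_skills", social = "social_interaction")

#' Summarize a cohort by diagnostic group
#'
#' Per-group and overall mean/SD of each domain score, per-group and overall
#' family-history proportions, prevalence, female proportion, the
#' point-biserial correlation of each domain with diagnosis, and the phi
#' coefficient of family history with diagnosis.
#'
#' @param records A cohort \code{data.frame} as produced by
#'   \code{\link{generate_cohort}}.
#' @return An object of class \code{cohort_summary}: a list with elements
#'   \code{domains} (data.frame of group/overall means and SDs),
#'   \code{proportions}, and \code{correlations}.
#' @export
summarize_cohort <- function(records) {
  required <- c(cohort_domains, "family_history", "diagnosis", "sex")
  missing_cols <- setdiff(unname(required), names(records))
  if (length(missing_cols) > 0) {
    stop("summarize_cohort: missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(records) == 0) stop("summarize_cohort: empty cohort")
  dx <- records$diagnosis
  if (length(unique(dx)) < 2) {
    stop("summarize_cohort: both diagnostic groups must be present")
  }
  dom <- do.call(rbind, lapply(names(cohort_domains), function(d) {
    v <- records[[cohort_domains[[d]]]]
    data.frame(
      domain = d,
      mean_group0 = mean(v[dx == 0]), sd_group0 = stats::sd(v[dx == 0]),
      mean_group1 = mean(v[dx == 1]), sd_group1 = stats::sd(v[dx == 1]),
      mean_overall = mean(v), sd_overall = stats::sd(v),
      r_point_biserial = point_biserial(v, dx),
      stringsAsFactors = FALSE
    )
  }))
  props <- list(
    prevalence = mean(dx),
    p_female = mean(records$sex == "female"),
    fh_group0 = mean(records$family_history[dx == 0]),
    fh_group1 = mean(records$family_history[dx == 1]),
    fh_overall = mean(records$family_history)
  )
  structure(list(
    domains = dom,
    proportions = props,
    phi_family_history = phi_coefficient(records$family_history, dx),
    n = nrow(records)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary (n = %d)\n", x$n))
  cat(sprintf("  prevalence %.3f, female %.3f, family history %.3f (group0 %.3f / group1 %.3f)\n",
              x$proportions$prevalence, x$proportions$p_female,
              x$proportions$fh_overall, x$proportions$fh_group0,
              x$proportions$fh_group1))
  print(x$domains, digits = 4, row.names = FALSE)
  cat(sprintf("  phi(family history, diagnosis) = %.3f\n", x$phi_family_history))
  invisible(x)
}

#' Write / read a cohort CSV
#'
#' The on-disk schema is fixed: header
#' \code{child_id,age,sex,cognitive_score,behavioral_score,motor_skills,social_interaction,family_history,diagnosis}
#' with sex stored as "male"/"female".
#'
#' @param records Cohort data.frame.
#' @param path File path.
#' @return \code{write_cohort} returns \code{path} invisibly;
#'   \code{read_cohort} returns the cohort data.frame.
#' @export
write_cohort <- function(records, path) {
  cols <- c("child_id", "age", "sex", "cognitive_score", "behavioral_score",
            "motor_skills", "social_interaction", "family_history", "diagnosis")
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols) > 0) {
    stop("write_cohort: missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  utils::write.csv(records[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("child_id", "age", "sex", "cognitive_score", "behavioral_score",
            "motor_skills", "social_interaction", "family_history", "diagnosis")
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols) > 0) {
    stop("read_cohort: file lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  records
}
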