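#' Encode sex as binary
#'
#' Maps \code{"male"} to 0 and \code{"female"} to 1. Matching is
#' case-sensitive by default; set \code{case_fold = TRUE} to fold input to
#' lower case first. The mapping is stored as an attribute so it can be
#' reversed.
#'
#' @param records Data.frame with a \code{sex} column holding only the two
#'   recognized labels.
#' @param case_fold Fold labels to lower case before matching (default off).
#' @return The records with \code{sex} recoded to integer 0/1; the attribute
#'   \code{sex_codes} holds the label-to-code map.
#' @export
encode_sex <- function(records, case_fold = FALSE) {
  sex <- records$sex
  if (is.null(sex)) stop("encode_sex: no 'sex' column")
  if (case_fold) sex <- tolower(sex)
  bad <- setdiff(unique(sex), c("male", "female"))
  if (length(bad) > 0) {
    stop("encode_sex: unrecognized sex label(s): ",
         paste(shQuote(bad), collapse = ", "))
  }
  records$sex <- ifelse(sex == "female", 1L, 0L)
  attr(records, "sex_codes") <- c(male = 0L, female = 1L)
  records
}

#' Default key developmental variables for the missing-data policy
#' @return Character vector of the six key column names.
#' @export
default_key_columns <- function() {
  c("cognitive_score", "behavioral_score", "motor_skills",
    "social_interaction", "age", "family_history")
}

#' Apply the missing-data policy
#'
#' Rows missing more than \code{max_missing_fraction} of the key columns are
#' dropped; remaining missing cells are replaced by the column mean computed
#' over the kept rows (mean-value imputation).
#'
#' @param records Data.frame.
#' @param key_columns Columns subject to the row-exclusion threshold;
#'   defaults to the four domain scores plus age and family history.
#' @param max_missing_fraction Row-exclusion threshold (default 0.10).
#' @return A list with \code{records} (cleaned data) and \code{log}, a list
#'   recording \code{n_dropped} and per-column imputation counts.
#' @export
apply_missing_policy <- function(records,
                                 key_columns = default_key_columns(),
                                 max_missing_fraction = 0.10) {
  missing_cols <- setdiff(key_columns, names(records))
  if (length(missing_cols) > 0) {
    stop("apply_missing_policy: key columns absent from data: ",
         paste(missing_cols, collapse = ", "))
  }
  key <- as.matrix(is.na(records[, key_columns, drop = FALSE]))
  frac_missing <- rowMeans(key)
  keep <- frac_missing <= max_missing_fraction
  kept <- records[keep, , drop = FALSE]
  imputed <- integer(0)
  for (col in key_columns) {
    n_na <- sum(is.na(kept[[col]]))
    if (n_na > 0) {
      col_mean <- mean(kept[[col]], na.rm = TRUE)
      if (!is.finite(col_mean)) {
        stop("apply_missing_policy: column entirely missing, cannot impute: ", col)
      }
      kept[[col]][is.na(kept[[col]])] <- col_mean
      imputed[col] <- n_na
    }
  }
  rownames(kept) <- NULL
  list(records = kept,
       log = list(n_dropped = sum(!keep), imputations = as.list(imputed)))
}

#' Fit a min-max scaler on training data
#'
#' Records the per-feature minimum and maximum observed in the training data.
#' \code{scaler_transform} then maps each value x to (x - min) / (max - min);
#' values outside the fitted range (e.g. in test data) are clamped to [0, 1].
#' Fit on the training partition only, to avoid information leaking from the
#' test partition into the feature scale.
#'
#' @param records Data.frame (or matrix) of training data.
#' @param feature_columns Columns to scale; defaults to all numeric columns.
#' @return An object of class \code{scaler_params}: list with \code{min} and
#'   \code{max} named vectors.
#' @export
fit_scaler <- function(records, feature_columns = NULL) {
  if (is.null(feature_columns)) {
    feature_columns <- names(records)[vapply(records, is.numeric, logical(1))]
  }
  mins <- maxs <- stats::setNames(numeric(length(feature_columns)), feature_columns)
  for (col in feature_columns) {
    v <- records[[col]]
    if (length(unique(v[is.finite(v)])) < 2) {
      stop("fit_scaler: zero-range (constant) feature: ", col)
    }
    mins[col] <- min(v, na.rm = TRUE)
    maxs[col] <- max(v, na.rm = TRUE)
  }
  structure(list(min = mins, max = maxs), class = "scaler_params")
}

#' @rdname fit_scaler
#' @param scaler A fitted \code{scaler_params}.
#' @export
scaler_transform <- function(records, scaler) {
  stopifnot(inherits(scaler, "scaler_params"))
  for (col in names(scaler$min)) {
    if (is.null(records[[col]])) {
      stop("scaler_transform: column absent from data: ", col)
    }
    z <- (records[[col]] - scaler$min[col]) / (scaler$max[col] - scaler$min[col])
    records[[col]] <- pmin(pmax(z, 0), 1)
  }
  records
}

#' Stratified train/test split
#'
#' Splits records into train and test partitions preserving the class
#' proportions of \code{stratify_on}. Per-class test counts are
#' round-half-away-from-zero of \code{test_fraction} times the class size;
#' totals are reconciled by adjusting the majority class by at most one so
#' that the overall test fraction is honoured.
#'
#' @param records Data.frame.
#' @param test_fraction Proportion assigned to the test partition.
#' @param stratify_on Column defining the classes (default "diagnosis").
#' @param seed Integer seed for the shuffle.
#' @return List with \code{train} and \code{test} data.frames.
#' @export
stratified_split <- function(records, test_fraction = 0.20,
                             stratify_on = "diagnosis", seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("stratified_split: test_fraction must lie in (0, 1)")
  }
  y <- records[[stratify_on]]
  if (is.null(y)) stop("stratified_split: no column ", stratify_on)
  classes <- sort(unique(y))
  sizes <- vapply(classes, function(cl) sum(y == cl), integer(1))
  if (length(classes) < 2 || any(sizes < 2)) {
    stop("stratified_split: each class needs >= 2 members to stratify")
  }
  round_half_away <- function(x) trunc(x + 0.5 * sign(x))
  n_test <- round_half_away(test_fraction * sizes)
  target_total <- round_half_away(test_fraction * nrow(records))
  excess <- sum(n_test) - target_total
  if (excess != 0) {
    maj <- which.max(sizes)
    n_test[maj] <- n_test[maj] - sign(excess) * min(abs(excess), 1)
  }
  if (any(n_test < 1) || any(n_test >= sizes)) {
    stop("stratified_split: a class is too small for this test_fraction")
  }
  set.seed(seed)
  test_idx <- unlist(lapply(seq_along(classes), function(i) {
    idx <- which(y == classes[i])
    sample(idx, n_test[i])
  }))
  list(train = records[-test_idx, , drop = FALSE],
       test = records[test_idx, , drop = FALSE])
}
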