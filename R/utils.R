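# Internal helpers shared across the pipeline stages.

# Named validation error so callers can distinguish bad inputs from bugs.
stop_invalid <- function(msg, class = "bccstrat_invalid") {
  rlang::abort(msg, class = class)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop_invalid(sprintf("`%s` must be a probability in [0, 1].", name))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    stop_invalid(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# Stratified fold assignment: within each class, shuffle and deal fold ids
# round-robin so fold sizes differ by at most one per class. Uses the
# caller's RNG state.
stratified_folds <- function(y, k) {
  y <- as.factor(y)
  if (any(table(y) < k)) {
    stop_invalid(sprintf(
      "each class needs at least k = %d members for stratified %d-fold CV",
      k, k
    ))
  }
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# z-score columns with supplied or freshly computed centers/scales;
# zero-variance columns scale to 0 rather than NaN.
standardize_cols <- function(X, center = NULL, scale = NULL) {
  X <- as.matrix(X)
  if (is.null(center)) center <- colMeans(X, na.rm = TRUE)
  if (is.null(scale)) scale <- col_sds(X, center)
  zero <- which(is.na(scale) | scale < .Machine$double.eps)
  scale_safe <- ifelse(is.na(scale) | scale < .Machine$double.eps, 1, scale)
  Xs <- sweep(X, 2L, center, "-")
  Xs <- sweep(Xs, 2L, scale_safe, "/")
  if (length(zero)) Xs[, zero] <- 0
  attr(Xs, "center") <- center
  attr(Xs, "scale") <- scale_safe
  Xs
}

# Column standard deviations without per-column apply() overhead.
col_sds <- function(X, center = NULL) {
  if (anyNA(X)) {
    return(apply(X, 2L, stats::sd, na.rm = TRUE))
  }
  n <- nrow(X)
  if (is.null(center)) center <- colMeans(X)
  ss <- colSums(X * X) - n * center^2
  sqrt(pmax(ss, 0) / (n - 1))
}

#' Extract the BCC measurement matrix from a cohort table
#'
#' Pulls the `bcc_*` columns of a cohort tibble into a numeric matrix
#' (patients x BCCs).
#'
#' @param cohort Cohort tibble.
#' @return Numeric matrix.
#' @export
bcc_matrix <- function(cohort) {
  cols <- grep("^bcc_", names(cohort), value = TRUE)
  if (length(cols) == 0L) {
    stop_invalid("cohort has no `bcc_*` columns")
  }
  as.matrix(cohort[, cols, drop = FALSE])
}

# Derive independent substream seeds from a master seed; kept below 2^31.
substream_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
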