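#' Univariate sex comparison of one BCC
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) comparison of a single BCC
#' between women and men, with per-sex medians and IQRs. The rank-based
#' test is used because hematology values are typically skewed and the
#' natural summaries are medians/IQRs; set `test = "t"` for a Welch t-test
#' instead.
#'
#' @param cohort Cohort tibble with a `sex` factor (levels F, M).
#' @param variable Name of the numeric column to compare.
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @return One-row tibble: `variable`, `stat`, `p`, `median_F`, `median_M`,
#'   `IQR_F`, `IQR_M`, `n_F`, `n_M`.
#' @export
#' @examples
#' sim <- simulate_cohort(bcc_config(n_female = 40, n_male = 40, seed = 2))
#' compare_by_sex(sim$cohort, "bcc_001")
compare_by_sex <- function(cohort, variable, test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  x <- cohort[[variable]]
  if (is.null(x)) stop_invalid(sprintf("no column `%s` in cohort", variable))
  xf <- x[cohort$sex == "F" & !is.na(x)]
  xm <- x[cohort$sex == "M" & !is.na(x)]
  if (length(xf) == 0L && length(xm) == 0L) {
    stop_invalid(sprintf("`%s` is entirely missing", variable))
  }
  if (length(xf) < 2L || length(xm) < 2L) {
    stop_invalid(sprintf("`%s` needs >= 2 non-missing values per sex",
                         variable))
  }
  iqr <- function(v) unname(diff(quantile(v, c(0.25, 0.75))))
  if (sd(c(xf, xm)) < .Machine$double.eps) {
    # constant column: no evidence of a difference by convention
    stat <- NA_real_
    p <- 1
  } else if (test == "wilcoxon") {
    ht <- suppressWarnings(wilcox.test(xf, xm, exact = FALSE, correct = TRUE))
    stat <- unname(ht$statistic)
    p <- ht$p.value
  } else {
    ht <- t.test(xf, xm)
    stat <- unname(ht$statistic)
    p <- ht$p.value
  }
  tibble::tibble(
    variable = variable, stat = stat, p = p,
    median_F = median(xf), median_M = median(xm),
    IQR_F = iqr(xf), IQR_M = iqr(xm),
    n_F = length(xf), n_M = length(xm)
  )
}

#' FDR-corrected univariate sex screen over all BCCs
#'
#' Runs [compare_by_sex()] for every BCC column (or a supplied subset) and
#' applies Benjamini-Hochberg FDR correction across the tested variables.
#'
#' @inheritParams compare_by_sex
#' @param variables Columns to screen; defaults to every `bcc_*` column.
#' @param alpha FDR significance level (default 0.05).
#' @return Tibble with one row per variable: the [compare_by_sex()] columns
#'   plus `q` (BH-adjusted p) and `significant` (`q < alpha`).
#' @export
screen_by_sex <- function(cohort, variables = NULL, alpha = 0.05,
                          test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  if (is.null(variables)) {
    variables <- grep("^bcc_", names(cohort), value = TRUE)
  }
  if (!length(variables)) stop_invalid("no variables to screen")
  res <- purrr::map_dfr(variables, compare_by_sex, cohort = cohort,
                        test = test)
  res$q <- bh_adjust(res$p)
  res$significant <- res$q < alpha
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH q-values; thin wrapper over [stats::p.adjust()] with input
#' validation.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as the input.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(pvalues) {
  check_prob(pvalues[!is.na(pvalues)], "pvalues")
  p.adjust(pvalues, method = "BH")
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson chi-square without continuity correction, from the closed form
#' \eqn{N (ad - bc)^2 / (r_1 r_2 c_1 c_2)} for the table
#' \eqn{\begin{pmatrix} a & b \\ c & d \end{pmatrix}} with row sums
#' \eqn{r_1, r_2} and column sums \eqn{c_1, c_2}.
#'
#' @param a,b,c,d Nonnegative cell counts (row-wise: a, b / c, d).
#' @return One-row tibble: `statistic`, `p`, `df` (= 1).
#' @export
#' @examples
#' chi_square_2x2(73, 70, 88, 102)
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_invalid("cell counts must be nonnegative integers")
  }
  n <- sum(counts)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (min(r1, r2, c1, c2) == 0) {
    stop_invalid("chi-square undefined: a table margin is zero")
  }
  stat <- n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2)
  tibble::tibble(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE),
                 df = 1L)
}
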