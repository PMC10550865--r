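#' Logistic regression by iteratively reweighted least squares
#'
#' In-house Newton/IRLS fit of a binomial-logit GLM: coefficients from
#' repeated weighted least-squares solves, convergence on the deviance
#' (tolerance `1e-8`, at most 50 iterations), covariance from the inverse
#' observed (= expected, for the canonical link) information. Divergence
#' of any coefficient beyond +/- 15 is reported as a separation error;
#' rank-deficient designs are rejected.
#'
#' @param X Design matrix (include an intercept column yourself).
#' @param y Binary 0/1 response (or a two-level factor; the second level
#'   is the event).
#' @param tol Deviance convergence tolerance.
#' @param max_iter Iteration cap.
#' @return List: `coefficients`, `vcov`, `deviance`, `iterations`,
#'   `converged`, `n`.
#' @export
#' @examples
#' x <- cbind(1, rnorm(200))
#' y <- rbinom(200, 1, plogis(x %*% c(-0.5, 1)))
#' logistic_irls(x, y)$coefficients
logistic_irls <- function(X, y, tol = 1e-8, max_iter = 50L) {
  X <- as.matrix(X)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop_invalid("y must be binary 0/1")
  if (nrow(X) != length(y)) stop_invalid("X and y sizes differ")
  if (qr(X)$rank < ncol(X)) {
    rlang::abort("design matrix is rank deficient",
                 class = "bccstrat_rank_error")
  }
  p <- ncol(X)
  beta <- numeric(p)
  dev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- solve(XtW %*% X, XtW %*% z)
    beta <- as.vector(beta_new)
    if (any(abs(beta) > 15)) {
      rlang::abort(
        "|coefficient| exceeded 15: likely (quasi-)separation; consider a penalized fit",
        class = "bccstrat_separation_error"
      )
    }
    dev_new <- -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
    if (abs(dev - dev_new) < tol) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  if (!converged) {
    rlang::warn("IRLS did not converge; returning last iterate")
  }
  eta <- as.vector(X %*% beta)
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  info <- t(X * w) %*% X
  vcov <- solve(info)
  names(beta) <- colnames(X) %||% paste0("x", seq_len(p))
  dimnames(vcov) <- list(names(beta), names(beta))
  list(coefficients = beta, vcov = vcov, deviance = dev,
       iterations = it, converged = converged, n = length(y))
}

#' Default adjustment set for step 7
#'
#' Cardiovascular risk factors, antithrombotic medication, and IVT before
#' EVT — the covariates adjusted for in the per-cluster logistic models.
#'
#' @return Character vector of covariate column names.
#' @export
default_covariates <- function() {
  c("hypertension", "hyperlipidemia", "atrial_fibrillation",
    "diabetes_mellitus", "smoking", "prior_stroke_tia", "prior_mi",
    "antiplatelet", "doac", "ivt")
}

#' Covariate-adjusted effect of one BCC cluster on recanalization
#'
#' Complete-case logistic model of successful recanalization on one
#' standardized cluster representative plus the cardiovascular covariates,
#' fitted with [logistic_irls()]. `beta` is the log-odds of success per SD
#' of the representative (negative beta: higher values associate with
#' unsuccessful recanalization), with 95% Wald confidence bounds reported
#' on both the log-odds and odds-ratio scales.
#'
#' @param cohort Cohort tibble with `recanalization` and the covariates.
#' @param representative Numeric vector, the cluster representative for
#'   every cohort row (standardized internally).
#' @param cluster Cluster id used to label the output row.
#' @param covariates Covariate column names (default
#'   [default_covariates()]).
#' @param conf_level Wald confidence level (default 0.95).
#' @return One-row tibble: `cluster`, `beta`, `se`, `ci_low`, `ci_high`,
#'   `p`, `or`, `or_low`, `or_high`, `n_used`, `covariates_included`.
#' @export
adjusted_cluster_effect <- function(cohort, representative, cluster = NA,
                                    covariates = default_covariates(),
                                    conf_level = 0.95) {
  covariates <- intersect(covariates, names(cohort))
  if (!"recanalization" %in% names(cohort)) {
    stop_invalid("cohort has no `recanalization` column")
  }
  if (length(representative) != nrow(cohort)) {
    stop_invalid("`representative` must match the cohort rows")
  }
  y <- as.character(cohort$recanalization)
  df <- dplyr::bind_cols(
    tibble::tibble(.y = as.integer(y == "success"), .rep = representative),
    cohort[, covariates, drop = FALSE]
  )
  cc <- complete.cases(df)
  df <- df[cc, , drop = FALSE]
  n_used <- nrow(df)
  n_par <- 2L + length(covariates)
  if (n_used < 10L * n_par) {
    rlang::warn(sprintf(
      "only %d complete cases for %d parameters (< 10 per parameter)",
      n_used, n_par
    ))
  }
  rep_sd <- sd(df$.rep)
  if (rep_sd < .Machine$double.eps) {
    stop_invalid("cluster representative is constant on complete cases")
  }
  rep_std <- (df$.rep - mean(df$.rep)) / rep_sd
  X <- cbind(`(Intercept)` = 1, cluster = rep_std,
             as.matrix(df[, covariates, drop = FALSE]))
  fit <- logistic_irls(X, df$.y)
  b <- fit$coefficients[["cluster"]]
  se <- sqrt(fit$vcov["cluster", "cluster"])
  zq <- qnorm(1 - (1 - conf_level) / 2)
  zval <- b / se
  tibble::tibble(
    cluster = cluster,
    beta = b, se = se,
    ci_low = b - zq * se, ci_high = b + zq * se,
    p = 2 * stats::pnorm(-abs(zval)),
    or = exp(b), or_low = exp(b - zq * se), or_high = exp(b + zq * se),
    n_used = n_used,
    covariates_included = paste(covariates, collapse = ",")
  )
}

#' Adjusted effects for a set of stable clusters
#'
#' Runs [adjusted_cluster_effect()] for each requested cluster, building
#' representatives from the supplied partition, optionally within one sex
#' stratum, yielding a per-cluster adjusted-effects table.
#'
#' @param cohort Cohort tibble.
#' @param partition Named vector BCC -> cluster id.
#' @param clusters Cluster ids or `cluster_<id>` names.
#' @param sex Optional `"F"` or `"M"` stratum.
#' @inheritParams adjusted_cluster_effect
#' @return Tibble, one row per cluster, as in [adjusted_cluster_effect()].
#' @export
adjusted_effects <- function(cohort, partition, clusters, sex = NULL,
                             covariates = default_covariates(),
                             conf_level = 0.95) {
  if (!is.null(sex)) cohort <- cohort[cohort$sex == sex, , drop = FALSE]
  ids <- sort(unique(cluster_ids(clusters)))
  part <- partition[partition %in% ids]
  reps <- make_representatives(bcc_matrix(cohort)[, names(part),
                                                  drop = FALSE], part)
  purrr::map_dfr(ids, function(cl) {
    adjusted_cluster_effect(cohort, reps[, paste0("cluster_", cl)],
                            cluster = cl, covariates = covariates,
                            conf_level = conf_level)
  })
}

#' @rdname logistic_irls
#' @param x A list returned by [logistic_irls()].
#' @param conf_level Wald confidence level.
#' @param ... Unused.
#' @export
tidy_logistic_irls <- function(x, conf_level = 0.95, ...) {
  se <- sqrt(diag(x$vcov))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(x$coefficients / se),
    p.value = 2 * stats::pnorm(-abs(x$coefficients / se)),
    conf.low = unname(x$coefficients - zq * se),
    conf.high = unname(x$coefficients + zq * se)
  )
}
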