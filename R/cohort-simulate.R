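#' Simulate a synthetic EVT cohort with planted ground truth
#'
#' Draws a patient-level table with the statistical structure the analysis
#' pipeline assumes: BCC columns from a multivariate normal with a planted
#' block-correlation structure (blocks = collinearity clusters), sex-shifted
#' means for a designated BCC subset, a recanalization outcome from a
#' logistic model on standardized cluster representatives with sex-specific
#' coefficients, a three-class stroke etiology from a multinomial-logit
#' model, independent Bernoulli cardiovascular covariates, and optional
#' MCAR missingness on the BCC columns.
#'
#' The generator is deterministic given `config$seed`: the same config
#' yields an identical cohort.
#'
#' @param config A [bcc_config()] object.
#' @return A list of class `bcc_sim` with elements
#'   \describe{
#'     \item{cohort}{tibble, one row per patient: `patient_id`, `sex`
#'       (factor F/M), `bcc_001..`, `recanalization` (factor
#'       success/failure), `etiology` (factor CE/LAA/UND), the binary
#'       covariates, `ivt`.}
#'     \item{truth}{planted ground truth: `cluster_assignment` (named
#'       vector BCC name -> cluster id), the informative/etiology cluster
#'       sets, `sex_shift`, and the latent cluster representatives used to
#'       draw the outcomes.}
#'   }
#' @export
#' @examples
#' sim <- simulate_cohort(bcc_config(seed = 7))
#' dim(sim$cohort)
#' table(sim$cohort$sex)
simulate_cohort <- function(config) {
  if (!inherits(config, "bcc_config")) config <- validate_bcc_config(config)
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  n_f <- config$n_female
  n_m <- config$n_male
  n <- n_f + n_m
  p <- config$n_bcc
  assign <- planted_assignment(p, config$n_clusters)
  bcc_names <- sprintf("bcc_%03d", seq_len(p))

  # Block-structured correlation: rho_between everywhere, rho_within inside
  # a cluster. Positive-definite for rho_between < rho_within < 1.
  sigma <- matrix(config$rho_between, p, p)
  same <- outer(assign, assign, "==")
  sigma[same] <- config$rho_within
  diag(sigma) <- 1
  Z <- matrix(rnorm(n * p), n, p) %*% chol(sigma)

  sex <- factor(c(rep("F", n_f), rep("M", n_m)), levels = c("F", "M"))
  if (length(config$sex_shift)) {
    j <- as.integer(names(config$sex_shift))
    Z[sex == "F", j] <- sweep(Z[sex == "F", j, drop = FALSE], 2L,
                              config$sex_shift, "+")
  }
  X <- if (config$marginal == "lognormal") exp(0.5 * Z) else Z
  colnames(X) <- bcc_names

  # Latent cluster representatives (z-scored member means, re-standardized)
  # drive the outcome models; computed before missingness is applied.
  reps <- representatives_impl(X, assign)
  reps <- scale(reps)

  lp <- rep(config$recan_intercept, n)
  add_effects <- function(lp, coefs, rows) {
    if (!length(coefs)) return(lp)
    idx <- as.integer(names(coefs))
    lp[rows] <- lp[rows] +
      as.vector(reps[rows, idx, drop = FALSE] %*% unname(coefs))
    lp
  }
  inf <- config$informative_clusters
  lp <- add_effects(lp, inf$shared, seq_len(n))
  lp <- add_effects(lp, inf$female_only, which(sex == "F"))
  lp <- add_effects(lp, inf$male_only, which(sex == "M"))
  recan <- factor(ifelse(runif(n) < stats::plogis(lp), "success", "failure"),
                  levels = c("success", "failure"))

  # Multinomial logit vs UND with sex-stratum-specific cluster effects.
  lp_ce <- rep(config$etiology_intercepts[["CE"]], n)
  lp_laa <- rep(config$etiology_intercepts[["LAA"]], n)
  et <- config$etiology_clusters
  if (!is.null(et) && nrow(et)) {
    for (i in seq_len(nrow(et))) {
      rows <- switch(et$group[i],
        shared = seq_len(n),
        female_only = which(sex == "F"),
        male_only = which(sex == "M")
      )
      contrib <- et$coef[i] * reps[rows, et$cluster[i]]
      if (et$class[i] == "CE") {
        lp_ce[rows] <- lp_ce[rows] + contrib
      } else {
        lp_laa[rows] <- lp_laa[rows] + contrib
      }
    }
  }
  denom <- exp(lp_ce) + exp(lp_laa) + 1
  pr <- cbind(CE = exp(lp_ce), LAA = exp(lp_laa), UND = 1) / denom
  u <- runif(n)
  et_idx <- 1L + (u > pr[, 1L]) + (u > pr[, 1L] + pr[, 2L])
  etiology <- factor(c("CE", "LAA", "UND")[et_idx],
                     levels = c("CE", "LAA", "UND"))

  cov_draws <- purrr::imap(
    as.list(config$covariate_prevalences),
    function(prob, nm) rbinom(n, 1L, prob)
  )
  ivt <- rbinom(n, 1L, config$ivt_prevalence)

  if (config$missing_rate > 0) {
    mask <- matrix(runif(n * p) < config$missing_rate, n, p)
    X[mask] <- NA_real_
  }

  cohort <- tibble::tibble(
    patient_id = sprintf("P%04d", seq_len(n)),
    sex = sex,
    tibble::as_tibble(X),
    recanalization = recan,
    etiology = etiology,
    tibble::as_tibble(cov_draws),
    ivt = ivt
  )

  truth <- list(
    cluster_assignment = stats::setNames(assign, bcc_names),
    informative_clusters = config$informative_clusters,
    etiology_clusters = config$etiology_clusters,
    sex_shift = config$sex_shift,
    representatives = reps,
    config = config
  )
  structure(list(cohort = cohort, truth = truth), class = "bcc_sim")
}

#' @export
print.bcc_sim <- function(x, ...) {
  cat(sprintf(
    "<bcc_sim> %d patients (%d F / %d M), %d BCCs, success rate %.2f\n",
    nrow(x$cohort), sum(x$cohort$sex == "F"), sum(x$cohort$sex == "M"),
    sum(grepl("^bcc_", names(x$cohort))),
    mean(x$cohort$recanalization == "success")
  ))
  invisible(x)
}

#' Simulate radiology report texts with TICI mentions
#'
#' Writes one free-text report per patient. Each report carries a TICI
#' mention consistent with the patient's recanalization label (success =
#' grade 3, failure = a grade drawn from 0/1/2a/2b/2c) with probability
#' `1 - report_mismatch`. A configured fraction of reports contains no
#' TICI mention and another fraction a second, distinct grade; both route
#' to the manual-labeling queue downstream.
#'
#' @param cohort Cohort tibble from [simulate_cohort()].
#' @param config The same [bcc_config()] used to generate the cohort (its
#'   `report_*` fields and seed control the text).
#' @return Tibble `patient_id`, `text`, plus the planted `report_kind`
#'   (`"clean"`, `"none"`, `"conflict"`) for triage tests.
#' @export
#' @examples
#' sim <- simulate_cohort(bcc_config(n_female = 10, n_male = 10, seed = 1))
#' simulate_reports(sim$cohort, sim$truth$config)$text[1]
simulate_reports <- function(cohort, config) {
  if (!inherits(config, "bcc_config")) config <- validate_bcc_config(config)
  withr::with_seed(config$seed + 1L, {
    n <- nrow(cohort)
    failure_grades <- c("0", "1", "2a", "2b", "2c")
    grade <- ifelse(cohort$recanalization == "success", "3",
                    sample(failure_grades, n, replace = TRUE))
    flip <- runif(n) < config$report_mismatch
    flip_to_fail <- which(flip & grade == "3")
    flip_to_succ <- which(flip & grade != "3")
    grade[flip_to_fail] <- sample(failure_grades, length(flip_to_fail),
                                  replace = TRUE)
    grade[flip_to_succ] <- "3"
    u <- runif(n)
    kind <- dplyr::case_when(
      u < config$report_none_rate ~ "none",
      u < config$report_none_rate + config$report_conflict_rate ~ "conflict",
      TRUE ~ "clean"
    )
    spelling <- sample(c("TICI", "mTICI", "eTICI"), n, replace = TRUE)
    sep <- sample(c(" ", " ", "-", ": "), n, replace = TRUE)
    openers <- sample(c(
      "Mechanical thrombectomy of the M1 occlusion.",
      "EVT performed under conscious sedation.",
      "Aspiration thrombectomy, two passes.",
      "Stent-retriever thrombectomy of the carotid terminus."
    ), n, replace = TRUE)
    text <- dplyr::case_when(
      kind == "none" ~ paste(
        openers, "Procedure completed without complications.",
        "Final angiographic result documented separately."
      ),
      kind == "conflict" ~ paste0(
        openers, " Initial result ", spelling, sep,
        conflicting_grade(grade), " after the first pass; final result ",
        spelling, sep, grade, "."
      ),
      TRUE ~ paste0(
        openers, " Final angiographic result: ", spelling, sep, grade, "."
      )
    )
    tibble::tibble(patient_id = cohort$patient_id, text = text,
                   report_kind = kind)
  })
}

# A grade guaranteed distinct from the final one (next grade cyclically).
conflicting_grade <- function(grade) {
  levels_tici <- c("0", "1", "2a", "2b", "2c", "3")
  idx <- match(grade, levels_tici)
  levels_tici[idx %% length(levels_tici) + 1L]
}
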