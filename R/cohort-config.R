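#' Configuration for the synthetic EVT cohort generator
#'
#' Builds and validates the full parameterization of the synthetic-cohort
#' generator: cohort dimensions, the block-correlation structure of the
#' blood cell characteristics (BCCs), planted sex shifts, planted
#' cluster-level effects on recanalization and stroke etiology, covariate
#' prevalences, and the radiology-report corruption rates.
#'
#' Defaults mirror a single-center EVT cohort: 143 women and 190 men, 71
#' BCCs collapsing to 58 collinearity clusters (13 pairs + 45 singletons),
#' 21 sex-shifted BCCs at 0.8 SD, stable-cluster patterns of 13 shared /
#' 12 female-specific / 20 male-specific recanalization signals with a
#' 3 / 12 / 11 etiology overlap, Bernoulli covariates at the observed
#' baseline prevalences, and etiology marginals of roughly 39% / 34% / 27%
#' for cardioembolism (CE), large-artery atherosclerosis (LAA), and
#' undetermined (UND).
#'
#' @param n_female,n_male Number of women / men in the cohort.
#' @param n_bcc Number of BCC columns.
#' @param n_clusters Number of collinearity clusters planted in the BCC
#'   correlation matrix; must not exceed `n_bcc`. Cluster sizes are as even
#'   as possible (extras distributed one variable at a time from cluster 1).
#' @param rho_within,rho_between Within-block and between-block
#'   correlations; `rho_between < rho_within`.
#' @param sex_shift Named numeric vector: BCC index -> mean shift for women
#'   in SD units (positive = higher in women). Default plants 21 shifted
#'   BCCs at +/- 0.8 SD.
#' @param informative_clusters List with numeric elements `shared`,
#'   `female_only`, `male_only`: cluster index -> log-odds of successful
#'   recanalization per SD of the cluster representative. The three sets
#'   must be pairwise disjoint.
#' @param etiology_clusters Data frame with columns `cluster`, `group`
#'   (`"shared"`, `"female_only"`, `"male_only"`), `class` (`"CE"` or
#'   `"LAA"`), `coef`: multinomial log-odds (vs UND) per SD of the cluster
#'   representative, applied in the matching sex stratum.
#' @param recan_intercept Log-odds of success when all representatives are
#'   at their mean; the default gives an overall success rate near 0.48.
#' @param etiology_intercepts Length-2 named vector `c(CE = , LAA = )` of
#'   multinomial intercepts relative to UND.
#' @param covariate_prevalences Named probabilities for the binary
#'   cardiovascular covariates (independent Bernoulli draws).
#' @param ivt_prevalence Probability of intravenous thrombolysis before EVT.
#' @param missing_rate MCAR missingness fraction applied to BCC columns
#'   (in `[0, 1)`).
#' @param marginal `"gaussian"` (default) or `"lognormal"` BCC marginals;
#'   the lognormal option exponentiates the latent Gaussian block draw, so
#'   rank-based stages see the same structure.
#' @param report_mismatch Probability that a report's single TICI mention
#'   contradicts the planted recanalization label.
#' @param report_none_rate,report_conflict_rate Fractions of reports with
#'   no TICI mention / with a second, conflicting grade (these exercise the
#'   manual-labeling triage downstream).
#' @param seed Integer master seed; mandatory.
#'
#' @return A validated list of class `bcc_config`.
#' @seealso [simulate_cohort()], [simulate_reports()]
#' @export
#' @examples
#' cfg <- bcc_config(seed = 1)
#' cfg$n_bcc
bcc_config <- function(n_female = 143L,
                       n_male = 190L,
                       n_bcc = 71L,
                       n_clusters = 58L,
                       rho_within = 0.9,
                       rho_between = 0.1,
                       sex_shift = default_sex_shift(n_bcc),
                       informative_clusters = default_informative_clusters(n_clusters),
                       etiology_clusters = default_etiology_clusters(informative_clusters),
                       recan_intercept = -0.07,
                       etiology_intercepts = c(CE = log(0.39 / 0.27),
                                               LAA = log(0.34 / 0.27)),
                       covariate_prevalences = default_covariate_prevalences(),
                       ivt_prevalence = 0.342,
                       missing_rate = 0,
                       marginal = c("gaussian", "lognormal"),
                       report_mismatch = 0,
                       report_none_rate = 0.05,
                       report_conflict_rate = 0.05,
                       seed) {
  if (missing(seed)) {
    stop_invalid("`seed` is mandatory in a generator config.")
  }
  config <- list(
    n_female = check_count(n_female, "n_female"),
    n_male = check_count(n_male, "n_male"),
    n_bcc = check_count(n_bcc, "n_bcc"),
    n_clusters = check_count(n_clusters, "n_clusters"),
    rho_within = rho_within,
    rho_between = rho_between,
    sex_shift = sex_shift,
    informative_clusters = informative_clusters,
    etiology_clusters = etiology_clusters,
    recan_intercept = recan_intercept,
    etiology_intercepts = etiology_intercepts,
    covariate_prevalences = covariate_prevalences,
    ivt_prevalence = ivt_prevalence,
    missing_rate = missing_rate,
    marginal = match.arg(marginal),
    report_mismatch = report_mismatch,
    report_none_rate = report_none_rate,
    report_conflict_rate = report_conflict_rate,
    seed = check_count(seed, "seed", min = 0L)
  )
  validate_bcc_config(config)
}

validate_bcc_config <- function(config) {
  if (config$n_clusters > config$n_bcc) {
    stop_invalid("`n_clusters` must not exceed `n_bcc`.")
  }
  check_prob(config$rho_within, "rho_within")
  check_prob(config$rho_between, "rho_between")
  if (config$rho_between >= config$rho_within) {
    stop_invalid("`rho_between` must be strictly less than `rho_within`.")
  }
  check_prob(config$covariate_prevalences, "covariate_prevalences")
  check_prob(config$ivt_prevalence, "ivt_prevalence")
  check_prob(config$report_mismatch, "report_mismatch")
  check_prob(config$report_none_rate, "report_none_rate")
  check_prob(config$report_conflict_rate, "report_conflict_rate")
  if (config$report_none_rate + config$report_conflict_rate > 1) {
    stop_invalid("report none/conflict fractions must sum to at most 1.")
  }
  if (!is.numeric(config$missing_rate) || config$missing_rate < 0 ||
      config$missing_rate >= 1) {
    stop_invalid("`missing_rate` must lie in [0, 1).")
  }
  shift_idx <- as.integer(names(config$sex_shift))
  if (length(shift_idx) && (anyNA(shift_idx) || any(shift_idx < 1L) ||
                            any(shift_idx > config$n_bcc))) {
    stop_invalid("`sex_shift` names must be BCC indices in 1..n_bcc.")
  }
  inf <- config$informative_clusters
  if (!is.list(inf) ||
      !all(c("shared", "female_only", "male_only") %in% names(inf))) {
    stop_invalid(
      "`informative_clusters` needs elements shared, female_only, male_only."
    )
  }
  sets <- lapply(inf[c("shared", "female_only", "male_only")],
                 function(x) as.integer(names(x)))
  all_idx <- unlist(sets)
  if (anyDuplicated(all_idx)) {
    stop_invalid("shared/female_only/male_only cluster sets must be disjoint.")
  }
  if (length(all_idx) && (anyNA(all_idx) || any(all_idx < 1L) ||
                          any(all_idx > config$n_clusters))) {
    stop_invalid("informative cluster indices must lie in 1..n_clusters.")
  }
  et <- config$etiology_clusters
  if (!is.null(et) && nrow(et)) {
    stopifnot(all(c("cluster", "group", "class", "coef") %in% names(et)))
    if (!all(et$class %in% c("CE", "LAA"))) {
      stop_invalid("etiology classes with planted effects must be CE or LAA.")
    }
    if (!all(et$group %in% c("shared", "female_only", "male_only"))) {
      stop_invalid("etiology groups must be shared/female_only/male_only.")
    }
    if (any(et$cluster < 1L | et$cluster > config$n_clusters)) {
      stop_invalid("etiology cluster indices must lie in 1..n_clusters.")
    }
  }
  structure(config, class = "bcc_config")
}

#' @export
print.bcc_config <- function(x, ...) {
  cat("<bcc_config>\n")
  cat(sprintf("  cohort: %d women + %d men, %d BCCs in %d clusters\n",
              x$n_female, x$n_male, x$n_bcc, x$n_clusters))
  cat(sprintf("  correlation: within %.2f, between %.2f; missing %.2f\n",
              x$rho_within, x$rho_between, x$missing_rate))
  cat(sprintf("  planted: %d sex-shifted BCCs; recan clusters %d/%d/%d (shared/F/M)\n",
              length(x$sex_shift),
              length(x$informative_clusters$shared),
              length(x$informative_clusters$female_only),
              length(x$informative_clusters$male_only)))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Cluster sizes as even as possible: extras (n_bcc - n_clusters variables)
# are dealt one at a time starting at cluster 1. For 71 variables over 58
# clusters this yields 13 pairs followed by 45 singletons.
cluster_sizes <- function(n_bcc, n_clusters) {
  sizes <- rep(1L, n_clusters)
  extras <- n_bcc - n_clusters
  if (extras > 0L) {
    bump <- (seq_len(extras) - 1L) %% n_clusters + 1L
    tab <- tabulate(bump, n_clusters)
    sizes <- sizes + tab
  }
  sizes
}

planted_assignment <- function(n_bcc, n_clusters) {
  rep(seq_len(n_clusters), times = cluster_sizes(n_bcc, n_clusters))
}

# 21 sex-shifted BCCs at |delta| = 0.8 SD. Shift whole correlation blocks
# (10 pairs, sign alternating per pair, plus the first singleton) so a
# pair's members are shifted coherently and pooled within-block
# correlations stay near the target.
default_sex_shift <- function(n_bcc) {
  if (n_bcc < 27L) {
    idx <- seq_len(min(21L, n_bcc))
    return(stats::setNames(rep(0.8, length(idx)), idx))
  }
  pair_vars <- 1:20
  delta <- 0.8 * (-1)^(ceiling(pair_vars / 2) + 1)
  stats::setNames(c(delta, 0.8), c(pair_vars, 27L))
}

# Planted recanalization pattern: 13 shared, 12 female-only, 20 male-only
# informative clusters with weak alternating-sign effects, so stratified
# classifiers sit well above chance but far from perfect separation.
default_informative_clusters <- function(n_clusters, effect = 0.15) {
  pick <- function(idx) {
    stats::setNames(effect * (-1)^(seq_along(idx) + 1), idx)
  }
  n_shared <- min(13L, n_clusters)
  n_f <- min(12L, max(0L, n_clusters - n_shared))
  n_m <- min(20L, max(0L, n_clusters - n_shared - n_f))
  list(
    shared = pick(seq_len(n_shared)),
    female_only = pick(seq_len(n_f) + n_shared),
    male_only = pick(seq_len(n_m) + n_shared + n_f)
  )
}

# Etiology effects ride on a subset of the recanalization-informative
# clusters (3 shared, 12 female-only, 11 male-only), pointing mostly at CE
# for the female-specific set and LAA for the male-specific set.
default_etiology_clusters <- function(informative_clusters, effect = 0.3) {
  shared <- as.integer(names(informative_clusters$shared))
  f_only <- as.integer(names(informative_clusters$female_only))
  m_only <- as.integer(names(informative_clusters$male_only))
  sh <- utils::head(shared, 3L)
  fe <- utils::head(f_only, 12L)
  ma <- utils::head(m_only, 11L)
  tibble::tibble(
    cluster = c(sh, fe, ma),
    group = c(rep("shared", length(sh)), rep("female_only", length(fe)),
              rep("male_only", length(ma))),
    class = c(rep_len(c("LAA", "CE", "LAA"), length(sh)),
              rep_len(c("CE", "CE", "LAA"), length(fe)),
              rep_len(c("LAA", "LAA", "CE"), length(ma))),
    coef = effect
  )
}

# Marginal prevalences pooled over sexes from the baseline table of a
# single-center EVT cohort.
default_covariate_prevalences <- function() {
  c(
    hypertension = 0.565,
    hyperlipidemia = 0.405,
    atrial_fibrillation = 0.172,
    diabetes_mellitus = 0.143,
    smoking = 0.188,
    prior_stroke_tia = 0.165,
    prior_mi = 0.140,
    antiplatelet = 0.289,
    doac = 0.127
  )
}
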