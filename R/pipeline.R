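#' Eligibility filter on timestamps and EVT status
#'
#' Applies the cohort eligibility rules to raw records: patients whose EVT
#' was not performed are excluded, as are patients without a BCC panel
#' within 60 minutes of arriving at the emergency department (inclusive
#' boundary) and patients whose panel was drawn after the EVT start (only
#' pre-EVT panels are analyzable). Rows with unparseable timestamps are
#' excluded with reason `bad_timestamp`. Each excluded row gets exactly
#' one reason (first applicable in the order above), so the tally sums:
#' input = retained + sum(exclusions).
#'
#' @param records Tibble with columns `evt_performed` (logical/0-1),
#'   `arrival_time`, `bcc_time`, `evt_start` (POSIXct or parseable
#'   character timestamps); other columns pass through.
#' @param window_min BCC collection window after arrival, in minutes
#'   (default 60, inclusive).
#' @return List: `retained` (tibble of eligible rows), `exclusions`
#'   (tibble `reason`, `n`).
#' @export
eligibility_filter <- function(records, window_min = 60) {
  needed <- c("evt_performed", "arrival_time", "bcc_time", "evt_start")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop_invalid(sprintf("records lack column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  parse_ts <- function(x) {
    if (inherits(x, "POSIXct")) return(x)
    x <- as.character(x)
    vals <- vapply(x, function(el) {
      if (is.na(el)) return(NA_real_)
      v <- suppressWarnings(
        tryCatch(as.POSIXct(el, tz = "UTC"), error = function(e) NA)
      )
      as.numeric(v)[1L]
    }, numeric(1L), USE.NAMES = FALSE)
    as.POSIXct(vals, origin = "1970-01-01", tz = "UTC")
  }
  arrival <- parse_ts(records$arrival_time)
  bcc <- parse_ts(records$bcc_time)
  evt <- parse_ts(records$evt_start)
  reason <- rep(NA_character_, nrow(records))
  not_performed <- !as.logical(records$evt_performed)
  reason[is.na(reason) & not_performed] <- "evt_not_performed"
  bad <- is.na(arrival) | is.na(bcc) | is.na(evt)
  reason[is.na(reason) & bad] <- "bad_timestamp"
  mins_from_arrival <- as.numeric(difftime(bcc, arrival, units = "mins"))
  reason[is.na(reason) & mins_from_arrival > window_min] <- "no_bcc_60min"
  reason[is.na(reason) & bcc >= evt] <- "post_evt_sample"
  retained <- records[is.na(reason), , drop = FALSE]
  exclusions <- tibble::as_tibble(table(reason = reason[!is.na(reason)]),
                                  .name_repair = "minimal")
  names(exclusions) <- c("reason", "n")
  exclusions$n <- as.integer(exclusions$n)
  list(retained = retained, exclusions = exclusions)
}

#' Run the full seven-step analysis pipeline
#'
#' End-to-end orchestration on a (by default simulated) cohort:
#' (1) TICI labels from report text, with ambiguous reports falling back
#' to the reference label (emulating manual labeling); (2) FDR-corrected
#' univariate sex screen; (3) collinearity clustering with sex-concordance
#' selection of k; (4-5) pooled and sex-stratified sparse PLS-DA with
#' repeated-CV stability selection and Welch comparisons; (6) etiology
#' consistency mapping; (7) covariate-adjusted per-cluster logistic
#' models. All randomness flows from `config$seed` through named
#' substreams, so a rerun with the same config reproduces every artifact.
#'
#' @param config A [bcc_config()]; drives the simulation and seeds.
#' @param cohort,reports Optional pre-existing cohort/report tables (then
#'   the generator is skipped; reports may be `NULL` to skip text mining).
#' @param K,R,keepX_grid,ncomp,threshold Passed to the CV engine. The
#'   default `R = 100` mirrors the fivefold-CV-repeated-100-times scheme;
#'   scale `R` down for quick runs.
#' @param k_grid Candidate cluster numbers for [select_k()].
#' @param covariates Adjustment set for step 7.
#' @param etiology_classes Contrast for step 6 (default CE vs LAA).
#' @return A `bcc_pipeline` list: `labels`, `screen`, `clusters`,
#'   `stratified`, `consistency`, `adjusted` (per sex), and `manifest`
#'   (seed, parameters, row counts).
#' @export
run_bcc_pipeline <- function(config = bcc_config(seed = 1L),
                             cohort = NULL, reports = NULL,
                             K = 5L, R = 100L,
                             k_grid = 40:70,
                             keepX_grid = c(5L, 10L, 15L, 20L, 25L, 30L),
                             ncomp = 2L, threshold = 0.9,
                             covariates = default_covariates(),
                             etiology_classes = c("CE", "LAA")) {
  truth <- NULL
  if (is.null(cohort)) {
    sim <- simulate_cohort(config)
    cohort <- sim$cohort
    truth <- sim$truth
    if (is.null(reports)) reports <- simulate_reports(cohort, config)
  }
  seeds <- substream_seeds(config$seed + 2L, 2L)

  # Step 1a: text-mined outcome labels; ambiguous reports fall back to the
  # reference label, standing in for manual neurologist labeling.
  labels <- NULL
  n_manual <- 0L
  if (!is.null(reports)) {
    labels <- extract_tici(reports)
    merged <- dplyr::left_join(
      cohort, dplyr::select(labels, "patient_id", "outcome"),
      by = "patient_id"
    )
    manual <- merged$outcome == "needs_manual"
    n_manual <- sum(manual)
    mined <- ifelse(manual, as.character(merged$recanalization),
                    merged$outcome)
    cohort$recanalization <- factor(mined, levels = c("success", "failure"))
  }

  # Step 1b: univariate sex screen with BH correction.
  screen <- screen_by_sex(cohort)

  # Step 2: collinearity clustering, k chosen by sex concordance.
  X <- bcc_matrix(cohort)
  k_grid <- k_grid[k_grid <= ncol(X)]
  clusters <- select_k(X, cohort$sex, k_grid)

  # Steps 3-5: pooled + stratified sPLS-DA with stability selection.
  stratified <- stratified_comparison(
    cohort, clusters$partition, outcome = "recanalization",
    K = K, R = R, keepX_grid = keepX_grid, ncomp = ncomp,
    threshold = threshold, seed = seeds[1L]
  )

  # Step 6: etiology consistency of the stable clusters.
  consistency <- etiology_consistency(
    cohort, clusters$partition, stratified, classes = etiology_classes,
    K = K, R = R, keepX_grid = keepX_grid, ncomp = ncomp,
    threshold = threshold, seed = seeds[2L]
  )

  # Step 7: adjusted models for the per-sex dual-stable clusters (falling
  # back to the recanalization-stable set when the intersection is empty).
  adjust_for <- function(el) {
    cl <- if (length(el$both_stable)) el$both_stable else el$recan_stable
    if (!length(cl)) return(NULL)
    cl
  }
  adjusted <- list(
    female = if (!is.null(adjust_for(consistency$female))) {
      adjusted_effects(cohort, clusters$partition,
                       adjust_for(consistency$female), sex = "F",
                       covariates = covariates)
    },
    male = if (!is.null(adjust_for(consistency$male))) {
      adjusted_effects(cohort, clusters$partition,
                       adjust_for(consistency$male), sex = "M",
                       covariates = covariates)
    }
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("bccstrat")),
    seed = config$seed,
    n_input = nrow(cohort),
    n_female = sum(cohort$sex == "F"),
    n_male = sum(cohort$sex == "M"),
    n_bcc = ncol(X),
    n_reports_manual = n_manual,
    n_significant_screen = sum(screen$significant),
    k_chosen = clusters$k,
    concordance_rand = clusters$concordance,
    parameters = list(K = K, R = R, k_grid = range(k_grid),
                      keepX_grid = keepX_grid, ncomp = ncomp,
                      threshold = threshold,
                      etiology_classes = etiology_classes,
                      covariates = covariates)
  )
  structure(
    list(cohort = cohort, truth = truth, labels = labels, screen = screen,
         clusters = clusters, stratified = stratified,
         consistency = consistency, adjusted = adjusted,
         manifest = manifest),
    class = "bcc_pipeline"
  )
}

#' @export
print.bcc_pipeline <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<bcc_pipeline> %d patients (%d F / %d M), %d BCCs -> k = %d clusters\n",
    m$n_input, m$n_female, m$n_male, m$n_bcc, m$k_chosen
  ))
  cat(sprintf("  screen: %d/%d BCCs sex-different (FDR < 0.05)\n",
              m$n_significant_screen, m$n_bcc))
  print(x$stratified)
  print(x$consistency$overlap)
  invisible(x)
}
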