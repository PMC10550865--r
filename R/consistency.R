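#' Stability selection with stroke etiology as outcome
#'
#' Reruns the [repeated_cv()] stability machinery with acute-ischemic-
#' stroke etiology as the outcome, by default as the binary cardioembolism
#' (CE) vs large-artery atherosclerosis (LAA) contrast with undetermined
#' (UND) strokes excluded. Candidate variables can be restricted to the
#' clusters already found stable for recanalization, which is how the
#' etiology rerun lends biological meaning to those clusters.
#'
#' @param cohort Cohort tibble with an `etiology` column.
#' @param partition Named vector BCC -> cluster id.
#' @param candidates Optional cluster ids (or `cluster_<id>` names) to
#'   restrict the analysis to; default uses all clusters.
#' @param sex Optional `"F"` or `"M"` to restrict to one stratum.
#' @param classes Etiology classes contrasted (default `c("CE", "LAA")`);
#'   supply all three for a three-class run.
#' @param ... Passed to [repeated_cv()].
#' @param seed Integer seed.
#' @return A `bcc_stability` object for the etiology contrast.
#' @export
etiology_stability <- function(cohort, partition, candidates = NULL,
                               sex = NULL, classes = c("CE", "LAA"), ...,
                               seed) {
  if (missing(seed)) stop_invalid("`seed` is required")
  if (!"etiology" %in% names(cohort)) {
    stop_invalid("cohort has no `etiology` column")
  }
  if (!is.null(sex)) cohort <- cohort[cohort$sex == sex, , drop = FALSE]
  rows <- !is.na(cohort$etiology) & cohort$etiology %in% classes
  cohort <- cohort[rows, , drop = FALSE]
  if (!is.null(candidates)) {
    ids <- cluster_ids(candidates)
    partition <- partition[partition %in% ids]
    if (!length(partition)) {
      stop_invalid("no BCC maps to the candidate clusters")
    }
  }
  y <- factor(as.character(cohort$etiology), levels = classes)
  repeated_cv(bcc_matrix(cohort), y, partition = partition, seed = seed, ...)
}

# Accept clusters as ids (26) or representative names ("cluster_26").
cluster_ids <- function(x) {
  as.integer(sub("^cluster_", "", as.character(x)))
}

#' Assign median-based direction labels to stable clusters
#'
#' For each stable cluster, reports the outcome class in which the median
#' of the cluster representative is highest (e.g. green = successful
#' recanalization vs red = unsuccessful in a loading plot, or red = CE vs
#' yellow = LAA for the etiology outcome). An exact median tie yields
#' direction `"none"`.
#'
#' @param cohort Cohort tibble.
#' @param partition Named vector BCC -> cluster id.
#' @param clusters Stable cluster ids or `cluster_<id>` names.
#' @param outcome Outcome column name (`"recanalization"` or `"etiology"`).
#' @param classes Optional subset of outcome classes to compare (used to
#'   drop UND for the etiology outcome).
#' @return Tibble: `cluster`, one `median_<class>` column per class,
#'   `direction`.
#' @export
direction_assignment <- function(cohort, partition, clusters,
                                 outcome = "recanalization",
                                 classes = NULL) {
  if (!length(clusters)) stop_invalid("`clusters` must be non-empty")
  ids <- sort(unique(cluster_ids(clusters)))
  yy <- cohort[[outcome]]
  if (is.null(yy)) stop_invalid(sprintf("no `%s` column", outcome))
  if (is.null(classes)) classes <- levels(droplevels(as.factor(yy)))
  rows <- !is.na(yy) & yy %in% classes
  sub <- cohort[rows, , drop = FALSE]
  yy <- factor(as.character(yy[rows]), levels = classes)
  part <- partition[partition %in% ids]
  reps <- make_representatives(bcc_matrix(sub)[, names(part), drop = FALSE],
                               part)
  med <- purrr::map_dfr(ids, function(cl) {
    v <- reps[, paste0("cluster_", cl)]
    m <- vapply(classes, function(lv) median(v[yy == lv], na.rm = TRUE),
                numeric(1L))
    out <- tibble::as_tibble(as.list(setNames(m, paste0("median_", classes))))
    top <- which(m == max(m))
    out$direction <- if (length(top) > 1L) "none" else classes[top]
    out$cluster <- cl
    out
  })
  if (any(med$direction == "none")) {
    rlang::inform("exact median tie(s): direction set to \"none\"")
  }
  dplyr::relocate(med, "cluster")
}

#' Count shared and sex-specific stable clusters
#'
#' Tabulates, for each analysis stage, how many stable clusters are shared
#' between the sexes and how many are female- or male-specific.
#'
#' @param female,male Lists with character elements `recan_stable` and
#'   `both_stable` (clusters stable for recanalization, and for both
#'   recanalization and etiology).
#' @return Tibble: `stage`, `shared`, `female_specific`, `male_specific`.
#' @export
overlap_summary <- function(female, male) {
  stage_counts <- function(stage) {
    f <- unique(female[[stage]]); m <- unique(male[[stage]])
    tibble::tibble(
      stage = stage,
      shared = length(intersect(f, m)),
      female_specific = length(setdiff(f, m)),
      male_specific = length(setdiff(m, f))
    )
  }
  dplyr::bind_rows(stage_counts("recan_stable"), stage_counts("both_stable"))
}

#' Map consistency of stable clusters across outcomes and sexes
#'
#' The dual-outcome consistency step: starting from the sex-stratified
#' recanalization stability results, reruns stability selection per sex
#' with etiology (CE vs LAA by default) as the outcome, restricted to each
#' sex's recanalization-stable clusters; intersects the two stable sets;
#' computes median-based direction labels for both outcomes; and tabulates
#' shared vs sex-specific clusters.
#'
#' @param cohort Cohort tibble.
#' @param partition Named vector BCC -> cluster id.
#' @param stratified A `bcc_stratified` result from
#'   [stratified_comparison()] (its female/male stable sets seed the
#'   candidate lists).
#' @param classes Etiology classes for the contrast (default CE vs LAA).
#' @param ... Passed to [repeated_cv()] via [etiology_stability()].
#' @param seed Master seed (per-sex substreams drawn from it).
#' @return A `bcc_consistency` object: per-sex lists (`recan_stable`,
#'   `etiology_stable`, `both_stable`, `etiology_model`, `direction`),
#'   and `overlap` (the [overlap_summary()] table).
#' @export
etiology_consistency <- function(cohort, partition, stratified,
                                 classes = c("CE", "LAA"), ..., seed) {
  if (missing(seed)) stop_invalid("`seed` is required")
  if (!inherits(stratified, "bcc_stratified")) {
    stop_invalid("`stratified` must come from stratified_comparison()")
  }
  seeds <- substream_seeds(seed, 2L)
  per_sex <- function(sx, model, s) {
    recan_stable <- model$stable_set
    if (!length(recan_stable)) {
      return(list(recan_stable = character(0),
                  etiology_stable = character(0),
                  both_stable = character(0),
                  etiology_model = NULL, direction = NULL))
    }
    et <- etiology_stability(cohort, partition, candidates = recan_stable,
                             sex = sx, classes = classes, ..., seed = s)
    both <- intersect(recan_stable, et$stable_set)
    direction <- NULL
    if (length(both)) {
      dir_recan <- direction_assignment(
        cohort[cohort$sex == sx, , drop = FALSE], partition, both,
        outcome = "recanalization"
      )
      dir_et <- direction_assignment(
        cohort[cohort$sex == sx, , drop = FALSE], partition, both,
        outcome = "etiology", classes = classes
      )
      direction <- dplyr::left_join(
        dplyr::select(dir_recan, "cluster", recan_direction = "direction"),
        dplyr::select(dir_et, "cluster", etiology_direction = "direction"),
        by = "cluster"
      )
    }
    list(recan_stable = recan_stable, etiology_stable = et$stable_set,
         both_stable = both, etiology_model = et, direction = direction)
  }
  female <- per_sex("F", stratified$models$female, seeds[1L])
  male <- per_sex("M", stratified$models$male, seeds[2L])
  structure(
    list(female = female, male = male,
         overlap = overlap_summary(female, male),
         classes = classes, seed = seed),
    class = "bcc_consistency"
  )
}

#' @export
print.bcc_consistency <- function(x, ...) {
  cat("<bcc_consistency> stable clusters (recan / etiology / both):\n")
  cat(sprintf("  female: %d / %d / %d\n", length(x$female$recan_stable),
              length(x$female$etiology_stable),
              length(x$female$both_stable)))
  cat(sprintf("  male:   %d / %d / %d\n", length(x$male$recan_stable),
              length(x$male$etiology_stable), length(x$male$both_stable)))
  print(x$overlap)
  invisible(x)
}

#' @describeIn etiology_consistency Long per-cluster table with stability
#'   stage and direction labels per sex.
#' @param x A `bcc_consistency` object.
#' @param ... Unused.
#' @export
tidy.bcc_consistency <- function(x, ...) {
  one <- function(sx, el) {
    if (!length(el$recan_stable)) return(NULL)
    out <- tibble::tibble(
      sex = sx,
      cluster = cluster_ids(el$recan_stable),
      etiology_stable = el$recan_stable %in% el$etiology_stable
    )
    if (!is.null(el$direction)) {
      out <- dplyr::left_join(out, el$direction, by = "cluster")
    }
    out
  }
  dplyr::bind_rows(one("F", x$female), one("M", x$male))
}
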