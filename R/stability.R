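#' Repeated stratified cross-validation with stability selection
#'
#' The validation engine behind the stability analysis: `R` repeats of
#' stratified `K`-fold cross-validation of a sparse PLS-DA classifier.
#' Within every training fold, cluster representatives are rebuilt from
#' training-fold means/SDs (when a `partition` is supplied), `keepX` is
#' tuned on an inner stratified holdout of the training fold, the model is
#' fitted and the held-out fold predicted. Each fold-fit records which
#' variables carried nonzero component weights; the selection frequency of
#' a variable is the fraction of all `K * R` fold-fits that selected it,
#' and the stable set contains the variables whose component-1 frequency
#' strictly exceeds `threshold`.
#'
#' @param X Patients x variables matrix. If `partition` is given, `X` holds
#'   the raw BCCs and cluster representatives are constructed inside each
#'   fold; otherwise the columns of `X` are used as-is.
#' @param y Class labels (each class needs at least `K` members).
#' @param partition Optional named vector variable -> cluster id.
#' @param K Folds (default 5). @param R Repeats (default 100).
#' @param keepX_grid Candidate `keepX` values tuned per component on an
#'   inner 75/25 stratified holdout of each training fold; a length-1 grid
#'   skips tuning.
#' @param ncomp Number of sPLS-DA components (default 2).
#' @param threshold Stability threshold on the component-1 selection
#'   frequency (strict inequality; default 0.9).
#' @param distance_rule Passed to [fit_splsda()].
#' @param seed Integer seed; the whole run is reproducible given it.
#' @return A `bcc_stability` object: `error_rates` (length `R`, mean fold
#'   error per repeat), `mean_error`, `sd_error`, `selection_frequency`
#'   (tibble variable x component), `stable_set`, plus the settings.
#' @export
#' @examples
#' sim <- simulate_cohort(bcc_config(n_female = 40, n_male = 40, seed = 4))
#' st <- repeated_cv(bcc_matrix(sim$cohort), sim$cohort$recanalization,
#'                   partition = sim$truth$cluster_assignment,
#'                   K = 3, R = 2, keepX_grid = 5, seed = 9)
#' st$mean_error
repeated_cv <- function(X, y, partition = NULL, K = 5L, R = 100L,
                        keepX_grid = c(5L, 10L, 15L, 20L, 25L, 30L),
                        ncomp = 2L, threshold = 0.9,
                        distance_rule = "max_dist", seed) {
  if (missing(seed)) stop_invalid("`seed` is required")
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  K <- check_count(K, "K", min = 2L)
  R <- check_count(R, "R")
  if (any(table(y) < K)) {
    stop_invalid(sprintf("every class needs at least K = %d members", K))
  }
  n_feat <- if (is.null(partition)) ncol(X) else length(unique(partition))
  keepX_grid <- sort(unique(pmin(as.integer(keepX_grid), n_feat)))
  ncomp <- min(as.integer(ncomp), n_feat)
  feat_names <- if (is.null(partition)) {
    colnames(X) %||% paste0("V", seq_len(ncol(X)))
  } else {
    paste0("cluster_", sort(unique(partition)))
  }

  sel_counts <- matrix(0L, n_feat, ncomp, dimnames = list(feat_names, NULL))
  error_rates <- numeric(R)
  fold_seeds <- substream_seeds(seed, R)
  for (r in seq_len(R)) {
    res_r <- withr::with_seed(fold_seeds[r], {
      folds <- stratified_folds(y, K)
      fold_err <- numeric(K)
      counts <- matrix(0L, n_feat, ncomp)
      for (k in seq_len(K)) {
        test_idx <- which(folds == k)
        train_idx <- which(folds != k)
        # stratification guarantees all classes in training when counts >= K;
        # refold defensively if a degenerate split ever occurs
        guard <- 0L
        while (length(unique(y[train_idx])) < nlevels(y) && guard < 10L) {
          folds <- stratified_folds(y, K)
          test_idx <- which(folds == k)
          train_idx <- which(folds != k)
          guard <- guard + 1L
        }
        if (is.null(partition)) {
          Xtr <- X[train_idx, , drop = FALSE]
          Xte <- X[test_idx, , drop = FALSE]
        } else {
          Xtr <- make_representatives(X[train_idx, , drop = FALSE],
                                      partition)
          Xte <- make_representatives(X[test_idx, , drop = FALSE], partition,
                                      center = attr(Xtr, "center"),
                                      scale = attr(Xtr, "scale"))
        }
        # warnings from the thousands of inner fits (rare non-convergence,
        # component truncation on tiny candidate sets) would flood the log
        suppressWarnings({
          keepx <- tune_keepx(Xtr, y[train_idx], keepX_grid, ncomp,
                              distance_rule)
          fit <- fit_splsda(Xtr, y[train_idx], ncomp = ncomp, keepX = keepx,
                            distance_rule = distance_rule)
        })
        fold_err[k] <- error_rate(predict(fit, Xte), y[test_idx])
        nz <- fit$weights != 0
        counts[, seq_len(ncol(nz))] <- counts[, seq_len(ncol(nz)),
                                              drop = FALSE] + nz
      }
      list(err = mean(fold_err), counts = counts)
    })
    error_rates[r] <- res_r$err
    sel_counts <- sel_counts + res_r$counts
  }

  freq <- sel_counts / (K * R)
  selection_frequency <- tibble::tibble(
    variable = rep(feat_names, ncomp),
    component = rep(seq_len(ncomp), each = n_feat),
    frequency = as.vector(freq)
  )
  stable_set <- feat_names[freq[, 1L] > threshold]
  structure(
    list(
      error_rates = error_rates,
      mean_error = mean(error_rates),
      sd_error = sd(error_rates),
      selection_frequency = selection_frequency,
      stable_set = stable_set,
      threshold = threshold, K = K, R = R, ncomp = ncomp,
      keepX_grid = keepX_grid, seed = seed
    ),
    class = "bcc_stability"
  )
}

# Sequential per-component keepX tuning on a single stratified 75/25
# holdout of the training fold: cheap, leakage-free (uses training rows
# only), and deterministic under the caller's RNG state.
tune_keepx <- function(Xtr, ytr, grid, ncomp, distance_rule) {
  if (length(grid) == 1L) return(rep_len(grid, ncomp))
  folds <- stratified_folds(ytr, 4L)
  val_idx <- which(folds == 1L)
  fit_idx <- which(folds != 1L)
  chosen <- integer(0)
  for (h in seq_len(ncomp)) {
    errs <- vapply(grid, function(g) {
      fit <- fit_splsda(Xtr[fit_idx, , drop = FALSE], ytr[fit_idx],
                        ncomp = h, keepX = c(chosen, g),
                        distance_rule = distance_rule,
                        tol = 1e-6, max_iter = 100L)
      error_rate(predict(fit, Xtr[val_idx, , drop = FALSE]), ytr[val_idx])
    }, numeric(1L))
    chosen <- c(chosen, grid[which.min(errs)])  # ties -> smallest keepX
  }
  chosen
}

#' Welch two-sample t-test between error-rate distributions
#'
#' Welch statistic with Welch-Satterthwaite degrees of freedom and a
#' two-sided p-value, as used to compare the pooled and sex-stratified
#' cross-validation error distributions.
#'
#' @param e1,e2 Numeric vectors (length >= 2; at least one with nonzero
#'   variance).
#' @return One-row tibble: `t`, `df`, `p`, `mean1`, `mean2`.
#' @export
#' @examples
#' welch_t(rnorm(20, 0.41, 0.02), rnorm(20, 0.43, 0.02))
welch_t <- function(e1, e2) {
  if (length(e1) < 2L || length(e2) < 2L) {
    stop_invalid("each sample needs length >= 2")
  }
  if (sd(e1) < .Machine$double.eps && sd(e2) < .Machine$double.eps) {
    stop_invalid("both samples have zero variance; Welch test undefined")
  }
  ht <- t.test(e1, e2, var.equal = FALSE)
  tibble::tibble(
    t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
    mean1 = mean(e1), mean2 = mean(e2)
  )
}

#' Pooled vs sex-stratified sPLS-DA comparison
#'
#' Runs [repeated_cv()] on the pooled cohort and on the women-only and
#' men-only strata with common settings, and compares the three error-rate
#' distributions pairwise with Welch t-tests. This is the core
#' stratification contrast: a lower stratified error indicates that
#' sex-specific models explain the outcome better than a pooled model.
#'
#' @param cohort Cohort tibble (needs `sex` and the outcome column).
#' @param partition Named vector BCC -> cluster id (e.g. from [select_k()]).
#' @param outcome Name of the outcome column (default `"recanalization"`).
#' @param ... Passed to [repeated_cv()] (`K`, `R`, `keepX_grid`, `ncomp`,
#'   `threshold`, `distance_rule`).
#' @param seed Master seed; pooled/female/male runs draw substream seeds
#'   from it.
#' @return A `bcc_stratified` object: `models` (list of three
#'   `bcc_stability` results: pooled, female, male), `welch` (pairwise
#'   comparisons tibble), `errors` (long tibble of per-repeat errors).
#' @export
stratified_comparison <- function(cohort, partition,
                                  outcome = "recanalization", ..., seed) {
  if (missing(seed)) stop_invalid("`seed` is required")
  if (!outcome %in% names(cohort)) {
    stop_invalid(sprintf("no `%s` column in cohort", outcome))
  }
  if (length(unique(cohort$sex)) < 2L) {
    stop_invalid("both sexes must be present")
  }
  keep <- !is.na(cohort[[outcome]])
  cohort <- cohort[keep, , drop = FALSE]
  X <- bcc_matrix(cohort)
  y <- cohort[[outcome]]
  seeds <- substream_seeds(seed, 3L)
  run <- function(rows, s) {
    repeated_cv(X[rows, , drop = FALSE], y[rows], partition = partition,
                seed = s, ...)
  }
  models <- list(
    pooled = run(seq_len(nrow(X)), seeds[1L]),
    female = run(which(cohort$sex == "F"), seeds[2L]),
    male = run(which(cohort$sex == "M"), seeds[3L])
  )
  pairs <- list(c("female", "pooled"), c("male", "pooled"),
                c("female", "male"))
  welch <- purrr::map_dfr(pairs, function(pr) {
    dplyr::bind_cols(
      tibble::tibble(comparison = paste(pr, collapse = " vs ")),
      welch_t(models[[pr[1L]]]$error_rates, models[[pr[2L]]]$error_rates)
    )
  })
  errors <- purrr::imap_dfr(models, function(m, nm) {
    tibble::tibble(model = nm, repeat_id = seq_along(m$error_rates),
                   error = m$error_rates)
  })
  errors$model <- factor(errors$model, levels = c("pooled", "female", "male"))
  structure(list(models = models, welch = welch, errors = errors,
                 outcome = outcome, seed = seed),
            class = "bcc_stratified")
}

#' @export
print.bcc_stability <- function(x, ...) {
  cat(sprintf(
    "<bcc_stability> %d-fold CV x %d repeats: error %.3f (SD = %.3f); %d stable variable(s) at > %.2f\n",
    x$K, x$R, x$mean_error, x$sd_error, length(x$stable_set), x$threshold
  ))
  invisible(x)
}

#' @describeIn repeated_cv Selection frequencies as a tibble.
#' @param x,object A `bcc_stability` object.
#' @param ... Unused.
#' @export
tidy.bcc_stability <- function(x, ...) {
  dplyr::mutate(x$selection_frequency,
                stable = .data$component == 1L &
                  .data$frequency > x$threshold)
}

#' @describeIn repeated_cv One-row summary (mean/SD error, stable count).
#' @export
glance.bcc_stability <- function(x, ...) {
  tibble::tibble(
    K = x$K, R = x$R,
    mean_error = x$mean_error, sd_error = x$sd_error,
    n_stable = length(x$stable_set), threshold = x$threshold
  )
}

#' @describeIn repeated_cv Component-1 selection-frequency profile with the
#'   stability threshold marked.
#' @export
autoplot.bcc_stability <- function(object, ...) {
  df <- dplyr::filter(object$selection_frequency, .data$component == 1L)
  df <- dplyr::arrange(df, dplyr::desc(.data$frequency))
  df$variable <- factor(df$variable, levels = df$variable)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variable,
                                   y = .data$frequency)) +
    ggplot2::geom_col(fill = "grey55") +
    ggplot2::geom_hline(yintercept = object$threshold, color = "red") +
    ggplot2::labs(x = NULL, y = "selection frequency (component 1)",
                  title = sprintf("Stability selection (threshold %.2f)",
                                  object$threshold)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' @export
print.bcc_stratified <- function(x, ...) {
  cat("<bcc_stratified> mean CV error by model:\n")
  for (nm in names(x$models)) {
    cat(sprintf("  %-6s %.3f (SD = %.3f), %d stable\n", nm,
                x$models[[nm]]$mean_error, x$models[[nm]]$sd_error,
                length(x$models[[nm]]$stable_set)))
  }
  invisible(x)
}

#' @describeIn stratified_comparison Pairwise Welch comparisons.
#' @param x,object A `bcc_stratified` object.
#' @param ... Unused.
#' @export
tidy.bcc_stratified <- function(x, ...) x$welch

#' @describeIn stratified_comparison One row per model with mean/SD error.
#' @export
glance.bcc_stratified <- function(x, ...) {
  purrr::imap_dfr(x$models, function(m, nm) {
    dplyr::bind_cols(tibble::tibble(model = nm), glance(m))
  })
}

#' @describeIn stratified_comparison Error-rate distributions of the
#'   pooled, female and male models.
#' @export
autoplot.bcc_stratified <- function(object, ...) {
  ggplot2::ggplot(object$errors, ggplot2::aes(x = .data$model,
                                              y = .data$error,
                                              fill = .data$model)) +
    ggplot2::geom_boxplot(alpha = 0.7, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "mean CV error per repeat",
                  title = "Pooled vs sex-stratified classification error") +
    ggplot2::theme_minimal()
}
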