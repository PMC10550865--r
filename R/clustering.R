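#' Spearman correlation distance between BCCs
#'
#' Pairwise distance `d(i, j) = 1 - |rho_Spearman(i, j)|` on
#' pairwise-complete observations. The absolute value makes strongly
#' anti-correlated variables close, and the rank correlation makes the
#' distance invariant to monotone transforms of each variable. A constant
#' column has undefined correlation; it is placed at distance 1 from every
#' other variable, with a warning.
#'
#' @param X Numeric matrix or data frame, patients x variables.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
correlation_distance <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop_invalid("need at least two variables")
  rho <- suppressWarnings(cor(X, method = "spearman",
                              use = "pairwise.complete.obs"))
  if (anyNA(rho)) {
    rlang::warn(
      "constant (or all-missing-overlap) columns: distance set to 1"
    )
    rho[is.na(rho)] <- 0
  }
  d <- 1 - abs(rho)
  diag(d) <- 0
  # numeric guard: correlations can exceed 1 by eps
  d[d < 0] <- 0
  (d + t(d)) / 2
}

#' Cut an average-linkage tree at k clusters
#'
#' Agglomerative hierarchical clustering (average linkage) of a
#' variable-by-variable distance matrix, cut at `k` clusters. Deterministic
#' given the distance matrix and `k`.
#'
#' @param D Distance matrix from [correlation_distance()].
#' @param k Number of clusters, `1 <= k <= ncol(D)`.
#' @return Named integer vector variable -> cluster id (1..k).
#' @export
cluster_variables <- function(D, k) {
  D <- as.matrix(D)
  p <- ncol(D)
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > p) {
    stop_invalid(sprintf("`k` must lie in 1..%d", p))
  }
  hc <- hclust(as.dist(D), method = "average")
  cutree(hc, k = as.integer(k))
}

#' Rand index and adjusted Rand index between two partitions
#'
#' Pair-counting agreement between two partitions of the same items: the
#' Rand index is the fraction of item pairs on which the partitions agree
#' (together in both, or apart in both); the adjusted Rand index (ARI)
#' corrects it for chance agreement under the permutation model.
#'
#' @param p1,p2 Partition vectors over the same items (same length; names,
#'   if present on both, must match).
#' @return One-row tibble: `rand` in `[0, 1]` and `adjusted_rand` (<= 1).
#' @export
#' @examples
#' rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2))
rand_index <- function(p1, p2) {
  if (length(p1) != length(p2)) {
    stop_invalid("partitions must cover the same items")
  }
  if (!is.null(names(p1)) && !is.null(names(p2))) {
    if (!setequal(names(p1), names(p2))) {
      stop_invalid("partition label sets do not match")
    }
    p2 <- p2[names(p1)]
  }
  n <- length(p1)
  if (n < 2L) stop_invalid("need at least two items")
  tab <- table(p1, p2)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_i <- sum(choose2(rowSums(tab)))
  sum_j <- sum(choose2(colSums(tab)))
  total <- choose2(n)
  # agreements = pairs together in both + pairs apart in both
  rand <- (total + 2 * sum_ij - sum_i - sum_j) / total
  expected <- sum_i * sum_j / total
  max_index <- (sum_i + sum_j) / 2
  ari <- if (abs(max_index - expected) < .Machine$double.eps) {
    1  # both partitions degenerate (all-singletons or single cluster)
  } else {
    (sum_ij - expected) / (max_index - expected)
  }
  tibble::tibble(rand = rand, adjusted_rand = ari)
}

#' Select the number of BCC clusters by sex concordance
#'
#' For each candidate `k`, clusters the women-only and men-only Spearman
#' distance matrices separately and scores the agreement of the two
#' partitions by the adjusted Rand index. The chosen `k` maximizes this
#' sex concordance (ties go to the smallest `k`); the final partition is
#' then fitted on the pooled data at the chosen `k`, and cluster
#' representatives are constructed.
#'
#' @param X Patients x variables BCC matrix (or data frame).
#' @param sex Factor/vector with levels F and M, one per row of `X`.
#' @param k_grid Candidate numbers of clusters.
#' @return A `bcc_clusters` object: `partition` (named vector), `k`,
#'   `concordance` (Rand index between the sex-specific partitions at the
#'   chosen `k`), `concordance_ari`, `path` (tibble k x ARI), and
#'   `representatives` (patients x k matrix; see [make_representatives()]).
#' @export
select_k <- function(X, sex, k_grid) {
  X <- as.matrix(X)
  sex <- as.factor(sex)
  if (nrow(X) != length(sex)) stop_invalid("`sex` must match rows of `X`")
  if (length(unique(sex[!is.na(sex)])) < 2L) {
    stop_invalid("both sexes must be present to score concordance")
  }
  k_grid <- sort(unique(as.integer(k_grid)))
  if (any(k_grid < 1L) || any(k_grid > ncol(X))) {
    stop_invalid("`k_grid` out of range")
  }
  d_f <- correlation_distance(X[sex == "F", , drop = FALSE])
  d_m <- correlation_distance(X[sex == "M", , drop = FALSE])
  hc_f <- hclust(as.dist(d_f), method = "average")
  hc_m <- hclust(as.dist(d_m), method = "average")
  path <- purrr::map_dfr(k_grid, function(k) {
    ri <- rand_index(cutree(hc_f, k), cutree(hc_m, k))
    tibble::tibble(k = k, rand = ri$rand, adjusted_rand = ri$adjusted_rand)
  })
  best <- path$k[which.max(path$adjusted_rand)]  # which.max: first max = smallest k
  d_pool <- correlation_distance(X)
  partition <- cluster_variables(d_pool, best)
  names(partition) <- colnames(X)
  reps <- make_representatives(X, partition)
  structure(
    list(
      partition = partition,
      k = best,
      concordance = path$rand[path$k == best],
      concordance_ari = path$adjusted_rand[path$k == best],
      path = path,
      representatives = reps
    ),
    class = "bcc_clusters"
  )
}

#' Build synthetic cluster-representative variables
#'
#' The representative of a cluster is the mean of its member BCCs after
#' z-scoring each member; a singleton cluster passes through z-scored.
#' When called inside cross-validation, supply `center`/`scale` computed on
#' the training rows so test rows are standardized without leakage.
#' Members with zero SD are excluded from the mean with a warning.
#'
#' @param X Patients x variables matrix (columns must cover the partition).
#' @param partition Named vector variable -> cluster id.
#' @param center,scale Optional per-variable standardization constants
#'   (defaults: computed from `X`).
#' @return Patients x k matrix, columns `cluster_<id>`, with attributes
#'   `center` and `scale` for reuse on new data.
#' @export
make_representatives <- function(X, partition, center = NULL, scale = NULL) {
  X <- as.matrix(X)
  if (!is.null(names(partition))) {
    missing_vars <- setdiff(names(partition), colnames(X))
    if (length(missing_vars)) {
      stop_invalid(sprintf("variables not in X: %s",
                           paste(head(missing_vars, 3L), collapse = ", ")))
    }
    X <- X[, names(partition), drop = FALSE]
  } else if (length(partition) != ncol(X)) {
    stop_invalid("partition must cover all columns of X")
  }
  sds <- if (is.null(scale)) col_sds(X) else scale
  drop_cols <- which(is.na(sds) | sds < .Machine$double.eps)
  if (length(drop_cols)) {
    rlang::warn("zero-SD member(s) excluded from cluster representatives")
  }
  Xs <- standardize_cols(X, center = center, scale = scale)
  if (length(drop_cols)) Xs[, drop_cols] <- NA_real_
  out <- representatives_impl(Xs, partition, standardized = TRUE)
  out[is.nan(out)] <- 0  # cluster whose members are all constant
  attr(out, "center") <- attr(Xs, "center")
  attr(out, "scale") <- attr(Xs, "scale")
  out
}

# Core representative computation: per-cluster mean of z-scored members,
# missing values dropped row-wise. Columns set to NA upstream (zero-SD
# members) are thereby excluded from the mean.
representatives_impl <- function(X, partition, standardized = FALSE) {
  if (!standardized) X <- standardize_cols(X)
  ids <- sort(unique(partition))
  if (!anyNA(X)) {
    # single matrix product: B[j, cl] = 1/size(cl) for members of cl
    cl_idx <- match(partition, ids)
    B <- matrix(0, ncol(X), length(ids))
    sizes <- tabulate(cl_idx, length(ids))
    B[cbind(seq_len(ncol(X)), cl_idx)] <- 1 / sizes[cl_idx]
    out <- X %*% B
  } else {
    out <- vapply(ids, function(cl) {
      members <- which(partition == cl)
      rowMeans(X[, members, drop = FALSE], na.rm = TRUE)
    }, numeric(nrow(X)))
    out <- matrix(out, nrow = nrow(X))
  }
  colnames(out) <- paste0("cluster_", ids)
  out
}

#' @export
print.bcc_clusters <- function(x, ...) {
  cat(sprintf(
    "<bcc_clusters> %d variables in k = %d clusters; sex concordance Rand %.3f (ARI %.3f)\n",
    length(x$partition), x$k, x$concordance, x$concordance_ari
  ))
  invisible(x)
}

#' @describeIn select_k Tidy the variable -> cluster mapping (a
#'   cluster-membership lookup table).
#' @param x,object A `bcc_clusters` object.
#' @param ... Unused.
#' @export
tidy.bcc_clusters <- function(x, ...) {
  tibble::tibble(
    variable = names(x$partition),
    cluster = unname(x$partition)
  ) |>
    dplyr::arrange(.data$cluster, .data$variable)
}

#' @describeIn select_k One-row model summary.
#' @export
glance.bcc_clusters <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n_variables = length(x$partition),
    concordance_rand = x$concordance,
    concordance_ari = x$concordance_ari
  )
}

#' @describeIn select_k Concordance path over the `k` grid.
#' @export
autoplot.bcc_clusters <- function(object, ...) {
  ggplot2::ggplot(object$path, ggplot2::aes(x = .data$k,
                                            y = .data$adjusted_rand)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = 2,
                        color = "red") +
    ggplot2::labs(
      x = "number of clusters k",
      y = "adjusted Rand (women vs men partitions)",
      title = sprintf("Cluster-number selection: k = %d", object$k)
    ) +
    ggplot2::theme_minimal()
}
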