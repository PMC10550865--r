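#' Dummy-code class labels for PLS-DA
#'
#' Builds the n x C zero/one indicator matrix of class membership used as
#' the response block of PLS discriminant analysis. Column order follows
#' factor levels, or order of first appearance for non-factor input.
#'
#' @param y Class labels (factor or vector), at least two classes.
#' @return n x C 0/1 matrix with class names as columns.
#' @export
#' @examples
#' dummy_code(c("success", "failure", "success"))
dummy_code <- function(y) {
  if (!is.factor(y)) y <- factor(y, levels = unique(as.character(y)))
  y <- droplevels(y)
  if (nlevels(y) < 2L) stop_invalid("need at least two classes")
  if (anyNA(y)) stop_invalid("class labels must be non-missing")
  out <- matrix(0L, length(y), nlevels(y),
                dimnames = list(NULL, levels(y)))
  out[cbind(seq_along(y), as.integer(y))] <- 1L
  out
}

#' Soft-threshold a weight vector to a fixed number of nonzeros
#'
#' The sparsity operator of sparse PLS: entries whose magnitude falls below
#' the (keep+1)-th largest are zeroed, the surviving entries are shrunk
#' toward zero by that magnitude, and the result is renormalized to unit
#' norm. Ties at the cutoff are broken by first index. In the degenerate
#' case where every surviving entry is exactly tied with the cutoff
#' (shrinkage would zero the whole vector), the surviving entries are kept
#' unshrunk (hard threshold) so a direction is always returned.
#'
#' @param v Numeric vector.
#' @param keep Number of nonzero entries to retain, `1 <= keep <= length(v)`.
#' @return Unit-norm vector with (at most ties excepted) `keep` nonzeros.
#' @export
#' @examples
#' soft_threshold(c(3, 1, -2), keep = 1)
soft_threshold <- function(v, keep) {
  p <- length(v)
  if (!is.numeric(keep) || length(keep) != 1L || keep < 1L || keep > p) {
    stop_invalid(sprintf("`keep` must lie in 1..%d", p))
  }
  nv <- sqrt(sum(v^2))
  if (nv < .Machine$double.eps) stop_invalid("cannot threshold a zero vector")
  if (keep == p) return(v / nv)
  a <- abs(v)
  # radix sort is stable: ties keep the earliest index
  ord <- order(a, decreasing = TRUE, method = "radix")
  lambda <- a[ord[keep + 1L]]
  idx <- ord[seq_len(keep)]
  w <- numeric(p)
  w[idx] <- sign(v[idx]) * (a[idx] - lambda)
  if (all(w == 0)) w[idx] <- v[idx]  # all retained entries tied with cutoff
  w / sqrt(sum(w^2))
}

#' Fit a sparse PLS discriminant analysis model
#'
#' From-scratch sparse PLS-DA by soft-thresholded NIPALS. Per component,
#' the X-weight vector is the dominant direction of the X-Y cross
#' covariance (Y dummy-coded and column-centered), with [soft_threshold()]
#' applied at every power-iteration step to retain `keepX[h]` variables;
#' after convergence X (and Y) are deflated by regression on the component
#' score. Predictors are standardized with training means/SDs stored on
#' the model. The sign of each weight vector is fixed so its
#' largest-magnitude entry is positive, making fits reproducible
#' run-to-run.
#'
#' @param X Numeric matrix/data frame of predictors (no missing values).
#' @param y Class labels, length `nrow(X)`.
#' @param ncomp Number of components (default 2).
#' @param keepX Integer vector (recycled to `ncomp`): nonzero weights per
#'   component. Default keeps all variables (dense PLS-DA).
#' @param distance_rule Classification rule for [predict.bcc_splsda()]:
#'   `"max_dist"` (largest predicted class indicator; default),
#'   `"centroid"` (nearest class centroid in score space), or
#'   `"mahalanobis"` (centroid distance whitened by the pooled
#'   within-class score covariance).
#' @param tol,max_iter NIPALS convergence tolerance on the weight vector
#'   and iteration cap; non-convergence warns and keeps the last iterate.
#' @return A `bcc_splsda` object: `weights` (p x ncomp sparse weight
#'   matrix), `x_loadings`, `y_loadings`, `x_scores`, `class_centroids`,
#'   `train_means`, `train_sds`, `y_levels`, `keepX`, `distance_rule`.
#' @export
#' @examples
#' sim <- simulate_cohort(bcc_config(n_female = 50, n_male = 50, seed = 3))
#' X <- bcc_matrix(sim$cohort)[, 1:10]
#' fit <- fit_splsda(X, sim$cohort$recanalization, ncomp = 2, keepX = 5)
#' table(predict(fit, X), sim$cohort$recanalization)
fit_splsda <- function(X, y, ncomp = 2L, keepX = NULL,
                       distance_rule = c("max_dist", "centroid",
                                         "mahalanobis"),
                       tol = 1e-9, max_iter = 500L) {
  distance_rule <- match.arg(distance_rule)
  X <- as.matrix(X)
  if (anyNA(X)) stop_invalid("X must be complete; impute or filter upstream")
  n <- nrow(X); p <- ncol(X)
  ncomp <- check_count(ncomp, "ncomp")
  if (n <= ncomp) stop_invalid("need n > ncomp")
  if (length(y) != n) stop_invalid("y must match rows of X")
  if (is.null(keepX)) keepX <- p
  keepX <- rep_len(as.integer(keepX), ncomp)
  if (any(keepX < 1L) || any(keepX > p)) {
    stop_invalid(sprintf("keepX must lie in 1..%d", p))
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))

  Xs <- standardize_cols(X)
  train_means <- attr(Xs, "center")
  train_sds <- attr(Xs, "scale")
  Y <- dummy_code(y)
  y_levels <- colnames(Y)
  y_means <- colMeans(Y)
  Yc <- sweep(Y, 2L, y_means, "-")

  W <- matrix(0, p, ncomp, dimnames = list(colnames(X), NULL))
  P <- matrix(0, p, ncomp, dimnames = list(colnames(X), NULL))
  Q <- matrix(0, ncol(Y), ncomp, dimnames = list(y_levels, NULL))
  Tm <- matrix(0, n, ncomp)
  Xh <- Xs; Yh <- Yc
  ncomp_eff <- ncomp
  for (h in seq_len(ncomp)) {
    M <- crossprod(Xh, Yh)  # p x C cross-covariance (up to 1/(n-1))
    if (sqrt(sum(M^2)) < 1e-12) {
      if (h == 1L) stop_invalid("X carries no covariance with the classes")
      rlang::warn(sprintf(
        "cross-covariance exhausted after %d component(s); truncating ncomp",
        h - 1L
      ))
      ncomp_eff <- h - 1L
      break
    }
    sv <- svd(M, nu = 1L, nv = 1L)
    cvec <- sv$v[, 1L]
    w <- soft_threshold(as.vector(M %*% cvec), keepX[h])
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      tvec <- as.vector(Xh %*% w)
      cvec <- as.vector(crossprod(Yh, tvec))
      cn <- sqrt(sum(cvec^2))
      if (cn < .Machine$double.eps) break
      cvec <- cvec / cn
      w_new <- soft_threshold(as.vector(M %*% cvec), keepX[h])
      if (max(abs(w_new - w)) < tol) {
        w <- w_new
        converged <- TRUE
        break
      }
      w <- w_new
    }
    if (!converged && max_iter > 1L) {
      rlang::warn(sprintf(
        "component %d did not converge in %d iterations; using last iterate",
        h, max_iter
      ))
    }
    # deterministic sign: largest-magnitude weight entry positive
    top <- which.max(abs(w))
    if (w[top] < 0) w <- -w
    tvec <- as.vector(Xh %*% w)
    tt <- sum(tvec^2)
    if (tt < .Machine$double.eps) {
      stop_invalid("degenerate component: zero score variance")
    }
    pvec <- as.vector(crossprod(Xh, tvec)) / tt
    qvec <- as.vector(crossprod(Yh, tvec)) / tt
    W[, h] <- w; P[, h] <- pvec; Q[, h] <- qvec; Tm[, h] <- tvec
    Xh <- Xh - tcrossprod(tvec, pvec)
    Yh <- Yh - tcrossprod(tvec, qvec)
  }

  if (ncomp_eff < ncomp) {
    W <- W[, seq_len(ncomp_eff), drop = FALSE]
    P <- P[, seq_len(ncomp_eff), drop = FALSE]
    Q <- Q[, seq_len(ncomp_eff), drop = FALSE]
    Tm <- Tm[, seq_len(ncomp_eff), drop = FALSE]
    keepX <- keepX[seq_len(ncomp_eff)]
    ncomp <- ncomp_eff
  }

  y_fac <- factor(as.character(y), levels = y_levels)
  centroids <- rowsum(Tm, y_fac) / as.vector(table(y_fac))
  # pooled within-class score covariance for the mahalanobis rule
  within <- Tm - centroids[as.integer(y_fac), , drop = FALSE]
  pooled_cov <- crossprod(within) / (n - length(y_levels))

  structure(
    list(
      ncomp = ncomp, keepX = keepX,
      weights = W, x_loadings = P, y_loadings = Q, x_scores = Tm,
      class_centroids = centroids, pooled_score_cov = pooled_cov,
      train_means = train_means, train_sds = train_sds,
      y_levels = y_levels, y_means = y_means, y_train = y_fac,
      distance_rule = distance_rule
    ),
    class = "bcc_splsda"
  )
}

#' Predict classes from a fitted sparse PLS-DA model
#'
#' New data are standardized with the model's training means/SDs and
#' projected onto the component space; classes are assigned by the model's
#' distance rule. `max_dist` picks the class with the largest predicted
#' (dummy-coded) indicator value; `centroid` and `mahalanobis` pick the
#' nearest class centroid in score space, the latter whitening by the
#' pooled within-class score covariance. Exact ties break deterministically
#' to the earlier class level.
#'
#' @param object A `bcc_splsda` model.
#' @param newdata Matrix/data frame with the model's predictor columns.
#' @param type `"class"` (default) for labels, `"scores"` for the projected
#'   component scores, `"response"` for predicted class-indicator values.
#' @param ... Unused.
#' @return Factor of class labels (or a matrix for the other `type`s).
#' @export
predict.bcc_splsda <- function(object, newdata,
                               type = c("class", "scores", "response"),
                               ...) {
  type <- match.arg(type)
  Xn <- as.matrix(newdata)
  if (ncol(Xn) != length(object$train_means)) {
    stop_invalid("newdata has the wrong number of columns")
  }
  Xs <- standardize_cols(Xn, center = object$train_means,
                         scale = object$train_sds)
  # projection weights accounting for deflation: W* = W (P'W)^{-1}
  PW <- crossprod(object$x_loadings, object$weights)
  Wstar <- object$weights %*% solve(PW)
  scores <- Xs %*% Wstar
  if (type == "scores") return(scores)
  yhat <- scores %*% t(object$y_loadings)
  yhat <- sweep(yhat, 2L, object$y_means, "+")
  colnames(yhat) <- object$y_levels
  if (type == "response") return(yhat)
  cls <- switch(object$distance_rule,
    max_dist = max.col(yhat, ties.method = "first"),
    centroid = nearest_centroid(scores, object$class_centroids),
    mahalanobis = nearest_centroid(scores, object$class_centroids,
                                   cov = object$pooled_score_cov)
  )
  factor(object$y_levels[cls], levels = object$y_levels)
}

nearest_centroid <- function(scores, centroids, cov = NULL) {
  if (!is.null(cov)) {
    L <- tryCatch(chol(cov), error = function(e) NULL)
    if (!is.null(L)) {
      scores <- scores %*% solve(L)
      centroids <- centroids %*% solve(L)
    }
  }
  d2 <- outer(rowSums(scores^2), rowSums(centroids^2), "+") -
    2 * scores %*% t(centroids)
  max.col(-d2, ties.method = "first")
}

#' Misclassification rate
#'
#' Fraction of misclassified samples: the number of mismatches divided by
#' the total number of samples.
#'
#' @param pred,truth Equal-length label vectors.
#' @return A fraction in `[0, 1]`.
#' @export
#' @examples
#' error_rate(c("a", "a", "b"), c("a", "b", "b"))
error_rate <- function(pred, truth) {
  if (length(pred) == 0L || length(truth) == 0L) {
    stop_invalid("empty input")
  }
  if (length(pred) != length(truth)) stop_invalid("length mismatch")
  mean(as.character(pred) != as.character(truth))
}

#' @export
print.bcc_splsda <- function(x, ...) {
  cat(sprintf(
    "<bcc_splsda> %d component(s), keepX = %s, classes: %s (%s rule)\n",
    x$ncomp, paste(x$keepX, collapse = "/"),
    paste(x$y_levels, collapse = ", "), x$distance_rule
  ))
  invisible(x)
}

#' @describeIn fit_splsda Per-variable, per-component sparse weights and
#'   loadings (nonzero weights only unless `all = TRUE`).
#' @param x,object A `bcc_splsda` object.
#' @param all Keep zero-weight rows too?
#' @param ... Unused.
#' @export
tidy.bcc_splsda <- function(x, all = FALSE, ...) {
  out <- purrr::map_dfr(seq_len(x$ncomp), function(h) {
    tibble::tibble(
      variable = rownames(x$weights),
      component = h,
      weight = x$weights[, h],
      loading = x$x_loadings[, h]
    )
  })
  if (!all) out <- dplyr::filter(out, .data$weight != 0)
  out
}

#' @describeIn fit_splsda One-row fit summary.
#' @export
glance.bcc_splsda <- function(x, ...) {
  tibble::tibble(
    ncomp = x$ncomp,
    n = nrow(x$x_scores),
    n_variables = nrow(x$weights),
    keepX = paste(x$keepX, collapse = "/"),
    distance_rule = x$distance_rule
  )
}

#' @describeIn fit_splsda Score plot of the first two components, colored
#'   by class.
#' @export
autoplot.bcc_splsda <- function(object, ...) {
  if (object$ncomp < 2L) stop_invalid("score plot needs ncomp >= 2")
  sc <- tibble::tibble(
    comp1 = object$x_scores[, 1L],
    comp2 = object$x_scores[, 2L],
    class = object$y_train
  )
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$comp1, y = .data$comp2,
                                   color = .data$class,
                                   shape = .data$class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::stat_ellipse(level = 0.95) +
    ggplot2::labs(x = "component 1", y = "component 2",
                  title = "sPLS-DA scores") +
    ggplot2::theme_minimal()
}
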