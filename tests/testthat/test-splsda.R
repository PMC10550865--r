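test_that("dummy coding builds the class indicator matrix", {
  Y <- dummy_code(c("success", "failure", "success"))
  expect_equal(colnames(Y), c("success", "failure"))
  expect_equal(unname(Y), rbind(c(1, 0), c(0, 1), c(1, 0)))
  Y3 <- dummy_code(factor(c("CE", "LAA", "UND", "CE")))
  expect_equal(ncol(Y3), 3L)
  expect_equal(unname(colSums(Y3)), c(2, 1, 1))
  expect_error(dummy_code(rep("one", 5L)), class = "bccstrat_invalid")
})

test_that("soft thresholding matches the hand-worked example", {
  w <- soft_threshold(c(3, 1, -2), keep = 1L)
  expect_equal(w, c(1, 0, 0))  # lambda = 2, shrink 3 -> 1, normalize
  v <- c(0.5, -3, 2, 0.1)
  expect_equal(soft_threshold(v, 4L), v / sqrt(sum(v^2)))
  expect_equal(soft_threshold(-v, 2L), -soft_threshold(v, 2L))
  expect_error(soft_threshold(v, 0L), class = "bccstrat_invalid")
  expect_error(soft_threshold(v, 5L), class = "bccstrat_invalid")
})

test_that("soft thresholding keeps exactly `keep` nonzeros on generic input", {
  set.seed(97)
  for (i in 1:20) {
    v <- rnorm(40L)
    keep <- sample(1:39, 1L)
    w <- soft_threshold(v, keep)
    expect_equal(sum(w != 0), keep)
    expect_equal(sum(w^2), 1)
    # retained entries are the top-|v| ones
    expect_setequal(which(w != 0), order(abs(v), decreasing = TRUE)[1:keep])
  }
})

test_that("dense component 1 equals the dominant cross-covariance direction", {
  set.seed(101)
  for (i in 1:5) {
    X <- matrix(rnorm(150 * 20), 150L)
    y <- factor(sample(c("success", "failure"), 150L, replace = TRUE))
    fit <- fit_splsda(X, y, ncomp = 1L, keepX = 20L)
    Z <- scale(X)
    Yc <- scale(dummy_code(y), scale = FALSE)
    u <- svd(crossprod(Z, Yc), nu = 1L)$u[, 1L]
    if (sign(u[which.max(abs(u))]) < 0) u <- -u
    expect_lt(max(abs(fit$weights[, 1L] - u)), 1e-6)
  }
})

test_that("scores are orthogonal across components and the fit is deterministic", {
  sim <- small_sim(seed = 103L)
  X <- bcc_matrix(sim$cohort)[, 1:30]
  y <- sim$cohort$recanalization
  f1 <- fit_splsda(X, y, ncomp = 3L, keepX = c(10L, 8L, 5L))
  f2 <- fit_splsda(X, y, ncomp = 3L, keepX = c(10L, 8L, 5L))
  expect_identical(f1$weights, f2$weights)
  G <- crossprod(f1$x_scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  # sign convention: largest-magnitude weight entry positive
  for (h in 1:3) {
    w <- f1$weights[, h]
    expect_gt(w[which.max(abs(w))], 0)
  }
  expect_equal(unname(colSums(f1$weights != 0)), c(10L, 8L, 5L))
})

test_that("planted informative variables carry the nonzero weights", {
  set.seed(107)
  n <- 200L
  X <- matrix(rnorm(n * 20L), n)
  y <- rep(c("a", "b"), each = n / 2L)
  X[y == "a", 3L] <- X[y == "a", 3L] + 3
  X[y == "a", 17L] <- X[y == "a", 17L] - 3
  fit <- fit_splsda(X, y, ncomp = 1L, keepX = 2L)
  expect_setequal(which(fit$weights[, 1L] != 0), c(3L, 17L))
})

test_that("prediction matches a reference dense PLS-DA without sparsity", {
  set.seed(109)
  n <- 200L
  X <- matrix(rnorm(n * 15L), n,
              dimnames = list(NULL, paste0("V", 1:15)))
  y <- rep(c("success", "failure"), each = n / 2L)
  X[y == "success", 1:3] <- X[y == "success", 1:3] + 1.2
  fit <- fit_splsda(X, y, ncomp = 2L, keepX = 15L)
  pred_mine <- predict(fit, X)
  ref <- mixOmics::plsda(X, factor(y, levels = c("success", "failure")),
                         ncomp = 2L)
  pred_ref <- predict(ref, X, dist = "max.dist")$class$max.dist[, 2L]
  expect_gte(mean(as.character(pred_mine) == as.character(pred_ref)), 0.95)
})

test_that("prediction geometry: interior points, ties, dimension checks", {
  set.seed(113)
  X <- rbind(matrix(rnorm(80L, mean = 3, sd = 0.3), 40L),
             matrix(rnorm(80L, mean = -3, sd = 0.3), 40L))
  y <- rep(c("hi", "lo"), each = 40L)
  fit <- fit_splsda(X, y, ncomp = 1L, keepX = 2L)
  deep <- matrix(c(3, 3), 1L)
  expect_equal(as.character(predict(fit, deep)), "hi")
  # exact midpoint ties deterministically to the first class level
  mid <- matrix(colMeans(rbind(c(3, 3), c(-3, -3))), 1L)
  expect_equal(as.character(predict(fit, mid)), "hi")
  expect_error(predict(fit, matrix(0, 1L, 5L)), class = "bccstrat_invalid")
})

test_that("distance rules agree on well-separated classes", {
  sim <- small_sim(seed = 127L)
  X <- bcc_matrix(sim$cohort)[, 1:20]
  y <- sim$cohort$sex  # strongly separable via shifted BCCs
  preds <- lapply(c("max_dist", "centroid", "mahalanobis"), function(rule) {
    fit <- fit_splsda(X, y, ncomp = 2L, keepX = 10L, distance_rule = rule)
    predict(fit, X)
  })
  expect_gte(mean(preds[[1L]] == preds[[2L]]), 0.9)
  expect_gte(mean(preds[[1L]] == preds[[3L]]), 0.9)
})

test_that("error rate is a simple mismatch fraction with guards", {
  expect_equal(error_rate(c("a", "b"), c("a", "b")), 0)
  expect_equal(error_rate(c("a", "b"), c("b", "a")), 1)
  pred <- c(rep("x", 57L), rep("y", 43L))
  truth <- rep("x", 100L)
  expect_equal(error_rate(pred, truth), 0.43)
  # invariant to consistent relabeling
  map <- c(x = "success", y = "failure")
  expect_equal(error_rate(map[pred], map[truth]), 0.43)
  expect_error(error_rate(character(0), character(0)),
               class = "bccstrat_invalid")
})

test_that("duplicated feature blocks resolve deterministically", {
  set.seed(131)
  X <- matrix(rnorm(100L * 5L), 100L)
  X <- cbind(X, X[, 1L])  # exact duplicate column
  y <- rep(c("a", "b"), each = 50L)
  X[y == "a", 1L] <- X[y == "a", 1L] + 1
  X[y == "a", 6L] <- X[y == "a", 6L] + 1
  f1 <- suppressWarnings(fit_splsda(X, y, ncomp = 1L, keepX = 2L))
  f2 <- suppressWarnings(fit_splsda(X, y, ncomp = 1L, keepX = 2L))
  expect_identical(f1$weights, f2$weights)
})
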