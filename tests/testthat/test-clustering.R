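test_that("correlation distance has the right fixed points", {
  set.seed(53)
  x <- rnorm(400)
  X <- cbind(a = x, b = 2 * x + 3, c = -x, d = rnorm(400))
  D <- correlation_distance(X)
  expect_equal(unname(diag(D)), rep(0, 4L))
  expect_equal(D["a", "b"], 0, tolerance = 1e-12)  # perfect correlation
  expect_equal(D["a", "c"], 0, tolerance = 1e-12)  # sign is ignored
  expect_equal(D, t(D))
})

test_that("independent variables sit near distance 1", {
  set.seed(59)
  X <- matrix(rnorm(2000), ncol = 2L)
  D <- correlation_distance(X)
  expect_lt(abs(D[1L, 2L] - 1), 0.08)  # null Spearman SE ~ 1/sqrt(n)
})

test_that("constant columns warn and go to distance 1", {
  X <- cbind(a = rnorm(30), b = rep(1, 30))
  expect_warning(D <- correlation_distance(X), "constant")
  expect_equal(D["a", "b"], 1)
})

test_that("distance (and clustering) is invariant to monotone transforms", {
  sim <- small_sim(seed = 61L)
  X <- bcc_matrix(sim$cohort)[, 1:12]
  D1 <- correlation_distance(X)
  X2 <- X
  X2[, 1:6] <- exp(X2[, 1:6])        # monotone increasing
  X2[, 7:12] <- -X2[, 7:12]^3        # monotone decreasing (|rho| unchanged)
  D2 <- correlation_distance(X2)
  expect_equal(D1, D2, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(cluster_variables(D1, 4L), cluster_variables(D2, 4L))
})

test_that("trivial cuts behave and k is validated", {
  sim <- small_sim(seed = 67L)
  D <- correlation_distance(bcc_matrix(sim$cohort)[, 1:10])
  expect_equal(length(unique(cluster_variables(D, 10L))), 10L)
  expect_equal(length(unique(cluster_variables(D, 1L))), 1L)
  expect_error(cluster_variables(D, 0L), class = "bccstrat_invalid")
  expect_error(cluster_variables(D, 11L), class = "bccstrat_invalid")
})

test_that("planted block structure is recovered exactly at the true k", {
  sim <- simulate_cohort(bcc_config(seed = 71L))
  X <- bcc_matrix(sim$cohort)
  D <- correlation_distance(X)
  part <- cluster_variables(D, 58L)
  ri <- rand_index(part, sim$truth$cluster_assignment)
  expect_equal(ri$adjusted_rand, 1)
})

test_that("Rand index matches hand enumeration and mclust on random cases", {
  # {ab|cd} vs {ac|bd}: of the 6 pairs only ad and bc agree (apart in both)
  ri <- rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2))
  expect_equal(ri$rand, 2 / 6)
  p <- c(a = 1, b = 1, c = 2, d = 3)
  expect_equal(rand_index(p, p)$rand, 1)
  expect_equal(rand_index(p, p)$adjusted_rand, 1)
  set.seed(73)
  for (i in 1:10) {
    p1 <- sample.int(4L, 25L, replace = TRUE)
    p2 <- sample.int(3L, 25L, replace = TRUE)
    expect_equal(rand_index(p1, p2)$adjusted_rand,
                 mclust::adjustedRandIndex(p1, p2))
    # symmetry
    expect_equal(rand_index(p1, p2), rand_index(p2, p1))
  }
  expect_error(rand_index(c(a = 1, b = 2), c(a = 1, x = 2)),
               class = "bccstrat_invalid")
})

test_that("select_k recovers the planted number of clusters", {
  for (s in 1:3) {
    sim <- simulate_cohort(bcc_config(seed = 800L + s))
    cm <- select_k(bcc_matrix(sim$cohort), sim$cohort$sex, k_grid = 40:70)
    expect_equal(cm$k, 58L)
    expect_gte(
      rand_index(cm$partition, sim$truth$cluster_assignment)$adjusted_rand,
      0.95
    )
    expect_gte(cm$concordance, 0)
    expect_lte(cm$concordance, 1)
  }
})

test_that("a single planted block collapses to k = 1", {
  cfg <- bcc_config(n_female = 100L, n_male = 100L, n_bcc = 12L,
                    n_clusters = 1L, rho_within = 0.95, rho_between = 0.1,
                    sex_shift = empty_set(),
                    informative_clusters = list(shared = empty_set(),
                                                female_only = empty_set(),
                                                male_only = empty_set()),
                    etiology_clusters = NULL,
                    seed = 79L)
  sim <- simulate_cohort(cfg)
  cm <- select_k(bcc_matrix(sim$cohort), sim$cohort$sex, k_grid = 1:3)
  expect_equal(cm$k, 1L)
})

test_that("representatives pass singletons through and pool blocks", {
  sim <- small_sim(seed = 83L)
  X <- bcc_matrix(sim$cohort)[, 1:4]
  part <- c(bcc_001 = 1L, bcc_002 = 1L, bcc_003 = 2L, bcc_004 = 3L)
  reps <- make_representatives(X, part)
  expect_equal(colnames(reps), c("cluster_1", "cluster_2", "cluster_3"))
  # singleton representative equals the z-scored member
  expect_equal(unname(reps[, "cluster_2"]),
               as.vector(scale(X[, "bcc_003"])), tolerance = 1e-12)
  # two-member representative correlates equally with both members
  expect_equal(cor(reps[, "cluster_1"], X[, "bcc_001"]),
               cor(reps[, "cluster_1"], X[, "bcc_002"]), tolerance = 0.2)
  # block representative is closer to the latent factor than either member
  z <- scale(X[, "bcc_001"]) + scale(X[, "bcc_002"])
  expect_gte(cor(reps[, "cluster_1"], z),
             max(cor(X[, "bcc_001"], z), cor(X[, "bcc_002"], z)) - 1e-12)
})

test_that("training-set standardization is reused on held-out rows", {
  sim <- small_sim(seed = 89L)
  X <- bcc_matrix(sim$cohort)
  part <- sim$truth$cluster_assignment
  tr <- 1:80; te <- 81:120
  reps_tr <- make_representatives(X[tr, ], part)
  reps_te <- make_representatives(X[te, ], part,
                                  center = attr(reps_tr, "center"),
                                  scale = attr(reps_tr, "scale"))
  # recompute one held-out representative by hand from training stats
  members <- names(part)[part == 1L]
  z <- sweep(X[te, members, drop = FALSE], 2L,
             attr(reps_tr, "center")[members], "-")
  z <- sweep(z, 2L, attr(reps_tr, "scale")[members], "/")
  expect_equal(unname(reps_te[, "cluster_1"]), unname(rowMeans(z)),
               tolerance = 1e-12)
})

test_that("zero-SD members are excluded from representatives with warning", {
  X <- cbind(bcc_001 = rnorm(40), bcc_002 = rep(5, 40), bcc_003 = rnorm(40))
  part <- c(bcc_001 = 1L, bcc_002 = 1L, bcc_003 = 2L)
  expect_warning(reps <- make_representatives(X, part), "zero-SD")
  expect_equal(unname(reps[, "cluster_1"]),
               as.vector(scale(X[, "bcc_001"])), tolerance = 1e-12)
})
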