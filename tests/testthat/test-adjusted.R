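test_that("intercept-only fit returns the closed-form logit", {
  y <- c(rep(1L, 70L), rep(0L, 73L))
  fit <- logistic_irls(matrix(1, length(y), 1L), y)
  expect_equal(unname(fit$coefficients), log(70 / 73), tolerance = 1e-9)
})

test_that("a single binary covariate recovers the sample log odds ratio", {
  set.seed(233)
  for (i in 1:10) {
    tab <- matrix(rpois(4L, 25L) + 2L, 2L)  # a c / b d, all cells > 0
    a <- tab[1, 1]; b <- tab[2, 1]; c_ <- tab[1, 2]; d <- tab[2, 2]
    x <- c(rep(1L, a + b), rep(0L, c_ + d))
    y <- c(rep(1L, a), rep(0L, b), rep(1L, c_), rep(0L, d))
    fit <- logistic_irls(cbind(1, x), y)
    expect_equal(unname(fit$coefficients[2L]), log(a * d / (b * c_)),
                 tolerance = 1e-8)
  }
})

test_that("IRLS matches the reference GLM on random small datasets", {
  set.seed(239)
  for (i in 1:20) {
    n <- sample(60:120, 1L)
    p <- sample(2:4, 1L)
    X <- cbind(1, matrix(rnorm(n * p), n))
    beta <- runif(p + 1L, -1, 1)
    y <- rbinom(n, 1L, plogis(X %*% beta))
    if (length(unique(y)) < 2L) next
    mine <- logistic_irls(X, y)
    ref <- suppressWarnings(glm.fit(X, y, family = binomial()))
    expect_lt(max(abs(mine$coefficients - ref$coefficients)), 1e-6)
    # Wald covariance agrees too (looser: both fits stop at slightly
    # different near-converged iterates)
    vr <- chol2inv(chol(t(X * ref$weights) %*% X))
    expect_lt(max(abs(mine$vcov - vr)), 1e-4)
  }
})

test_that("true coefficients are recovered within 3 SE at large n", {
  set.seed(241)
  n <- 5000L
  X <- cbind(1, rnorm(n), rbinom(n, 1L, 0.4))
  beta <- c(-0.4, 0.7, -0.5)
  y <- rbinom(n, 1L, plogis(X %*% beta))
  fit <- logistic_irls(X, y)
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(fit$coefficients - beta) < 3 * se))
})

test_that("Wald CI width shrinks like 1/sqrt(n)", {
  set.seed(251)
  width_at <- function(n) {
    X <- cbind(1, rnorm(n))
    y <- rbinom(n, 1L, plogis(X %*% c(0, 0.5)))
    fit <- logistic_irls(X, y)
    2 * 1.96 * sqrt(fit$vcov[2L, 2L])
  }
  w1 <- mean(replicate(5L, width_at(400L)))
  w2 <- mean(replicate(5L, width_at(1600L)))
  expect_equal(w1 / w2, 2, tolerance = 0.25)
})

test_that("separation and rank deficiency raise named errors", {
  x <- c(rep(0, 20L), rep(1, 20L))
  y <- x  # perfectly separated
  expect_error(logistic_irls(cbind(1, x), y),
               class = "bccstrat_separation_error")
  X <- cbind(1, x, 2 * x)
  expect_error(logistic_irls(X, rbinom(40L, 1L, 0.5)),
               class = "bccstrat_rank_error")
})

test_that("adjusted cluster effect finds a planted positive log-odds", {
  hits <- 0L
  for (s in 1:10) {
    withr::with_seed(260L + s, {
      n <- 400L
      rep_var <- rnorm(n)
      covs <- tibble::tibble(
        hypertension = rbinom(n, 1L, 0.5),
        ivt = rbinom(n, 1L, 0.3)
      )
      y <- rbinom(n, 1L, plogis(1.0 * rep_var))
      cohort <- dplyr::bind_cols(
        tibble::tibble(
          recanalization = factor(ifelse(y == 1L, "success", "failure"),
                                  levels = c("success", "failure"))
        ),
        covs
      )
      eff <- adjusted_cluster_effect(cohort, rep_var, cluster = 1L,
                                     covariates = c("hypertension", "ivt"))
      if (eff$beta > 0 && eff$ci_low > 0) hits <- hits + 1L
    })
  }
  expect_gte(hits, 8L)
})

test_that("a null cluster's CI covers zero at roughly the nominal rate", {
  cover <- 0L
  for (s in 1:20) {
    withr::with_seed(280L + s, {
      n <- 300L
      rep_var <- rnorm(n)
      cohort <- tibble::tibble(
        recanalization = factor(sample(c("success", "failure"), n, TRUE),
                                levels = c("success", "failure")),
        ivt = rbinom(n, 1L, 0.3)
      )
      eff <- adjusted_cluster_effect(cohort, rep_var, cluster = 1L,
                                     covariates = "ivt")
      if (eff$ci_low <= 0 && eff$ci_high >= 0) cover <- cover + 1L
    })
  }
  expect_gte(cover, 16L)  # ~95% coverage, binomial slack at 20 draws
})

test_that("sign convention: negative beta means higher values hurt success", {
  withr::with_seed(271L, {
    n <- 600L
    rep_var <- rnorm(n)
    y <- rbinom(n, 1L, plogis(-0.8 * rep_var))
    cohort <- tibble::tibble(
      recanalization = factor(ifelse(y == 1L, "success", "failure"),
                              levels = c("success", "failure")),
      ivt = rbinom(n, 1L, 0.3)
    )
    eff <- adjusted_cluster_effect(cohort, rep_var, covariates = "ivt")
    expect_lt(eff$beta, 0)
    expect_lt(eff$ci_high, 0)
    expect_true(eff$ci_low <= eff$beta && eff$beta <= eff$ci_high)
    # odds-ratio scale reported alongside the log-odds scale
    expect_equal(eff$or, exp(eff$beta))
  })
})

test_that("complete-case filtering and cluster standardization are applied", {
  sim <- small_sim(seed = 293L)
  part <- sim$truth$cluster_assignment
  cohort <- sim$cohort
  cohort$hypertension[1:10] <- NA_integer_
  eff <- adjusted_effects(cohort, part, clusters = 1L,
                          covariates = c("hypertension", "ivt"))
  expect_equal(eff$n_used, nrow(cohort) - 10L)
  expect_equal(eff$covariates_included, "hypertension,ivt")
})
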