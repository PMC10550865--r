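# Generator with dual-signal clusters: the same clusters drive
# recanalization and (CE vs LAA) etiology in the matching sex stratum.
dual_signal_config <- function(seed, shared = 1:3, f_only = 14:16,
                               m_only = 26:28, recan_effect = 1.0,
                               etio_effect = 1.2) {
  set_of <- function(idx) stats::setNames(rep(recan_effect, length(idx)), idx)
  bcc_config(
    sex_shift = empty_set(),
    informative_clusters = list(shared = set_of(shared),
                                female_only = set_of(f_only),
                                male_only = set_of(m_only)),
    etiology_clusters = tibble::tibble(
      cluster = c(shared, f_only, m_only),
      group = c(rep("shared", length(shared)),
                rep("female_only", length(f_only)),
                rep("male_only", length(m_only))),
      class = rep_len(c("CE", "LAA"), length(c(shared, f_only, m_only))),
      coef = etio_effect
    ),
    seed = seed
  )
}

test_that("direction assignment follows the planted group shift", {
  set.seed(199)
  n <- 200L
  cohort <- tibble::tibble(
    sex = factor(rep(c("F", "M"), each = n / 2L), levels = c("F", "M")),
    bcc_001 = rnorm(n),
    bcc_002 = rnorm(n),
    recanalization = factor(sample(c("success", "failure"), n, TRUE),
                            levels = c("success", "failure"))
  )
  up <- cohort$recanalization == "success"
  cohort$bcc_001[up] <- cohort$bcc_001[up] + 1  # higher in success
  part <- c(bcc_001 = 1L, bcc_002 = 2L)
  dir <- direction_assignment(cohort, part, c(1L, 2L))
  expect_equal(dir$direction[dir$cluster == 1L], "success")
  # exact tie: both classes see the identical value sequence
  cohort2 <- cohort
  cohort2$recanalization <- factor(rep(c("success", "failure"), n / 2L),
                                   levels = c("success", "failure"))
  cohort2$bcc_002 <- rep(c(1, 1, 2, 2), n / 4L)
  dir2 <- suppressMessages(direction_assignment(cohort2, part, 2L))
  expect_equal(dir2$direction, "none")
})

test_that("direction labels are invariant to monotone rescaling", {
  sim <- small_sim(seed = 211L)
  part <- sim$truth$cluster_assignment
  d1 <- direction_assignment(sim$cohort, part, 1:5)
  cohort2 <- sim$cohort
  for (v in names(part)[part %in% 1:5]) {
    cohort2[[v]] <- 10 * cohort2[[v]] + 3  # affine, order-preserving
  }
  d2 <- direction_assignment(cohort2, part, 1:5)
  expect_equal(d1$direction, d2$direction)
})

test_that("overlap summary counts shared and sex-specific sets", {
  f <- list(recan_stable = c("cluster_1", "cluster_2", "cluster_3"),
            both_stable = c("cluster_1", "cluster_2"))
  m <- list(recan_stable = c("cluster_3", "cluster_4"),
            both_stable = c("cluster_9"))
  os <- overlap_summary(f, m)
  expect_equal(os$shared, c(1L, 0L))
  expect_equal(os$female_specific, c(2L, 2L))
  expect_equal(os$male_specific, c(1L, 1L))
  # disjoint and identical edge cases
  os2 <- overlap_summary(list(recan_stable = "a", both_stable = "a"),
                         list(recan_stable = "a", both_stable = "a"))
  expect_equal(os2$shared, c(1L, 1L))
  expect_equal(os2$female_specific, c(0L, 0L))
})

test_that("etiology rerun restricts candidates and nests stable sets", {
  sim <- simulate_cohort(dual_signal_config(seed = 223L))
  part <- sim$truth$cluster_assignment
  et <- etiology_stability(sim$cohort, part, candidates = c(1L, 2L, 3L),
                           sex = "F", K = 4L, R = 4L,
                           keepX_grid = 2L, seed = 23L)
  expect_true(all(et$selection_frequency$variable %in%
                    paste0("cluster_", 1:3)))
  expect_true(all(et$stable_set %in% paste0("cluster_", 1:3)))
  expect_error(
    etiology_stability(dplyr::select(sim$cohort, -"etiology"), part,
                       seed = 1L),
    class = "bccstrat_invalid"
  )
})

test_that("dual-signal clusters survive both stability stages", {
  sim <- simulate_cohort(dual_signal_config(seed = 227L))
  part <- sim$truth$cluster_assignment
  sc <- stratified_comparison(sim$cohort, part, K = 5L, R = 10L, seed = 29L)
  cons <- etiology_consistency(sim$cohort, part, sc, K = 5L, R = 10L,
                               seed = 31L)
  # nesting invariant: both_stable within recan_stable, per sex
  expect_true(all(cons$female$both_stable %in% cons$female$recan_stable))
  expect_true(all(cons$male$both_stable %in% cons$male$recan_stable))
  # planted female-only dual clusters appear for women, not men
  expect_gt(length(intersect(cons$female$both_stable,
                             paste0("cluster_", c(1:3, 14:16)))), 0L)
  expect_equal(intersect(cons$male$both_stable, paste0("cluster_", 14:16)),
               character(0))
  # overlap table is consistent with the per-sex sets
  expect_equal(cons$overlap$shared[1L],
               length(intersect(cons$female$recan_stable,
                                cons$male$recan_stable)))
  td <- tidy(cons)
  expect_true(all(c("sex", "cluster", "etiology_stable") %in% names(td)))
})

test_that("no-etiology-signal runs leave the etiology stable set small", {
  cfg <- planted_stability_config(seed = 229L)  # recan signal only
  sim <- simulate_cohort(cfg)
  part <- sim$truth$cluster_assignment
  et <- etiology_stability(sim$cohort, part, sex = "F",
                           K = 4L, R = 10L, seed = 37L)
  # etiology labels carry only the weak default intercept structure here;
  # spurious stability can touch a cluster or two but not the planted set
  expect_lte(length(et$stable_set), 3L)
})
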