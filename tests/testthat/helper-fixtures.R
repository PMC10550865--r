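# Shared fixtures: all synthetic, built in code at test time.

empty_set <- function() stats::setNames(numeric(0), character(0))

# Small cohort reused across fast unit tests.
small_sim <- function(seed = 42L, n = 60L) {
  simulate_cohort(bcc_config(n_female = n, n_male = n, seed = seed))
}

# Generator config with a known set of informative clusters for the
# recanalization outcome and nothing else planted.
planted_stability_config <- function(seed, effect = 0.8,
                                     clusters = c(5L, 15L, 25L, 35L, 45L),
                                     n_female = 150L, n_male = 150L) {
  bcc_config(
    n_female = n_female, n_male = n_male,
    sex_shift = empty_set(),
    informative_clusters = list(
      shared = stats::setNames(rep(effect, length(clusters)), clusters),
      female_only = empty_set(),
      male_only = empty_set()
    ),
    etiology_clusters = NULL,
    seed = seed
  )
}

# Generator config whose recanalization signal lives only in women.
female_only_config <- function(seed, effect = 1.0,
                               clusters = 14:18) {
  bcc_config(
    sex_shift = empty_set(),
    informative_clusters = list(
      shared = empty_set(),
      female_only = stats::setNames(rep(effect, length(clusters)), clusters),
      male_only = empty_set()
    ),
    seed = seed
  )
}

# All outcome coefficients zero: pure-noise labels.
null_signal_config <- function(seed, ...) {
  planted_stability_config(seed, effect = 0, ...)
}
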