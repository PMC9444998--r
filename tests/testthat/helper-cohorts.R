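# Small, fast cohort configurations used across tests.

# Two time-series indices plus one error fraction: enough structure for the
# quantifier/selection/clock paths while keeping generation cheap.
small_index_specs <- function(noise_sd = 60, mixture_weight = 0,
                              saturation_age = NULL) {
  list(
    index_spec("CM t+", "series", n_trials = 8L, baseline = 900,
               age_slope = 7, noise_sd = noise_sd,
               mixture_weight = mixture_weight, slow_mode_shift = 250,
               unit = "time", saturation_age = saturation_age),
    index_spec("SM2 MR", "series", n_trials = 8L, baseline = 430,
               age_slope = 3.2, noise_sd = noise_sd * 0.6,
               mixture_weight = mixture_weight, slow_mode_shift = 150,
               unit = "time", saturation_age = saturation_age),
    index_spec("SM1 ERR-1", "scalar", n_trials = 40L, baseline = 0.08,
               age_slope = 0.03, noise_sd = 1, unit = "fraction")
  )
}

small_cohort <- function(n = 60, seed = 1, ...) {
  generate_cohort(cohort_config(n_participants = n,
                                index_specs = small_index_specs(),
                                bio_clock_specs = default_bio_clock_specs(),
                                seed = seed, ...))
}

# Cohort whose quantifiers carry a strong linear age signal (small noise
# relative to the age drift) - used for clock-recovery checks.
strong_signal_config <- function(n = 500, seed = 1, saturation_age = NULL,
                                 accel_sd = 1) {
  specs <- list(
    index_spec("CM t+", "series", n_trials = 10L, baseline = 900,
               age_slope = 7, noise_sd = 40, unit = "time",
               saturation_age = saturation_age),
    index_spec("CM t-", "series", n_trials = 10L, baseline = 800,
               age_slope = 6, noise_sd = 40, unit = "time",
               saturation_age = saturation_age),
    index_spec("SM1 SMR", "series", n_trials = 10L, baseline = 950,
               age_slope = 6, noise_sd = 40, unit = "time",
               saturation_age = saturation_age),
    index_spec("SM2 MR", "series", n_trials = 10L, baseline = 430,
               age_slope = 3.2, noise_sd = 25, unit = "time",
               saturation_age = saturation_age)
  )
  cohort_config(n_participants = n, index_specs = specs,
                accel_sd = accel_sd, trait_sd = 0,
                bio_clock_specs = NULL, seed = seed)
}

with_seed_sample <- function(x, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample(x)
}

# All-noise cohort: every index has zero age slope.
noise_config <- function(n = 118, n_indices = 8, seed = 1) {
  specs <- lapply(seq_len(n_indices), function(i) {
    index_spec(sprintf("NOISE %d", i), "series", n_trials = 8L,
               baseline = 500, age_slope = 0, noise_sd = 80, unit = "time")
  })
  cohort_config(n_participants = n, index_specs = specs, accel_sd = 0,
                trait_sd = 0, bio_clock_specs = NULL, seed = seed)
}
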