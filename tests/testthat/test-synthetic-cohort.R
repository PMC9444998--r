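test_that("generation is deterministic given the seed", {
  a <- small_cohort(n = 25, seed = 42)
  b <- small_cohort(n = 25, seed = 42)
  expect_identical(a$participants, b$participants)
  expect_identical(a$series, b$series)
  expect_identical(a$truth, b$truth)
  c <- small_cohort(n = 25, seed = 43)
  expect_false(identical(a$series$value, c$series$value))
})

test_that("the noise-free limit reproduces the configured linear trend exactly", {
  spec <- index_spec("CM t+", "series", n_trials = 5L, baseline = 900,
                     age_slope = 7, noise_sd = 0, unit = "time")
  cfg <- cohort_config(n_participants = 10, index_specs = list(spec),
                       accel_sd = 0, trait_sd = 0, bio_clock_specs = NULL,
                       seed = 5)
  co <- generate_cohort(cfg)
  means <- tapply(co$series$value, co$series$id, mean)
  expected <- 900 + 7 * (co$participants$age - 20)
  expect_equal(as.numeric(means[co$participants$id]), expected)
  # every trial equals the location, so within-participant SD is zero
  expect_true(all(tapply(co$series$value, co$series$id, sd) == 0))
})

test_that("least squares on per-participant means recovers the injected age slope", {
  spec <- index_spec("X", "series", n_trials = 5L, baseline = 500,
                     age_slope = 5, noise_sd = 50, unit = "time")
  cfg <- cohort_config(n_participants = 2000, index_specs = list(spec),
                       accel_sd = 0, trait_sd = 0, bio_clock_specs = NULL,
                       seed = 11)
  co <- generate_cohort(cfg)
  means <- tapply(co$series$value, co$series$id, mean)[co$participants$id]
  fit <- summary(lm(means ~ co$participants$age))
  slope <- fit$coefficients[2, 1]
  se <- fit$coefficients[2, 2]
  expect_lt(abs(slope - 5), 3 * se)
})

test_that("biological ages follow the configured loading model", {
  # identity limit: loading 0, noise 0, slope 1, intercept 0
  spec0 <- list(Clock = list(intercept = 0, slope = 1,
                             shared_accel_loading = 0,
                             independent_noise_sd = 0))
  expect_equal(generate_biological_ages(50, 10, spec0)[["Clock"]], 50)
  # full loading, no noise: bio - chrono equals the latent exactly
  spec1 <- list(Clock = list(intercept = 0, slope = 1,
                             shared_accel_loading = 1,
                             independent_noise_sd = 0))
  expect_equal(generate_biological_ages(50, 7.5, spec1)[["Clock"]] - 50, 7.5)
})

test_that("bio-age acceleration correlates with the latent per the closed form", {
  loading <- 0.8; noise <- 3; accel_sd <- 5
  cfg <- cohort_config(
    n_participants = 2000, index_specs = small_index_specs(),
    accel_sd = accel_sd, trait_sd = 0,
    bio_clock_specs = list(Clock = list(intercept = 0, slope = 1,
                                        shared_accel_loading = loading,
                                        independent_noise_sd = noise)),
    seed = 21)
  co <- generate_cohort(cfg)
  accel <- co$participants$Clock - co$participants$age
  expected <- loading * accel_sd / sqrt(loading^2 * accel_sd^2 + noise^2)
  expect_lt(abs(cor(accel, co$truth$latent_accel) - expected), 0.05)
})

test_that("fraction indices stay in [0, 1] and drift on the logit scale", {
  co <- small_cohort(n = 200, seed = 3)
  err <- co$series$value[co$series$index == "SM1 ERR-1"]
  expect_true(all(err >= 0 & err <= 1))
  # deterministic limit: noise_sd = 0 returns the logistic location
  spec <- index_spec("E", "scalar", n_trials = 40L, baseline = 0.1,
                     age_slope = 0.05, noise_sd = 0, unit = "fraction")
  cfg <- cohort_config(n_participants = 5, index_specs = list(spec),
                       accel_sd = 0, trait_sd = 0, bio_clock_specs = NULL,
                       seed = 2)
  co2 <- generate_cohort(cfg)
  expected <- plogis(qlogis(0.1) + 0.05 * (co2$participants$age - 20))
  expect_equal(co2$series$value[match(co2$participants$id, co2$series$id)],
               expected)
})

test_that("subgroup assignment shifts the latent acceleration", {
  cfg <- cohort_config(
    n_participants = 600, index_specs = small_index_specs(), accel_sd = 2,
    trait_sd = 0,
    bio_clock_specs = NULL,
    subgroups = list(fast = list(fraction = 0.2, accel_shift = -8),
                     slow = list(fraction = 0.2, accel_shift = 8)),
    seed = 9)
  co <- generate_cohort(cfg)
  by_group <- tapply(co$truth$latent_accel, co$truth$subgroup, mean)
  expect_lt(by_group[["fast"]], -5)
  expect_gt(by_group[["slow"]], 5)
  expect_lt(abs(by_group[["none"]]), 1)
})

test_that("invalid configurations fail with the offending field named", {
  expect_error(cohort_config(age_min = 90, age_max = 19), "age_min")
  expect_error(cohort_config(accel_sd = -1), "accel_sd")
  expect_error(cohort_config(female_fraction = 2), "female_fraction")
  expect_error(index_spec("X", "series", n_trials = 0, baseline = 1,
                          age_slope = 0), "n_trials")
  expect_error(index_spec("X", mixture_weight = 1.5, baseline = 1,
                          age_slope = 0), "mixture_weight")
})

test_that("cohorts round-trip through CSV, with errors naming the problem", {
  co <- small_cohort(n = 12, seed = 8)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir, expected_indices = index_names(co))
  expect_equal(back$participants, co$participants, tolerance = 1e-12)
  expect_equal(back$series, co$series, tolerance = 1e-12)
  expect_equal(back$truth, co$truth, tolerance = 1e-12)

  # missing age column is reported by name
  p <- read.csv(file.path(dir, "cohort.csv"))
  write.csv(p[setdiff(names(p), "age")], file.path(dir, "cohort.csv"),
            row.names = FALSE)
  expect_error(read_cohort(dir), "'age'")

  # unknown index names are listed against the known ones
  write_cohort(co, dir)
  s <- read.csv(file.path(dir, "indices.csv"))
  s$index[1] <- "BOGUS"
  write.csv(s, file.path(dir, "indices.csv"), row.names = FALSE)
  err <- tryCatch(read_cohort(dir, expected_indices = index_names(co)),
                  error = conditionMessage)
  expect_match(err, "BOGUS")
  expect_match(err, "CM t\\+")
})
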