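test_that("gaussian_weighted_stats reduces to unweighted statistics when weights are flat", {
  v <- c(3, 5, 9, 11)
  # all participants at the center age -> equal weights, population form
  st <- gaussian_weighted_stats(v, rep(40, 4), 40, 7)
  expect_equal(st$mean, mean(v))
  expect_equal(st$sd, sqrt(mean((v - mean(v))^2)))
  # enormous kernel SD -> flat kernel limit
  ages <- c(20, 35, 60, 80)
  st2 <- gaussian_weighted_stats(v, ages, 50, 1e6)
  expect_equal(st2$mean, mean(v), tolerance = 1e-6)
  expect_equal(st2$sd, sqrt(mean((v - mean(v))^2)), tolerance = 1e-6)
})

test_that("gaussian_weighted_stats matches direct summation", {
  st <- gaussian_weighted_stats(c(1, 2, 4), c(20, 30, 40), 30, 7)
  o <- oracle_weighted_stats(c(1, 2, 4), c(20, 30, 40), 30, 7)
  expect_equal(st$mean, o$mean, tolerance = 1e-12)
  expect_equal(st$sd, o$sd, tolerance = 1e-12)
  set.seed(31)
  for (i in 1:100) {
    n <- sample(3:60, 1)
    v <- rnorm(n, 500, 100); a <- runif(n, 19, 85)
    c0 <- runif(1, 19, 85); sd0 <- runif(1, 2, 15)
    st <- gaussian_weighted_stats(v, a, c0, sd0)
    o <- oracle_weighted_stats(v, a, c0, sd0)
    expect_equal(st$mean, o$mean, tolerance = 1e-12)
    expect_equal(st$sd, o$sd, tolerance = 1e-12)
  }
  expect_error(gaussian_weighted_stats(1:5, rep(20, 5), 300, 7), "no peers")
})

test_that("classification uses strict half-SD bands with direction semantics", {
  expect_equal(classify_performance(10, 10, 2, "lower_is_better"), "normal")
  expect_equal(classify_performance(10 - 0.6 * 2, 10, 2, "lower_is_better"),
               "better")
  expect_equal(classify_performance(10 + 0.6 * 2, 10, 2, "lower_is_better"),
               "worse")
  # exactly on the boundary stays normal (strict inequality)
  expect_equal(classify_performance(10 + 0.5 * 2, 10, 2, "lower_is_better"),
               "normal")
  # flipping the direction swaps better <-> worse for the same value
  set.seed(8)
  for (i in 1:50) {
    v <- rnorm(1); m <- rnorm(1); s <- runif(1, 0.1, 3)
    lo <- classify_performance(v, m, s, "lower_is_better")
    hi <- classify_performance(v, m, s, "higher_is_better")
    expected <- c(better = "worse", normal = "normal", worse = "better")
    expect_equal(hi, unname(expected[lo]))
  }
  # zero SD: any deviation classified by direction
  expect_equal(classify_performance(9, 10, 0, "lower_is_better"), "better")
})

test_that("pattern encoding is invariant to affine rescaling of a column", {
  co <- small_cohort(n = 40, seed = 17)
  qm <- build_quantifier_matrix(co)
  dm <- setNames(rep("lower_is_better", 2), c("CM t+ mean", "SM2 MR mean"))
  pm <- build_pattern_matrix(qm, co$participants$age, dm)
  qm2 <- qm
  qm2[, "CM t+ mean"] <- 3 * qm2[, "CM t+ mean"] + 100
  pm2 <- build_pattern_matrix(qm2, co$participants$age, dm)
  expect_identical(unclass(pm2)[, ], unclass(pm)[, ])
})

test_that("identical cohorts are all-normal; a uniformly fast participant is all-better", {
  qm <- matrix(100, nrow = 8, ncol = 2,
               dimnames = list(paste0("P", 1:8), c("CM t+ mean", "SM2 MR mean")))
  ages <- seq(20, 80, length.out = 8)
  dm <- setNames(rep("lower_is_better", 2), colnames(qm))
  pm <- build_pattern_matrix(qm, ages, dm)
  expect_true(all(pm == "normal"))
  # one participant much faster than everyone else
  qm[1, ] <- 50
  pm2 <- build_pattern_matrix(qm, ages, dm)
  expect_true(all(pm2[1, ] == "better"))
  expect_error(build_pattern_matrix(qm, ages, dm["CM t+ mean"],
                                    pattern_quantifiers = colnames(qm)),
               "no direction")
})

test_that("an injected fast subgroup is labeled better on most cells", {
  hits <- total <- 0
  for (seed in 1:10) {
    cfg <- cohort_config(
      n_participants = 120, index_specs = small_index_specs(noise_sd = 40),
      accel_sd = 3, trait_sd = 0, bio_clock_specs = NULL,
      subgroups = list(fast = list(fraction = 0.15, accel_shift = -12)),
      seed = seed)
    co <- generate_cohort(cfg)
    qm <- build_quantifier_matrix(co)
    dm <- setNames(rep("lower_is_better", 2), c("CM t+ mean", "SM2 MR mean"))
    pm <- build_pattern_matrix(qm, co$participants$age, dm)
    fast <- co$truth$subgroup == "fast"
    hits <- hits + sum(pm[fast, ] == "better")
    total <- total + sum(fast) * ncol(pm)
  }
  expect_gte(hits / total, 0.9)
})

test_that("K-means separates orthogonal pattern blocks and is deterministic", {
  enc_labels <- rbind(matrix("better", 10, 4), matrix("worse", 10, 4))
  rownames(enc_labels) <- paste0("P", 1:20)
  colnames(enc_labels) <- paste0("q", 1:4)
  enc <- rbind(matrix(1, 10, 4), matrix(-1, 10, 4))
  dimnames(enc) <- dimnames(enc_labels)
  pm <- structure(enc_labels, encoding = enc,
                  class = c("pattern_matrix", "matrix"))
  g <- cluster_patterns(pm, k = 2, seed = 1, n_restarts = 10)
  expect_equal(as.character(g[1:10]), rep("A", 10))   # better block first
  expect_equal(as.character(g[11:20]), rep("B", 10))
  expect_equal(attr(g, "within_ss"), 0)
  expect_identical(as.character(cluster_patterns(pm, k = 2, seed = 7)),
                   as.character(cluster_patterns(pm, k = 2, seed = 7)))
  expect_error(cluster_patterns(pm, k = 5), "smaller k")
})

test_that("group acceleration tests match the closed-form one-sample t", {
  r <- test_group_acceleration(c(5, 6, 7, 8), rep("A", 4))
  o <- oracle_one_sample_t(c(5, 6, 7, 8))
  expect_equal(r$mean_accel, 6.5)
  expect_equal(r$t, o$t, tolerance = 1e-12)
  expect_equal(r$p, o$p, tolerance = 1e-12)
  # zero-variance group reported with NA test
  r2 <- test_group_acceleration(c(0, 0, 0), rep("A", 3))
  expect_equal(r2$mean_accel, 0)
  expect_true(is.na(r2$p))
  # singleton group
  r3 <- test_group_acceleration(c(1, 2, 3), c("A", "A", "B"))
  expect_true(is.na(r3$p[r3$group == "B"]))
})
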