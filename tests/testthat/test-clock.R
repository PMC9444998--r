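test_that("stratified folds balance sizes overall and within age bins", {
  # divisibility: 35 participants over 5 folds -> exactly 7 each
  ages <- runif(35, 19, 85)
  f <- stratified_folds(ages, 5, seed = 1)
  expect_equal(as.vector(table(f)), rep(7L, 5))

  # exact stratification: 10 participants in each of 7 bins
  ages2 <- rep(seq(15, 85, length.out = 7), each = 10)
  f2 <- stratified_folds(ages2, 5, seed = 2)
  bins <- findInterval(ages2, seq(10, 90, length.out = 8),
                       rightmost.closed = TRUE, all.inside = TRUE)
  counts <- table(bins, f2)
  expect_true(all(counts == 2))

  # random ages: per-bin fold counts never differ by more than 1
  for (seed in 1:20) {
    set.seed(seed)
    ages3 <- runif(118, 19, 85)
    f3 <- stratified_folds(ages3, 5, seed = seed)
    expect_equal(max(table(f3)) - min(table(f3)) <= 1, TRUE)
    bins3 <- findInterval(pmin(pmax(ages3, 10), 90),
                          seq(10, 90, length.out = 8),
                          rightmost.closed = TRUE, all.inside = TRUE)
    for (b in unique(bins3)) {
      per_fold <- tabulate(f3[bins3 == b], 5)
      expect_lte(max(per_fold) - min(per_fold), 1)
    }
  }
  # deterministic given seed; errors when n < folds
  expect_identical(stratified_folds(ages, 5, seed = 3),
                   stratified_folds(ages, 5, seed = 3))
  expect_error(stratified_folds(runif(3), 5), "folds")
})

test_that("evaluate_metrics matches the definitional formulas", {
  y <- c(20, 40, 60, 80)
  m <- evaluate_metrics(y, y)
  expect_equal(m$ev, 1); expect_equal(m$mae, 0); expect_equal(m$medae, 0)
  # EV is shift-invariant
  m2 <- evaluate_metrics(y, y + 10)
  expect_equal(m2$ev, 1); expect_equal(m2$mae, 10); expect_equal(m2$medae, 10)
  yhat <- c(25, 35, 65, 75)
  m3 <- evaluate_metrics(y, yhat)
  o <- oracle_metrics(y, yhat)
  expect_equal(m3$ev, o$ev, tolerance = 1e-12)
  expect_equal(m3$mae, 5); expect_equal(m3$medae, 5)
  expect_true(is.na(evaluate_metrics(rep(1, 4), c(1, 2, 3, 4))$ev))
})

test_that("every model family fits and predicts finite ages", {
  co <- generate_cohort(strong_signal_config(n = 120, seed = 6))
  qm <- build_quantifier_matrix(co)
  age <- co$participants$age
  sel <- select_quantifiers(qm, age)
  for (fam in c("linear", "elastic_net", "svr_rbf", "nu_svr_rbf",
                "random_forest", "knn", "theil_sen")) {
    grid <- lapply(default_hyperparameter_grids()[[fam]], function(v) v[1])
    w <- list(family = fam, hyper = grid, top_k = 6L)
    clk <- fit_final(w, qm, sel, age, seed = 2)
    pred <- predict_age(clk, qm)
    expect_true(all(is.finite(pred)), info = fam)
    expect_gt(cor(pred, age), 0.5)
  }
})

test_that("1-nearest-neighbour memorizes its training data (diagnostic)", {
  co <- generate_cohort(strong_signal_config(n = 60, seed = 3))
  qm <- build_quantifier_matrix(co)
  age <- co$participants$age
  sel <- select_quantifiers(qm, age)
  clk <- fit_final(list(family = "knn", hyper = list(k = 1), top_k = 4L),
                   qm, sel, age)
  expect_equal(unname(predict_age(clk, qm)), age, tolerance = 1e-8)
})

test_that("cross-validation recovers a strong linear signal and fails on permuted ages", {
  co <- generate_cohort(strong_signal_config(n = 300, seed = 10))
  qm <- build_quantifier_matrix(co)
  age <- co$participants$age
  sel <- select_quantifiers(qm, age)
  spec <- clock_spec("linear", top_k_range = c(4L, 8L), seed = 1)
  cv <- cross_validate(spec, qm, sel, age)
  expect_gt(max(cv$mean_ev), 0.9)

  perm_age <- with_seed_sample(age, 4)
  sel_p <- select_quantifiers(qm, perm_age)
  cv_p <- cross_validate(spec, qm, sel_p, perm_age)
  expect_lt(max(cv_p$mean_ev), 0.05)
})

test_that("select_optimal applies the objective and deterministic tie-breaks", {
  res <- data.frame(family = c("a", "a"), hyper = c("h", "h"),
                    top_k = c(10L, 24L), mean_ev = c(0.5, 0.52),
                    mean_mae = c(6, 7), stringsAsFactors = FALSE)
  expect_equal(select_optimal(res)$mean_ev, 0.52)
  expect_equal(select_optimal(res, "mean_MAE")$mean_mae, 6)
  res$mean_ev <- c(0.5, 0.5)
  expect_equal(select_optimal(res)$top_k, 10L)   # equal EV -> smaller top_k
  expect_identical(select_optimal(res), select_optimal(res))  # pure function
  expect_error(select_optimal(res[0, ]), "non-empty")
})

test_that("clocks serialize and reload with identical predictions", {
  co <- generate_cohort(strong_signal_config(n = 80, seed = 2))
  qm <- build_quantifier_matrix(co)
  sel <- select_quantifiers(qm, co$participants$age)
  clk <- fit_final(list(family = "svr_rbf",
                        hyper = list(cost = 10, gamma_scale = 1),
                        top_k = 6L),
                   qm, sel, co$participants$age)
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(clk, path)
  clk2 <- readRDS(path)
  expect_identical(predict_age(clk2, qm), predict_age(clk, qm))
})

test_that("prediction handles missing columns and missing values", {
  co <- generate_cohort(strong_signal_config(n = 50, seed = 8))
  qm <- build_quantifier_matrix(co)
  sel <- select_quantifiers(qm, co$participants$age)
  clk <- fit_final(list(family = "linear", hyper = list(), top_k = 4L),
                   qm, sel, co$participants$age)
  expect_error(predict_age(clk, qm[, 1:2, drop = FALSE]), "missing column")
  qm_na <- qm
  qm_na[1, clk$quantifiers[1]] <- NA
  pred <- suppressMessages(predict_age(clk, qm_na))
  expect_true(is.na(pred[1]))
  expect_true(all(is.finite(pred[-1])))
  # batch and row-by-row prediction agree
  rowwise <- vapply(2:6, function(i) {
    suppressMessages(predict_age(clk, qm[i, , drop = FALSE]))
  }, numeric(1))
  expect_equal(unname(rowwise), unname(pred[2:6]))
})

test_that("strict per-fold ranking does not beat full-data ranking on pure noise", {
  co <- generate_cohort(noise_config(n = 118, seed = 13))
  qm <- build_quantifier_matrix(co)
  age <- co$participants$age
  sel <- select_quantifiers(qm, age)
  mk <- function(mode) clock_spec("linear", top_k_range = c(4L, 8L),
                                  ranking_mode = mode, seed = 5)
  cv_pooled <- suppressMessages(cross_validate(mk("pooled"), qm, sel, age))
  cv_strict <- suppressMessages(cross_validate(mk("strict"), qm, sel, age))
  expect_lte(max(cv_strict$mean_ev), max(cv_pooled$mean_ev) + 0.05)
  expect_lt(max(cv_strict$mean_ev), 0.1)
})
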