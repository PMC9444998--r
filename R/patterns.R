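# Age-relative performance patterns: Gaussian-weighted moving statistics
# over age, ternary better/normal/worse coding, K-means phenotyping, and
# group-wise tests of mean cognitive age acceleration against zero.

#' Gaussian age-weighted mean and SD
#'
#' Weights every observation by a Gaussian kernel in age centered at
#' `center_age` (`w_i = exp(-(age_i - center_age)^2 / (2 kernel_sd^2))`)
#' and returns the weighted mean and the population-form weighted SD
#' (`sqrt(sum w (v - m)^2 / sum w)`).
#'
#' @param values,ages Aligned numeric vectors.
#' @param center_age Age (years) at which the moving statistics are taken.
#' @param kernel_sd Kernel SD in years (default 7).
#' @return List with `mean`, `sd` and the effective weight sum `sum_w`.
#' @export
gaussian_weighted_stats <- function(values, ages, center_age, kernel_sd = 7) {
  if (length(values) != length(ages)) {
    stop_validation("'values' and 'ages' must align")
  }
  check_number(kernel_sd, "kernel_sd", lower = .Machine$double.eps)
  ok <- is.finite(values) & is.finite(ages)
  values <- values[ok]; ages <- ages[ok]
  if (length(values) < 2L) stop_data("need at least 2 observations")
  w <- exp(-(ages - center_age)^2 / (2 * kernel_sd^2))
  if (sum(w) <= 0 || !any(w > 1e-12)) {
    stop_data("no peers in age window around ", format(center_age))
  }
  m <- sum(w * values) / sum(w)
  s <- sqrt(sum(w * (values - m)^2) / sum(w))
  list(mean = m, sd = s, sum_w = sum(w))
}

#' Ternary performance label relative to age peers
#'
#' A value deviating from the age-weighted peer mean by more than
#' `threshold_factor` peer SDs (strict inequality) is labeled `"better"`
#' or `"worse"` according to the quantifier's direction; everything else is
#' `"normal"`. With a zero peer SD any deviation is classified by
#' direction.
#'
#' @param value Observed quantifier value(s).
#' @param weighted_mean,weighted_sd Peer statistics from
#'   [gaussian_weighted_stats()].
#' @param direction `"lower_is_better"` or `"higher_is_better"`.
#' @param threshold_factor Multiple of the peer SD defining the band
#'   (default 0.5, i.e. half an SD).
#' @return Character vector of labels in `c("better", "normal", "worse")`.
#' @export
classify_performance <- function(value, weighted_mean, weighted_sd,
                                 direction = c("lower_is_better",
                                               "higher_is_better"),
                                 threshold_factor = 0.5) {
  direction <- match.arg(direction)
  check_number(threshold_factor, "threshold_factor",
               lower = .Machine$double.eps)
  if (any(weighted_sd < 0, na.rm = TRUE)) {
    stop_validation("'weighted_sd' must be >= 0")
  }
  lo <- weighted_mean - threshold_factor * weighted_sd
  hi <- weighted_mean + threshold_factor * weighted_sd
  lab <- ifelse(value < lo, "low", ifelse(value > hi, "high", "normal"))
  if (direction == "lower_is_better") {
    lab[lab == "low"] <- "better"; lab[lab == "high"] <- "worse"
  } else {
    lab[lab == "low"] <- "worse"; lab[lab == "high"] <- "better"
  }
  lab
}

PATTERN_LABELS <- c(better = 1, normal = 0, worse = -1)

#' Default pattern quantifiers and directions
#'
#' The eight psychophysiological quantifiers used for phenotyping: the
#' campimetry shade-step counts (dH+, dH-) and stimulus
#' recognition/hiding-time means, and the motor and sensorimotor reaction
#' time means of the two sensorimotor tests. All are "smaller is better".
#'
#' @return Named character vector mapping quantifier name to direction.
#' @export
default_direction_map <- function() {
  q <- c("CM dH+ identity", "CM dH- identity", "CM t+ mean", "CM t- mean",
         "SM1 MR mean", "SM1 SMR mean", "SM2 MR mean", "SM2 SMR mean")
  stats::setNames(rep("lower_is_better", length(q)), q)
}

#' Build the ternary performance-pattern matrix
#'
#' For each participant and pattern quantifier, peer statistics are
#' computed over the whole cohort (the participant included) with a
#' Gaussian kernel centered at that participant's age, and the
#' participant's value is classified better/normal/worse.
#'
#' @param qm Quantifier matrix.
#' @param ages Chronological ages aligned with `qm` rows.
#' @param direction_map Named vector mapping each pattern quantifier to its
#'   direction; default [default_direction_map()].
#' @param pattern_quantifiers Quantifier columns to use (default: the names
#'   of `direction_map`).
#' @param kernel_sd Gaussian kernel SD in years.
#' @param threshold_factor Deviation threshold in peer SDs.
#' @return Character matrix of labels with a numeric `encoding` attribute
#'   (+1 better, 0 normal, -1 worse) of the same shape.
#' @export
build_pattern_matrix <- function(qm, ages, direction_map = default_direction_map(),
                                 pattern_quantifiers = names(direction_map),
                                 kernel_sd = 7, threshold_factor = 0.5) {
  if (nrow(qm) != length(ages)) stop_validation("'qm' rows and 'ages' must align")
  missing_cols <- setdiff(pattern_quantifiers, colnames(qm))
  if (length(missing_cols)) {
    stop_data("pattern quantifier(s) not in matrix: ",
              paste(sQuote(missing_cols), collapse = ", "))
  }
  nodir <- setdiff(pattern_quantifiers, names(direction_map))
  if (length(nodir)) {
    stop_validation("no direction for quantifier(s): ",
                    paste(sQuote(nodir), collapse = ", "))
  }
  labels <- matrix(NA_character_, nrow = nrow(qm),
                   ncol = length(pattern_quantifiers),
                   dimnames = list(rownames(qm), pattern_quantifiers))
  for (q in pattern_quantifiers) {
    v <- qm[, q]
    for (i in seq_len(nrow(qm))) {
      if (!is.finite(v[i]) || !is.finite(ages[i])) next
      st <- gaussian_weighted_stats(v, ages, ages[i], kernel_sd)
      labels[i, q] <- classify_performance(v[i], st$mean, st$sd,
                                           direction_map[[q]],
                                           threshold_factor)
    }
  }
  enc <- matrix(PATTERN_LABELS[labels], nrow = nrow(labels),
                dimnames = dimnames(labels))
  attr(labels, "encoding") <- enc
  class(labels) <- c("pattern_matrix", class(labels))
  labels
}

#' Cluster participants by performance pattern
#'
#' K-means on the numeric (+1/0/-1) encoding with Euclidean distance, best
#' of `n_restarts` random starts by within-cluster sum of squares. Groups
#' are relabeled `A`, `B`, ... in descending order of their mean count of
#' "better" cells (ties by size then by original cluster index), so labels
#' are deterministic given the seed.
#'
#' @param patterns A `pattern_matrix` from [build_pattern_matrix()].
#' @param k Number of clusters (default 7).
#' @param seed RNG seed.
#' @param n_restarts Number of random K-means starts.
#' @return Factor of group letters (one per participant, named by id) with
#'   attribute `within_ss`.
#' @export
cluster_patterns <- function(patterns, k = 7L, seed = 1L, n_restarts = 50L) {
  enc <- attr(patterns, "encoding")
  if (is.null(enc)) stop_validation("'patterns' must come from build_pattern_matrix()")
  ok <- stats::complete.cases(enc)
  x <- enc[ok, , drop = FALSE]
  n_distinct <- nrow(unique(x))
  if (k > n_distinct) {
    stop_validation(sprintf(
      "k = %d exceeds the %d distinct patterns; choose a smaller k",
      k, n_distinct))
  }
  # MacQueen updates behave better than Hartigan-Wong on ternary data with
  # many duplicated rows
  km <- with_local_seed(seed, stats::kmeans(x, centers = k,
                                            nstart = n_restarts,
                                            iter.max = 100L,
                                            algorithm = "MacQueen"))
  better_per_cluster <- vapply(seq_len(k), function(cl) {
    mean(rowSums(x[km$cluster == cl, , drop = FALSE] == 1))
  }, numeric(1))
  ord <- order(-better_per_cluster, -as.vector(km$size), seq_len(k))
  letter <- character(k)
  letter[ord] <- LETTERS[seq_len(k)]
  labels <- factor(rep(NA_character_, nrow(enc)), levels = LETTERS[seq_len(k)])
  labels[ok] <- letter[km$cluster]
  names(labels) <- rownames(enc)
  attr(labels, "within_ss") <- km$tot.withinss
  labels
}

#' Test each group's mean age acceleration against zero
#'
#' One-sample two-sided t-test of the group's cognitive age accelerations
#' against a zero mean (no acceleration). Groups of fewer than two members
#' with finite accelerations, or with zero variance, are reported with `NA`
#' test statistics.
#'
#' @param accelerations Numeric vector of accelerations (years), aligned
#'   with `labels`.
#' @param labels Group labels (factor or character).
#' @return data.frame: `group`, `n`, `mean_accel`, `t`, `p`.
#' @export
test_group_acceleration <- function(accelerations, labels) {
  if (length(accelerations) != length(labels)) {
    stop_validation("'accelerations' and 'labels' must align")
  }
  labels <- factor(labels)
  rows <- lapply(levels(labels), function(g) {
    a <- accelerations[labels == g]
    a <- a[is.finite(a)]
    if (length(a) < 2L || stats::sd(a) == 0) {
      return(data.frame(group = g, n = length(a),
                        mean_accel = if (length(a)) mean(a) else NA_real_,
                        t = NA_real_, p = NA_real_, stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(a, mu = 0, alternative = "two.sided")
    data.frame(group = g, n = length(a), mean_accel = mean(a),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
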