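# Screening of quantifiers by Pearson correlation with an age variable,
# with Benjamini-Hochberg control of the false discovery rate.

#' Pearson correlation with a t-based two-sided p-value
#'
#' Tests the null hypothesis of zero Pearson correlation using
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' Pairs with a missing value in either vector are dropped.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `rho`, `p`, `n` and a logical `degenerate` flag; a
#'   constant input (or fewer than 3 complete pairs) yields `NA` statistics
#'   with `degenerate = TRUE` rather than an error.
#' @export
pearson_with_pvalue <- function(x, y) {
  if (length(x) != length(y)) stop_validation("'x' and 'y' must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(rho = unname(ct$estimate), p = ct$p.value, n = n, degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `adj_(i) = min_{j >= i} (m * p_(j) / j)` on the
#' sorted p-values, capped at 1 and mapped back to the input order. `NA`
#' entries propagate as `NA` and are excluded from `m`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
benjamini_hochberg <- function(p) {
  if (!is.numeric(p)) stop_validation("'p' must be numeric")
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop_validation("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Screen quantifiers for association with an age variable
#'
#' Computes the Pearson correlation of every quantifier column with `age`,
#' a t-based two-sided p-value, Benjamini-Hochberg adjusted p-values, and a
#' deterministic rank (ascending adjusted p, ties by raw p then name;
#' degenerate quantifiers last). The `significant` flag marks adjusted
#' p below `alpha` (default 0.001).
#'
#' @param qm Quantifier matrix (participants x quantifiers).
#' @param age Numeric age vector aligned with the rows of `qm`.
#' @param alpha Significance threshold on the adjusted p-value.
#' @param age_name Label of the screened age variable, recorded in the output.
#' @return data.frame with one row per quantifier: `quantifier`, `rho`,
#'   `p_raw`, `p_adj`, `rank`, `significant`, `degenerate`, `n`, `target`.
#' @export
select_quantifiers <- function(qm, age, alpha = 0.001,
                               age_name = "chronological") {
  if (nrow(qm) != length(age)) {
    stop_validation("rows of 'qm' and length of 'age' must match")
  }
  check_number(alpha, "alpha", lower = 0, upper = 1)
  res <- lapply(colnames(qm), function(q) {
    r <- pearson_with_pvalue(qm[, q], age)
    data.frame(quantifier = q, rho = r$rho, p_raw = r$p, n = r$n,
               degenerate = r$degenerate, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adj <- benjamini_hochberg(res$p_raw)
  ord <- order(res$degenerate, res$p_adj, res$p_raw, res$quantifier)
  res$rank <- NA_integer_
  res$rank[ord] <- seq_len(nrow(res))
  res$significant <- !res$degenerate & !is.na(res$p_adj) & res$p_adj < alpha
  res$target <- age_name
  res <- res[order(res$rank),
             c("quantifier", "rho", "p_raw", "p_adj", "rank",
               "significant", "degenerate", "n", "target")]
  rownames(res) <- NULL
  res
}

#' Ranked quantifier names for clock building
#'
#' Returns quantifier names in screening-rank order. When at least
#' `min_significant` quantifiers are significant, the list is restricted to
#' the significant set (the top-k search then never extends past it);
#' otherwise all non-degenerate quantifiers are returned.
#'
#' @param selection Output of [select_quantifiers()].
#' @param restrict_to_significant Restrict to the significant set when it is
#'   large enough.
#' @param min_significant Minimum size of the significant set required for
#'   the restriction.
#' @return Character vector of quantifier names, strongest association first.
#' @export
ranked_quantifiers <- function(selection, restrict_to_significant = TRUE,
                               min_significant = 5L) {
  sel <- selection[order(selection$rank), ]
  sel <- sel[!sel$degenerate & !is.na(sel$p_adj), ]
  if (restrict_to_significant && sum(sel$significant) >= min_significant) {
    sel <- sel[sel$significant, ]
  }
  sel$quantifier
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Utility for cohort/subset comparability checks (e.g. whether the subset
#' with methylation data has the same age distribution as the full cohort).
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return List with the KS statistic `D` and asymptotic p-value `p`.
#' @export
ks_compare <- function(sample_a, sample_b) {
  sample_a <- sample_a[is.finite(sample_a)]
  sample_b <- sample_b[is.finite(sample_b)]
  if (!length(sample_a) || !length(sample_b)) {
    stop_validation("both samples must be non-empty")
  }
  kt <- suppressWarnings(stats::ks.test(sample_a, sample_b, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}
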