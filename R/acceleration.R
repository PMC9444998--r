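# Age accelerations and their correlation structure across clocks.

#' Per-participant age acceleration
#'
#' `"difference"` mode is `clock_age - chronological_age`; `"residual"`
#' mode (default, standard in the aging-clock literature) is the residual
#' of the ordinary least-squares regression of clock age on chronological
#' age, which is mean-zero and uncorrelated with chronological age by
#' construction. Missing clock ages propagate as `NA` (residual mode fits
#' on the complete pairs).
#'
#' @param clock_age,chronological_age Aligned numeric vectors (years).
#' @param mode `"residual"` or `"difference"`.
#' @return Numeric vector of accelerations (years).
#' @export
compute_acceleration <- function(clock_age, chronological_age,
                                 mode = c("residual", "difference")) {
  mode <- match.arg(mode)
  if (length(clock_age) != length(chronological_age)) {
    stop_validation("'clock_age' and 'chronological_age' must align")
  }
  if (mode == "difference") return(clock_age - chronological_age)
  ok <- is.finite(clock_age) & is.finite(chronological_age)
  if (sum(ok) < 3L) stop_validation("residual mode needs >= 3 complete pairs")
  if (stats::sd(chronological_age[ok]) == 0) {
    stop_validation("residual mode requires non-constant chronological age")
  }
  fit <- stats::lm.fit(cbind(1, chronological_age[ok]), clock_age[ok])
  out <- rep(NA_real_, length(clock_age))
  out[ok] <- fit$residuals
  out
}

#' Build an acceleration panel for several clocks
#'
#' @param ages data.frame/matrix of clock-age columns (years), one row per
#'   participant; must include the column named by `chronological`.
#' @param chronological Name of the chronological-age column.
#' @param mode Passed to [compute_acceleration()].
#' @return data.frame of accelerations, one column per non-chronological
#'   clock, with attribute `mode`.
#' @export
acceleration_panel <- function(ages, chronological = "age",
                               mode = c("residual", "difference")) {
  mode <- match.arg(mode)
  ages <- as.data.frame(ages)
  if (!chronological %in% names(ages)) {
    stop_data("missing chronological-age column: ", chronological)
  }
  chrono <- ages[[chronological]]
  clocks <- setdiff(names(ages), chronological)
  out <- as.data.frame(lapply(ages[clocks], compute_acceleration,
                              chronological_age = chrono, mode = mode))
  names(out) <- clocks
  attr(out, "mode") <- mode
  out
}

#' Pairwise Pearson correlation matrix
#'
#' Pairwise-complete Pearson correlations (rows with `NA` are dropped per
#' pair, supporting clocks measured only on a subset). Constant columns
#' produce `NA` entries and are reported in the `degenerate` attribute.
#'
#' @param panel data.frame or matrix with at least two numeric columns.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(panel) {
  m <- as.matrix(as.data.frame(panel))
  if (ncol(m) < 2L) stop_validation("'panel' needs at least 2 columns")
  storage.mode(m) <- "double"
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  degenerate <- colnames(m)[!is.na(sds) & sds == 0]
  out <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs",
                                     method = "pearson"))
  diag(out) <- 1
  attr(out, "degenerate") <- degenerate
  out
}
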