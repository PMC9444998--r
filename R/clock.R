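# Cognitive-clock construction: age-stratified cross-validated grid search
# over model family, hyperparameters and the number of top-ranked
# quantifiers, followed by a final refit on the full cohort.

CLOCK_FAMILIES <- c("linear", "elastic_net", "svr_rbf", "nu_svr_rbf",
                    "random_forest", "knn", "theil_sen")

#' Default hyperparameter grids per model family
#'
#' Small log-spaced grids for the kernel and penalized families, a modest
#' neighbour range for kNN, and a single forest size; `gamma_scale` for the
#' RBF kernels multiplies the `1/n_features` heuristic width.
#'
#' @return Named list mapping family to a named list of value vectors.
#' @export
default_hyperparameter_grids <- function() {
  list(
    linear = list(),
    elastic_net = list(alpha = c(0.2, 0.5, 0.8), lambda = c(0.01, 0.1, 1)),
    svr_rbf = list(cost = c(1, 10, 100), gamma_scale = c(0.5, 1, 2)),
    nu_svr_rbf = list(nu = c(0.25, 0.5, 0.75), cost = c(1, 10),
                      gamma_scale = 1),
    random_forest = list(num_trees = 300),
    knn = list(k = c(3, 5, 7, 9, 11, 15)),
    theil_sen = list(n_subsets = 200)
  )
}

#' Specification of a clock search
#'
#' @param model_family One of `"linear"`, `"elastic_net"`, `"svr_rbf"`,
#'   `"nu_svr_rbf"`, `"random_forest"`, `"knn"`, `"theil_sen"`.
#' @param hyperparameter_grid Named list of value vectors; `NULL` for the
#'   family's default grid.
#' @param top_k_range Integer vector of feature-count candidates.
#' @param n_folds Number of cross-validation folds.
#' @param age_bins Strictly increasing bin edges used to stratify folds by
#'   age; default 7 equal-width bins on \[10, 90\].
#' @param objective `"mean_EV"` (maximize mean explained variance, default)
#'   or `"mean_MAE"` (minimize mean absolute error).
#' @param ranking_mode `"pooled"` ranks quantifiers once on the full data
#'   before cross-validation (fidelity to the common practice, but the
#'   ranking leaks across folds); `"strict"` re-ranks inside each training
#'   fold.
#' @param seed RNG seed for fold assignment and stochastic families.
#' @return An object of class `clock_spec`.
#' @export
clock_spec <- function(model_family, hyperparameter_grid = NULL,
                       top_k_range = c(4L, 8L, 12L, 16L, 20L, 24L),
                       n_folds = 5L,
                       age_bins = seq(10, 90, length.out = 8),
                       objective = c("mean_EV", "mean_MAE"),
                       ranking_mode = c("pooled", "strict"),
                       seed = 1L) {
  if (!model_family %in% CLOCK_FAMILIES) {
    stop_validation(sprintf("unknown model family '%s'; expected one of %s",
                            model_family,
                            paste(CLOCK_FAMILIES, collapse = ", ")))
  }
  objective <- match.arg(objective)
  ranking_mode <- match.arg(ranking_mode)
  check_number(n_folds, "n_folds", lower = 2)
  if (any(top_k_range < 1)) stop_validation("'top_k_range' values must be >= 1")
  if (any(diff(age_bins) <= 0)) {
    stop_validation("'age_bins' edges must be strictly increasing")
  }
  grid <- hyperparameter_grid %||% default_hyperparameter_grids()[[model_family]]
  structure(list(model_family = model_family, hyperparameter_grid = grid,
                 top_k_range = sort(unique(as.integer(top_k_range))),
                 n_folds = as.integer(n_folds), age_bins = age_bins,
                 objective = objective, ranking_mode = ranking_mode,
                 seed = as.integer(seed)),
            class = "clock_spec")
}

#' Age-stratified fold assignment
#'
#' Participants are binned by age (ages outside the edge range are clamped
#' to the boundary bins), shuffled within bins, and dealt cyclically into
#' folds so that total fold sizes differ by at most one and, within every
#' age bin, per-fold counts differ by at most one. Deterministic given the
#' seed.
#'
#' @param ages Numeric vector of ages.
#' @param n_folds Number of folds.
#' @param bin_edges Strictly increasing bin edges.
#' @param seed RNG seed.
#' @return Integer vector of fold labels in `1..n_folds`.
#' @export
stratified_folds <- function(ages, n_folds = 5L,
                             bin_edges = seq(10, 90, length.out = 8),
                             seed = 1L) {
  n <- length(ages)
  if (n < n_folds) stop_validation("need at least as many participants as folds")
  if (any(diff(bin_edges) <= 0)) {
    stop_validation("'bin_edges' must be strictly increasing")
  }
  clamped <- pmin(pmax(ages, bin_edges[1]), bin_edges[length(bin_edges)])
  bin <- findInterval(clamped, bin_edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  with_local_seed(seed, {
    folds <- integer(n)
    pos <- 0L
    for (b in sort(unique(bin))) {
      members <- which(bin == b)
      members <- members[sample.int(length(members))]
      folds[members] <- ((pos + seq_along(members) - 1L) %% n_folds) + 1L
      pos <- pos + length(members)
    }
    relabel <- sample.int(n_folds)
    relabel[folds]
  })
}

#' Prediction-quality metrics
#'
#' Explained variance `EV = 1 - Var(y - yhat) / Var(y)` (shift-invariant;
#' equals R-squared when the residuals are centered), mean absolute error
#' and median absolute error.
#'
#' @param y_true,y_pred Aligned numeric vectors (years).
#' @return List with `ev`, `mae`, `medae`; `ev` is `NA` when `Var(y_true)`
#'   is zero.
#' @export
evaluate_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || !length(y_true)) {
    stop_validation("'y_true' and 'y_pred' must be non-empty and aligned")
  }
  err <- y_true - y_pred
  vy <- stats::var(y_true)
  ev <- if (length(y_true) < 2L || vy == 0) NA_real_ else 1 - stats::var(err) / vy
  list(ev = ev, mae = mean(abs(err)), medae = stats::median(abs(err)))
}

# --- standardization ---------------------------------------------------------

fit_standardization <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  keep <- is.finite(scale) & scale > 0
  list(center = center[keep], scale = scale[keep],
       columns = colnames(x)[keep], dropped = colnames(x)[!keep])
}

apply_standardization <- function(std, x) {
  x <- x[, std$columns, drop = FALSE]
  sweep(sweep(x, 2, std$center, "-"), 2, std$scale, "/")
}

# --- model fitting per family ------------------------------------------------

fit_model <- function(family, hyper, x, y, seed = 1L) {
  fit <- switch(family,
    linear = {
      co <- qr.coef(qr(cbind(`(Intercept)` = 1, x)), y)
      co[is.na(co)] <- 0
      list(coef = co)
    },
    elastic_net = {
      xx <- if (ncol(x) < 2L) cbind(x, .pad. = 0) else x
      list(fit = glmnet::glmnet(xx, y, alpha = hyper$alpha,
                                standardize = FALSE),
           lambda = hyper$lambda, padded = ncol(x) < 2L)
    },
    svr_rbf = {
      gamma <- (hyper$gamma_scale %||% 1) / ncol(x)
      list(fit = e1071::svm(x, y, type = "eps-regression", kernel = "radial",
                            cost = hyper$cost %||% 1, gamma = gamma,
                            scale = FALSE))
    },
    nu_svr_rbf = {
      gamma <- (hyper$gamma_scale %||% 1) / ncol(x)
      list(fit = e1071::svm(x, y, type = "nu-regression", kernel = "radial",
                            cost = hyper$cost %||% 1, nu = hyper$nu %||% 0.5,
                            gamma = gamma, scale = FALSE))
    },
    random_forest = {
      list(fit = ranger::ranger(x = as.data.frame(x), y = y,
                                num.trees = hyper$num_trees %||% 300,
                                seed = seed, num.threads = 1L))
    },
    knn = {
      k <- min(hyper$k %||% 5, nrow(x))
      list(fit = caret::knnreg(as.data.frame(x), y, k = k))
    },
    theil_sen = {
      fit_theil_sen(x, y, n_subsets = hyper$n_subsets %||% 200, seed = seed)
    },
    stop_validation("unknown model family: ", family)
  )
  structure(list(family = family, fit = fit, columns = colnames(x)),
            class = "clock_model")
}

predict_model <- function(model, x) {
  x <- x[, model$columns, drop = FALSE]
  f <- model$fit
  switch(model$family,
    linear = drop(cbind(1, x) %*% f$coef),
    elastic_net = {
      xx <- if (isTRUE(f$padded)) cbind(x, .pad. = 0) else x
      drop(stats::predict(f$fit, newx = xx, s = f$lambda))
    },
    svr_rbf = ,
    nu_svr_rbf = unname(stats::predict(f$fit, x)),
    random_forest = stats::predict(f$fit, data = as.data.frame(x))$predictions,
    knn = unname(stats::predict(f$fit, as.data.frame(x))),
    theil_sen = predict_theil_sen(f, x)
  )
}

# Multivariate Theil-Sen: exact least-squares fits on random subsets of
# p + 1 points, coordinate-wise median of the coefficient vectors. For a
# single predictor this reduces to the classical median of pairwise slopes
# (all pairs when feasible).
fit_theil_sen <- function(x, y, n_subsets = 200, seed = 1L) {
  n <- nrow(x); p <- ncol(x)
  m <- p + 1L
  if (n <= m) {
    co <- qr.coef(qr(cbind(1, x)), y)
    co[is.na(co)] <- 0
    return(list(coef = co))
  }
  coefs <- with_local_seed(seed, {
    if (p == 1L && choose(n, 2) <= n_subsets * 4) {
      idx <- utils::combn(n, 2)
      t(apply(idx, 2, function(ii) {
        dx <- x[ii[2], 1] - x[ii[1], 1]
        if (dx == 0) return(c(NA_real_, NA_real_))
        sl <- (y[ii[2]] - y[ii[1]]) / dx
        c(NA_real_, sl)
      }))
    } else {
      t(vapply(seq_len(n_subsets), function(b) {
        ii <- sample.int(n, m)
        co <- qr.coef(qr(cbind(1, x[ii, , drop = FALSE])), y[ii])
        co[is.na(co)] <- 0
        co
      }, numeric(m)))
    }
  })
  slope <- apply(coefs[, -1, drop = FALSE], 2, stats::median, na.rm = TRUE)
  intercept <- stats::median(y - drop(x %*% slope))
  list(coef = c(intercept, slope))
}

predict_theil_sen <- function(fit, x) drop(cbind(1, x) %*% fit$coef)

expand_hyper_grid <- function(grid) {
  if (!length(grid)) return(list(list()))
  df <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

hyper_label <- function(hyper) {
  if (!length(hyper)) return("default")
  paste(sprintf("%s=%g", names(hyper), unlist(hyper)), collapse = ";")
}

# --- cross-validation --------------------------------------------------------

#' Cross-validated grid search for one model family
#'
#' For every (hyperparameter, top_k) grid point: standardization is fit on
#' the training folds only, the model is fit on the top-k ranked quantifier
#' columns, and EV/MAE/MedAE are measured on the held-out fold. In
#' `ranking_mode = "strict"` the screening ranking itself is recomputed
#' inside each training fold; in `"pooled"` mode the supplied full-data
#' ranking is reused.
#'
#' @param spec A [clock_spec()].
#' @param qm Quantifier matrix.
#' @param selection Output of [select_quantifiers()] on (`qm`, `age`).
#' @param age Target age vector aligned with `qm` rows.
#' @param alpha Screening threshold used when re-ranking in strict mode.
#' @return data.frame with one row per grid point: `family`, `hyper`
#'   (label), `top_k`, mean and SD of EV/MAE/MedAE across folds, plus
#'   list-columns `hyper_list` and `fold_metrics`; attribute `folds` holds
#'   the fold assignment.
#' @export
cross_validate <- function(spec, qm, selection, age, alpha = 0.001) {
  if (nrow(qm) != length(age)) stop_validation("'qm' rows and 'age' must align")
  candidates <- ranked_quantifiers(selection)
  keep <- stats::complete.cases(qm[, candidates, drop = FALSE]) & is.finite(age)
  if (sum(!keep)) {
    message(sprintf("cross_validate: dropping %d participant(s) with missing values",
                    sum(!keep)))
  }
  qm <- qm[keep, , drop = FALSE]
  age <- age[keep]
  folds <- stratified_folds(age, spec$n_folds, spec$age_bins, spec$seed)
  hypers <- expand_hyper_grid(spec$hyperparameter_grid)

  grid <- list()
  for (h in seq_along(hypers)) {
    for (k in spec$top_k_range) grid[[length(grid) + 1L]] <- list(hyper = hypers[[h]], top_k = k)
  }

  per_fold_rank <- lapply(seq_len(spec$n_folds), function(f) {
    if (spec$ranking_mode == "strict") {
      tr <- folds != f
      sel <- select_quantifiers(qm[tr, , drop = FALSE], age[tr], alpha = alpha,
                                age_name = selection$target[1] %||% "age")
      ranked_quantifiers(sel)
    } else {
      candidates
    }
  })

  rows <- list()
  for (g in grid) {
    metrics <- matrix(NA_real_, nrow = spec$n_folds, ncol = 3,
                      dimnames = list(NULL, c("ev", "mae", "medae")))
    usable <- TRUE
    for (f in seq_len(spec$n_folds)) {
      ranked <- per_fold_rank[[f]]
      if (g$top_k > length(ranked)) { usable <- FALSE; break }
      tr <- folds != f
      std <- fit_standardization(qm[tr, ranked, drop = FALSE])
      cols <- intersect(ranked, std$columns)[seq_len(min(g$top_k, length(std$columns)))]
      if (!length(cols)) { usable <- FALSE; break }
      xtr <- apply_standardization(std, qm[tr, , drop = FALSE])[, cols, drop = FALSE]
      xte <- apply_standardization(std, qm[!tr, , drop = FALSE])[, cols, drop = FALSE]
      model <- fit_model(spec$model_family, g$hyper, xtr, age[tr],
                         seed = spec$seed + f)
      m <- evaluate_metrics(age[!tr], predict_model(model, xte))
      metrics[f, ] <- c(m$ev, m$mae, m$medae)
    }
    if (!usable) {
      message(sprintf("cross_validate: skipping top_k=%d (%s): exceeds available quantifiers",
                      g$top_k, hyper_label(g$hyper)))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      family = spec$model_family, hyper = hyper_label(g$hyper),
      top_k = g$top_k,
      mean_ev = mean(metrics[, "ev"]), sd_ev = stats::sd(metrics[, "ev"]),
      mean_mae = mean(metrics[, "mae"]), sd_mae = stats::sd(metrics[, "mae"]),
      mean_medae = mean(metrics[, "medae"]), sd_medae = stats::sd(metrics[, "medae"]),
      stringsAsFactors = FALSE)
    rows[[length(rows)]]$hyper_list <- I(list(g$hyper))
    rows[[length(rows)]]$fold_metrics <- I(list(metrics))
  }
  if (!length(rows)) stop_validation("no usable grid points (top_k too large?)")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "folds") <- folds
  attr(out, "kept") <- keep
  out
}

#' Pick the winning grid point
#'
#' Maximizes mean EV (or minimizes mean MAE under `objective = "mean_MAE"`).
#' Ties break deterministically by smaller `top_k`, then hyperparameter
#' label, then family name.
#'
#' @param results One or several row-bound [cross_validate()] tables.
#' @param objective `"mean_EV"` or `"mean_MAE"`.
#' @return The winning row as a one-row data.frame (with `hyper_list`).
#' @export
select_optimal <- function(results, objective = c("mean_EV", "mean_MAE")) {
  objective <- match.arg(objective)
  if (!nrow(results)) stop_validation("'results' must be non-empty")
  score <- if (objective == "mean_EV") results$mean_ev else -results$mean_mae
  ord <- order(-score, results$top_k, results$hyper, results$family)
  results[ord[1L], , drop = FALSE]
}

#' Fit the final clock on the full cohort
#'
#' Refits the winning specification on all rows and retains everything
#' needed for prediction: standardization parameters, the selected top-k
#' quantifier names, and the trained model state.
#'
#' @param winner One-row result from [select_optimal()] (or a list with
#'   `family`, `hyper_list`, `top_k`).
#' @param qm Quantifier matrix.
#' @param selection Output of [select_quantifiers()].
#' @param age Target age vector.
#' @param target Name of the predicted age variable.
#' @param seed RNG seed for stochastic families.
#' @return An object of class `cognitive_clock`.
#' @export
fit_final <- function(winner, qm, selection, age, target = "chronological",
                      seed = 1L) {
  hyper <- if (is.data.frame(winner)) winner$hyper_list[[1]] else winner$hyper
  family <- if (is.data.frame(winner)) winner$family else winner$family
  top_k <- if (is.data.frame(winner)) winner$top_k else winner$top_k
  ranked <- ranked_quantifiers(selection)
  keep <- stats::complete.cases(qm[, ranked, drop = FALSE]) & is.finite(age)
  qm <- qm[keep, , drop = FALSE]; age <- age[keep]
  std <- fit_standardization(qm[, ranked, drop = FALSE])
  cols <- intersect(ranked, std$columns)[seq_len(min(top_k, length(std$columns)))]
  x <- apply_standardization(std, qm)[, cols, drop = FALSE]
  model <- fit_model(family, hyper, x, age, seed = seed)
  structure(list(family = family, hyper = hyper, top_k = top_k,
                 quantifiers = cols, standardization = std, model = model,
                 target = target, seed = seed,
                 n_train = nrow(x)),
            class = "cognitive_clock")
}

#' @exportS3Method base::print
print.cognitive_clock <- function(x, ...) {
  cat(sprintf("<cognitive_clock> family=%s (%s), %d quantifiers, target=%s, n=%d\n",
              x$family, hyper_label(x$hyper), length(x$quantifiers),
              x$target, x$n_train))
  invisible(x)
}

#' Predict ages with a fitted cognitive clock
#'
#' @param clock A `cognitive_clock` from [fit_final()].
#' @param qm Quantifier matrix containing every selected quantifier column.
#' @return Named numeric vector of predicted ages (years); rows with a
#'   missing value in any selected quantifier yield `NA`.
#' @export
predict_age <- function(clock, qm) {
  missing_cols <- setdiff(clock$quantifiers, colnames(qm))
  if (length(missing_cols)) {
    stop_data("quantifier matrix is missing column(s): ",
              paste(sQuote(missing_cols), collapse = ", "))
  }
  x <- qm[, clock$quantifiers, drop = FALSE]
  ok <- stats::complete.cases(x)
  out <- stats::setNames(rep(NA_real_, nrow(qm)), rownames(qm))
  if (any(ok)) {
    std <- clock$standardization
    xs <- sweep(sweep(x[ok, , drop = FALSE], 2,
                      std$center[clock$quantifiers], "-"),
                2, std$scale[clock$quantifiers], "/")
    out[ok] <- predict_model(clock$model, xs)
  }
  if (any(!ok)) {
    message(sprintf("predict_age: %d row(s) with missing quantifiers -> NA",
                    sum(!ok)))
  }
  out
}
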