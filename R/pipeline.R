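# End-to-end orchestration with file-based stage handoff: every stage
# reads and writes CSV in the run directory, so runs are inspectable,
# resumable and byte-reproducible given the config seed.

#' Default pipeline configuration
#'
#' A complete run on a simulated cohort of 118 participants: quantify,
#' screen against chronological age at adjusted p < 0.001, grid-search the
#' configured model families by stratified 5-fold cross-validation,
#' compute residual-mode accelerations and their correlations, and cluster
#' age-relative performance patterns into 7 groups.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param model_families Families entered in the clock grid search.
#' @return Nested list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L,
                                    model_families = c("linear", "elastic_net",
                                                       "svr_rbf", "nu_svr_rbf",
                                                       "random_forest", "knn",
                                                       "theil_sen")) {
  list(
    seed = as.integer(seed),
    simulate = list(n_participants = 118L, age_min = 19, age_max = 85,
                    female_fraction = 81 / 118, accel_sd = 5, trait_sd = 12),
    targets = "chronological",
    select = list(alpha = 0.001),
    fit = list(model_families = model_families,
               top_k_range = c(4L, 8L, 12L, 16L, 20L, 24L),
               n_folds = 5L, objective = "mean_EV", ranking_mode = "pooled"),
    accelerate = list(mode = "residual"),
    cluster = list(k = 7L, kernel_sd = 7, threshold_factor = 0.5,
                   n_restarts = 50L)
  )
}

validate_pipeline_config <- function(config) {
  if (is.null(config$seed)) stop_validation("config must set 'seed'")
  fams <- config$fit$model_families %||% "svr_rbf"
  bad <- setdiff(fams, CLOCK_FAMILIES)
  if (length(bad)) {
    stop_validation("unknown model family(ies) in config: ",
                    paste(sQuote(bad), collapse = ", "),
                    "; expected one of ", paste(CLOCK_FAMILIES, collapse = ", "))
  }
  targets <- config$targets %||% "chronological"
  mode <- config$accelerate$mode %||% "residual"
  if (!mode %in% c("residual", "difference")) {
    stop_validation("accelerate$mode must be 'residual' or 'difference'")
  }
  invisible(config)
}

stage_seed <- function(config, stage) {
  offsets <- c(simulate = 0L, fit = 101L, cluster = 211L)
  (as.integer(config$seed) + unname(offsets[stage])) %% .Machine$integer.max
}

target_age_column <- function(target) {
  map <- c(chronological = "age", phenoage = "PhenoAge", dnamage = "DNAmAge",
           hannum = "DNAmAgeHannum", dnamphenoage = "DNAmPhenoAge",
           grimage = "DNAmGrimAge")
  if (target %in% names(map)) unname(map[target]) else target
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> quantify -> select -> fit (per age
#' target) -> accelerate -> cluster -> report, writing every intermediate
#' table as CSV into `out_dir`. All randomness derives from the single
#' config seed, so a rerun with the same config reproduces every CSV
#' byte-identically.
#'
#' @param config Configuration list (see [default_pipeline_config()]) or
#'   path to a YAML file with the same structure.
#' @param out_dir Run directory (created if absent).
#' @return Invisibly, a list with the fitted clocks, cross-validation
#'   tables, acceleration panel, cluster report and output paths.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_pipeline_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  t0 <- Sys.time()
  timings <- list()
  outputs <- character()
  tick <- function(stage, start) {
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), start, units = "secs"))
  }

  # -- simulate (or load) -----------------------------------------------------
  s <- Sys.time()
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    cfg <- cohort_config(
      n_participants = sim$n_participants %||% 118L,
      age_min = sim$age_min %||% 19, age_max = sim$age_max %||% 85,
      female_fraction = sim$female_fraction %||% 81 / 118,
      index_specs = sim$index_specs %||% default_index_specs(
        saturation_age = sim$saturation_age %||% NULL),
      accel_sd = sim$accel_sd %||% 5,
      trait_sd = sim$trait_sd %||% 12,
      bio_clock_specs = if (isFALSE(sim$bio_clocks)) NULL else
        default_bio_clock_specs(sim$shared_accel_loading %||% 0.6),
      subgroups = sim$subgroups,
      seed = stage_seed(config, "simulate"))
    cohort <- generate_cohort(cfg)
    outputs <- c(outputs, write_cohort(cohort, out_dir))
    mapping <- default_quantifier_mapping(cfg$index_specs)
  } else {
    input_dir <- config$input_dir %||% out_dir
    cohort <- read_cohort(input_dir)
    mapping <- config$mapping %||%
      default_quantifier_mapping(default_index_specs())
  }
  tick("simulate", s)
  message(sprintf("[simulate] participants=%d indices=%d",
                  nrow(cohort$participants), length(index_names(cohort))))

  # -- quantify ---------------------------------------------------------------
  s <- Sys.time()
  qm <- build_quantifier_matrix(cohort, mapping)
  qpath <- file.path(out_dir, "quantifiers.csv")
  write_quantifier_matrix(qm, qpath)
  outputs <- c(outputs, qpath)
  tick("quantify", s)
  message(sprintf("[quantify] quantifiers=%d", ncol(qm)))

  # -- select + fit per target ------------------------------------------------
  targets <- config$targets %||% "chronological"
  alpha <- config$select$alpha %||% 0.001
  clocks <- list(); cv_tables <- list(); selections <- list()
  for (target in targets) {
    s <- Sys.time()
    col <- target_age_column(target)
    if (!col %in% names(cohort$participants)) {
      stop_data(sprintf("cohort lacks the '%s' column needed for target '%s'",
                        col, target))
    }
    age <- cohort$participants[[col]]
    selection <- select_quantifiers(qm, age, alpha = alpha, age_name = target)
    spath <- file.path(out_dir, sprintf("selection_%s.csv", target))
    utils::write.csv(selection, spath, row.names = FALSE)
    outputs <- c(outputs, spath)
    selections[[target]] <- selection
    message(sprintf("[select] target=%s significant=%d/%d", target,
                    sum(selection$significant), nrow(selection)))

    fit_cfg <- config$fit %||% list()
    fams <- fit_cfg$model_families %||% "svr_rbf"
    results <- list()
    for (fam in fams) {
      spec <- clock_spec(fam,
                         hyperparameter_grid = fit_cfg$hyperparameter_grids[[fam]],
                         top_k_range = fit_cfg$top_k_range %||% c(4L, 8L, 12L, 16L, 20L, 24L),
                         n_folds = fit_cfg$n_folds %||% 5L,
                         objective = fit_cfg$objective %||% "mean_EV",
                         ranking_mode = fit_cfg$ranking_mode %||% "pooled",
                         seed = stage_seed(config, "fit"))
      results[[fam]] <- suppressMessages(
        cross_validate(spec, qm, selection, age, alpha = alpha))
    }
    cv <- do.call(rbind, lapply(results, function(r) {
      r[setdiff(names(r), c("hyper_list", "fold_metrics"))]
    }))
    rownames(cv) <- NULL
    cvpath <- file.path(out_dir, sprintf("cv_results_%s.csv", target))
    utils::write.csv(cv, cvpath, row.names = FALSE)
    outputs <- c(outputs, cvpath)
    all_results <- do.call(rbind, results)
    winner <- select_optimal(all_results, fit_cfg$objective %||% "mean_EV")
    clock <- fit_final(winner, qm, selection, age, target = target,
                       seed = stage_seed(config, "fit"))
    clocks[[target]] <- clock
    cv_tables[[target]] <- all_results
    pred <- suppressMessages(predict_age(clock, qm))
    ppath <- file.path(out_dir, sprintf("predicted_%s.csv", target))
    utils::write.csv(data.frame(id = names(pred), predicted = unname(pred)),
                     ppath, row.names = FALSE)
    outputs <- c(outputs, ppath)
    tick(paste0("fit_", target), s)
    message(sprintf("[fit] target=%s winner=%s (%s) top_k=%d mean_EV=%.3f mean_MAE=%.2f",
                    target, winner$family, winner$hyper, winner$top_k,
                    winner$mean_ev, winner$mean_mae))
  }

  # -- accelerate -------------------------------------------------------------
  s <- Sys.time()
  mode <- config$accelerate$mode %||% "residual"
  chrono <- cohort$participants$age
  primary <- targets[1]
  cog_pred <- suppressMessages(predict_age(clocks[[primary]], qm))
  age_table <- data.frame(age = chrono, CognitiveAge = unname(cog_pred))
  bio_cols <- setdiff(names(cohort$participants), c("id", "sex", "age"))
  for (bc in bio_cols) age_table[[bc]] <- cohort$participants[[bc]]
  panel <- acceleration_panel(age_table, chronological = "age", mode = mode)
  apath <- file.path(out_dir, "accelerations.csv")
  utils::write.csv(cbind(id = cohort$participants$id, panel, mode = mode),
                   apath, row.names = FALSE)
  cor_ages <- correlation_matrix(age_table)
  cor_accel <- correlation_matrix(panel)
  c1 <- file.path(out_dir, "correlations_ages.csv")
  c2 <- file.path(out_dir, "correlations_accelerations.csv")
  utils::write.csv(as.data.frame(cor_ages), c1)
  utils::write.csv(as.data.frame(cor_accel), c2)
  outputs <- c(outputs, apath, c1, c2)
  tick("accelerate", s)
  message(sprintf("[accelerate] mode=%s clocks=%d", mode, ncol(panel)))

  # -- cluster ----------------------------------------------------------------
  s <- Sys.time()
  ccfg <- config$cluster %||% list()
  patterns <- build_pattern_matrix(
    qm, chrono,
    direction_map = ccfg$direction_map %||% default_direction_map(),
    kernel_sd = ccfg$kernel_sd %||% 7,
    threshold_factor = ccfg$threshold_factor %||% 0.5)
  labels <- cluster_patterns(patterns, k = ccfg$k %||% 7L,
                             seed = stage_seed(config, "cluster"),
                             n_restarts = ccfg$n_restarts %||% 50L)
  report <- test_group_acceleration(panel$CognitiveAge, labels)
  p1 <- file.path(out_dir, "patterns.csv")
  p2 <- file.path(out_dir, "clusters.csv")
  p3 <- file.path(out_dir, "cluster_report.csv")
  utils::write.csv(data.frame(id = rownames(patterns),
                              unclass(patterns)[, , drop = FALSE],
                              check.names = FALSE), p1, row.names = FALSE)
  utils::write.csv(data.frame(id = names(labels), group = as.character(labels)),
                   p2, row.names = FALSE)
  utils::write.csv(report, p3, row.names = FALSE)
  outputs <- c(outputs, p1, p2, p3)
  tick("cluster", s)
  message(sprintf("[cluster] k=%d significant_groups=%d", ccfg$k %||% 7L,
                  sum(report$p < 0.05, na.rm = TRUE)))

  # -- manifest ---------------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("cogclock")),
    seed = config$seed,
    config = config[setdiff(names(config), "mapping")],
    outputs = basename(unname(outputs)),
    stage_timings_sec = timings,
    total_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)

  invisible(list(cohort = cohort, quantifiers = qm, selections = selections,
                 cv = cv_tables, clocks = clocks, accelerations = panel,
                 correlations = list(ages = cor_ages, accelerations = cor_accel),
                 patterns = patterns, groups = labels, cluster_report = report,
                 outputs = unname(outputs)))
}
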