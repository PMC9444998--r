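# Synthetic cohort generation for cognitive-clock analyses.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: per-index trial series whose location drifts with an "effective
# age" (chronological age plus a latent per-participant aging acceleration
# shared across all indices), heteroscedastic and optionally bimodal trial
# noise, bounded error fractions, and biological-age columns that load
# partially on the same latent acceleration.

#' Describe one cognitive index for the synthetic generator
#'
#' An index is either a `series` (one value per trial, e.g. a reaction time)
#' or a `scalar` (one value per participant, e.g. an error fraction or a
#' shade-step count). The location of the index drifts linearly with the
#' participant's effective age (chronological age + latent acceleration);
#' an optional saturation age flattens the drift beyond that age, producing
#' a nonlinear age-response.
#'
#' @param name Index identifier, e.g. `"CM t+"`.
#' @param kind `"series"` (trial series) or `"scalar"` (one value).
#' @param n_trials Trials per participant for series indices; for
#'   fraction-unit indices it is the binomial denominator (number of items).
#' @param baseline Location at the reference age of 20 years (ms, steps, or
#'   a fraction in (0,1) for `unit = "fraction"`).
#' @param age_slope Location change per year of effective age. For fraction
#'   indices the slope acts on the logit scale.
#' @param noise_sd Trial-level Gaussian noise SD (ignored for fraction
#'   indices, whose dispersion is binomial; `noise_sd = 0` there yields the
#'   deterministic success probability).
#' @param mixture_weight Probability that a trial comes from a slow mode
#'   (location mixture producing multimodal trial distributions).
#' @param slow_mode_shift Added location of the slow mode.
#' @param direction `"lower_is_better"` or `"higher_is_better"`.
#' @param unit `"time"`, `"count"` or `"fraction"`; fraction values are
#'   generated as Binomial(`n_trials`, p(age))/`n_trials` and so stay in
#'   \[0, 1\].
#' @param saturation_age Optional age (years) beyond which the age drift
#'   saturates (location held at its value at `saturation_age`); `NULL` for
#'   a purely linear drift.
#' @return An object of class `index_spec`.
#' @export
index_spec <- function(name, kind = c("series", "scalar"), n_trials = 10L,
                       baseline, age_slope, noise_sd = 0,
                       mixture_weight = 0, slow_mode_shift = 0,
                       direction = c("lower_is_better", "higher_is_better"),
                       unit = c("time", "count", "fraction"),
                       saturation_age = NULL) {
  kind <- match.arg(kind)
  direction <- match.arg(direction)
  unit <- match.arg(unit)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_validation("'name' must be a non-empty string")
  }
  check_number(n_trials, "n_trials", lower = 1)
  check_number(baseline, "baseline")
  check_number(age_slope, "age_slope")
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(mixture_weight, "mixture_weight", lower = 0, upper = 1)
  check_number(slow_mode_shift, "slow_mode_shift")
  if (unit == "fraction" && (baseline <= 0 || baseline >= 1)) {
    stop_validation("'baseline' must lie in (0, 1) for fraction indices")
  }
  if (!is.null(saturation_age)) check_number(saturation_age, "saturation_age")
  structure(list(name = name, kind = kind, n_trials = as.integer(n_trials),
                 baseline = baseline, age_slope = age_slope,
                 noise_sd = noise_sd, mixture_weight = mixture_weight,
                 slow_mode_shift = slow_mode_shift, direction = direction,
                 unit = unit, saturation_age = saturation_age),
            class = "index_spec")
}

#' Default set of 16 cognitive index specifications
#'
#' Eight time-valued trial series (campimetry stimulus recognition/hiding
#' times; motor, sensorimotor and decision times of two sensorimotor tests)
#' and eight scalar indices (campimetry shade-step counts dH+/dH-, error
#' fractions, accuracy fractions). Baselines and slopes are in the ranges
#' typical for computerized psychophysiological batteries: reaction-time
#' indices slow by a few ms per year, error fractions grow on the logit
#' scale, and trial noise includes a minority slow mode so trial
#' distributions are broad and often bimodal. Only a subset of indices is
#' strongly age-sensitive (the campimetry recognition/hiding times and
#' first-recognized-shade count, the arithmetic false-rejection fraction,
#' and the reversed-letter motor reaction); the rest drift weakly, so that
#' feature screening has genuine work to do at realistic cohort sizes.
#'
#' @param mixture_weight Slow-mode probability shared by all time series.
#' @param saturation_age Optional saturation age applied to every index
#'   (see [index_spec()]); `NULL` keeps the drift linear.
#' @return A list of [index_spec()] objects.
#' @export
default_index_specs <- function(mixture_weight = 0.15, saturation_age = NULL) {
  time_series <- function(name, baseline, slope, noise) {
    index_spec(name, "series", n_trials = 10L, baseline = baseline,
               age_slope = slope, noise_sd = noise,
               mixture_weight = mixture_weight, slow_mode_shift = 250,
               direction = "lower_is_better", unit = "time",
               saturation_age = saturation_age)
  }
  count_scalar <- function(name, baseline, slope, noise) {
    index_spec(name, "scalar", baseline = baseline, age_slope = slope,
               noise_sd = noise, direction = "lower_is_better",
               unit = "count", saturation_age = saturation_age)
  }
  frac_scalar <- function(name, baseline, slope, direction) {
    index_spec(name, "scalar", n_trials = 40L, baseline = baseline,
               age_slope = slope, noise_sd = 1, direction = direction,
               unit = "fraction", saturation_age = saturation_age)
  }
  list(
    time_series("CM t+",   900, 7.0, 120),
    time_series("CM t-",   800, 6.0, 110),
    time_series("SM1 MR",  420, 0.4,  70),
    time_series("SM1 SMR", 950, 0.8, 130),
    time_series("SM1 DT",  530, 0.3,  90),
    time_series("SM2 MR",  430, 3.2,  70),
    time_series("SM2 SMR", 1000, 0.8, 140),
    time_series("SM2 DT",  570, 0.3,  95),
    count_scalar("CM dH+",  8, 0.12, 1.8),
    count_scalar("CM dH-", 10, 0.02, 2.0),
    frac_scalar("SM1 ERR-1", 0.08,  0.030, "lower_is_better"),
    frac_scalar("SM1 ERR-2", 0.06,  0.004, "lower_is_better"),
    frac_scalar("SM2 ERR-1", 0.09,  0.008, "lower_is_better"),
    frac_scalar("SM2 ERR-2", 0.07,  0.004, "lower_is_better"),
    frac_scalar("SM1 ACC",  0.90, -0.004, "higher_is_better"),
    frac_scalar("SM2 ACC",  0.88, -0.004, "higher_is_better")
  )
}

#' Default biological-clock simulation parameters
#'
#' Each simulated clock is `intercept + slope * chronological_age +
#' shared_accel_loading * latent_accel + Normal(0, independent_noise_sd)`.
#' The shared loading makes part of each clock's acceleration common with
#' the cognitive latent, which is what the acceleration-correlation analysis
#' is designed to detect. Noise SDs differ across clocks so that their
#' agreement with chronological age spans the few-years range reported for
#' phenotypic and epigenetic clocks.
#'
#' @param shared_accel_loading Loading of every clock on the latent
#'   acceleration (unitless multiplier on years).
#' @return Named list of per-clock parameter lists.
#' @export
default_bio_clock_specs <- function(shared_accel_loading = 0.6) {
  clock <- function(noise_sd) {
    list(intercept = 0, slope = 1,
         shared_accel_loading = shared_accel_loading,
         independent_noise_sd = noise_sd)
  }
  list(
    PhenoAge     = clock(3),
    DNAmAge      = clock(6),
    DNAmAgeHannum = clock(7),
    DNAmPhenoAge = clock(10),
    DNAmGrimAge  = clock(5)
  )
}

#' Configuration for a synthetic cohort
#'
#' Defaults mirror the study design the analysis targets: 118 participants
#' aged 19-85 (ages uniform over the range), roughly two-thirds female, a
#' latent per-participant aging acceleration with SD 5 years shared across
#' all cognitive indices and (partially) across biological clocks.
#'
#' @param n_participants Cohort size.
#' @param age_min,age_max Age range in years (uniform sampling).
#' @param female_fraction Expected fraction of females.
#' @param index_specs List of [index_spec()] objects.
#' @param accel_sd SD (years) of the latent per-participant acceleration.
#' @param trait_sd SD (years-equivalent) of a latent age-independent
#'   performance level shared across all indices but, unlike the
#'   acceleration, not loaded by any biological clock. This is what makes
#'   age prediction from cognitive data genuinely hard: two people of the
#'   same age and aging rate still differ stably in performance.
#' @param bio_clock_specs Named list of biological-clock parameters
#'   (see [default_bio_clock_specs()]); `NULL` for none.
#' @param subgroups Optional list of `list(fraction=, accel_shift=)`
#'   entries; each participant is independently assigned to at most one
#'   subgroup with the given probability, and the subgroup's `accel_shift`
#'   (years) is added to the latent acceleration. Used to inject
#'   fast/decelerated or slow/accelerated phenotypes for recovery studies.
#' @param seed RNG seed; generation is fully deterministic given the seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 118L, age_min = 19, age_max = 85,
                          female_fraction = 81 / 118,
                          index_specs = default_index_specs(),
                          accel_sd = 5, trait_sd = 12,
                          bio_clock_specs = default_bio_clock_specs(),
                          subgroups = NULL, seed = 1L) {
  check_number(n_participants, "n_participants", lower = 0)
  check_number(age_min, "age_min")
  check_number(age_max, "age_max")
  if (age_min >= age_max) stop_validation("'age_min' must be < 'age_max'")
  check_number(female_fraction, "female_fraction", lower = 0, upper = 1)
  check_number(accel_sd, "accel_sd", lower = 0)
  check_number(trait_sd, "trait_sd", lower = 0)
  check_number(seed, "seed")
  if (!length(index_specs)) stop_validation("'index_specs' must be non-empty")
  for (sp in index_specs) {
    if (!inherits(sp, "index_spec")) {
      stop_validation("every element of 'index_specs' must be an index_spec")
    }
  }
  nms <- vapply(index_specs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop_validation("index names must be unique")
  if (!is.null(bio_clock_specs)) {
    if (is.null(names(bio_clock_specs)) || any(!nzchar(names(bio_clock_specs)))) {
      stop_validation("'bio_clock_specs' must be a named list")
    }
    for (bc in bio_clock_specs) {
      for (f in c("intercept", "slope", "shared_accel_loading",
                  "independent_noise_sd")) {
        if (is.null(bc[[f]]) || !is.finite(bc[[f]])) {
          stop_validation(sprintf("bio clock spec field '%s' must be finite", f))
        }
      }
      if (bc$independent_noise_sd < 0) {
        stop_validation("'independent_noise_sd' must be >= 0")
      }
    }
  }
  if (!is.null(subgroups)) {
    tot <- 0
    for (sg in subgroups) {
      check_number(sg$fraction, "subgroup fraction", lower = 0, upper = 1)
      check_number(sg$accel_shift, "subgroup accel_shift")
      tot <- tot + sg$fraction
    }
    if (tot > 1) stop_validation("subgroup fractions must sum to <= 1")
  }
  names(index_specs) <- nms
  structure(list(n_participants = as.integer(n_participants),
                 age_min = age_min, age_max = age_max,
                 female_fraction = female_fraction,
                 index_specs = index_specs, accel_sd = accel_sd,
                 trait_sd = trait_sd,
                 bio_clock_specs = bio_clock_specs,
                 subgroups = subgroups, seed = as.integer(seed)),
            class = "cohort_config")
}

saturate_age <- function(age, saturation_age) {
  if (is.null(saturation_age)) age else pmin(age, saturation_age)
}

index_location <- function(spec, effective_age) {
  a <- saturate_age(effective_age, spec$saturation_age)
  if (spec$unit == "fraction") {
    stats::plogis(stats::qlogis(spec$baseline) + spec$age_slope * (a - 20))
  } else {
    spec$baseline + spec$age_slope * (a - 20)
  }
}

generate_index_values <- function(spec, effective_age) {
  loc <- index_location(spec, effective_age)
  if (spec$unit == "fraction") {
    if (spec$noise_sd == 0) return(loc)
    k <- spec$n_trials
    return(stats::rbinom(1L, k, loc) / k)
  }
  n <- if (spec$kind == "series") spec$n_trials else 1L
  shift <- if (spec$mixture_weight > 0) {
    spec$slow_mode_shift * stats::rbinom(n, 1L, spec$mixture_weight)
  } else numeric(n)
  noise <- if (spec$noise_sd > 0) stats::rnorm(n, 0, spec$noise_sd) else numeric(n)
  rep(loc, n) + shift + noise
}

#' Simulate biological ages for one participant
#'
#' Each clock's age is `intercept + slope * chronological_age +
#' shared_accel_loading * latent_accel + Normal(0, independent_noise_sd)`.
#' Draws come from the current RNG stream, so results are deterministic
#' inside a seeded generation run.
#'
#' @param chronological_age Chronological age in years.
#' @param latent_accel Latent aging acceleration in years.
#' @param bio_clock_specs Named list of clock parameter lists.
#' @return Named numeric vector of simulated biological ages (years).
#' @export
generate_biological_ages <- function(chronological_age, latent_accel,
                                     bio_clock_specs) {
  vapply(bio_clock_specs, function(bc) {
    noise <- if (bc$independent_noise_sd > 0) {
      stats::rnorm(1L, 0, bc$independent_noise_sd)
    } else 0
    bc$intercept + bc$slope * chronological_age +
      bc$shared_accel_loading * latent_accel + noise
  }, numeric(1))
}

#' Generate a synthetic cohort
#'
#' Draws ages uniformly over the configured range, a latent per-participant
#' acceleration (Normal with SD `accel_sd`, plus any subgroup shift) and a
#' latent performance trait (Normal with SD `trait_sd`), trial series for
#' every configured index at the participant's effective age
#' (`chronological + latent_accel + latent_trait`), and biological-age
#' columns (which load on the acceleration only). Sex is generated but
#' carries no effect on any index by default.
#'
#' @param config A [cohort_config()] object.
#' @return An object of class `cohort`: a list with `participants`
#'   (data.frame: id, sex, age and one column per biological clock),
#'   `series` (long data.frame: id, index, trial, value) and `truth`
#'   (data.frame: id, latent_accel, latent_trait, subgroup). The `truth`
#'   table is ground truth for recovery tests only and is never consumed by
#'   analysis stages.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop_validation("'config' must be a cohort_config object")
  }
  n <- config$n_participants
  with_local_seed(config$seed, {
    id <- sprintf("P%04d", seq_len(n))
    sex <- ifelse(stats::runif(n) < config$female_fraction, "F", "M")
    age <- stats::runif(n, config$age_min, config$age_max)
    latent <- if (config$accel_sd > 0) stats::rnorm(n, 0, config$accel_sd) else rep(0, n)
    trait <- if (config$trait_sd > 0) stats::rnorm(n, 0, config$trait_sd) else rep(0, n)
    subgroup <- rep("none", n)
    if (!is.null(config$subgroups) && n > 0) {
      fr <- vapply(config$subgroups, `[[`, numeric(1), "fraction")
      labs <- names(config$subgroups) %||%
        paste0("subgroup", seq_along(config$subgroups))
      if (is.null(names(config$subgroups))) names(fr) <- labs
      u <- stats::runif(n)
      cuts <- cumsum(fr)
      for (i in seq_len(n)) {
        j <- which(u[i] <= cuts)[1]
        if (!is.na(j)) {
          subgroup[i] <- labs[j]
          latent[i] <- latent[i] + config$subgroups[[j]]$accel_shift
        }
      }
    }
    eff <- age + latent + trait

    series <- vector("list", n * length(config$index_specs))
    k <- 0L
    for (i in seq_len(n)) {
      for (sp in config$index_specs) {
        v <- generate_index_values(sp, eff[i])
        k <- k + 1L
        series[[k]] <- data.frame(id = id[i], index = sp$name,
                                  trial = seq_along(v), value = v,
                                  stringsAsFactors = FALSE)
      }
    }
    series <- do.call(rbind, series)
    rownames(series) <- NULL

    participants <- data.frame(id = id, sex = sex, age = age,
                               stringsAsFactors = FALSE)
    if (!is.null(config$bio_clock_specs)) {
      n_clocks <- length(config$bio_clock_specs)
      bio <- vapply(seq_len(n), function(i) {
        generate_biological_ages(age[i], latent[i], config$bio_clock_specs)
      }, numeric(n_clocks))
      bio <- matrix(bio, nrow = n, ncol = n_clocks, byrow = TRUE,
                    dimnames = list(NULL, names(config$bio_clock_specs)))
      participants <- cbind(participants, as.data.frame(bio))
    }
    truth <- data.frame(id = id, latent_accel = latent, latent_trait = trait,
                        subgroup = subgroup, stringsAsFactors = FALSE)
    structure(list(participants = participants, series = series,
                   truth = truth, config = config),
              class = "cohort")
  })
}

#' @exportS3Method base::print
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants, %d indices, ages %.1f-%.1f\n",
              nrow(x$participants), length(unique(x$series$index)),
              min(x$participants$age), max(x$participants$age)))
  invisible(x)
}

#' Names of the indices present in a cohort
#' @param cohort A `cohort` object.
#' @return Character vector of index names.
#' @export
index_names <- function(cohort) unique(cohort$series$index)

#' Write a cohort to CSV files
#'
#' Writes `cohort.csv` (participant level), `indices.csv` (long trial table)
#' and `truth.csv` (latent acceleration; ground truth for recovery tests,
#' never an analysis input) into `dir`.
#'
#' @param cohort A `cohort` object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(cohort = file.path(dir, "cohort.csv"),
             indices = file.path(dir, "indices.csv"),
             truth = file.path(dir, "truth.csv"))
  utils::write.csv(cohort$participants, paths[["cohort"]], row.names = FALSE)
  utils::write.csv(cohort$series, paths[["indices"]], row.names = FALSE)
  utils::write.csv(cohort$truth, paths[["truth"]], row.names = FALSE)
  invisible(paths)
}

#' Read a cohort from CSV files
#'
#' Reads the tables written by [write_cohort()]. The truth file is optional
#' and, when present, is attached only for recovery tests.
#'
#' @param dir Directory containing `cohort.csv` and `indices.csv`.
#' @param expected_indices Optional character vector of known index names;
#'   unknown names in `indices.csv` raise an error listing the known ones.
#' @return A `cohort` object.
#' @export
read_cohort <- function(dir, expected_indices = NULL) {
  cohort_path <- file.path(dir, "cohort.csv")
  indices_path <- file.path(dir, "indices.csv")
  if (!file.exists(cohort_path)) stop_data("missing file: ", cohort_path)
  if (!file.exists(indices_path)) stop_data("missing file: ", indices_path)
  participants <- utils::read.csv(cohort_path, stringsAsFactors = FALSE)
  for (col in c("id", "sex", "age")) {
    if (!col %in% names(participants)) {
      stop_data(sprintf("cohort.csv is missing required column '%s'", col))
    }
  }
  if (anyDuplicated(participants$id)) stop_data("cohort.csv: duplicated ids")
  series <- utils::read.csv(indices_path, stringsAsFactors = FALSE)
  for (col in c("id", "index", "trial", "value")) {
    if (!col %in% names(series)) {
      stop_data(sprintf("indices.csv is missing required column '%s'", col))
    }
  }
  if (!is.null(expected_indices)) {
    unknown <- setdiff(unique(series$index), expected_indices)
    if (length(unknown)) {
      stop_data(sprintf("indices.csv contains unknown index name(s) %s; known indices: %s",
                        paste(sQuote(unknown), collapse = ", "),
                        paste(sQuote(expected_indices), collapse = ", ")))
    }
  }
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) {
    utils::read.csv(truth_path, stringsAsFactors = FALSE)
  } else NULL
  structure(list(participants = participants, series = series,
                 truth = truth, config = NULL),
            class = "cohort")
}
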