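# Transformation of cognitive index series into named summary quantifiers.

SERIES_STATS <- c("mean", "min", "max", "sd", "median", "q1", "q3")

#' Summary statistics of one index series
#'
#' Computes the requested statistics of a trial series. Quartiles use
#' linear interpolation between order statistics (the common "type 7"
#' definition); `sd` uses the unbiased (n-1) denominator, with the
#' convention that a single-element series has `sd = 0`. An empty series
#' yields `NA` for every requested statistic.
#'
#' @param values Numeric vector of trial values.
#' @param stats Character vector drawn from
#'   `c("mean","min","max","sd","median","q1","q3","identity")`.
#' @return Named numeric vector, one element per requested statistic.
#' @export
summarize_series <- function(values, stats = SERIES_STATS) {
  bad <- setdiff(stats, c(SERIES_STATS, "identity"))
  if (length(bad)) {
    stop_validation("unknown statistic(s): ", paste(sQuote(bad), collapse = ", "))
  }
  values <- values[!is.na(values)]
  out <- stats::setNames(rep(NA_real_, length(stats)), stats)
  if (!length(values)) return(out)
  for (s in stats) {
    out[[s]] <- switch(s,
      mean = mean(values),
      min = min(values),
      max = max(values),
      sd = if (length(values) == 1L) 0 else stats::sd(values),
      median = stats::median(values),
      q1 = unname(stats::quantile(values, 0.25, type = 7)),
      q3 = unname(stats::quantile(values, 0.75, type = 7)),
      identity = if (length(values) == 1L) values else mean(values)
    )
  }
  out
}

#' Default index-to-quantifier mapping
#'
#' All seven series statistics for every series-kind index, and the identity
#' for every scalar-kind index. With the default 16 indices (8 series + 8
#' scalars) this yields 8 x 7 + 8 = 64 quantifiers. The exact composition
#' of a real battery's quantifier list is study-specific, so the mapping is
#' data: a two-column table that can be edited or read from file.
#'
#' @param index_specs List of [index_spec()] objects.
#' @return data.frame with columns `index` and `stat`.
#' @export
default_quantifier_mapping <- function(index_specs = default_index_specs()) {
  rows <- lapply(index_specs, function(sp) {
    if (sp$kind == "series") {
      data.frame(index = sp$name, stat = SERIES_STATS, stringsAsFactors = FALSE)
    } else {
      data.frame(index = sp$name, stat = "identity", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

quantifier_name <- function(index, stat) paste(index, stat)

#' Build the participant-by-quantifier matrix
#'
#' One row per participant (in cohort order), one column per mapping entry,
#' named `"<index> <stat>"`. Values are computed with [summarize_series()];
#' a participant with no trials for an index gets `NA`.
#'
#' @param cohort A `cohort` object.
#' @param mapping data.frame with columns `index` and `stat`
#'   (default: [default_quantifier_mapping()] on the cohort's indices).
#' @return Numeric matrix with participant ids as rownames and quantifier
#'   names as colnames.
#' @export
build_quantifier_matrix <- function(cohort, mapping = NULL) {
  if (is.null(mapping)) {
    mapping <- if (!is.null(cohort$config)) {
      default_quantifier_mapping(cohort$config$index_specs)
    } else {
      stop_validation("'mapping' must be supplied for cohorts read from file")
    }
  }
  if (!all(c("index", "stat") %in% names(mapping))) {
    stop_validation("'mapping' must have columns 'index' and 'stat'")
  }
  if (anyDuplicated(mapping[c("index", "stat")])) {
    stop_validation("mapping entries must be unique")
  }
  known <- index_names(cohort)
  unknown <- setdiff(unique(mapping$index), known)
  if (length(unknown)) {
    stop_validation(sprintf("mapping refers to unknown index name(s) %s; available: %s",
                            paste(sQuote(unknown), collapse = ", "),
                            paste(sQuote(known), collapse = ", ")))
  }
  ids <- cohort$participants$id
  qnames <- quantifier_name(mapping$index, mapping$stat)
  out <- matrix(NA_real_, nrow = length(ids), ncol = nrow(mapping),
                dimnames = list(ids, qnames))
  series_by <- split(cohort$series[c("index", "value")], cohort$series$id)
  for (i in seq_along(ids)) {
    pid <- ids[i]
    s <- series_by[[pid]]
    if (is.null(s)) next
    vals_by_index <- split(s$value, s$index)
    for (j in seq_len(nrow(mapping))) {
      v <- vals_by_index[[mapping$index[j]]]
      if (is.null(v)) next
      out[i, j] <- summarize_series(v, mapping$stat[j])[[1]]
    }
  }
  out
}

#' Write / read a quantifier matrix as CSV
#'
#' The CSV has an `id` first column followed by one column per quantifier.
#'
#' @param qm Numeric matrix from [build_quantifier_matrix()].
#' @param path Output file.
#' @return `write_quantifier_matrix`: the path, invisibly.
#' @export
write_quantifier_matrix <- function(qm, path) {
  df <- data.frame(id = rownames(qm), qm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_quantifier_matrix
#' @export
read_quantifier_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop_data("quantifier file is missing column 'id'")
  m <- as.matrix(df[setdiff(names(df), "id")])
  storage.mode(m) <- "double"
  rownames(m) <- df$id
  m
}
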