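`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' Run code with a local RNG seed, restoring the caller's RNG state afterwards.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("cogclock_validation_error", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("cogclock_data_error", "error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_validation(sprintf("'%s' must be a single finite number in [%s, %s]",
                            name, format(lower), format(upper)))
  }
  invisible(x)
}
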