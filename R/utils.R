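# Classed error conditions so the CLI can map failures to exit codes
# (2 = configuration, 3 = data, 4 = numerical).

stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("pertnet_config_error", "pertnet_error", "error")))
}

stop_data <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("pertnet_data_error", "pertnet_error", "error")))
}

stop_num <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("pertnet_numerical_error", "pertnet_error", "error")))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_config("seed must be a single finite number, got %s", deparse(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# lexicographic comparison of two sorted character vectors; TRUE if a < b
lex_less <- function(a, b) {
  n <- min(length(a), length(b))
  if (n > 0L) {
    for (i in seq_len(n)) {
      if (a[i] < b[i]) return(TRUE)
      if (a[i] > b[i]) return(FALSE)
    }
  }
  length(a) < length(b)
}
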