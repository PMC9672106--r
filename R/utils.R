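#' Evaluate an expression under a temporary RNG seed
#'
#' All stochastic generators in this package are pure functions of their
#' parameters and a seed: the global RNG state is saved, the seed applied,
#' and the previous state restored afterwards.
#'
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# stop() with a call-free, classed condition so callers can test on class
abort <- function(msg, class = "toccsl_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}

assert <- function(cond, msg, class = "toccsl_invalid_argument") {
  if (!isTRUE(cond)) abort(msg, class)
}

# trapezoidal integral on a uniform grid
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
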