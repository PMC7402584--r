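# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed, restoring global RNG state afterwards
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that a single integer seed per operation fully determines
#' the output and no global RNG state leaks.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# scalar validators; stop() with the argument name in the message
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("'%s' must be > %s", name, lower), call. = FALSE)
  if (!strict_lower && x < lower)
    stop(sprintf("'%s' must be >= %s", name, lower), call. = FALSE)
  if (x > upper)
    stop(sprintf("'%s' must be <= %s", name, upper), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  invisible(x)
}

# message-level logging for skipped-record counts (never silent)
log_msg <- function(fmt, ...) message(sprintf(fmt, ...))
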