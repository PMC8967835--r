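# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{expr} with the global RNG seeded at \code{seed} and restores
#' the prior RNG state afterwards, so library functions that simulate
#' internally do not perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Derive a reproducible child seed from a master seed and an index,
# kept within the 32-bit signed integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(index) * 7919) %% 2147483647L)
}

stop_if_not_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max)
    stop(sprintf("'%s' must be a single finite number in [%s, %s]", name,
                 format(min), format(max)), call. = FALSE)
  invisible(x)
}

# Sample standard deviation (n-1 denominator); NA-free input expected.
sample_sd <- function(x) stats::sd(x)

# Root mean square of successive differences.
rmssd <- function(x) {
  d <- diff(x)
  sqrt(mean(d^2))
}
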