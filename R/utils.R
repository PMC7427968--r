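#' Round half away from zero
#'
#' Decimal rounding where ties go away from zero (the convention used when
#' formatting reported numbers), unlike [round()] which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded at `digits` decimals.
#' @examples
#' round_half_up(0.2745, 3) # 0.275
#' round(0.2745, 3)         # 0.274 (banker's rounding)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # the eps nudge keeps values that are decimal ties (stored just below .5 in
  # binary, e.g. 0.2745) on the away-from-zero side
  sign(x) * trunc(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed`, then restores the caller's
#' `.Random.seed`, so seeded library internals (the landscape simulator, the
#' bootstrap) never perturb the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
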