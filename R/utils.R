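# Internal helpers shared across modules.

#' Trapezoidal integral
#'
#' @param x abscissae (strictly increasing)
#' @param y ordinates
#' @return scalar integral
#' @keywords internal
#' @noRd
trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations take an explicit seed; no global state leaks.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

db_to_amp <- function(db) 10^(db / 20)
db_to_pow <- function(db) 10^(db / 10)
pow_to_db <- function(p) 10 * log10(p)

# unit vector, errors on zero norm
unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n <= 0) stop("zero-norm vector cannot be normalized")
  v / n
}

stop_hprfd <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "hprfd_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
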