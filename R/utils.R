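#' @keywords internal
"_PACKAGE"

# Validation helpers shared across the package. All user-facing errors go
# through stop_bad() so messages carry the offending argument name.

stop_bad <- function(arg, msg) {
  stop(sprintf("invalid `%s`: %s", arg, msg), call. = FALSE)
}

check_flag <- function(ok, arg, msg) {
  if (!isTRUE(ok)) stop_bad(arg, msg)
  invisible(TRUE)
}

check_count <- function(x, arg, min = 1L) {
  check_flag(length(x) == 1L && is.numeric(x) && is.finite(x) &&
               x == round(x) && x >= min,
             arg, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

check_number <- function(x, arg, min = -Inf, max = Inf) {
  check_flag(length(x) == 1L && is.numeric(x) && is.finite(x) &&
               x >= min && x <= max,
             arg, sprintf("must be a single number in [%s, %s]", min, max))
  as.numeric(x)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so package internals that need
#' reproducible draws do not disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive an independent child seed from a parent seed
#'
#' One global seed fans out to per-fold and per-model streams through an
#' integer mixing step (multiply-xor hash in double arithmetic, reduced
#' modulo 2^31 - 1 so the result is always a valid 32-bit R seed).
#'
#' @param seed parent integer seed.
#' @param ... one or more integer stream indices (fold, model, stage ...).
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1, 3, 2)
derive_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.numeric(seed) %% 2147483647
  for (k in c(idx, 0)) {
    x <- (x * 48271 + as.numeric(k) * 16807 + 12345) %% 2147483647
    # xor-fold the high bits back in, staying in exact double-int range
    hi <- floor(x / 65536)
    x <- (x + hi * 31 + 7919) %% 2147483647
  }
  as.integer(x %% 2147483646) + 1L
}

# clamp numeric vector
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
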