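# RNG scoping and stream derivation.
#
# Every simulator takes an explicit integer seed and evaluates its random
# draws inside with_seed(), which restores the caller's RNG state afterwards.
# Multi-stage runs derive per-stage seeds from one master seed through
# derive_seed(), so adding a stage never perturbs the draws of another.

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the random seed, evaluates `expr`, then restores the global RNG
#' state, so seeded functions do not disturb the caller's random stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

#' Derive a stream seed from a master seed
#'
#' Deterministic splitting rule `(seed + 7919 * stream) mod (2^31 - 160)`,
#' used to give each pipeline stage (and each replicate within a stage) an
#' independent, reproducible seed. The modulus keeps derived seeds inside
#' the 32-bit integer range.
#'
#' @param seed Master integer seed.
#' @param stream Non-negative integer stream index.
#' @return An integer seed.
#' @export
#' @examples
#' derive_seed(1, 0:3)
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(stream)) %% 2147483487)
}

# Shared argument checks ----------------------------------------------------

check_number <- function(x, name, lower = -Inf, upper = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("'%s' must be in [%s, %s], got %s", name,
                 format(lower), format(upper), format(x)), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("'%s' must be an integer, got %s", name, format(x)),
         call. = FALSE)
  invisible(x)
}

check_range <- function(x, name, lower = 0) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)) ||
      x[1] > x[2] || x[1] < lower)
    stop(sprintf("'%s' must be an increasing numeric pair >= %s", name,
                 format(lower)), call. = FALSE)
  invisible(x)
}
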