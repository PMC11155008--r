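#' @keywords internal
"_PACKAGE"

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded internals never perturb the user's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed and a counter, staying within the
# 32-bit signed range. The scheme (master + 100003 * counter mod 2^31 - 1)
# is fixed so that cohorts and epoch shuffles are extensible without
# rewriting earlier draws.
derive_seed <- function(master, counter) {
  as.integer((as.double(master) + 100003 * as.double(counter)) %% 2147483647)
}

# round-half-up, elementwise (base round() is half-to-even)
round_half_up <- function(x) floor(x + 0.5)

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single value in [0, 1]", name), call. = FALSE)
  }
}
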