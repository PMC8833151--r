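#' Round half away from zero
#'
#' Decimal rounding with halves going up (2.5 -> 3), the convention used for
#' the reported tables, as opposed to the banker's rounding of [round()].
#'
#' @param x numeric vector.
#' @param digits decimal places (default 0).
#' @return rounded numeric vector.
#' @examples
#' roundHalfUp(c(2.5, 3.5, 42.46), 0)
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derive a reproducible child seed from a root seed and a stream label, so
# each stochastic operation is independently reproducible. Polynomial string
# hash folded into [1, 2^31 - 2].
#' @noRd
childSeed <- function(seed, ...) {
  label <- paste(c(...), collapse = ":")
  h <- as.double(seed %% 2147483647L)
  for (v in utf8ToInt(label)) h <- (h * 31 + v) %% 2147483647
  as.integer(h %% 2147483646) + 1L
}

# Evaluate expr under a given seed without disturbing the caller's RNG state.
#' @noRd
withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Case-fold and trim species names; synonym resolution is out of scope.
#' @noRd
normalizeSpecies <- function(x) casefold(trimws(x), upper = FALSE)

#' @noRd
abdCondition <- function(msg, class, call = sys.call(-1)) {
  structure(
    class = c(class, "arbodiv_error", "error", "condition"),
    list(message = msg, call = call)
  )
}

#' @noRd
abdStop <- function(msg, class) stop(abdCondition(msg, class))
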