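# Internal helpers: seed handling and argument checks.

#' Derive a stream-specific sub-seed from a global seed
#'
#' All stochastic operations in the package draw their randomness from a
#' sub-seed derived from one global integer seed by this fixed splitting rule,
#' so that independent stages (imputation cycles, permutation tests,
#' simulators) use decorrelated streams while the whole run stays reproducible
#' from a single integer.
#'
#' @param seed Global integer seed.
#' @param stream Non-negative integer stream index.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
split_seed <- function(seed, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(stream), length(stream) == 1L, stream >= 0)
  m <- 2147483647 # 2^31 - 1, Mersenne prime; multiplicative congruential step
  s <- (as.double(seed) %% m) + 1
  k <- as.double(stream) + 1
  as.integer(((s * 48271) %% m * k + 69621 * k) %% m)
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Reject non-finite or out-of-range scalar config fields with a message
# naming the field.
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("config field '", name, "' must be a single finite number", call. = FALSE)
  if (strict_lower && x <= lower)
    stop("config field '", name, "' must be > ", lower, call. = FALSE)
  if (!strict_lower && x < lower)
    stop("config field '", name, "' must be >= ", lower, call. = FALSE)
  if (x > upper)
    stop("config field '", name, "' must be <= ", upper, call. = FALSE)
  if (integer && x != round(x))
    stop("config field '", name, "' must be an integer", call. = FALSE)
  invisible(x)
}
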