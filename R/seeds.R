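#' Derive a stream-specific seed from a master seed
#'
#' All randomness in the package flows from one integer seed. Independent
#' stages (path jitter, noise injection, augmentation draws, weight
#' initialisation, splits) derive their own sub-seed by hashing the master
#' seed together with a string tag and an optional counter, so stages can
#' be re-run or tested in isolation without perturbing each other's
#' streams.
#'
#' @param seed master integer seed.
#' @param tag character tag naming the consumer stream.
#' @param counter optional non-negative integer for per-item streams.
#' @return an integer in `[0, 2^31 - 2]`, suitable for `set.seed()`.
#' @export
#' @examples
#' derive_seed(1, "noise")
#' derive_seed(1, "noise", 3)
derive_seed <- function(seed, tag, counter = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647  # 2^31 - 1 (Mersenne prime, keeps seeds in integer range)
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(tag)) h <- (h * 131 + code) %% m
  h <- (h * 131 + (as.numeric(counter) %% m)) %% m
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded from (seed, tag, counter).
with_seed <- function(seed, tag, counter = 0L, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, tag, counter))
  expr
}
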