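#' @import methods
#' @importFrom stats aggregate as.formula binomial coef complete.cases cor
#'   glm logLik median quantile rbinom runif sd setNames vcov rnorm
#' @importFrom utils head read.csv tail write.csv
NULL

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.  All stochastic functions in the package
# route their randomness through this so no call mutates global RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_seed) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a stream-specific child seed so independent stages of a pipeline
# seeded once do not share RNG streams.  Kept below 2^31 - 1.
childSeed <- function(seed, stream) {
  (as.double(seed) * 7919 + as.double(stream) * 104729) %% 2147483629
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
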