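# Internal helpers shared across modules.

#' @importFrom methods new validObject is as slot slotNames
#' @importFrom stats phyper p.adjust runif rbinom setNames
#' @importFrom utils head tail
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards.  All stochastic
# operations in the package funnel through this so that per-unit
# substreams are independent of evaluation order.
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic substream derivation: fold (seed, i, j) into [0, 2^31).
# Plain integer arithmetic on doubles; stays exact below 2^53.
deriveSeed <- function(seed, i, j = 0L) {
  s <- (as.numeric(seed) * 48271 + as.numeric(i) * 7919 + as.numeric(j) * 104729) %% 2147483647
  as.integer(s)
}

# Strict scalar checks used by constructors/validity.
isScalarNumber <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
isScalarCount <- function(x) isScalarNumber(x) && x >= 0 && x == floor(x)
isScalarString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Reverse-complement for plain character DNA.
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
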