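#' @import methods
#' @importFrom stats cor dist median quantile rnorm runif predict sd
#' @importFrom utils read.csv write.csv
NULL

# Evaluate expr with a temporary RNG state seeded by `seed`; the caller's
# RNG state is untouched.
withSeed <- function(seed, expr) {
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

# 32-bit FNV-1a over the UTF-8 bytes of the "|"-joined arguments, masked to
# 31 bits so the result is a valid set.seed() argument. Stable across
# sessions and platforms; used for per-instance seeds and stage cache keys.
stableHash <- function(...) {
  txt <- paste(vapply(list(...), function(x) paste(format(x, digits = 15),
                                                   collapse = ","),
                      character(1)), collapse = "|")
  bytes <- as.integer(charToRaw(enc2utf8(txt)))
  h <- 2166136261
  for (b in bytes) {
    # XOR with a byte only touches the low 8 bits; keeps h a double < 2^32
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by the FNV prime 16777619, split into 16-bit
    # halves so every intermediate stays exactly representable in a double
    h <- (((floor(h / 65536) * 16777619) %% 65536) * 65536 +
            (h %% 65536) * 16777619) %% 4294967296
  }
  as.integer(h %% 2147483647)
}

#' Deterministic per-instance seed
#'
#' Derives the random seed of one noise instance from the cohort-level base
#' seed and the instance coordinates, so that replicates are independent yet
#' every instance is exactly reproducible.
#'
#' @param baseSeed integer base seed.
#' @param subjectID subject identifier.
#' @param levelIndex 1-based index of the noise level.
#' @param replicateIndex 1-based replicate index.
#' @return An integer seed in `[0, 2^31)`.
#' @export
instanceSeed <- function(baseSeed, subjectID, levelIndex, replicateIndex) {
  stableHash("instance", baseSeed, subjectID, levelIndex, replicateIndex)
}

isCount <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    abs(x - round(x)) < 1e-8
}
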