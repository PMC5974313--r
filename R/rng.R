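#' Derive a deterministic sub-stream seed
#'
#' All scene-level simulation takes one integer seed; each population (and
#' each stage of a pipeline) draws from a sub-stream whose seed is derived
#' arithmetically from the scene seed and a small integer offset, so adding
#' one population never perturbs the coordinates of another. The derivation
#' is `(seed * 48271 + offset * 10007) mod (2^31 - 1)` (Lehmer-style mixing;
#' the modulus keeps derived seeds valid 32-bit integers).
#'
#' @param seed integer scene seed.
#' @param offset non-negative integer identifying the sub-stream.
#' @return an integer seed below 2^31.
#' @export
#' @examples
#' derive_seed(42, 1)
derive_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(offset), length(offset) == 1L, offset >= 0)
  m <- 2147483647
  s <- (abs(as.double(seed)) %% m) * 48271 + as.double(offset) * 10007
  as.integer(s %% m)
}

# Evaluate `expr` under `seed` (if non-NULL) without disturbing the caller's
# RNG stream; with seed = NULL the global stream is consumed as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
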