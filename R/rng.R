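# Deterministic per-library RNG streams.

#' Derive a child seed from a master seed and a string identifier
#'
#' Combines an integer master seed with a polynomial rolling hash of `id`
#' modulo 2^31 - 1, so every library (or stage) gets its own reproducible
#' stream without consuming the global RNG state.
#'
#' @param seed Integer master seed.
#' @param id Character scalar identifying the stream (e.g. a library id).
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, id) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(id), length(id) == 1L)
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(id)) h <- (h * 131 + ch) %% m
  as.integer(((abs(seed) %% m) * 48271 + h) %% m)
}

# Evaluate `code` under `set.seed(seed)`, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
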