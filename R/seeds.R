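#' Derive a deterministic child seed from a global seed
#'
#' One global seed fans out to named per-generator streams so that adding
#' a generator (or re-running one) never shifts another's random stream.
#' The mapping hashes the stream name into an integer offset and combines
#' it with the parent seed by modular multiplication; the result is always
#' a positive 32-bit integer.
#'
#' @param seed integer parent seed
#' @param key character stream name (e.g. "counts", "calcium")
#' @return integer child seed in `[1, 2^31 - 2]`
#' @export
child_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(key))
  b <- utf8ToInt(key)
  h <- 0
  for (ch in b) h <- (h * 131 + ch) %% 2147483629
  out <- (abs(as.numeric(seed)) %% 2147483629) * 48271 + h
  as.integer(out %% 2147483629 + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
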