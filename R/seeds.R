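#' Derive a named sub-stream seed from a global seed
#'
#' One global seed is expanded into independent named sub-streams (simulation
#' dynamics, accessible-surface-area sampling, clustering restarts, sweep
#' replicates) so that each stage is reproducible on its own.  The derivation
#' is a small multiplicative hash over the stream name, kept below 2^31 - 1 so
#' the result is always a valid [set.seed()] input.
#'
#' @param seed integer global seed.
#' @param stream character scalar naming the sub-stream, e.g. `"simulation"`.
#' @return an integer seed.
#' @export
#' @examples
#' derive_seed(1, "simulation")
#' derive_seed(1, "asa")
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(stream), length(stream) == 1L)
  h <- abs(as.double(seed)) %% 2147483647
  for (ch in utf8ToInt(stream)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# run code under a given seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}
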