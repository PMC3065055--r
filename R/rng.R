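#' Independent seeded RNG streams
#'
#' A small wrapper holding a private `.Random.seed` state, so that each
#' simulation module (lattice, vessels, cell division, treatment) draws from
#' its own reproducible stream: module-level results do not change when an
#' unrelated module consumes more or fewer random numbers.
#'
#' @param seed integer seed.
#' @return an object of class `rng_stream`.
#' @export
rng_stream <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed)
  env$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(env) <- "rng_stream"
  env
}

#' Draw from an RNG stream
#'
#' Evaluates `fn()` with the stream's RNG state installed, then captures the
#' advanced state back into the stream and restores the global state.
#'
#' @param stream an [rng_stream()].
#' @param fn a zero-argument function performing the random draws.
#' @return the value of `fn()`.
#' @export
rng_draw <- function(stream, fn) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  fn()
}
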