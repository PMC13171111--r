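# Internal helpers shared across modules.

# Seed the RNG for a scoped computation and return a restorer closure, so
# seeded operations do not disturb the caller's RNG stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    invisible(NULL)
  }
}

#' Derive a per-stage seed from a base seed
#'
#' A single pipeline seed fans out to independent per-stage seeds by a
#' stable hash of the stage name, so each stage is independently
#' reproducible. Result is a positive integer below 2^31.
#'
#' @param seed Base integer seed.
#' @param stage Stage name (character).
#' @return Integer seed.
#' @export
derive_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- 0
  for (cc in codes) h <- (h * 131 + cc) %% 2147480009
  as.integer((as.numeric(seed) * 7919 + h) %% 2147480009 + 1)
}
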