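#' Derive a child seed from a top-level seed
#'
#' Deterministic fan-out of one user-facing seed into independent per-stage
#' seeds, so that re-running a single stage reproduces exactly the stream it
#' saw inside a full pipeline run. Values stay inside the 32-bit integer
#' range `set.seed()` requires.
#'
#' @param seed integer top-level seed.
#' @param stage integer stage index (>= 1).
#' @return an integer seed.
#' @export
fanout_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stage),
            length(stage) >= 1L)
  x <- (abs(as.numeric(seed)) %% 1999993) * 1009 + 7919 * as.numeric(stage)
  as.integer(x %% 2147483647)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Local RNG scope: runs `expr` under `seed` and restores the caller's RNG
# state afterwards, so package functions never clobber the session stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}
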