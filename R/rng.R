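#' Derive a deterministic sub-stream seed
#'
#' Every stochastic stage of the pipeline draws from its own seed, derived
#' deterministically from a root seed plus a purpose tag, so that changing
#' one stage (say, response noise) never perturbs another (say, geometry).
#'
#' @param seed integer root seed.
#' @param ... purpose tags (strings or integers) identifying the sub-stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @examples
#' substream_seed(1, "geometry")
#' substream_seed(1, "noise", 3)
#' @export
substream_seed <- function(seed, ...) {
  tags <- unlist(lapply(list(...), function(x) {
    if (is.character(x)) utf8ToInt(x) else as.integer(x)
  }))
  # 32-bit-safe multiplicative hash, kept in double precision
  h <- as.numeric(seed) %% 2147483647
  for (t in tags) {
    h <- (h * 48271 + as.numeric(t) + 1) %% 2147483647
  }
  as.integer(h)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG to `seed`, evaluates `expr`, and restores the caller's RNG
#' state, so library code never clobbers user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  expr
}
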