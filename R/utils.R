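#' @importFrom rlang %||% .data
#' @importFrom stats rnorm runif sd cor predict setNames quantile var
#' @importFrom utils head tail
NULL

# scoped RNG: run `expr` under a fixed seed without disturbing the caller's
# RNG stream
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

# derive a stream-specific child seed from a master seed (kept below 2^31)
child_seed <- function(seed, stream) {
  (seed * 48271 + stream * 9973) %% 2147483647L
}
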