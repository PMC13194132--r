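# Seed derivation and scoped RNG use.
#
# Every stochastic component draws from its own stream, keyed by
# (global seed, stream label). Streams are realized as integer seeds produced
# by a fixed polynomial hash, so reproducibility does not depend on the order
# in which components are built or stepped.

#' Derive a child seed from a global seed and a stream label
#'
#' Hashes `(seed, label)` into a nonnegative integer below 2^31 usable with
#' [set.seed()]. The hash is a fixed FNV-style polynomial over the label
#' characters mixed with the seed, so the same inputs always give the same
#' stream, independent of build or execution order.
#'
#' @param seed Integer global seed.
#' @param label Character scalar naming the stream (e.g. a node id), or an
#'   integer sub-stream index.
#' @return A single integer in `[0, 2^31 - 1]`.
#' @export
#' @examples
#' derive_seed(1, "exc_a")
#' derive_seed(1, "exc_b")
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (is.numeric(label)) label <- sprintf("#%d", as.integer(label))
  h <- (as.double(seed %% 2147483647) * 31 + 17) %% 2147483647
  for (code in utf8ToInt(label)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}
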