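#' Derive a reproducible sub-stream seed from a master seed and a label
#'
#' Every stochastic stage of the pipeline draws from its own named random
#' stream so that adding or re-ordering stages never perturbs the draws of
#' other stages. The sub-stream seed is a deterministic hash of the master
#' seed and the stage label, kept below 2^31.
#'
#' @param seed Master integer seed.
#' @param label Character stage label, e.g. `"t0"` or `"selection_T5"`.
#' @return An integer seed.
#' @export
#' @examples
#' substream_seed(1, "t0")
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  h <- abs(as.numeric(seed)) %% 2147483647
  for (k in utf8ToInt(label)) {
    h <- (h * 69069 + k) %% 2147483647
  }
  as.integer(h)
}

## Evaluate `code` under the RNG sub-stream (seed, label), restoring RNG state.
with_substream <- function(seed, label, code) {
  withr::with_seed(substream_seed(seed, label), code)
}

## stop() with a consistent call. style
tn_stop <- function(...) stop(..., call. = FALSE)

## reverse complement of plain character DNA (vectorized)
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
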