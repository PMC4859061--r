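#' Derive a reproducible child seed from a base seed and context labels
#'
#' Folds any number of integer-valued labels into the base seed with a
#' multiplicative-congruential mix modulo 2^31 - 1. Used to give every
#' species, phase, time step and sweep replicate its own independent,
#' reproducible random stream: adding a species (or re-ordering runs)
#' never perturbs the draws of another.
#'
#' @param base_seed integer base seed.
#' @param ... integer-valued context labels (species id, step index, ...).
#' @return an integer in `[1, 2^31 - 2]`, suitable for [set.seed()].
#' @export
derive_seed <- function(base_seed, ...) {
  h <- as.numeric(base_seed) %% 2147483647
  for (x in list(...)) {
    for (xi in as.numeric(x)) {
      h <- (h * 69069 + xi %% 2147483647 + 1) %% 2147483647
    }
  }
  as.integer(h %% 2147483645) + 1L
}

mode_code <- function(mode) {
  match(mode, c("parapatric", "sympatric", "combined"))
}
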