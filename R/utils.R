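`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic substream seeds from one master seed, kept inside the
# 32-bit integer range R requires for set.seed().
derive_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offset <- c(expression = 1, go = 2, interactome = 3, permutation = 4)
  k <- if (is.character(component)) offset[[component]] else component
  as.integer((abs(seed) * 7919 + k * 104729) %% 2147483647)
}
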