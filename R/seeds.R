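# Deterministic seed derivation: one master seed fans out into named
# substreams (data cells, per-candidate chains, noise) so that experiments
# are reproducible end to end and substreams stay disjoint. A small
# polynomial string hash keeps every derived seed in 1..2^31-2; exact
# doubles throughout (intermediates stay far below 2^53).

#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' @param master Integer master seed.
#' @param stream Character label naming the substream (e.g. `"data-cell-7"`).
#' @return A single integer seed in `1..2147483646`.
#' @export
derive_seed <- function(master, stream) {
  m <- 2147483647 # 2^31 - 1
  h <- as.numeric(master) %% m
  for (c in utf8ToInt(as.character(stream))) h <- (h * 131 + c) %% m
  as.integer(h %% (m - 1) + 1)
}
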