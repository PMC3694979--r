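# Independent brute-force oracles shared across test files.

# Exhaustive double-loop pair counting for the concordance statistic.
brute_force_c <- function(pred, y) {
  pos <- pred[y == 1]; neg <- pred[y == 0]
  conc <- 0; tied <- 0
  for (a in pos) for (b in neg) {
    if (a > b) conc <- conc + 1 else if (a == b) tied <- tied + 1
  }
  (conc + 0.5 * tied) / (length(pos) * length(neg))
}
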