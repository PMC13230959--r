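# Shared fixture builders.

toy_repertoire <- function(n, len = 30, seed = 1) {
  set.seed(seed)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  setNames(
    vapply(seq_len(n), function(i) paste(sample(aa, len, TRUE), collapse = ""), ""),
    sprintf("p%02d", seq_len(n))
  )
}
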