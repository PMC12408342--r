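# Random test strings over small alphabets, under the suite's RNG.
random_strings <- function(n, min_len = 2, max_len = 10,
                           alphabet = c("a", "b", "c")) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, sample(min_len:max_len, 1), replace = TRUE),
          collapse = "")
  }, character(1))
}

# All strings of the given length over an alphabet (exhaustive grids).
all_strings <- function(len, alphabet) {
  grid <- expand.grid(rep(list(alphabet), len), stringsAsFactors = FALSE)
  apply(grid, 1, paste, collapse = "")
}
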