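#' Shannon entropy of a string
#'
#' The entropy \eqn{H = -\sum_c p_c \log_2 p_c} of the character frequency
#' distribution of `s`, in bits per symbol.  Entropy depends only on the
#' character multiset, so any two anagrams -- e.g. "zbzbzc" and "zzzbbc",
#' whose assembly indices differ -- have identical entropy.
#'
#' @param s a single non-empty string.
#' @return A number in `[0, log2(alphabet size)]`.
#' @export
#' @examples
#' shannon_entropy("zzzz")    # 0
#' shannon_entropy("zb")      # 1
#' shannon_entropy("zbzbzc") == shannon_entropy("zzzbbc")
shannon_entropy <- function(s) {
  check_string(s, "s")
  counts <- frequency_table(s)
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

#' Character frequency table
#'
#' Occurrence counts of each distinct character of `s`, in order of first
#' appearance (the order used for deterministic Huffman construction and
#' for the initial LZW dictionary).
#'
#' @param s a single non-empty string.
#' @return A named integer vector; the counts sum to `nchar(s)`.
#' @export
frequency_table <- function(s) {
  check_string(s, "s")
  cs <- chars(s)
  u <- unique(cs)
  counts <- tabulate(match(cs, u), nbins = length(u))
  names(counts) <- u
  counts
}
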