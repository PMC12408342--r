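#' Deterministic Huffman code of a string
#'
#' Builds the Huffman code for the character frequencies of `s` by
#' repeatedly combining the two least frequent nodes into a new parent
#' until one root remains.  Huffman trees are degenerate (many optimal
#' trees exist), so a fixed tie-breaking convention makes the output
#' bit-exact and reproducible:
#'
#' * node priority is `(weight, creation order)`, leaves being created
#'   first in order of first appearance of their character in `s`;
#' * of the two merged children the heavier gets bit `1`; on equal
#'   weights the leaf (or the earlier-created node) gets bit `1`.
#'
#' Under this convention the anagrams "zbzbzc" and "zzzbbc" share the code
#' `z -> 1`, `b -> 01`, `c -> 00`: the code depends only on the frequency
#' table, so anagrams are indistinguishable to Huffman coding even when
#' their assembly indices differ.
#'
#' @param s a single non-empty string.  A single-symbol string gets the
#'   one-entry code `"0"`.
#' @return An object of class `huffman_code`: a list with elements `code`
#'   (named character vector, character to bitstring), `tree` (nested
#'   list; leaves are characters, internal nodes are `list(bit0, bit1)`)
#'   and `freq` (the frequency table).
#' @seealso [huffman_encode()], [huffman_decode()]
#' @export
#' @examples
#' huffman_code("zbzbzc")$code
huffman_code <- function(s) {
  freq <- frequency_table(s)
  k <- length(freq)
  if (k == 1L) {
    code <- stats::setNames("0", names(freq))
    tree <- names(freq)
    return(structure(list(code = code, tree = tree, freq = freq),
                     class = "huffman_code"))
  }
  # node arrays; leaves first, in first-appearance order
  weight <- as.numeric(freq)
  created <- seq_len(k) - 1L
  is_leaf <- rep(TRUE, k)
  node <- as.list(names(freq))      # leaf char, or list(bit0, bit1)
  active <- seq_len(k)
  counter <- k
  while (length(active) > 1L) {
    ord <- active[order(weight[active], created[active])]
    a <- ord[1L]  # least (weight, creation order)
    b <- ord[2L]
    # bit assignment: heavier child gets 1; ties go to a, which the sort
    # guarantees is the leaf or the earlier-created node
    if (weight[b] > weight[a]) {
      child0 <- a; child1 <- b
    } else {
      child0 <- b; child1 <- a
    }
    counter <- counter + 1L
    weight <- c(weight, weight[a] + weight[b])
    created <- c(created, counter - 1L)
    is_leaf <- c(is_leaf, FALSE)
    node[[counter]] <- list(node[[child0]], node[[child1]])
    active <- c(setdiff(active, c(a, b)), counter)
  }
  tree <- node[[active]]
  code <- character(0)
  walk <- function(nd, bits) {
    if (is.character(nd)) {
      code[[nd]] <<- bits
    } else {
      walk(nd[[1L]], paste0(bits, "0"))
      walk(nd[[2L]], paste0(bits, "1"))
    }
  }
  walk(tree, "")
  code <- code[names(freq)]
  structure(list(code = code, tree = tree, freq = freq),
            class = "huffman_code")
}

#' @export
print.huffman_code <- function(x, ...) {
  cat("Huffman code over", length(x$code), "symbols:\n")
  for (ch in names(x$code)) {
    cat("  ", ch, " -> ", x$code[[ch]], "  (count ", x$freq[[ch]], ")\n",
        sep = "")
  }
  invisible(x)
}

#' Huffman-encode and decode a string
#'
#' `huffman_encode()` concatenates the codewords of the characters of `s`;
#' the encoded length is \eqn{\sum_c \mathrm{count}(c)\,|code(c)|} bits.
#' `huffman_decode()` inverts it; decoding is unambiguous because the code
#' is prefix-free.
#'
#' @param s a single non-empty string.
#' @param code a [huffman_code()]; computed from `s` when omitted.
#' @param bits a bitstring (`"0"`/`"1"` characters).
#' @return `huffman_encode()` returns the encoded bitstring;
#'   `huffman_decode()` returns the decoded string, or raises an error if
#'   `bits` is not decodable under `code`.
#' @export
#' @examples
#' huffman_encode("zbzbzc")  # "101101100"
#' huffman_encode("zzzbbc")  # "111010100"
#' huffman_decode("101101100", huffman_code("zbzbzc"))
huffman_encode <- function(s, code = huffman_code(s)) {
  check_string(s, "s")
  stopifnot(inherits(code, "huffman_code"))
  cs <- chars(s)
  if (!all(cs %in% names(code$code))) {
    stop("`s` contains characters absent from the code", call. = FALSE)
  }
  paste(code$code[cs], collapse = "")
}

#' @rdname huffman_encode
#' @export
huffman_decode <- function(bits, code) {
  stopifnot(inherits(code, "huffman_code"))
  if (!is.character(bits) || length(bits) != 1L || is.na(bits)) {
    stop("`bits` must be a single bitstring", call. = FALSE)
  }
  if (nzchar(bits) && !grepl("^[01]+$", bits)) {
    stop("`bits` must contain only 0 and 1", call. = FALSE)
  }
  if (is.character(code$tree)) {
    # single-symbol code: every bit is one occurrence of the symbol
    if (nzchar(bits) && grepl("1", bits, fixed = TRUE)) {
      stop("undecodable bitstring under single-symbol code", call. = FALSE)
    }
    return(strrep(code$tree, nchar(bits)))
  }
  out <- character(0)
  nd <- code$tree
  for (b in chars(bits)) {
    nd <- if (b == "0") nd[[1L]] else nd[[2L]]
    if (is.character(nd)) {
      out[[length(out) + 1L]] <- nd
      nd <- code$tree
    }
  }
  if (!identical(nd, code$tree)) {
    stop("undecodable bitstring: trailing bits do not complete a codeword",
         call. = FALSE)
  }
  paste(out, collapse = "")
}
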