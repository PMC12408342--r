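#' LZW compression and decompression
#'
#' Left-to-right greedy dictionary compression: at each position the
#' longest dictionary match is consumed and emitted as an integer code,
#' and that match extended by the next input character is added to the
#' dictionary.  The initial dictionary holds the distinct characters of
#' the input in first-appearance order (so a single-letter string starts
#' from a one-entry dictionary, and the most compressible string of one
#' letter reachable in `n` steps has length `n(n+1)/2`); initialisation
#' with a full byte alphabet is available via `alphabet`.
#'
#' @param s a single non-empty string.
#' @param alphabet optional character vector giving the initial dictionary
#'   (e.g. `rawToChar(as.raw(1:255), multiple = TRUE)` for a byte
#'   alphabet).  Defaults to the distinct characters of `s` in
#'   first-appearance order.
#' @return `lzw_compress()` returns an object of class `lzw_result`: a
#'   list with elements `codes` (integer vector, 1-based into the
#'   dictionary), `dictionary` (named integer vector mapping substring to
#'   code, in creation order) and `alphabet` (the initial dictionary).
#'   `lzw_decompress()` returns the original string.
#' @seealso [lzw_size()] for size under a packing policy,
#'   [lzw_max_length()] for the unary growth law.
#' @export
#' @examples
#' r <- lzw_compress("zbzbzc")
#' r$codes
#' lzw_decompress(r)
lzw_compress <- function(s, alphabet = NULL) {
  check_string(s, "s")
  cs <- chars(s)
  if (is.null(alphabet)) {
    alphabet <- unique(cs)
  } else if (!all(cs %in% alphabet)) {
    stop("`s` contains characters outside `alphabet`", call. = FALSE)
  }
  dict <- new.env(parent = emptyenv(), size = 4L * nchar(s))
  entries <- character(length(alphabet) + nchar(s))
  nd <- 0L
  add <- function(str) {
    nd <<- nd + 1L
    entries[nd] <<- str
    assign(str, nd, envir = dict)
  }
  for (a in alphabet) add(a)

  codes <- integer(length(cs))
  nc <- 0L
  w <- cs[1L]
  for (c in cs[-1L]) {
    wc <- paste0(w, c)
    if (exists(wc, envir = dict, inherits = FALSE)) {
      w <- wc
    } else {
      nc <- nc + 1L
      codes[nc] <- get(w, envir = dict, inherits = FALSE)
      add(wc)
      w <- c
    }
  }
  nc <- nc + 1L
  codes[nc] <- get(w, envir = dict, inherits = FALSE)

  dictionary <- stats::setNames(seq_len(nd), entries[seq_len(nd)])
  structure(list(codes = codes[seq_len(nc)], dictionary = dictionary,
                 alphabet = alphabet),
            class = "lzw_result")
}

#' @rdname lzw_compress
#' @param r an `lzw_result`.
#' @export
lzw_decompress <- function(r) {
  stopifnot(inherits(r, "lzw_result"))
  codes <- r$codes
  entries <- as.list(r$alphabet)
  prev <- entries[[codes[1L]]]
  out <- prev
  if (length(codes) > 1L) {
    for (code in codes[-1L]) {
      cur <- if (code <= length(entries)) {
        entries[[code]]
      } else if (code == length(entries) + 1L) {
        # code emitted for the entry being defined: it must start and end
        # with the previous match (the cScSc case)
        paste0(prev, substr(prev, 1L, 1L))
      } else {
        stop("invalid code ", code, " in LZW stream", call. = FALSE)
      }
      entries[[length(entries) + 1L]] <- paste0(prev, substr(cur, 1L, 1L))
      out <- c(out, cur)
      prev <- cur
    }
  }
  paste(out, collapse = "")
}

#' @export
print.lzw_result <- function(x, ...) {
  cat("LZW compression: ", length(x$codes), " codes, final dictionary of ",
      length(x$dictionary), " entries\n", sep = "")
  cat("codes:", paste(x$codes, collapse = " "), "\n")
  invisible(x)
}

#' Size of an LZW compression under a packing policy
#'
#' The size of an LZW code stream depends on how codes are packed into
#' bytes, a convention the code stream itself does not fix.  Three
#' policies are supported:
#'
#' * `code_count`: the number of emitted codes;
#' * `fixed12_bytes`: 12 bits per code, `ceiling(12 * codes / 8)` bytes
#'   (a common fixed-width implementation choice);
#' * `minwidth_bytes`: every code packed at the minimal fixed width that
#'   can address the final dictionary,
#'   `ceiling(codes * ceiling(log2(dict_size)) / 8)` bytes.
#'
#' `minwidth_bytes` is the default used by the comparison experiments as
#' the closest reading of "number of bytes in the compressed string";
#' [correlation_experiment()] reports all policies side by side because
#' conclusions can be sensitive to the convention.
#'
#' @param r an [lzw_compress()] result.
#' @param policy one of `"minwidth_bytes"`, `"code_count"`,
#'   `"fixed12_bytes"`.
#' @return An integer size.
#' @export
#' @examples
#' lzw_size(lzw_compress("aaaaaa"), "code_count")     # 3
#' lzw_size(lzw_compress("aaaaaa"), "fixed12_bytes")  # ceiling(36/8) = 5
lzw_size <- function(r, policy = c("minwidth_bytes", "code_count",
                                   "fixed12_bytes")) {
  stopifnot(inherits(r, "lzw_result"))
  policy <- match.arg(policy)
  ncodes <- length(r$codes)
  switch(policy,
    code_count = ncodes,
    fixed12_bytes = as.integer(ceiling(12 * ncodes / 8)),
    minwidth_bytes = {
      bits <- ceiling(log2(length(r$dictionary)))
      as.integer(ceiling(ncodes * bits / 8))
    })
}

#' Longest single-letter string reachable in n LZW steps
#'
#' For a repeated single letter the LZW dictionary entries grow by one
#' character per step (\eqn{l_{i+1} = l_i + i + 1}, \eqn{l_1 = 1}), so the
#' longest string consumable in \eqn{n} steps is the triangular number
#' \deqn{l_n = \frac{n(n+1)}{2}.}
#' Assembly joins instead allow doubling (\eqn{l_a = 2^a}), which is the
#' root of the scaling gap between the two measures; see
#' [scaling_table()].
#'
#' @param n a positive integer number of compression steps.
#' @return The integer `n * (n + 1) / 2`.
#' @export
#' @examples
#' lzw_max_length(3)   # 6
#' lzw_max_length(10)  # 55
lzw_max_length <- function(n) {
  if (!is.numeric(n) || any(is.na(n)) || any(n < 1) || any(n != round(n))) {
    stop("`n` must be positive integers", call. = FALSE)
  }
  as.integer(n * (n + 1) / 2)
}
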