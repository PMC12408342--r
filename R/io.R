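#' Read labeled strings from plain text or FASTA
#'
#' Plain format: one string per line, empty lines skipped, labels
#' `s1, s2, ...` in reading order.  FASTA format: one string per record
#' (sequence lines concatenated, whitespace stripped, uppercased), labeled
#' by the header; parsing is delegated to \pkg{Biostrings}.  No alphabet
#' validation is performed -- the assembly index is alphabet-agnostic.
#'
#' @param path path to a readable file.
#' @param format `"plain"` or `"fasta"`.
#' @return A named character vector (possibly empty, with a warning).
#' @export
read_strings <- function(path, format = c("plain", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "plain") {
    lines <- readLines(path, warn = FALSE)
    keep <- nzchar(lines)
    out <- lines[keep]
    if (length(out) == 0L) {
      warning("no strings found in ", path, call. = FALSE)
      return(stats::setNames(character(0), character(0)))
    }
    names(out) <- paste0("s", seq_along(out))
    return(out)
  }
  # FASTA: reject sequence data before the first header, with line number
  lines <- readLines(path, warn = FALSE)
  meaningful <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), ";"))
  if (length(meaningful) == 0L) {
    warning("no records found in ", path, call. = FALSE)
    return(stats::setNames(character(0), character(0)))
  }
  first <- meaningful[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA: sequence before first header at line ", first,
         call. = FALSE)
  }
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA requires the Biostrings package", call. = FALSE)
  }
  seqs <- Biostrings::readBStringSet(path)
  out <- toupper(gsub("\\s", "", as.character(seqs)))
  names(out) <- names(seqs)
  out
}

#' Write labeled strings to plain text or FASTA
#'
#' @param x a character vector, optionally named (names become FASTA
#'   headers; unnamed entries get `s1, s2, ...`).
#' @param path output file path.
#' @param format `"plain"` or `"fasta"`.
#' @return `path`, invisibly.
#' @export
write_strings <- function(x, path, format = c("plain", "fasta")) {
  format <- match.arg(format)
  if (!is.character(x)) stop("`x` must be a character vector", call. = FALSE)
  if (format == "plain") {
    writeLines(x, path)
  } else {
    nm <- names(x) %||% paste0("s", seq_along(x))
    nm[!nzchar(nm)] <- paste0("s", which(!nzchar(nm)))
    writeLines(as.vector(rbind(paste0(">", nm), x)), path)
  }
  invisible(path)
}

#' Generate seeded random fixture strings
#'
#' Produces `count` reproducible random strings, either as shuffles of a
#' fixed character composition (each string an anagram of the multiset
#' given in `composition`) or as uniform draws of a given `length` over
#' `alphabet`.
#'
#' @param count number of strings to generate (0 gives an empty vector).
#' @param seed integer RNG seed; the same seed always yields the same
#'   strings and the caller's RNG state is untouched.
#' @param composition named integer vector mapping single characters to
#'   positive counts, e.g. `c(a = 6, b = 6, c = 4)`.
#' @param alphabet,length alternative specification: each string is
#'   `length` uniform draws (with replacement) from the characters of
#'   `alphabet`.
#' @return A character vector of `count` strings.
#' @export
#' @examples
#' generate_fixtures(3, seed = 7, composition = c(a = 6, b = 6, c = 4))
#' generate_fixtures(2, seed = 7, alphabet = "abc", length = 10)
generate_fixtures <- function(count, seed, composition = NULL,
                              alphabet = NULL, length = NULL) {
  if (!is.numeric(count) || length(count) != 1L || count < 0 ||
      count != round(count)) {
    stop("`count` must be a single non-negative integer", call. = FALSE)
  }
  if (count == 0L) return(character(0))
  if (!is.null(composition)) {
    if (is.null(names(composition)) || any(!nzchar(names(composition))) ||
        any(nchar(names(composition)) != 1L)) {
      stop("`composition` must be named by single characters", call. = FALSE)
    }
    if (any(is.na(composition)) || any(composition < 1) ||
        any(composition != round(composition))) {
      stop("`composition` counts must be positive integers", call. = FALSE)
    }
    cs <- rep(names(composition), times = composition)
    return(with_seed(seed, vapply(seq_len(count), function(i) {
      paste(sample(cs), collapse = "")
    }, character(1L))))
  }
  if (is.null(alphabet) || is.null(length)) {
    stop("supply either `composition` or both `alphabet` and `length`",
         call. = FALSE)
  }
  ab <- if (base::length(alphabet) == 1L) chars(alphabet) else alphabet
  if (base::length(ab) == 0L || any(nchar(ab) != 1L)) {
    stop("`alphabet` must give at least one single character", call. = FALSE)
  }
  if (!is.numeric(length) || length < 1 || length != round(length)) {
    stop("`length` must be a positive integer", call. = FALSE)
  }
  with_seed(seed, vapply(seq_len(count), function(i) {
    paste(sample(ab, length, replace = TRUE), collapse = "")
  }, character(1L)))
}

#' Write assembly results as JSON or CSV
#'
#' `write_results_json()` serialises one or more `assembly_result`
#' objects as a JSON array of `{target, index, exact, pathway}` records,
#' the pathway as a list of `[left, right, product]` triples.
#' `write_results_csv()` writes the one-row-per-target summary
#' (`target, index, exact, lower, upper, pathway_length`).
#'
#' @param results an `assembly_result` or a list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(results, path) {
  results <- as_result_list(results)
  recs <- lapply(results, function(r) {
    steps <- r$pathway$steps
    list(target = r$target, index = r$index, exact = r$exact,
         lower = r$lower, upper = r$upper,
         pathway = unname(lapply(seq_len(nrow(steps)), function(i) {
           c(steps$left[i], steps$right[i], steps$product[i])
         })))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_results_json
#' @export
write_results_csv <- function(results, path) {
  results <- as_result_list(results)
  df <- do.call(rbind, lapply(results, as.data.frame))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

as_result_list <- function(results) {
  if (inherits(results, "assembly_result")) return(list(results))
  if (is.list(results) &&
      all(vapply(results, inherits, logical(1L), "assembly_result"))) {
    return(results)
  }
  stop("`results` must be an assembly_result or a list of them",
       call. = FALSE)
}
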