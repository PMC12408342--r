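#' Construct an ensemble of observed objects
#'
#' An ensemble is a collection of distinguishable strings, each observed in
#' some number of identical copies.  `assembly_ensemble()` builds one from
#' explicit values, copy numbers and (optionally) precomputed assembly
#' indices; [ensemble_from_observations()] builds one by counting a raw
#' vector of observations.  "Identical" means exact string equality.
#'
#' @param values character vector of distinct object values.
#' @param copy_number integer vector of positive copy numbers, one per value.
#' @param index optional integer vector of assembly indices; computed with
#'   [assembly_index()] when missing.
#' @return An object of class `assembly_ensemble`: a data frame with columns
#'   `value`, `copy_number` and `index`, and attribute `N` holding the total
#'   object count \eqn{N = \sum_i n_i} (copies included).
#' @seealso [assembly_observable()]
#' @export
#' @examples
#' e <- assembly_ensemble(c("zbzbzc", "ab"), copy_number = c(10, 1))
#' attr(e, "N")
assembly_ensemble <- function(values, copy_number, index = NULL) {
  if (!is.character(values) || length(values) == 0L) {
    stop("`values` must be a non-empty character vector", call. = FALSE)
  }
  if (anyDuplicated(values)) {
    stop("ensemble objects must be distinguishable: `values` contains ",
         "duplicates (use ensemble_from_observations() to count copies)",
         call. = FALSE)
  }
  if (length(copy_number) != length(values) || any(is.na(copy_number)) ||
      any(copy_number < 1) || any(copy_number != round(copy_number))) {
    stop("`copy_number` must be positive integers, one per value",
         call. = FALSE)
  }
  if (is.null(index)) {
    index <- vapply(values, function(v) assembly_index(v)$index, integer(1L),
                    USE.NAMES = FALSE)
  } else if (length(index) != length(values) || any(is.na(index)) ||
             any(index < 0) || any(index != round(index))) {
    stop("`index` must be non-negative integers, one per value",
         call. = FALSE)
  }
  out <- data.frame(value = values,
                    copy_number = as.integer(copy_number),
                    index = as.integer(index),
                    stringsAsFactors = FALSE)
  structure(out, N = sum(out$copy_number),
            class = c("assembly_ensemble", "data.frame"))
}

#' Build an ensemble by counting identical observations
#'
#' Groups identical strings in `values`, sets their copy numbers, and
#' computes each distinct string's assembly index.
#'
#' @param values a non-empty character vector of observed strings (one
#'   entry per observed copy).
#' @return An [assembly_ensemble()] whose objects appear in order of first
#'   observation.
#' @export
#' @examples
#' ensemble_from_observations(c("ab", "ab", "ab"))
ensemble_from_observations <- function(values) {
  if (!is.character(values) || length(values) == 0L) {
    stop("`values` must be a non-empty character vector", call. = FALSE)
  }
  u <- unique(values)
  n <- tabulate(match(values, u), nbins = length(u))
  assembly_ensemble(u, copy_number = n)
}

#' The Assembly observable of an ensemble
#'
#' For an ensemble of \eqn{N} total (non-unique) objects, the Assembly is
#' \deqn{A = \sum_i e^{a_i} \frac{n_i - 1}{N}}
#' where \eqn{a_i} and \eqn{n_i} are the assembly index and copy number of
#' the \eqn{i}-th distinguishable object.  An object observed once
#' (\eqn{n_i = 1}) contributes nothing: copies beyond the first are what
#' signal that the object's formation was not a one-off accident, and the
#' exponential weight makes high-index objects in high copy number dominate.
#'
#' @param e an [assembly_ensemble()].
#' @param per_object if `TRUE`, return the vector of per-object terms
#'   \eqn{e^{a_i}(n_i - 1)/N} instead of their sum.
#' @return A non-negative number (or vector of per-object terms).
#' @export
#' @examples
#' e <- ensemble_from_observations(rep("zbzbzc", 10))
#' assembly_observable(e)
assembly_observable <- function(e, per_object = FALSE) {
  if (!inherits(e, "assembly_ensemble")) {
    stop("`e` must be an assembly_ensemble", call. = FALSE)
  }
  if (nrow(e) == 0L) stop("empty ensemble", call. = FALSE)
  N <- attr(e, "N")
  terms <- exp(e$index) * (e$copy_number - 1) / N
  if (per_object) terms else sum(terms)
}

#' @export
print.assembly_ensemble <- function(x, ...) {
  cat("Assembly ensemble: ", nrow(x), " distinguishable object",
      if (nrow(x) != 1L) "s", ", N = ", attr(x, "N"), " total\n", sep = "")
  print.data.frame(x, ...)
  cat("Assembly A =", format(assembly_observable(x)), "\n")
  invisible(x)
}

#' Read or write an ensemble as CSV
#'
#' The CSV has columns `value` and `copy_number`, and optionally `index`;
#' missing indices are computed with [assembly_index()] on reading.
#'
#' @param path file path.
#' @param e an [assembly_ensemble()].
#' @return `read_ensemble_csv()` returns an [assembly_ensemble()];
#'   `write_ensemble_csv()` returns `path` invisibly.
#' @export
read_ensemble_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = c(value = "character"))
  if (!all(c("value", "copy_number") %in% names(df))) {
    stop("ensemble CSV must have columns `value` and `copy_number`",
         call. = FALSE)
  }
  assembly_ensemble(df$value, df$copy_number,
                    index = if ("index" %in% names(df)) df$index else NULL)
}

#' @rdname read_ensemble_csv
#' @export
write_ensemble_csv <- function(e, path) {
  if (!inherits(e, "assembly_ensemble")) {
    stop("`e` must be an assembly_ensemble", call. = FALSE)
  }
  write.csv(as.data.frame(e), path, row.names = FALSE)
  invisible(path)
}

#' Write an ensemble and its Assembly value as JSON
#'
#' Emits the per-object values, copy numbers, indices and Assembly terms,
#' together with `N` and the total Assembly `A`.
#'
#' @param e an [assembly_ensemble()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_json <- function(e, path) {
  if (!inherits(e, "assembly_ensemble")) {
    stop("`e` must be an assembly_ensemble", call. = FALSE)
  }
  obj <- list(
    N = attr(e, "N"),
    A = assembly_observable(e),
    objects = data.frame(value = e$value, copy_number = e$copy_number,
                         index = e$index,
                         term = assembly_observable(e, per_object = TRUE),
                         stringsAsFactors = FALSE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
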