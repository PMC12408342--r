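#' Assembly pathways and results
#'
#' An assembly pathway is an ordered sequence of join steps that builds a
#' target string from its single characters.  Each step concatenates two
#' operands, each of which is either a single character of the target's
#' alphabet or the product of an earlier step; the final product is the
#' target itself.  The length of a pathway is its number of steps, and the
#' assembly index of a string is the length of its shortest pathway.
#'
#' `assembly_pathway()` constructs a pathway object from parallel vectors of
#' operands and products; [verify_pathway()] checks its invariants.
#'
#' @param target the string the pathway builds.
#' @param left,right,product character vectors of equal length: the operands
#'   and product of each join step, in order.
#' @return An object of class `assembly_pathway`: a list with elements
#'   `target` and `steps` (a data frame with columns `left`, `right`,
#'   `product`).
#' @seealso [assembly_index()], [verify_pathway()]
#' @export
#' @examples
#' p <- assembly_pathway("aaaa", left = c("a", "aa"), right = c("a", "aa"),
#'                       product = c("aa", "aaaa"))
#' verify_pathway(p)
assembly_pathway <- function(target, left = character(), right = character(),
                             product = character()) {
  check_string(target)
  if (length(left) != length(right) || length(left) != length(product)) {
    stop("`left`, `right` and `product` must have equal length", call. = FALSE)
  }
  structure(
    list(target = target,
         steps = data.frame(left = as.character(left),
                            right = as.character(right),
                            product = as.character(product),
                            stringsAsFactors = FALSE)),
    class = "assembly_pathway")
}

#' @export
length.assembly_pathway <- function(x) nrow(x$steps)

#' @export
print.assembly_pathway <- function(x, ...) {
  cat("Assembly pathway for \"", x$target, "\" (", nrow(x$steps),
      " join step", if (nrow(x$steps) != 1L) "s", ")\n", sep = "")
  if (nrow(x$steps) > 0L) {
    for (i in seq_len(nrow(x$steps))) {
      cat(sprintf("  %2d. %s + %s -> %s\n", i, x$steps$left[i],
                  x$steps$right[i], x$steps$product[i]))
    }
  }
  invisible(x)
}

#' @export
as.data.frame.assembly_pathway <- function(x, ...) x$steps

#' Check the invariants of an assembly pathway
#'
#' Verifies that every operand of every step is either a single character of
#' the target's alphabet or the product of an earlier step, that each
#' product is the concatenation of its operands and occurs contiguously in
#' the target, and that the final product equals the target.  A target
#' consisting of a single character is valid with an empty pathway.
#'
#' @param p an [assembly_pathway()] object.
#' @return `TRUE` if all invariants hold, otherwise `FALSE` with a `reason`
#'   attribute describing the first violated invariant.
#' @export
#' @examples
#' p <- assembly_pathway("aaaa", left = c("a", "aa"), right = c("a", "aa"),
#'                       product = c("aa", "aaaa"))
#' verify_pathway(p)
verify_pathway <- function(p) {
  fail <- function(reason) structure(FALSE, reason = reason)
  if (!inherits(p, "assembly_pathway")) {
    return(fail("not an assembly_pathway object"))
  }
  target <- p$target
  steps <- p$steps
  if (nrow(steps) == 0L) {
    if (nchar(target) == 1L) return(TRUE)
    return(fail("empty pathway for a multi-character target"))
  }
  pool <- unique(chars(target))
  for (i in seq_len(nrow(steps))) {
    l <- steps$left[i]
    r <- steps$right[i]
    w <- steps$product[i]
    if (!(l %in% pool)) {
      return(fail(sprintf("step %d: left operand \"%s\" not available", i, l)))
    }
    if (!(r %in% pool)) {
      return(fail(sprintf("step %d: right operand \"%s\" not available", i, r)))
    }
    if (!identical(paste0(l, r), w)) {
      return(fail(sprintf("step %d: product is not left + right", i)))
    }
    if (!grepl(w, target, fixed = TRUE)) {
      return(fail(sprintf(
        "step %d: product \"%s\" is not a substring of the target", i, w)))
    }
    pool <- c(pool, w)
  }
  if (!identical(steps$product[nrow(steps)], target)) {
    return(fail("final product does not equal the target"))
  }
  TRUE
}

new_assembly_result <- function(target, index, pathway, exact, lower, upper) {
  structure(
    list(target = target, index = as.integer(index), pathway = pathway,
         exact = isTRUE(exact), lower = as.integer(lower),
         upper = as.integer(upper)),
    class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  if (x$exact) {
    cat("Assembly index of \"", x$target, "\": ", x$index, " (exact)\n",
        sep = "")
  } else {
    cat("Assembly index of \"", x$target, "\": in [", x$lower, ", ",
        x$upper, "] (not proven exact; best pathway has ", x$upper,
        " steps)\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.assembly_result <- function(x, ...) {
  data.frame(target = x$target, index = x$index, exact = x$exact,
             lower = x$lower, upper = x$upper,
             pathway_length = length(x$pathway),
             stringsAsFactors = FALSE)
}
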