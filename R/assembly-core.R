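#' Distinct substrings of a string
#'
#' Enumerates all distinct non-empty contiguous substrings of `target`.
#' In a minimal assembly pathway every join product is eventually used
#' inside the target and therefore occurs contiguously in it, so this set
#' is the search universe for the exact index computation.
#'
#' @param target a single non-empty string.
#' @return A character vector of distinct substrings, sorted by decreasing
#'   length then lexicographically (the canonical branching order of the
#'   search).
#' @export
#' @examples
#' candidate_substrings("zbzbzc")
candidate_substrings <- function(target) {
  check_string(target)
  n <- nchar(target)
  subs <- unique(unlist(lapply(seq_len(n), function(i) {
    substring(target, i, i:n)
  })))
  lens <- nchar(subs)
  subs[order(-lens, subs, method = "radix")]
}

#' Lower bound on the assembly index
#'
#' The length of the longest available fragment can at most double with
#' each join, so building a string of length \eqn{l} takes at least
#' \eqn{\lceil \log_2 l \rceil} joins.  This is the fastest possible growth
#' (realised by repeated self-joining of a single letter, \eqn{l_a = 2^a}).
#'
#' @param target a single non-empty string.
#' @return A non-negative integer, guaranteed not to exceed the exact
#'   assembly index of `target`.
#' @export
#' @examples
#' assembly_lower_bound("zbzbzc")  # ceil(log2 6) = 3
assembly_lower_bound <- function(target) {
  check_string(target)
  max(as.integer(ceiling(log2(nchar(target)))), 0L)
}

# Longest substring of `t` (>= 2 chars, not already in `pool`) with at
# least two non-overlapping occurrences in `t`; ties broken by leftmost
# first occurrence, then lexicographically.  NULL if none.
longest_repeated_substring <- function(t, pool) {
  n <- nchar(t)
  if (n %/% 2L < 2L) return(NULL)
  for (len in seq.int(n %/% 2L, 2L, by = -1L)) {
    starts <- seq_len(n - len + 1L)
    cand <- substring(t, starts, starts + len - 1L)
    first <- !duplicated(cand)
    ord <- order(starts[first])   # leftmost first occurrence; at equal
    cand <- cand[first][ord]      # positions substrings of one length differ
    for (s in cand) {
      if (s %in% pool) next
      if (length(gregexpr(s, t, fixed = TRUE)[[1L]]) >= 2L) return(s)
    }
  }
  NULL
}

#' Greedy upper bound on the assembly index
#'
#' Builds a valid assembly pathway by repeatedly exploiting the longest
#' repeated substring: the longest fragment with at least two
#' non-overlapping occurrences (ties: leftmost, then lexicographic) is
#' built first, recursively, and the target is then assembled left to
#' right, always appending the longest already-built fragment that
#' matches.  The resulting pathway length is an upper bound on the exact
#' index and seeds the branch-and-bound search of [assembly_index()].
#'
#' @param target a single non-empty string.
#' @return An `assembly_result` with `exact = FALSE` whose pathway passes
#'   [verify_pathway()]; its `upper` element is the pathway length.
#' @export
#' @examples
#' greedy_upper_bound("zbzbzc")  # 4 joins: zb, zbzb, zbzbz, zbzbzc
greedy_upper_bound <- function(target) {
  check_string(target)
  g <- greedy_join_steps(target)
  pathway <- assembly_pathway(target, g$left, g$right, g$product)
  k <- length(pathway)
  new_assembly_result(target, k, pathway, exact = FALSE,
                      lower = assembly_lower_bound(target), upper = k)
}

# the greedy construction itself, kept free of result-object overhead so
# the experiment drivers can call it in bulk
greedy_join_steps <- function(target) {
  pool <- unique(chars(target))
  steps_l <- character()
  steps_r <- character()
  steps_p <- character()

  emit <- function(l, r) {
    w <- paste0(l, r)
    steps_l[[length(steps_l) + 1L]] <<- l
    steps_r[[length(steps_r) + 1L]] <<- r
    steps_p[[length(steps_p) + 1L]] <<- w
    pool <<- c(pool, w)
    w
  }

  # assemble t left-to-right from the pool, longest matching prefix first
  construct <- function(t) {
    if (t %in% pool) return(invisible())
    pref <- pool[startsWith(t, pool)]
    cur <- pref[which.max(nchar(pref))]
    while (nchar(cur) < nchar(t)) {
      rest <- substr(t, nchar(cur) + 1L, nchar(t))
      pref <- pool[startsWith(rest, pool)]
      nxt <- pref[which.max(nchar(pref))]
      cur <- emit(cur, nxt)
    }
    invisible()
  }

  build <- function(t) {
    if (nchar(t) == 1L || t %in% pool) return(invisible())
    r <- longest_repeated_substring(t, pool)
    if (!is.null(r)) build(r)
    construct(t)
  }

  build(target)
  list(left = steps_l, right = steps_r, product = steps_p)
}

# exact index only, skipping witness-object construction; the search is
# identical to assembly_index()
exact_index_value <- function(target) {
  if (nchar(target) == 1L) return(0L)
  ub <- length(greedy_join_steps(target)$product)
  lb <- assembly_lower_bound(target)
  if (ub == lb) return(ub)
  res <- cpp_assembly_search(target, lb, ub - 1L, node_limit = 9e18)
  if (isTRUE(res$found)) res$depth else ub
}

#' Exact assembly index of a string
#'
#' Computes the minimal number of binary concatenation joins needed to
#' construct `target` from its single characters, where any previously
#' built fragment (and any single character of the target's alphabet) may
#' be reused freely, together with one witnessing minimal pathway.
#'
#' The search works on the decomposition-set formulation: a pathway is
#' equivalent to a set of fragments containing the target in which every
#' fragment splits into two parts that are single characters or other set
#' members (products are strictly longer than operands, so any such set
#' orders into a pathway by length), and the index is the minimal set
#' size.  A branch-and-bound over these sets -- restricted to the distinct
#' substrings of the target, seeded with [greedy_upper_bound()], pruned by
#' [assembly_lower_bound()]-style doubling arguments and a visited-state
#' table, with canonical branching -- makes the result and its witnessing
#' pathway deterministic.  The decision problem is NP-complete, so
#' worst-case runtime is exponential in the string length; `budget` caps
#' the search depth for large inputs.
#'
#' @param target a single non-empty string.
#' @param budget optional maximum search depth (number of joins).  Defaults
#'   to the greedy upper bound, which always suffices for a proof of
#'   optimality.  If the budget is exhausted first, the result carries the
#'   best proven interval `[lower, upper]` and `exact = FALSE`.
#' @param max_nodes optional cap on branch-and-bound nodes, for very long
#'   inputs.  If hit, the result reports the best interval found so far
#'   with `exact = FALSE` rather than guessing.
#' @return An `assembly_result`: a list with elements `target`, `index`,
#'   `pathway` (an [assembly_pathway()]), `exact`, `lower` and `upper`.
#'   When `exact` is `TRUE`, `index == length(pathway)` and
#'   `lower == upper == index`.
#' @seealso [brute_force_assembly_index()] for the exhaustive oracle,
#'   [addition_chain_min()] for the single-letter special case.
#' @export
#' @examples
#' assembly_index("zbzbzc")   # 4
#' assembly_index("zzzbbc")   # 5: same length and composition, higher index
#' assembly_index(strrep("a", 8))  # 3, by repeated doubling
assembly_index <- function(target, budget = NULL, max_nodes = Inf) {
  check_string(target)
  if (nchar(target) == 1L) {
    return(new_assembly_result(target, 0L, assembly_pathway(target),
                               exact = TRUE, lower = 0L, upper = 0L))
  }
  g <- greedy_join_steps(target)
  greedy_pathway <- function() {
    assembly_pathway(target, g$left, g$right, g$product)
  }
  ub <- length(g$product)
  lb <- assembly_lower_bound(target)
  if (ub == lb) {
    return(new_assembly_result(target, ub, greedy_pathway(), exact = TRUE,
                               lower = ub, upper = ub))
  }
  max_depth <- ub - 1L
  if (!is.null(budget)) {
    if (!is.numeric(budget) || length(budget) != 1L || budget < 0) {
      stop("`budget` must be a single non-negative number", call. = FALSE)
    }
    max_depth <- min(max_depth, as.integer(budget))
  }
  res <- NULL
  if (max_depth >= lb) {
    res <- cpp_assembly_search(target, lb, max_depth, node_limit = max_nodes)
    if (isTRUE(res$found) && isTRUE(res$complete)) {
      # branch-and-bound exhausted everything below max_depth + 1, so this
      # witness is minimal
      pathway <- assembly_pathway(target, res$left, res$right, res$product)
      k <- res$depth
      return(new_assembly_result(target, k, pathway, exact = TRUE,
                                 lower = k, upper = k))
    }
    if (!isTRUE(res$complete)) {
      # node budget hit: only an interval is proven
      if (isTRUE(res$found) && res$depth < ub) {
        pathway <- assembly_pathway(target, res$left, res$right, res$product)
        return(new_assembly_result(target, res$depth, pathway,
                                   exact = FALSE, lower = lb,
                                   upper = res$depth))
      }
      return(new_assembly_result(target, ub, greedy_pathway(), exact = FALSE,
                                 lower = lb, upper = ub))
    }
  }
  proven_lower <- max(lb, max_depth + 1L)
  if (proven_lower >= ub) {
    # no shorter pathway exists; the greedy pathway is minimal
    return(new_assembly_result(target, ub, greedy_pathway(), exact = TRUE,
                               lower = ub, upper = ub))
  }
  new_assembly_result(target, ub, greedy_pathway(), exact = FALSE,
                      lower = proven_lower, upper = ub)
}

#' Brute-force assembly index by breadth-first search
#'
#' Independent exhaustive computation of the assembly index: a
#' breadth-first search over pools of built fragments, where level
#' \eqn{k} holds every pool reachable with \eqn{k} joins.  Used as a
#' validation oracle for [assembly_index()]; refuses targets longer than
#' `limit` characters because the state space grows explosively.
#'
#' @param target a single non-empty string of at most `limit` characters.
#' @param limit maximum accepted target length (default 10).
#' @return The exact assembly index as an integer.
#' @export
#' @examples
#' brute_force_assembly_index("abab")  # 2: build "ab", then double it
brute_force_assembly_index <- function(target, limit = 10L) {
  check_string(target)
  if (nchar(target) > limit) {
    stop("brute-force search is limited to strings of at most ", limit,
         " characters (got ", nchar(target), ")", call. = FALSE)
  }
  if (nchar(target) == 1L) return(0L)
  universe <- candidate_substrings(target)
  start <- sort(unique(chars(target)))
  if (target %in% start) return(0L)
  seen <- new.env(parent = emptyenv())
  key <- function(pool) paste(pool, collapse = "\r")
  assign(key(start), TRUE, envir = seen)
  frontier <- list(start)
  k <- 0L
  repeat {
    k <- k + 1L
    nxt <- list()
    for (pool in frontier) {
      prods <- outer(pool, pool, paste0)
      prods <- unique(prods[prods %in% universe & !(prods %in% pool)])
      for (w in prods) {
        if (w == target) return(k)
        np <- sort(c(pool, w))
        kk <- key(np)
        if (!exists(kk, envir = seen, inherits = FALSE)) {
          assign(kk, TRUE, envir = seen)
          nxt[[length(nxt) + 1L]] <- np
        }
      }
    }
    if (length(nxt) == 0L) {
      stop("search space exhausted without reaching the target",
           call. = FALSE) # cannot happen for valid input
    }
    frontier <- nxt
  }
}

#' Minimal addition chain length
#'
#' Length of the shortest addition chain for `l`: the least \eqn{k} such
#' that a sequence \eqn{1 = c_0, \dots, c_k = l} exists in which every
#' element is the sum of two (not necessarily distinct) earlier elements.
#' Building a single-letter string of length \eqn{l} by concatenation
#' joins is exactly this problem -- fragment lengths add, and any earlier
#' fragment may be reused -- so this equals
#' `assembly_index(strrep("a", l))$index`.
#'
#' Exhaustive iterative-deepening search over strictly increasing chains;
#' practical for `l` up to about 64.
#'
#' @param l a positive integer.
#' @return The minimal number of additions, an integer.
#' @export
#' @examples
#' addition_chain_min(8)   # 3: 1, 2, 4, 8
#' addition_chain_min(15)  # 5: e.g. 1, 2, 3, 6, 12, 15
addition_chain_min <- function(l) {
  if (!is.numeric(l) || length(l) != 1L || is.na(l) || l < 1 || l != round(l)) {
    stop("`l` must be a single positive integer", call. = FALSE)
  }
  l <- as.integer(l)
  if (l == 1L) return(0L)

  dfs <- function(chain, budget) {
    last <- chain[length(chain)]
    if (last == l) return(TRUE)
    if (budget == 0L) return(FALSE)
    if (last * 2^budget < l) return(FALSE)  # doubling bound
    sums <- unique(as.vector(outer(chain, chain, `+`)))
    sums <- sort(sums[sums > last & sums <= l], decreasing = TRUE)
    for (s in sums) {
      if (dfs(c(chain, s), budget - 1L)) return(TRUE)
    }
    FALSE
  }

  depth <- as.integer(ceiling(log2(l)))
  repeat {
    if (dfs(1L, depth)) return(depth)
    depth <- depth + 1L
  }
}
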