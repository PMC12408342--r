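#' Scaling of LZW steps versus assembly joins
#'
#' Tabulates, for `n = 1..max_steps`, the longest single-letter string
#' reachable by `n` LZW dictionary-construction steps
#' (\eqn{l_n = n(n+1)/2}, see [lzw_max_length()]) against the longest
#' reachable by `n` assembly joins (\eqn{l_a = 2^n}, repeated doubling).
#' The polynomial-versus-exponential gap is why the two measures cannot be
#' formally equivalent.  With `validate_upto > 0` the closed forms are
#' cross-checked by actually running [lzw_compress()] and
#' [assembly_index()] on the corresponding unary strings.
#'
#' @param max_steps largest step count tabulated.
#' @param validate_upto cross-validate rows `1..validate_upto` against the
#'   real algorithms (adds columns `lzw_codes_observed` and
#'   `assembly_index_observed`); 0 (default) skips validation.
#' @return A data frame with columns `steps`, `lzw_reachable_length` and
#'   `assembly_reachable_length` (plus the observed columns when
#'   validated).
#' @export
#' @examples
#' scaling_table(6, validate_upto = 3)
scaling_table <- function(max_steps, validate_upto = 0L) {
  if (!is.numeric(max_steps) || length(max_steps) != 1L || max_steps < 1) {
    stop("`max_steps` must be a positive integer", call. = FALSE)
  }
  n <- seq_len(max_steps)
  out <- data.frame(steps = n,
                    lzw_reachable_length = lzw_max_length(n),
                    assembly_reachable_length = 2^n)
  validate_upto <- min(validate_upto, max_steps)
  if (validate_upto >= 1L) {
    m <- seq_len(validate_upto)
    out$lzw_codes_observed <- NA_integer_
    out$assembly_index_observed <- NA_integer_
    out$lzw_codes_observed[m] <- vapply(m, function(i) {
      length(lzw_compress(strrep("a", lzw_max_length(i)))$codes)
    }, integer(1L))
    out$assembly_index_observed[m] <- vapply(m, function(i) {
      assembly_index(strrep("a", 2^i))$index
    }, integer(1L))
  }
  out
}

#' Number of distinct permutations of a string
#'
#' The multinomial coefficient \eqn{|s|! / \prod_c \mathrm{count}(c)!}:
#' the number of distinct rearrangements of the characters of `base`.
#' Computed as a product of binomial coefficients to stay exact in double
#' precision for far longer than factorials would.
#'
#' @param base a single non-empty string.
#' @return A number (exact for all practically enumerable sizes).
#' @export
#' @examples
#' count_permutations("aab")               # 3
#' count_permutations("aaaaaabbbbbbcccc")  # 1681680
count_permutations <- function(base) {
  check_string(base, "base")
  counts <- frequency_table(base)
  total <- 0L
  res <- 1
  for (k in counts) {
    total <- total + k
    res <- res * choose(total, k)
  }
  round(res)
}

#' Seeded uniform random rearrangements of a string
#'
#' Draws `k` independent uniform shuffles of the characters of `base`
#' (with replacement across draws: the same permutation can recur).
#' Reproducible: the same seed yields the same sequence, and the caller's
#' RNG state is left untouched.
#'
#' @param base a single non-empty string.
#' @param k number of draws (0 gives an empty vector).
#' @param seed integer RNG seed.
#' @return A character vector of `k` anagrams of `base`.
#' @export
#' @examples
#' sample_permutations("aaaaaabbbbbbcccc", 3, seed = 1)
sample_permutations <- function(base, k, seed) {
  check_string(base, "base")
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k != round(k)) {
    stop("`k` must be a single non-negative integer", call. = FALSE)
  }
  if (k == 0L) return(character(0))
  cs <- chars(base)
  with_seed(seed, vapply(seq_len(k), function(i) {
    paste(sample(cs), collapse = "")
  }, character(1L)))
}

#' Pearson product-moment correlation
#'
#' Standard Pearson correlation, with explicit validation: both vectors
#' must have equal length at least 2 and nonzero variance (a constant
#' vector leaves the correlation undefined and is an error, not an `NA`).
#'
#' @param xs,ys numeric vectors of equal length.
#' @return A number in `[-1, 1]`.
#' @export
#' @examples
#' pearson(c(1, 2, 3), c(2, 4, 6))  # 1
pearson <- function(xs, ys) {
  if (!is.numeric(xs) || !is.numeric(ys) || length(xs) != length(ys)) {
    stop("`xs` and `ys` must be numeric vectors of equal length",
         call. = FALSE)
  }
  if (length(xs) < 2L) {
    stop("need at least two observations", call. = FALSE)
  }
  if (sd(xs) == 0 || sd(ys) == 0) {
    stop("Pearson correlation is undefined for a zero-variance vector",
         call. = FALSE)
  }
  cor(xs, ys)
}

#' Correlation between assembly index and LZW size over rearrangements
#'
#' Samples `k` seeded uniform rearrangements of `base` (or, with
#' `full = TRUE`, enumerates every distinct permutation), computes each
#' string's exact assembly index and its LZW compressed size under each
#' packing policy, and reports the Pearson correlation between index and
#' size per policy, together with a histogram and moments of the
#' difference `lzw - a`.  Because all sampled strings share one length
#' and composition, any correlation observed is not an artefact of size:
#' this is the fixed-composition protocol under which the two measures
#' turn out to be only weakly correlated.
#'
#' Exact indices are memoized per distinct string, so repeated draws of
#' the same permutation cost one search.
#'
#' @param base a single non-empty string (exact search must be feasible
#'   for its length; the reference protocol uses the 16-character
#'   "aaaaaabbbbbbcccc").
#' @param k number of sampled rearrangements.
#' @param seed integer RNG seed.
#' @param policies LZW size policies to report (see [lzw_size()]).
#' @param full if `TRUE`, ignore `k`/`seed` and enumerate all
#'   [count_permutations()] distinct permutations (feasible only for
#'   short strings).
#' @param progress print a progress line every `progress` strings
#'   (0 = silent).
#' @return An object of class `correlation_result`: a list with elements
#'   `base`, `sample_size`, `seed`, `records` (data frame: `string`, `a`,
#'   one size column per policy), `pearson` (named per policy),
#'   `ratio_mean` (mean of `a / size` per policy), `histogram` (per
#'   policy: integer `breaks` midpoints and `counts` of `lzw - a`) and
#'   `moments` (per policy: mean and sd of `lzw - a`).
#' @export
#' @examples
#' r <- correlation_experiment("aaaaaabbbbbbcccc", k = 100, seed = 1)
#' r$pearson
correlation_experiment <- function(base, k = 10000L, seed = 1L,
                                   policies = c("code_count",
                                                "fixed12_bytes",
                                                "minwidth_bytes"),
                                   full = FALSE, progress = 0L) {
  check_string(base, "base")
  policies <- match.arg(policies, several.ok = TRUE)
  if (full) {
    strings <- enumerate_permutations(base)
    k <- length(strings)
    seed <- NA_integer_
  } else {
    strings <- sample_permutations(base, k, seed)
  }
  if (length(strings) == 0L) stop("no strings to analyse", call. = FALSE)

  cache <- new.env(parent = emptyenv())
  a <- integer(length(strings))
  sizes <- matrix(0L, nrow = length(strings), ncol = length(policies),
                  dimnames = list(NULL, policies))
  for (i in seq_along(strings)) {
    s <- strings[i]
    ai <- if (exists(s, envir = cache, inherits = FALSE)) {
      get(s, envir = cache, inherits = FALSE)
    } else {
      v <- exact_index_value(s)
      assign(s, v, envir = cache)
      v
    }
    a[i] <- ai
    r <- lzw_compress(s)
    for (p in policies) sizes[i, p] <- lzw_size(r, p)
    if (progress > 0L && i %% progress == 0L) {
      message(i, "/", length(strings), " strings processed")
    }
  }

  pear <- vapply(policies, function(p) pearson(a, as.numeric(sizes[, p])),
                 numeric(1L))
  ratio_mean <- vapply(policies, function(p) mean(a / sizes[, p]),
                       numeric(1L))
  histogram <- lapply(stats::setNames(policies, policies), function(p) {
    d <- sizes[, p] - a
    rng <- seq.int(min(d), max(d))
    list(breaks = rng, counts = vapply(rng, function(v) sum(d == v),
                                       integer(1L)))
  })
  moments <- lapply(stats::setNames(policies, policies), function(p) {
    d <- sizes[, p] - a
    list(mean = mean(d), sd = sd(d))
  })

  records <- data.frame(string = strings, a = a, stringsAsFactors = FALSE)
  for (p in policies) records[[paste0("lzw_", p)]] <- sizes[, p]

  structure(list(base = base, sample_size = k, seed = seed,
                 records = records, pearson = pear,
                 ratio_mean = ratio_mean, histogram = histogram,
                 moments = moments),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("Assembly index vs LZW size over ", x$sample_size,
      " rearrangements of \"", x$base, "\"\n", sep = "")
  for (p in names(x$pearson)) {
    cat(sprintf("  %-15s r = %.4f   mean(lzw - a) = %.3f\n", p,
                x$pearson[[p]], x$moments[[p]]$mean))
  }
  invisible(x)
}

# All distinct permutations of the characters of `base`, in a fixed
# (lexicographic over first-appearance ranks) order.  Grows as the
# multinomial coefficient; intended for short strings.
enumerate_permutations <- function(base) {
  counts <- frequency_table(base)
  syms <- names(counts)
  out <- character(count_permutations(base))
  pos <- 0L
  rec <- function(prefix, counts) {
    if (all(counts == 0L)) {
      pos <<- pos + 1L
      out[pos] <<- prefix
      return(invisible())
    }
    for (j in seq_along(syms)) {
      if (counts[j] > 0L) {
        counts[j] <- counts[j] - 1L
        rec(paste0(prefix, syms[j]), counts)
        counts[j] <- counts[j] + 1L
      }
    }
  }
  rec("", counts)
  out
}
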