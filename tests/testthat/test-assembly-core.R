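test_that("candidate_substrings enumerates all distinct substrings", {
  expect_setequal(candidate_substrings("aaa"), c("a", "aa", "aaa"))
  expect_setequal(candidate_substrings("ab"), c("a", "b", "ab"))
  # count frozen from an independent double-loop enumerator
  expect_length(candidate_substrings("zbzbzc"), 15L)
  # canonical order: length descending, then lexicographic
  subs <- candidate_substrings("zbzbzc")
  expect_identical(subs, subs[order(-nchar(subs), subs, method = "radix")])
  expect_error(candidate_substrings(""), "non-empty")
})

test_that("lower bound is the doubling-limit bound", {
  expect_identical(assembly_lower_bound("a"), 0L)
  expect_identical(assembly_lower_bound(strrep("a", 16)), 4L)
  expect_identical(assembly_lower_bound("zbzbzc"), 3L)
})

test_that("greedy upper bound builds valid pathways of the expected length", {
  cases <- list(list("aaaaaa", 3L), list("zbzbzc", 4L), list("ab", 1L))
  for (cs in cases) {
    g <- greedy_upper_bound(cs[[1]])
    expect_false(g$exact)
    expect_identical(g$upper, cs[[2]])
    expect_identical(length(g$pathway), cs[[2]])
    expect_true(verify_pathway(g$pathway))
  }
})

test_that("exact assembly index reproduces the worked examples", {
  expect_identical(assembly_index("z")$index, 0L)
  expect_identical(assembly_index("zbzbzc")$index, 4L)
  expect_identical(assembly_index("zzzbbc")$index, 5L)
  expect_identical(assembly_index(strrep("a", 8))$index, 3L)
  expect_identical(assembly_index("abc")$index, 2L)
})

test_that("exact results carry a verified minimal witness", {
  for (s in c("zbzbzc", "zzzbbc", "abcabc", strrep("ab", 5))) {
    r <- assembly_index(s)
    expect_true(r$exact)
    expect_identical(r$lower, r$index)
    expect_identical(r$upper, r$index)
    expect_identical(length(r$pathway), r$index)
    expect_true(verify_pathway(r$pathway))
  }
})

test_that("exact search is deterministic", {
  r1 <- assembly_index("zbzbzcabzb")
  r2 <- assembly_index("zbzbzcabzb")
  expect_identical(r1$pathway$steps, r2$pathway$steps)
})

test_that("brute-force oracle matches known indices and refuses big input", {
  expect_identical(brute_force_assembly_index("zz"), 1L)
  expect_identical(brute_force_assembly_index("abab"), 2L)
  expect_identical(brute_force_assembly_index("zbzbzc"), 4L)
  expect_error(brute_force_assembly_index(strrep("ab", 6)), "at most")
})

test_that("branch-and-bound agrees with the brute-force oracle", {
  set.seed(101)
  for (s in random_strings(25, 2, 8, c("a", "b"))) {
    expect_identical(assembly_index(s)$index, brute_force_assembly_index(s),
                     info = s)
  }
  for (s in random_strings(20, 2, 6, c("a", "b", "c"))) {
    expect_identical(assembly_index(s)$index, brute_force_assembly_index(s),
                     info = s)
  }
})

test_that("doubling law: a(a^(2^k)) = k", {
  for (k in 0:6) {
    expect_identical(assembly_index(strrep("a", 2^k))$index, k, info = k)
  }
})

test_that("unary assembly index equals the minimal addition chain", {
  expect_identical(addition_chain_min(1), 0L)
  expect_identical(addition_chain_min(8), 3L)
  # values frozen from an independent exhaustive chain enumerator
  expect_identical(addition_chain_min(15), 5L)
  expect_identical(addition_chain_min(23), 6L)
  expect_identical(addition_chain_min(32), 5L)
  expect_error(addition_chain_min(0), "positive")
  for (l in c(2, 7, 11, 15, 21, 27, 31)) {
    expect_identical(assembly_index(strrep("a", l))$index,
                     addition_chain_min(l), info = l)
  }
})

test_that("index is invariant under reversal and alphabet relabeling", {
  revstr <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  relabel <- function(s, from, to) chartr(from, to, s)
  set.seed(202)
  for (s in random_strings(40, 2, 10)) {
    a <- assembly_index(s)$index
    expect_identical(assembly_index(revstr(s))$index, a, info = s)
    expect_identical(assembly_index(relabel(s, "abc", "xqz"))$index, a,
                     info = s)
  }
})

test_that("all-distinct strings need length - 1 joins", {
  for (s in c("ab", "abc", "abcd", "abcdef", "abcdefgh")) {
    expect_identical(assembly_index(s)$index, nchar(s) - 1L, info = s)
  }
})

test_that("bounds sandwich the exact index", {
  set.seed(303)
  for (s in random_strings(30, 2, 12)) {
    r <- assembly_index(s)
    expect_gte(r$index, assembly_lower_bound(s))
    expect_lte(r$index, greedy_upper_bound(s)$upper)
  }
})

test_that("an exhausted depth budget yields a proven interval, not a guess", {
  r <- assembly_index("zzzbbc", budget = 3)
  expect_false(r$exact)
  expect_identical(r$lower, 4L)
  expect_identical(r$upper, 5L)
  expect_true(verify_pathway(r$pathway))  # the bound pathway is still valid
  # a budget at least the exact index proves optimality
  expect_true(assembly_index("zzzbbc", budget = 5)$exact)
})

test_that("a node budget yields sound bounds instead of wrong answers", {
  s <- paste(rep(c("a", "b", "c"), times = c(6, 6, 4))[
    order(rep(seq_len(16)%%7, length.out = 16))], collapse = "")
  full <- assembly_index(s)
  capped <- assembly_index(s, max_nodes = 5)
  expect_false(capped$exact)
  expect_lte(capped$lower, full$index)
  expect_gte(capped$upper, full$index)
  expect_true(verify_pathway(capped$pathway))
})

test_that("degenerate inputs are rejected", {
  expect_error(assembly_index(""), "non-empty")
  expect_error(assembly_index(c("a", "b")), "single")
  expect_error(greedy_upper_bound(""), "non-empty")
})
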