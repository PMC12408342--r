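test_that("scaling table tabulates both closed-form growth laws", {
  tab <- scaling_table(10)
  expect_identical(tab$lzw_reachable_length[1], 1L)
  expect_identical(tab$assembly_reachable_length[1], 2)
  expect_identical(tab$lzw_reachable_length[3], 6L)
  expect_identical(tab$assembly_reachable_length[3], 8)
  expect_identical(tab$lzw_reachable_length[10], 55L)
  expect_identical(tab$assembly_reachable_length[10], 1024)
  expect_true(all(diff(tab$lzw_reachable_length) > 0))
  expect_true(all(diff(tab$assembly_reachable_length) > 0))
})

test_that("closed forms match the real algorithms", {
  tab <- scaling_table(6, validate_upto = 6)
  expect_identical(tab$lzw_codes_observed, tab$steps)
  expect_identical(tab$assembly_index_observed, tab$steps)
})

test_that("permutation counts follow the multinomial coefficient", {
  expect_identical(count_permutations("ab"), 2)
  expect_identical(count_permutations("aab"), 3)
  expect_identical(count_permutations("aaaaaabbbbbbcccc"), 1681680)
  # exhaustive enumeration cross-check (independent recursive counter)
  enum_count <- function(counts) {
    if (sum(counts) == 0) return(1)
    total <- 0
    for (i in seq_along(counts)) {
      if (counts[i] > 0) {
        counts[i] <- counts[i] - 1
        total <- total + Recall(counts)
        counts[i] <- counts[i] + 1
      }
    }
    total
  }
  for (s in c("aabb", "aabbcc", "aaabbbcc", "abcdefgh")) {
    counts <- as.vector(table(strsplit(s, "")[[1]]))
    expect_identical(count_permutations(s), enum_count(counts), info = s)
  }
})

test_that("sampled permutations are seeded anagrams", {
  expect_identical(sample_permutations("abc", 0, seed = 1), character(0))
  s1 <- sample_permutations("aaaaaabbbbbbcccc", 25, seed = 9)
  s2 <- sample_permutations("aaaaaabbbbbbcccc", 25, seed = 9)
  expect_identical(s1, s2)
  s3 <- sample_permutations("aaaaaabbbbbbcccc", 25, seed = 10)
  expect_false(identical(s1, s3))
  sorted <- function(x) paste(sort(strsplit(x, "")[[1]]), collapse = "")
  expect_true(all(vapply(s1, sorted, "") == sorted("aaaaaabbbbbbcccc")))
  # the caller's RNG stream is not disturbed
  set.seed(40); before <- runif(3)
  set.seed(40); invisible(sample_permutations("abc", 5, seed = 1))
  expect_identical(runif(3), before)
})

test_that("pearson matches direct evaluation and validates input", {
  expect_equal(pearson(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson(c(1, 2, 3), c(3, 2, 1)), -1)
  # frozen from an independent hand computation of the product-moment sum
  expect_equal(pearson(c(1, 2, 4, 7, 11), c(2, 1, 5, 8, 9)),
               0.9400193421607683, tolerance = 1e-12)
  expect_error(pearson(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(pearson(1, 2), "at least two")
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
})

test_that("the correlation experiment is complete and reproducible", {
  r <- correlation_experiment("aaaaaabbbbbbcccc", k = 150, seed = 5)
  expect_s3_class(r, "correlation_result")
  expect_identical(nrow(r$records), 150L)
  expect_named(r$records, c("string", "a", "lzw_code_count",
                            "lzw_fixed12_bytes", "lzw_minwidth_bytes"))
  expect_true(all(abs(r$pearson) <= 1))
  for (h in r$histogram) expect_identical(sum(h$counts), 150L)
  # LZW code counts exceed the assembly index on these strings
  expect_gt(r$moments$code_count$mean, 0)
  r2 <- correlation_experiment("aaaaaabbbbbbcccc", k = 150, seed = 5)
  expect_identical(r$records, r2$records)
  expect_identical(r$pearson, r2$pearson)
})

test_that("full enumeration mode visits every distinct permutation", {
  r <- correlation_experiment("aabb", full = TRUE)
  expect_identical(r$sample_size, 6L)
  expect_identical(sort(unique(r$records$string)),
                   c("aabb", "abab", "abba", "baab", "baba", "bbaa"))
})
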