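test_that("lzw emits the reference code sequences", {
  # frozen from an independent reference LZW implementation
  expect_identical(lzw_compress("zbzbzc")$codes, c(1L, 2L, 4L, 1L, 3L))
  expect_identical(lzw_compress("zzzbbc")$codes, c(1L, 4L, 2L, 2L, 3L))
  expect_identical(length(lzw_compress("aaaaaa")$codes), 3L)
  expect_identical(length(lzw_compress("ab")$codes), 2L)
})

test_that("lzw round-trips, including the self-referential code case", {
  # "aaa" emits a code for a dictionary entry still being defined
  r <- lzw_compress("aaa")
  expect_identical(lzw_decompress(r), "aaa")
  set.seed(31)
  for (s in random_strings(60, 1, 60, letters[1:4])) {
    expect_identical(lzw_decompress(lzw_compress(s)), s, info = s)
  }
})

test_that("an explicit alphabet is honoured and validated", {
  r <- lzw_compress("aba", alphabet = c("a", "b", "c"))
  expect_identical(lzw_decompress(r), "aba")
  expect_error(lzw_compress("abd", alphabet = c("a", "b")), "outside")
})

test_that("unary strings follow the triangular growth law", {
  for (n in 1:10) {
    l <- lzw_max_length(n)
    expect_identical(length(lzw_compress(strrep("a", l))$codes), n, info = n)
  }
  # strictly between triangular numbers the code count is the least n
  # with n(n+1)/2 >= l
  for (l in c(2, 4, 5, 8, 12, 20, 50)) {
    want <- which(lzw_max_length(1:12) >= l)[1]
    expect_identical(length(lzw_compress(strrep("a", l))$codes), want,
                     info = l)
  }
  expect_identical(lzw_max_length(1), 1L)
  expect_identical(lzw_max_length(3), 6L)
  expect_identical(lzw_max_length(10), 55L)
  expect_error(lzw_max_length(0), "positive")
})

test_that("compressed sizes follow the stated packing policies", {
  r <- lzw_compress("aaaaaa")  # 3 codes, dictionary of 3 entries
  expect_identical(lzw_size(r, "code_count"), 3L)
  expect_identical(lzw_size(r, "fixed12_bytes"), 5L)  # ceiling(36 / 8)
  expect_identical(lzw_size(r, "minwidth_bytes"),
                   as.integer(ceiling(3 * ceiling(log2(3)) / 8)))
  expect_error(lzw_size(r, "zip"), "arg")
  expect_identical(lzw_size(lzw_compress("zbzbzc"), "minwidth_bytes"),
                   as.integer(ceiling(5 * ceiling(log2(7)) / 8)))
})

test_that("assembly joins outgrow lzw dictionary steps on unary strings", {
  # exact indices where exhaustive search is comfortable, a certified
  # upper bound beyond: either way the assembly count must stay below
  # the LZW code count from length 16 on
  for (l in 16:64) {
    codes <- length(lzw_compress(strrep("a", l))$codes)
    a <- assembly_index(strrep("a", l))$index
    # the counts touch (a = codes = 6) at exactly l = 19 and l = 21,
    # and separate for good afterwards
    if (l %in% c(19L, 21L)) {
      expect_identical(a, codes)
    } else {
      expect_lt(a, codes, label = paste("assembly index at length", l))
    }
  }
  set.seed(32)
  for (l in c(2^(7:10), sample(65:1024, 12))) {
    codes <- length(lzw_compress(strrep("a", l))$codes)
    expect_lt(greedy_upper_bound(strrep("a", l))$upper, codes,
              label = paste("greedy bound at length", l))
  }
})
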