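test_that("singly observed objects contribute nothing to Assembly", {
  e <- ensemble_from_observations(c("a", "b"))
  expect_identical(assembly_observable(e), 0)
  e2 <- ensemble_from_observations(c("zbzbzc", "zzzbbc"))
  expect_identical(assembly_observable(e2), 0)
})

test_that("Assembly evaluates the defining sum", {
  # one object, a = 0, n = 4: e^0 * 3/4
  e <- assembly_ensemble("a", copy_number = 4)
  expect_equal(assembly_observable(e), 0.75)
  # (a=2, n=2) and (a=3, n=3), N = 5; value frozen from hand evaluation
  e <- assembly_ensemble(c("u", "v"), copy_number = c(2, 3), index = c(2, 3))
  expect_equal(assembly_observable(e), 9.512025989061197, tolerance = 1e-12)
  expect_equal(sum(assembly_observable(e, per_object = TRUE)),
               assembly_observable(e))
})

test_that("ensembles are built by counting identical observations", {
  e <- ensemble_from_observations(c("ab", "ab", "ab"))
  expect_identical(nrow(e), 1L)
  expect_identical(e$copy_number, 3L)
  expect_identical(e$index, 1L)
  expect_identical(attr(e, "N"), 3L)
  e <- ensemble_from_observations(rep("zbzbzc", 10))
  expect_identical(e$copy_number, 10L)
  expect_identical(e$index, 4L)
})

test_that("Assembly is monotone in indices, copy weight and duplication", {
  base <- assembly_ensemble(c("u", "v"), copy_number = c(2, 3),
                            index = c(2, 3))
  a0 <- assembly_observable(base)
  # raising any index raises A
  higher_index <- assembly_ensemble(c("u", "v"), copy_number = c(2, 3),
                                    index = c(3, 3))
  expect_gt(assembly_observable(higher_index), a0)
  # extra copies of an object whose e^a exceeds the current A raise A
  # (extra copies of a sufficiently simple object can dilute it instead)
  more_copies <- assembly_ensemble(c("u", "v"), copy_number = c(2, 4),
                                   index = c(2, 3))
  expect_gt(assembly_observable(more_copies), a0)
  diluted <- assembly_ensemble(c("u", "v"), copy_number = c(3, 3),
                               index = c(2, 3))
  expect_lt(assembly_observable(diluted), a0)
  # for a single-object ensemble more copies always raise A
  expect_gt(assembly_observable(assembly_ensemble("u", 5, index = 2)),
            assembly_observable(assembly_ensemble("u", 4, index = 2)))
  # duplicating the whole ensemble raises A
  doubled <- assembly_ensemble(c("u", "v"), copy_number = c(4, 6),
                               index = c(2, 3))
  expect_gt(assembly_observable(doubled), a0)
})

test_that("Assembly is zero exactly when every copy number is one", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(1:4, 3, replace = TRUE)
    e <- assembly_ensemble(c("u", "v", "w"), copy_number = n,
                           index = c(1, 2, 3))
    if (all(n == 1)) {
      expect_identical(assembly_observable(e), 0)
    } else {
      expect_gt(assembly_observable(e), 0)
    }
  }
})

test_that("ensemble construction validates its inputs", {
  expect_error(assembly_ensemble(character(0), integer(0)), "non-empty")
  expect_error(assembly_ensemble(c("a", "a"), c(1, 1)), "distinguishable")
  expect_error(assembly_ensemble("a", 0), "positive")
  expect_error(assembly_ensemble("a", 2, index = -1), "non-negative")
  expect_error(assembly_observable(data.frame()), "assembly_ensemble")
})

test_that("ensembles round-trip through CSV and serialise to JSON", {
  e <- assembly_ensemble(c("zbzbzc", "ab"), copy_number = c(10, 2))
  csv <- tempfile(fileext = ".csv")
  write_ensemble_csv(e, csv)
  e2 <- read_ensemble_csv(csv)
  expect_identical(e2$value, e$value)
  expect_identical(e2$copy_number, e$copy_number)
  expect_identical(e2$index, e$index)
  expect_equal(assembly_observable(e2), assembly_observable(e))

  js <- tempfile(fileext = ".json")
  write_ensemble_json(e, js)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$A, assembly_observable(e))
  expect_identical(length(parsed$objects), 2L)

  # indices in the CSV are honoured without recomputation
  df <- utils::read.csv(csv)
  df$index <- df$index + 1L
  utils::write.csv(df, csv, row.names = FALSE)
  e3 <- read_ensemble_csv(csv)
  expect_identical(e3$index, e$index + 1L)
  unlink(c(csv, js))
})
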