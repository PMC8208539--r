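test_that("weight normalization divides by the sum and is scale-invariant", {
  expect_equal(normalize_weights(c(1, 1, 1, 1)), rep(0.25, 4))
  expect_equal(normalize_weights(c(1, 3)), c(0.25, 0.75))
  expect_equal(normalize_weights(5), 1)
  set.seed(31)
  w <- runif(20, 0.01, 10)
  for (c0 in c(0.001, 1, 1e6))
    expect_equal(normalize_weights(c0 * w), normalize_weights(w))
  expect_error(normalize_weights(numeric(0)))
  expect_error(normalize_weights(c(1, -2)))
  expect_error(normalize_weights(c(1, 0)))
})

make_pop <- function(n, seed = 41) {
  set.seed(seed)
  lapply(seq_len(n), function(i) random_diary(sprintf("p%04d", i)))
}

test_that("filtering matches all set fields, preserves order, and flags
           empty results", {
  pop <- make_pop(60)
  expect_identical(filter_diaries(pop, filter_criteria()), pop)

  fem <- filter_diaries(pop, filter_criteria(sex = "female"))
  expect_true(all(vapply(fem, `[[`, character(1), "sex") == "female"))
  ids <- vapply(pop, `[[`, character(1), "diary_id")
  expect_identical(vapply(fem, `[[`, character(1), "diary_id"),
                   ids[vapply(pop, `[[`, character(1), "sex") == "female"])

  both <- filter_diaries(pop, filter_criteria(sex = "male",
                                              day_type = "weekend",
                                              has_child_under_18 = TRUE))
  for (d in both) {
    expect_equal(d$sex, "male")
    expect_equal(d$day_type, "weekend")
    expect_true(d$has_child_under_18)
  }
  expect_warning(filter_diaries(pop, filter_criteria(state = "ZZ")),
                 "no diaries match")
})

test_that("subsampling saturates, is deterministic, and draws n distinct
           diaries", {
  pop <- make_pop(50)
  expect_identical(subsample_diaries(pop, n = 800, seed = 1), pop)

  big <- make_pop(1000, seed = 42)
  s1 <- subsample_diaries(big, n = 800, seed = 7)
  s2 <- subsample_diaries(big, n = 800, seed = 7)
  expect_identical(s1, s2)
  ids <- vapply(s1, `[[`, character(1), "diary_id")
  expect_length(unique(ids), 800L)
  s3 <- subsample_diaries(big, n = 800, seed = 8)
  expect_false(identical(vapply(s3, `[[`, character(1), "diary_id"), ids))
})

test_that("subsampling leaves the caller's RNG stream untouched", {
  pop <- make_pop(30)
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  invisible(subsample_diaries(pop, n = 5, seed = 3))
  expect_identical(runif(1), a)
})

test_that("filter + subsample + normalize always yields unit weight mass", {
  pop <- make_pop(120, seed = 43)
  for (seed in c(1, 2, 3)) {
    for (crit in list(filter_criteria(), filter_criteria(sex = "female"),
                      filter_criteria(day_type = "weekday"))) {
      sub <- subsample_diaries(filter_diaries(pop, crit), n = 20,
                               seed = seed)
      w <- normalize_weights(vapply(sub, `[[`, numeric(1), "weight"))
      expect_equal(sum(w), 1, tolerance = 1e-12)
    }
  }
})

test_that("over many seeds every diary is included about equally often", {
  pop <- make_pop(12, seed = 44)
  counts <- integer(12)
  n_draw <- 4L
  n_seeds <- 10000L
  for (s in seq_len(n_seeds)) {
    sub <- subsample_diaries(pop, n = n_draw, seed = s)
    idx <- match(vapply(sub, `[[`, character(1), "diary_id"),
                 vapply(pop, `[[`, character(1), "diary_id"))
    counts[idx] <- counts[idx] + 1L
  }
  expect_equal(sum(counts), n_draw * n_seeds)
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.001)
})
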