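test_that("minute expansion lays episodes end to end", {
  all_sleep <- new_diary("s", "010101", 1, 1440)
  ms <- minute_sequence(all_sleep, default_xw)
  expect_length(ms, 1440)
  expect_true(all(ms == "sleep"))

  two <- new_diary("t", c("010101", "050101"), c(1, 481), c(480, 960))
  ms2 <- minute_sequence(two, default_xw)
  expect_equal(as.character(ms2[c(1, 480, 481, 1440)]),
               c("sleep", "sleep", "work", "work"))
  expect_equal(sum(ms2 == "sleep"), 480)

  three <- new_diary("x", c("010101", "050101", "120101"),
                     c(1, 481, 961), c(480, 480, 480))
  expect_equal(rle(as.character(minute_sequence(three, default_xw)))$lengths,
               c(480, 480, 480))
})

test_that("uncapped or gappy diaries are refused at expansion", {
  gap <- new_diary("g", c("010101", "050101"), c(1, 91), c(60, 1350))
  expect_error(minute_sequence(gap, default_xw), "contiguous")
  long <- new_diary("l", "010101", 1, 1500)
  expect_error(minute_sequence(long, default_xw), "contiguous")
})

test_that("slot reduction keeps the category at each slot's first minute", {
  d <- new_diary("e", c("110101", "010101"), c(1, 21), c(20, 1420))
  sl <- reduce_to_slots(minute_sequence(d, default_xw))
  expect_length(sl, 96)
  expect_equal(as.character(sl[1:3]), c("eating", "eating", "sleep"))
  expect_true(all(sl[3:96] == "sleep"))
})

test_that("episodes missing every slot-first minute vanish from slots", {
  d <- new_diary("tiny", c("010101", "110101", "010101"),
                 c(1, 3, 13), c(2, 10, 1428))
  sl <- reduce_to_slots(minute_sequence(d, default_xw))
  expect_false(any(sl == "eating"))
})

test_that("slot reduction of a constant sequence is constant and the
           modal rule can recover mid-slot majorities", {
  cst <- minute_sequence(new_diary("c", "050101", 1, 1440), default_xw)
  expect_true(all(reduce_to_slots(cst) == "work"))
  # slot 1 minutes: 1-2 sleep, 3-12 eating, 13-15 sleep -> modal = eating
  d <- new_diary("m", c("010101", "110101", "010101"),
                 c(1, 3, 13), c(2, 10, 1428))
  expect_equal(as.character(
    reduce_to_slots(minute_sequence(d, default_xw), rule = "modal")[1]),
    "eating")
})

test_that("per-category minute counts conserve episode durations", {
  set.seed(21)
  for (i in 1:20) {
    d <- random_diary(paste0("c", i))
    ms <- minute_sequence(d, default_xw)
    cats <- map_code(d$episodes$activity_code, default_xw)
    expected <- tapply(d$episodes$duration_min, cats, sum)
    got <- table(ms)[names(expected)]
    expect_equal(as.numeric(got), as.numeric(expected))
  }
})

test_that("slot-resolution time shares stay within the binning error bound", {
  set.seed(22)
  for (i in 1:20) {
    d <- random_diary(paste0("b", i))
    ms <- minute_sequence(d, default_xw)
    sl <- reduce_to_slots(ms)
    bound <- 100 * nrow(d$episodes) * 14 / 1440
    for (a in activity_categories()) {
      p_min <- 100 * sum(ms == a) / 1440
      p_slot <- 100 * sum(sl == a) / 96
      expect_lte(abs(p_min - p_slot), bound + 1e-9)
    }
  }
})

test_that("sequence sets stack diaries in order with normalized weights", {
  ds <- list(new_diary("a", "010101", 1, 1440, weight = 1),
             new_diary("b", "050101", 1, 1440, weight = 1),
             new_diary("c", "120303", 1, 1440, weight = 2))
  ss <- build_sequence_set(ds, default_xw)
  expect_equal(dim(ss$seq), c(3L, 96L))
  expect_equal(ss$weights, c(0.25, 0.25, 0.5))
  expect_equal(ss$covariates$diary_id, c("a", "b", "c"))
  ss1 <- build_sequence_set(ds[1], default_xw)
  expect_equal(ss1$weights, 1)
  ssm <- build_sequence_set(ds, default_xw, resolution = "minute")
  expect_equal(ncol(ssm$seq), 1440L)
})

test_that("per-diary failures carry the diary id", {
  bad <- list(new_diary("fine", "010101", 1, 1440),
              new_diary("broken", "999999", 1, 1440))
  expect_error(build_sequence_set(bad, default_xw), "broken")
  expect_error(build_sequence_set(list(), default_xw), "no diaries")
})
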