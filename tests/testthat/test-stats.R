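two_diary_set <- function() {
  a <- new_diary("a", c("010101", "050101"), c(1, 721), c(720, 720),
                 weight = 1)
  b <- new_diary("b", "010101", 1, 1440, weight = 3)
  build_sequence_set(list(a, b), default_xw)
}

test_that("percent of total time reproduces the weighted worked example", {
  tot <- percent_of_total_time(two_diary_set())
  expect_equal(unname(tot["sleep"]), 87.5)
  expect_equal(unname(tot["work"]), 12.5)
  expect_equal(sum(tot), 100, tolerance = 1e-9)

  solo <- build_sequence_set(
    list(new_diary("s", "010101", 1, 1440)), default_xw)
  tot1 <- percent_of_total_time(solo)
  expect_equal(unname(tot1["sleep"]), 100)
  expect_true(all(tot1[names(tot1) != "sleep"] == 0))
})

test_that("transition matrix counts between-activity changes only", {
  three <- build_sequence_set(
    list(new_diary("x", c("010101", "050101", "010101"),
                   c(1, 481, 961), c(480, 480, 480))), default_xw)
  tm <- transition_matrix(three)
  expect_equal(tm["sleep", "work"], 50)
  expect_equal(tm["work", "sleep"], 50)
  expect_equal(sum(tm), 100, tolerance = 1e-9)
  expect_true(all(diag(tm) == 0))

  # two diaries, equal weights: changes 0.5*1 + 0.5*1 sleep->work,
  # 0.5*1 work->tv, total mass 1.5
  a <- new_diary("a", c("010101", "050101"), c(1, 721), c(720, 720))
  b <- new_diary("b", c("010101", "050101", "120303"),
                 c(1, 481, 961), c(480, 480, 480))
  tm2 <- transition_matrix(build_sequence_set(list(a, b), default_xw))
  expect_equal(tm2["sleep", "work"], 100 * (2 / 3), tolerance = 1e-12)
  expect_equal(tm2["work", "tv"], 100 * (1 / 3), tolerance = 1e-12)
})

test_that("a constant diary yields the warned all-zero matrix", {
  solo <- build_sequence_set(
    list(new_diary("s", "010101", 1, 1440)), default_xw)
  expect_warning(tm <- transition_matrix(solo), "no transitions")
  expect_true(all(tm == 0))
  expect_equal(attr(tm, "n_effective"), 0)
})

test_that("tempograms tally weighted occupancy per slot", {
  solo <- build_sequence_set(
    list(new_diary("s", "010101", 1, 1440)), default_xw)
  tg <- tempogram(solo, "count")
  expect_equal(dim(tg), c(96L, 11L))
  expect_true(all(tg[, "sleep"] == 1))
  expect_true(all(tg[, colnames(tg) != "sleep"] == 0))

  # equal weights, diaries differ only in slot 1
  a <- new_diary("a", c("010101", "050101"), c(1, 16), c(15, 1425))
  b <- new_diary("b", c("120303", "050101"), c(1, 16), c(15, 1425))
  tg2 <- tempogram(build_sequence_set(list(a, b), default_xw), "count")
  expect_equal(unname(tg2[1, c("sleep", "tv")]), c(1, 1))
  expect_true(all(tg2[2:96, "work"] == 2))

  tgp <- tempogram(two_diary_set(), "percent")
  expect_equal(unname(rowSums(tgp)), rep(100, 96), tolerance = 1e-9)
  expect_error(tempogram(build_sequence_set(
    list(new_diary("m", "010101", 1, 1440)), default_xw,
    resolution = "minute")), "slot")
})

test_that("state averages are 15 minutes per weighted timestamp and
           partition the day", {
  solo <- new_diary("s", "010101", 1, 1440, state = "MN")
  sa <- state_average_minutes(solo, default_xw)
  expect_equal(unname(sa$minutes["MN", "sleep"]), 1440)
  expect_true(all(sa$minutes["MN", colnames(sa$minutes) != "sleep"] == 0))

  one_slot <- new_diary("ac", c("010101", "030401", "010101"),
                        c(1, 601, 616), c(600, 15, 825),
                        weight = 2.7, state = "WI")
  sa2 <- state_average_minutes(one_slot, default_xw)
  expect_equal(unname(sa2$minutes["WI", "adult_care"]), 15)

  unk <- new_diary("u", "010101", 1, 1440, state = "unknown")
  sa3 <- state_average_minutes(list(solo, one_slot, unk), default_xw)
  expect_equal(sa3$n_excluded, 1L)
  expect_equal(unname(sa3$n_diaries[c("MN", "WI")]), c(1L, 1L))
  expect_equal(unname(rowSums(sa3$minutes)), rep(1440, 2),
               tolerance = 1e-6)
})

test_that("weights within a state are re-normalized independently", {
  # two MN diaries, weights 1 and 3: all-sleep and half-sleep/half-work
  a <- new_diary("a", "010101", 1, 1440, weight = 1, state = "MN")
  b <- new_diary("b", c("010101", "050101"), c(1, 721), c(720, 720),
                 weight = 3, state = "MN")
  c_ <- new_diary("c", "120303", 1, 1440, weight = 100, state = "CA")
  sa <- state_average_minutes(list(a, b, c_), default_xw)
  expect_equal(unname(sa$minutes["MN", "work"]), 0.75 * 720)
  expect_equal(unname(sa$minutes["MN", "sleep"]), 1440 - 0.75 * 720)
  expect_equal(unname(sa$minutes["CA", "tv"]), 1440)
})

test_that("equal weights reduce the statistics to unweighted means", {
  set.seed(51)
  ds <- lapply(1:6, function(i) random_diary(paste0("e", i)))
  for (d in seq_along(ds)) ds[[d]]$weight <- 2.5
  ss <- build_sequence_set(ds, default_xw)
  tot <- percent_of_total_time(ss)
  slot_seqs <- lapply(ds, oracle_slot_seq, xw = default_xw)
  manual <- sapply(activity_categories(), function(a)
    100 * mean(vapply(slot_seqs, function(s) sum(s == a) / 96, numeric(1))))
  expect_equal(unname(unclass(tot)), unname(manual), tolerance = 1e-12)
})

test_that("statistics are invariant to diary order", {
  set.seed(52)
  ds <- lapply(1:8, function(i) random_diary(paste0("p", i)))
  perm <- sample(length(ds))
  ss1 <- build_sequence_set(ds, default_xw)
  ss2 <- build_sequence_set(ds[perm], default_xw)
  expect_equal(unclass(percent_of_total_time(ss1)),
               unclass(percent_of_total_time(ss2)), tolerance = 1e-12)
  t1 <- transition_matrix(ss1); t2 <- transition_matrix(ss2)
  expect_equal(unclass(t1), unclass(t2),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unclass(tempogram(ss1, "percent")),
               unclass(tempogram(ss2, "percent")), tolerance = 1e-12)
})
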