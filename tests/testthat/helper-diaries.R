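# Shared fixtures and independent brute-force oracles.

default_xw <- load_crosswalk()

# a pool of detailed codes resolvable by the default crosswalk, spanning
# several categories and prefix depths
code_pool <- c("010101", "010102", "010201", "020101", "020203", "030101",
               "030401", "040501", "050101", "050201", "060301", "070101",
               "110101", "120101", "120303", "130131", "150101", "180501",
               "500101")

# random capped diary: <= max_episodes contiguous episodes covering 1440 min
random_diary <- function(id, max_episodes = 10, states = c("CA", "MN")) {
  k <- sample.int(max_episodes, 1L)
  cuts <- if (k > 1L) sort(sample(2:1440, k - 1L)) else integer(0)
  starts <- c(1L, cuts)
  durs <- diff(c(starts, 1441L))
  new_diary(id,
            activity_code = sample(code_pool, k, replace = TRUE),
            start_min = starts, duration_min = durs,
            weight = stats::runif(1, 0.1, 5),
            sex = sample(c("female", "male"), 1L),
            day_type = sample(c("weekday", "weekend"), 1L),
            marital = sample(c("married", "not_married"), 1L),
            has_child_under_18 = stats::runif(1) < 0.5,
            state = sample(states, 1L))
}

# oracle: expand a diary minute-by-minute, then take each slot's first
# minute; plain loops, no shared code with the package internals
oracle_slot_seq <- function(diary, xw) {
  minutes <- character(0)
  for (i in seq_len(nrow(diary$episodes))) {
    cat_i <- map_code(diary$episodes$activity_code[i], xw)
    minutes <- c(minutes, rep(cat_i, diary$episodes$duration_min[i]))
  }
  stopifnot(length(minutes) == 1440L)
  out <- character(96)
  for (t in 1:96) out[t] <- minutes[15 * (t - 1) + 1]
  out
}

# oracle for percent-of-total-time: integer slot counts tallied per diary,
# combined with exact weight ratios at the end
oracle_totals <- function(slot_seqs, raw_weights) {
  cats <- activity_categories()
  out <- stats::setNames(numeric(length(cats)), cats)
  for (j in seq_along(slot_seqs)) {
    for (a in cats) {
      n_a <- 0L
      for (t in 1:96) if (slot_seqs[[j]][t] == a) n_a <- n_a + 1L
      out[a] <- out[a] + (raw_weights[j] / sum(raw_weights)) * n_a / 96
    }
  }
  100 * out
}

# oracle for the transition matrix: tally every between-activity change,
# then express as percent of the total tallied mass
oracle_transitions <- function(slot_seqs, raw_weights) {
  cats <- activity_categories()
  m <- matrix(0, 11, 11, dimnames = list(cats, cats))
  w <- raw_weights / sum(raw_weights)
  for (j in seq_along(slot_seqs)) {
    s <- slot_seqs[[j]]
    for (t in 2:96) {
      if (s[t - 1] != s[t]) m[s[t - 1], s[t]] <- m[s[t - 1], s[t]] + w[j]
    }
  }
  if (sum(m) > 0) 100 * m / sum(m) else m
}
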