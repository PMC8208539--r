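#' Percent of total time by activity
#'
#' For each of the eleven activity categories, the weighted share of all
#' sequence steps the selected diaries spend in it: for activity i,
#' `100 * sum_j w_hat_j * #{t : seq[j,t] == i} / T`, where `w_hat` are the
#' normalized subsample weights and T is the sequence length (96 slots or
#' 1440 minutes). The eleven percentages partition the day, so they sum
#' to 100.
#'
#' @param ss A `sequence_set`.
#' @return A `totals_table`: named numeric vector of percentages over the
#'   11 categories, in fixed category order.
#' @export
#' @examples
#' xw <- load_crosswalk()
#' a <- new_diary("a", c("010101", "050101"), c(1, 721), c(720, 720),
#'                weight = 1)
#' b <- new_diary("b", "010101", 1, 1440, weight = 3)
#' percent_of_total_time(build_sequence_set(list(a, b), xw))
percent_of_total_time <- function(ss) {
  stopifnot(inherits(ss, "sequence_set"))
  n_t <- ncol(ss$seq)
  k <- length(ss$categories)
  shares <- numeric(k)
  for (i in seq_len(k)) {
    cnt <- rowSums(ss$seq == i)
    shares[i] <- sum(ss$weights * cnt) / n_t
  }
  out <- 100 * shares
  names(out) <- ss$categories
  class(out) <- c("totals_table", class(out))
  out
}

#' @export
print.totals_table <- function(x, ...) {
  cat("Percent of total time by activity:\n")
  print(round(unclass(x), 2))
  invisible(x)
}

#' Weighted activity transition matrix
#'
#' Counts the activity changes between adjacent slots of every selected
#' diary: each pair `t-1, t` with `seq[j,t-1] = u != v = seq[j,t]`
#' contributes the diary's normalized weight to cell (u, v).
#' Within-category continuations are ignored, giving the zero diagonal.
#' The weighted counts are expressed as percentages of all transitions
#' between different activities, so the off-diagonal entries sum to 100.
#'
#' @param ss A `sequence_set` (slot resolution).
#' @return A `transition_matrix`: 11 x 11 numeric matrix of percentages in
#'   fixed category order, diagonal 0, with attribute `n_effective` (the
#'   total weighted transition mass before normalization). With no
#'   transitions at all (every diary constant) an all-zero matrix with
#'   `n_effective = 0` is returned with a warning.
#' @export
transition_matrix <- function(ss) {
  stopifnot(inherits(ss, "sequence_set"))
  k <- length(ss$categories)
  n_t <- ncol(ss$seq)
  raw <- matrix(0, k, k, dimnames = list(ss$categories, ss$categories))
  from <- ss$seq[, -n_t, drop = FALSE]
  to <- ss$seq[, -1L, drop = FALSE]
  chg <- from != to
  for (j in seq_len(nrow(ss$seq))) {
    tt <- which(chg[j, ])
    if (length(tt))
      for (t in tt)
        raw[from[j, t], to[j, t]] <- raw[from[j, t], to[j, t]] + ss$weights[j]
  }
  total <- sum(raw)
  if (total == 0) {
    warning("no transitions between different activities in the input")
    pct <- raw
  } else {
    pct <- 100 * raw / total
  }
  structure(pct, n_effective = total,
            class = c("transition_matrix", "matrix", "array"))
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("Activity transition matrix (% of all between-activity transitions,",
      "\n weighted; n_effective =", format(attr(x, "n_effective")), ")\n")
  m <- x; attributes(m) <- attributes(x)[c("dim", "dimnames")]
  print(round(m, 2))
  invisible(x)
}

#' Tempogram: who does what at each time of day
#'
#' A 96 x 11 surface giving, for each fifteen-minute slot from 4:00 am to
#' 3:45 am, the weighted mass (count mode) or percentage (percent mode) of
#' diaries in each activity. In count mode normalized weights are scaled
#' by the number of displayed diaries so cells read as "number of
#' observations"; each slot's row then sums to n. In percent mode each
#' slot sums to 100.
#'
#' @param ss A `sequence_set` at slot resolution.
#' @param mode `"count"` or `"percent"`.
#' @return A `tempogram`: 96 x 11 matrix with slot clock-time labels as
#'   row names and categories as column names; attribute `mode`.
#' @export
tempogram <- function(ss, mode = c("count", "percent")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ss, "sequence_set"))
  if (ss$resolution != "slot")
    stop("tempogram requires slot (15-minute) resolution")
  k <- length(ss$categories)
  n <- nrow(ss$seq)
  vals <- matrix(0, 96L, k, dimnames = list(slot_labels(), ss$categories))
  w <- if (mode == "count") ss$weights * n else ss$weights
  for (i in seq_len(k))
    vals[, i] <- colSums((ss$seq == i) * w)
  if (mode == "percent") {
    tot <- rowSums(vals)
    vals <- 100 * vals / tot
  }
  structure(vals, mode = mode, class = c("tempogram", "matrix", "array"))
}

#' Clock-time labels of the 96 fifteen-minute slots
#'
#' Slot 1 starts at 4:00 am of the diary day; slot 96 starts at 3:45 am
#' the next morning.
#'
#' @return Character vector of length 96 ("4:00 am", "4:15 am", ...).
#' @export
slot_labels <- function() {
  start_min <- (seq_len(96L) - 1L) * 15L          # minutes from 4:00 am
  clock <- (240L + start_min) %% 1440L            # minutes from midnight
  h <- clock %/% 60L; m <- clock %% 60L
  ampm <- ifelse(h < 12L, "am", "pm")
  h12 <- h %% 12L; h12[h12 == 0L] <- 12L
  sprintf("%d:%02d %s", h12, m, ampm)
}

#' @export
print.tempogram <- function(x, ...) {
  cat("<tempogram>", attr(x, "mode"), "mode, 96 slots x",
      ncol(x), "categories\n")
  print(round(utils::head(unclass(x), 4), 2))
  cat("...\n")
  invisible(x)
}

#' State-level average minutes per day by activity
#'
#' Treats each US state's diaries as their own sample: weights are
#' re-normalized within the state, the weighted number of fifteen-minute
#' timestamps spent in each activity is computed as in the totals, and
#' multiplied by 15 (the duration of a timestamp) to give average minutes
#' per day. Per state the eleven averages partition the day and sum to
#' 1440. Diaries with unknown state are excluded and counted.
#'
#' @param diaries List of capped `diary` objects.
#' @param xw An `activity_crosswalk`.
#' @param unknown_state Label treated as missing (default `"unknown"`).
#' @return A `state_averages`: list with `minutes` (states x 11 matrix of
#'   average minutes/day), `n_diaries` (named count per state) and
#'   `n_excluded` (diaries without a usable state).
#' @export
state_average_minutes <- function(diaries, xw, unknown_state = "unknown") {
  if (inherits(diaries, "diary")) diaries <- list(diaries)
  states <- vapply(diaries, `[[`, character(1), "state")
  known <- !(states %in% unknown_state | is.na(states))
  n_excluded <- sum(!known)
  diaries <- diaries[known]
  states <- states[known]
  if (length(diaries) == 0L) stop("no diaries with a known state")
  st_levels <- sort(unique(states))
  k <- length(activity_categories())
  mins <- matrix(0, length(st_levels), k,
                 dimnames = list(st_levels, activity_categories()))
  n_d <- integer(length(st_levels)); names(n_d) <- st_levels
  for (s in st_levels) {
    grp <- diaries[states == s]
    n_d[s] <- length(grp)
    ss <- build_sequence_set(grp, xw, resolution = "slot")
    for (i in seq_len(k))
      mins[s, i] <- 15 * sum(ss$weights * rowSums(ss$seq == i))
  }
  structure(list(minutes = mins, n_diaries = n_d, n_excluded = n_excluded),
            class = "state_averages")
}

#' @export
print.state_averages <- function(x, ...) {
  cat("<state_averages>", nrow(x$minutes), "state(s),",
      x$n_excluded, "diaries excluded (unknown state)\n")
  print(round(x$minutes, 1))
  invisible(x)
}
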