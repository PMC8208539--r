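#' Construct a time-use diary
#'
#' A diary is one respondent-day: an ordered run of activity episodes
#' covering the 24-hour reporting window that starts at 4:00 am, plus a
#' survey weight and the covariates used for subgroup filtering. Minutes
#' are indexed 1..1440 from 4:00 am; an episode occupies the half-open
#' interval `[start_min, stop_min)`, so a full day runs from minute 1 to
#' stop minute 1441 and minute 1440 is the 3:59-4:00 am minute. Raw
#' diaries are recorded to the end of the last activity and may run past
#' minute 1441; [cap_final_episode()] truncates them to the uniform
#' 1440-minute day.
#'
#' @param diary_id Identifier (coerced to character).
#' @param activity_code Character vector of detailed activity codes, one
#'   per episode, in time order.
#' @param start_min Integer start minutes (1-based, minutes from 4:00 am).
#' @param duration_min Positive integer episode durations in minutes.
#' @param weight Positive survey weight.
#' @param sex `"female"`, `"male"` or `"unknown"`.
#' @param day_type `"weekday"` or `"weekend"`.
#' @param marital Marital-status label (free categorical).
#' @param has_child_under_18 Logical: child under 18 in the household.
#' @param state US-state code (any label) or `"unknown"`.
#' @return An object of class `diary`.
#' @export
#' @examples
#' d <- new_diary("d1", c("010101", "050101"), c(1, 481), c(480, 960),
#'                weight = 2.5)
#' d
new_diary <- function(diary_id, activity_code, start_min, duration_min,
                      weight = 1, sex = "unknown", day_type = "weekday",
                      marital = "unknown", has_child_under_18 = FALSE,
                      state = "unknown") {
  n <- length(activity_code)
  if (n < 1L) stop("a diary needs at least one episode")
  if (length(start_min) != n || length(duration_min) != n)
    stop("activity_code, start_min and duration_min must have equal length")
  start_min <- as.integer(start_min)
  duration_min <- as.integer(duration_min)
  if (!is.numeric(weight) || length(weight) != 1L || !is.finite(weight) ||
      weight <= 0)
    stop("weight must be a single positive number")
  sex <- match.arg(sex, c("female", "male", "unknown"))
  day_type <- match.arg(day_type, c("weekday", "weekend"))
  episodes <- data.frame(
    activity_code = as.character(activity_code),
    start_min = start_min,
    duration_min = duration_min,
    stop_min = start_min + duration_min,
    stringsAsFactors = FALSE
  )
  structure(
    list(diary_id = as.character(diary_id), episodes = episodes,
         weight = as.numeric(weight), sex = sex, day_type = day_type,
         marital = as.character(marital),
         has_child_under_18 = isTRUE(has_child_under_18),
         state = as.character(state)),
    class = "diary"
  )
}

#' @export
print.diary <- function(x, ...) {
  cat("<diary>", x$diary_id, "-", nrow(x$episodes), "episodes,",
      sum(x$episodes$duration_min), "min, weight", format(x$weight), "\n")
  cat("  ", x$sex, "/", x$day_type, "/ marital:", x$marital,
      "/ child<18:", x$has_child_under_18, "/ state:", x$state, "\n")
  invisible(x)
}

#' Validate a diary against time-diary quality checks
#'
#' Applies the standard diary quality checks: episodes must be in start
#' order (`NOT_SEQUENTIAL`), adjacent episodes must be contiguous with no
#' gap (`GAP`) or overlap (`OVERLAP`), the first episode must start at
#' minute 1, durations must be positive (`BAD_DURATION`), total recorded
#' time after capping must be exactly 1440 minutes (`SUM_NOT_1440`), and
#' every activity code must resolve in the crosswalk (`UNKNOWN_CODE`).
#' All problems are reported, none raised, and the diary is not modified.
#'
#' @param diary A `diary`.
#' @param xw Optional `activity_crosswalk`; when supplied, unmapped codes
#'   are reported as `UNKNOWN_CODE` issues.
#' @return A `validation_report`: list with `diary_id`, `is_valid`, and a
#'   data frame `issues` with columns `code`, `message`, `location`.
#' @export
#' @examples
#' d <- new_diary("d1", c("010101", "050101"), c(1, 481), c(480, 960))
#' validate_diary(d)$is_valid
validate_diary <- function(diary, xw = NULL) {
  stopifnot(inherits(diary, "diary"))
  ep <- diary$episodes
  issues <- list()
  add <- function(code, message, location) {
    issues[[length(issues) + 1L]] <<- data.frame(
      code = code, message = message, location = as.integer(location),
      stringsAsFactors = FALSE)
  }
  if (is.unsorted(ep$start_min, strictly = TRUE))
    add("NOT_SEQUENTIAL", "episodes are not in strictly increasing start order",
        which(diff(ep$start_min) <= 0)[1] + 1L)
  bad_dur <- which(ep$duration_min < 1L)
  for (i in bad_dur)
    add("BAD_DURATION",
        sprintf("episode %d has nonpositive duration %d", i, ep$duration_min[i]),
        i)
  if (ep$start_min[1] != 1L)
    add("GAP", sprintf("diary starts at minute %d, not 1", ep$start_min[1]), 1L)
  if (nrow(ep) > 1L) {
    for (i in seq_len(nrow(ep) - 1L)) {
      stp <- ep$stop_min[i]; nxt <- ep$start_min[i + 1L]
      if (nxt > stp)
        add("GAP", sprintf("gap of %d min between episodes %d and %d",
                           nxt - stp, i, i + 1L), stp)
      else if (nxt < stp)
        add("OVERLAP", sprintf("episodes %d and %d overlap by %d min",
                               i, i + 1L, stp - nxt), nxt)
    }
  }
  total <- sum(pmax(ep$duration_min, 0L))
  if (total != 1440L)
    add("SUM_NOT_1440",
        sprintf("episode durations sum to %d, not 1440", total), total)
  if (!is.null(xw)) {
    for (i in seq_len(nrow(ep))) {
      hit <- tryCatch(map_code(ep$activity_code[i], xw), error = function(e) NULL)
      if (is.null(hit))
        add("UNKNOWN_CODE",
            sprintf("episode %d code %s not in crosswalk", i,
                    ep$activity_code[i]), i)
    }
  }
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(code = character(), message = character(),
               location = integer(), stringsAsFactors = FALSE)
  structure(
    list(diary_id = diary$diary_id, is_valid = nrow(issues) == 0L,
         issues = issues),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>", x$diary_id,
      if (x$is_valid) "- valid\n" else
        paste("-", nrow(x$issues), "issue(s)\n"))
  if (!x$is_valid) print(x$issues)
  invisible(x)
}

#' Cap the final episode at 3:59 am
#'
#' Raw diaries are recorded to the end time of the last activity, so they
#' often extend past 24 hours. Capping truncates the final activity to end
#' at 3:59 am so every diary spans exactly 1440 minutes: episodes starting
#' after minute 1440 are dropped and the last remaining episode is
#' shortened so its stop minute is 1441. Diaries covering less than 1440
#' minutes cannot be extended and are an error. The operation is
#' idempotent.
#'
#' @param diary A sequential `diary` (no gaps/overlaps).
#' @return The capped `diary`, total duration exactly 1440 minutes.
#' @export
#' @examples
#' d28 <- new_diary("d1", c("010101", "120101"), c(1, 1201), c(1200, 480))
#' sum(cap_final_episode(d28)$episodes$duration_min)  # 1440
cap_final_episode <- function(diary) {
  stopifnot(inherits(diary, "diary"))
  ep <- diary$episodes
  keep <- ep$start_min <= 1440L
  if (!any(keep)) stop("no episode starts within the diary day")
  ep <- ep[keep, , drop = FALSE]
  last <- nrow(ep)
  if (ep$stop_min[last] > 1441L) {
    ep$stop_min[last] <- 1441L
    ep$duration_min[last] <- 1441L - ep$start_min[last]
  }
  if (ep$stop_min[last] < 1441L)
    stop(sprintf("diary %s covers only %d minutes; capping cannot extend it",
                 diary$diary_id, ep$stop_min[last] - 1L))
  rownames(ep) <- NULL
  diary$episodes <- ep
  diary
}
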