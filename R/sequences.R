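#' Expand a capped diary to its 1440-minute categorical sequence
#'
#' Minute `m` (1..1440, minutes from 4:00 am) holds the top-level category
#' of the episode covering it; every minute must be covered exactly once,
#' so the diary has to be capped and sequential.
#'
#' @param diary A capped, sequential `diary`.
#' @param xw An `activity_crosswalk`.
#' @return A factor of length 1440 with levels [activity_categories()],
#'   carrying the diary id in attribute `diary_id`.
#' @export
minute_sequence <- function(diary, xw) {
  stopifnot(inherits(diary, "diary"))
  ep <- diary$episodes
  if (ep$start_min[1] != 1L ||
      any(ep$stop_min[-nrow(ep)] != ep$start_min[-1]) ||
      ep$stop_min[nrow(ep)] != 1441L)
    stop(sprintf("diary %s is not a contiguous capped 1440-minute day",
                 diary$diary_id))
  cats <- map_code(ep$activity_code, xw)
  seq_m <- factor(rep(cats, times = ep$duration_min),
                  levels = activity_categories())
  attr(seq_m, "diary_id") <- diary$diary_id
  seq_m
}

#' Reduce a minute sequence to 96 fifteen-minute slots
#'
#' Slot `t` (1..96) covers clock minutes `15(t-1)+1 .. 15t` and takes the
#' category at its first minute, i.e. minute `15(t-1)+1`. This is the
#' floor rule applied to episode boundary times at 15-minute resolution:
#' episodes shorter than a slot whose span contains no slot-first minute
#' do not appear in the slot sequence.
#'
#' @param ms A length-1440 minute sequence (from [minute_sequence()]).
#' @param rule `"first"` (default, the floor rule) or `"modal"`: take the
#'   most frequent category within the slot instead, earliest category
#'   winning ties. The modal rule is provided for sensitivity checks.
#' @return A factor of length 96 with levels [activity_categories()].
#' @export
reduce_to_slots <- function(ms, rule = c("first", "modal")) {
  rule <- match.arg(rule)
  if (length(ms) != 1440L) stop("minute sequence must have length 1440")
  if (rule == "first") {
    out <- ms[15L * (seq_len(96L) - 1L) + 1L]
  } else {
    idx <- matrix(seq_len(1440L), nrow = 15L)
    out <- factor(apply(idx, 2L, function(m) {
      tab <- table(factor(as.character(ms[m]), levels = unique(as.character(ms[m]))))
      names(tab)[which.max(tab)]
    }), levels = activity_categories())
  }
  attr(out, "diary_id") <- attr(ms, "diary_id")
  out
}

#' Build a weighted sequence set from diaries
#'
#' Runs every diary through the crosswalk to its fixed-length categorical
#' sequence (1440 one-minute or 96 fifteen-minute slots), stacks them into
#' a matrix in input order, and normalizes the survey weights of the
#' selected diaries to sum to 1 (see [normalize_weights()]). Covariates
#' are carried along for downstream grouping.
#'
#' @param diaries List of capped `diary` objects.
#' @param xw An `activity_crosswalk`.
#' @param resolution `"slot"` (96 fifteen-minute slots, default) or
#'   `"minute"` (1440 slots).
#' @param slot_rule Passed to [reduce_to_slots()].
#' @return A `sequence_set`: list with `seq` (n x T integer matrix of
#'   category indices, levels in attribute and in `$categories`),
#'   `weights` (normalized), `raw_weights`, `covariates` data frame and
#'   `resolution`.
#' @export
#' @examples
#' xw <- load_crosswalk()
#' d <- new_diary("d1", c("010101", "050101"), c(1, 481), c(480, 960))
#' ss <- build_sequence_set(list(d), xw)
#' dim(ss$seq)  # 1 x 96
build_sequence_set <- function(diaries, xw,
                               resolution = c("slot", "minute"),
                               slot_rule = "first") {
  resolution <- match.arg(resolution)
  if (inherits(diaries, "diary")) diaries <- list(diaries)
  if (length(diaries) == 0L) stop("no diaries supplied")
  n_t <- if (resolution == "slot") 96L else 1440L
  seqs <- matrix(NA_integer_, nrow = length(diaries), ncol = n_t)
  ids <- character(length(diaries))
  for (j in seq_along(diaries)) {
    d <- diaries[[j]]
    s <- tryCatch({
      ms <- minute_sequence(d, xw)
      if (resolution == "slot") reduce_to_slots(ms, rule = slot_rule) else ms
    }, error = function(e) {
      stop(sprintf("diary %s: %s", d$diary_id, conditionMessage(e)),
           call. = FALSE)
    })
    seqs[j, ] <- as.integer(s)
    ids[j] <- d$diary_id
  }
  raw_w <- vapply(diaries, `[[`, numeric(1), "weight")
  cov <- data.frame(
    diary_id = ids,
    sex = vapply(diaries, `[[`, character(1), "sex"),
    day_type = vapply(diaries, `[[`, character(1), "day_type"),
    marital = vapply(diaries, `[[`, character(1), "marital"),
    has_child_under_18 = vapply(diaries, `[[`, logical(1),
                                "has_child_under_18"),
    state = vapply(diaries, `[[`, character(1), "state"),
    stringsAsFactors = FALSE
  )
  structure(
    list(seq = seqs, categories = activity_categories(),
         weights = normalize_weights(raw_w), raw_weights = raw_w,
         covariates = cov, resolution = resolution),
    class = "sequence_set"
  )
}

#' @export
print.sequence_set <- function(x, ...) {
  cat("<sequence_set>", nrow(x$seq), "diaries x", ncol(x$seq),
      paste0(if (x$resolution == "slot") "fifteen-minute" else "one-minute",
             " slots; weights sum "),
      format(sum(x$weights)), "\n")
  invisible(x)
}
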