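#' Describe the layout of an episode/person extract
#'
#' An extract dialect maps the column names and value codes of a
#' rectangular two-file extract (one episode-level file, one person-level
#' file, joined on the diary id) onto the roles the package needs. The
#' default dialect uses the IPUMS ATUS-X variable names (CASEID,
#' ACTIVITY, START, DURATION, WT06, SEX, DAY, MARST, KIDUND18, STATEFIP);
#' every name and code table can be remapped for other exports.
#'
#' @param episode_cols Named character vector with roles `diary_id`,
#'   `activity_code`, `start`, `duration`.
#' @param person_cols Named character vector with roles `diary_id`,
#'   `weight`, `sex`, `day`, `marital`, `child`, `state`.
#' @param delim Field delimiter.
#' @param time_format `"offset"`: start column holds integer minutes from
#'   4:00 am (1-based); `"clock"`: start column holds clock times such as
#'   `"04:00:00"` or `"13:30"`, converted to offsets at ingest.
#' @param sex_map Named vector mapping sex codes to
#'   `"female"`/`"male"`/`"unknown"`.
#' @param day_map Named vector mapping day-of-week codes to
#'   `"weekday"`/`"weekend"` (default: ATUS coding, 1 = Sunday,
#'   7 = Saturday).
#' @param child_true Codes of the child-under-18 column meaning TRUE.
#' @return An `extract_dialect`.
#' @export
extract_dialect <- function(
    episode_cols = c(diary_id = "CASEID", activity_code = "ACTIVITY",
                     start = "START", duration = "DURATION"),
    person_cols = c(diary_id = "CASEID", weight = "WT06", sex = "SEX",
                    day = "DAY", marital = "MARST", child = "KIDUND18",
                    state = "STATEFIP"),
    delim = ",",
    time_format = c("offset", "clock"),
    sex_map = c("1" = "male", "2" = "female", "9" = "unknown"),
    day_map = c("1" = "weekend", "2" = "weekday", "3" = "weekday",
                "4" = "weekday", "5" = "weekday", "6" = "weekday",
                "7" = "weekend"),
    child_true = c("1", "TRUE", "true", "yes")) {
  time_format <- match.arg(time_format)
  need_e <- c("diary_id", "activity_code", "start", "duration")
  need_p <- c("diary_id", "weight", "sex", "day", "marital", "child",
              "state")
  if (!all(need_e %in% names(episode_cols)))
    stop("episode_cols must name roles: ", paste(need_e, collapse = ", "))
  if (!all(need_p %in% names(person_cols)))
    stop("person_cols must name roles: ", paste(need_p, collapse = ", "))
  structure(
    list(episode_cols = episode_cols, person_cols = person_cols,
         delim = delim, time_format = time_format, sex_map = sex_map,
         day_map = day_map, child_true = child_true),
    class = "extract_dialect"
  )
}

# "04:00:00" / "4:00" -> 1-based minutes from 4:00 am
clock_to_offset <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) < 2L || anyNA(suppressWarnings(as.integer(p))))
      stop("malformed clock time: ", paste(p, collapse = ":"))
    mins <- as.integer(p[1]) * 60L + as.integer(p[2])   # from midnight
    ((mins - 240L) %% 1440L) + 1L
  }, integer(1))
}

#' Read an episode/person extract into diaries
#'
#' Joins the episode file to the person file on the diary id and builds
#' one [new_diary()] per person, episodes attached in start order, clock
#' times converted to minutes from 4:00 am and coded covariates mapped
#' through the dialect's value dictionaries. Episodes without a person
#' record, or persons without episodes, are an error naming the ids.
#'
#' @param episode_path,person_path Paths to the two delimited files.
#' @param dialect An [extract_dialect()].
#' @return List of `diary` objects in person-file order.
#' @export
read_extract <- function(episode_path, person_path,
                         dialect = extract_dialect()) {
  stopifnot(inherits(dialect, "extract_dialect"))
  ep <- utils::read.table(episode_path, sep = dialect$delim, header = TRUE,
                          colClasses = "character", strip.white = TRUE,
                          check.names = FALSE)
  pe <- utils::read.table(person_path, sep = dialect$delim, header = TRUE,
                          colClasses = "character", strip.white = TRUE,
                          check.names = FALSE)
  ec <- dialect$episode_cols; pc <- dialect$person_cols
  miss_e <- setdiff(unname(ec), names(ep))
  miss_p <- setdiff(unname(pc), names(pe))
  if (length(miss_e))
    stop("episode file lacks column(s): ", paste(miss_e, collapse = ", "))
  if (length(miss_p))
    stop("person file lacks column(s): ", paste(miss_p, collapse = ", "))
  e_id <- ep[[ec["diary_id"]]]; p_id <- pe[[pc["diary_id"]]]
  orphans <- setdiff(unique(e_id), p_id)
  if (length(orphans))
    stop("episode record(s) without person record: ",
         paste(orphans, collapse = ", "))
  childless <- setdiff(p_id, unique(e_id))
  if (length(childless))
    stop("person record(s) without episodes: ",
         paste(childless, collapse = ", "))
  starts <- if (dialect$time_format == "clock")
    clock_to_offset(ep[[ec["start"]]])
  else {
    s <- suppressWarnings(as.integer(ep[[ec["start"]]]))
    if (anyNA(s)) stop("malformed start offset(s) in episode file")
    s
  }
  durs <- suppressWarnings(as.integer(ep[[ec["duration"]]]))
  if (anyNA(durs)) stop("malformed duration(s) in episode file")
  lapply(seq_len(nrow(pe)), function(j) {
    id <- p_id[j]
    rows <- which(e_id == id)
    rows <- rows[order(starts[rows])]
    sex <- dialect$sex_map[pe[[pc["sex"]]][j]]
    day <- dialect$day_map[pe[[pc["day"]]][j]]
    new_diary(
      diary_id = id,
      activity_code = ep[[ec["activity_code"]]][rows],
      start_min = starts[rows], duration_min = durs[rows],
      weight = as.numeric(pe[[pc["weight"]]][j]),
      sex = if (is.na(sex)) "unknown" else unname(sex),
      day_type = if (is.na(day)) "weekday" else unname(day),
      marital = pe[[pc["marital"]]][j],
      has_child_under_18 = pe[[pc["child"]]][j] %in% dialect$child_true,
      state = pe[[pc["state"]]][j]
    )
  })
}

#' Write a summary object as a delimited table
#'
#' Emits the numeric table behind each summary in a fixed layout: totals
#' as `category,percent` rows in category order; transition matrices
#' row-major with a header row and column of category labels; tempograms
#' with slot labels as the first column; state averages with state as the
#' first column.
#'
#' @param x A `totals_table`, `transition_matrix`, `tempogram` or
#'   `state_averages`.
#' @param path Output file path.
#' @param delim Field delimiter.
#' @return Invisibly, `path`.
#' @export
write_summary <- function(x, path, delim = ",") {
  df <- summary_as_data_frame(x)
  utils::write.table(df, path, sep = delim, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

summary_as_data_frame <- function(x) {
  if (inherits(x, "totals_table")) {
    data.frame(category = names(x), percent = as.numeric(x),
               stringsAsFactors = FALSE)
  } else if (inherits(x, "transition_matrix")) {
    m <- unclass(x); attr(m, "n_effective") <- NULL
    data.frame(from = rownames(m), as.data.frame(m, check.names = FALSE),
               check.names = FALSE, stringsAsFactors = FALSE)
  } else if (inherits(x, "tempogram")) {
    data.frame(slot = rownames(x),
               as.data.frame(unclass(x), check.names = FALSE),
               check.names = FALSE, stringsAsFactors = FALSE)
  } else if (inherits(x, "state_averages")) {
    data.frame(state = rownames(x$minutes), n = as.integer(x$n_diaries),
               as.data.frame(x$minutes, check.names = FALSE),
               check.names = FALSE, stringsAsFactors = FALSE)
  } else stop("unsupported summary object of class ",
              paste(class(x), collapse = "/"))
}
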