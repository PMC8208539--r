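#' The eleven top-level activity categories
#'
#' Returns the fixed, ordered set of top-level activity categories used
#' throughout the package: sleep, personal care, housework, childcare,
#' adult care, work, shopping, TV watching, eating, leisure, and travel.
#' This order fixes the row/column order of every matrix and table the
#' package produces.
#'
#' @return Character vector of length 11.
#' @export
#' @examples
#' activity_categories()
activity_categories <- function() {
  c("sleep", "personal_care", "housework", "childcare", "adult_care",
    "work", "shopping", "tv", "eating", "leisure", "travel")
}

#' Construct an activity crosswalk
#'
#' An activity crosswalk is a total mapping from detailed activity codes
#' (2-, 4- or 6-digit ATUS-lexicon-style strings) to the eleven top-level
#' categories, realised as a longest-prefix-match table: a code matches the
#' entry whose pattern is the longest prefix of the code.
#'
#' @param patterns Character vector of digit-string prefixes (2-6 digits).
#' @param categories Character vector of category labels, one per pattern;
#'   each must be one of [activity_categories()].
#' @param name Version label for the crosswalk.
#' @return An object of class `activity_crosswalk`.
#' @export
new_crosswalk <- function(patterns, categories, name = "custom") {
  patterns <- as.character(patterns)
  categories <- as.character(categories)
  if (length(patterns) == 0L)
    stop("crosswalk must have at least one entry")
  if (length(patterns) != length(categories))
    stop("patterns and categories must have equal length")
  if (anyDuplicated(patterns))
    stop("duplicate crosswalk pattern(s): ",
         paste(unique(patterns[duplicated(patterns)]), collapse = ", "))
  bad <- setdiff(categories, activity_categories())
  if (length(bad))
    stop("unknown activity category label(s): ", paste(bad, collapse = ", "))
  if (!all(grepl("^[0-9]{2,6}$", patterns)))
    stop("crosswalk patterns must be 2-6 digit strings")
  structure(
    list(patterns = patterns, categories = categories, name = name),
    class = "activity_crosswalk"
  )
}

#' @export
print.activity_crosswalk <- function(x, ...) {
  cat("<activity_crosswalk>", x$name, "-", length(x$patterns),
      "entries covering", length(unique(x$categories)), "categories\n")
  invisible(x)
}

#' Map a detailed activity code to its top-level category
#'
#' Resolves `code` against the crosswalk by longest-prefix match: among all
#' entries whose pattern is a prefix of `code`, the longest wins. Patterns
#' are unique, so the result is deterministic.
#'
#' @param code Character vector of 2-6 digit activity codes.
#' @param xw An `activity_crosswalk`.
#' @param fallback Optional category returned for codes with no matching
#'   prefix; by default unmatched codes are an error (condition class
#'   `diaryviz_unknown_code`, carrying the offending codes in `$codes`).
#' @return Character vector of category labels, same length as `code`.
#' @export
#' @examples
#' xw <- new_crosswalk(c("0101", "01"), c("sleep", "personal_care"))
#' map_code("010101", xw)  # "sleep": longest prefix wins
map_code <- function(code, xw, fallback = NULL) {
  stopifnot(inherits(xw, "activity_crosswalk"))
  code <- as.character(code)
  out <- character(length(code))
  for (i in seq_along(code)) {
    hits <- startsWith(code[i], xw$patterns)
    if (any(hits)) {
      lens <- nchar(xw$patterns[hits])
      out[i] <- xw$categories[hits][which.max(lens)]
    } else if (!is.null(fallback)) {
      out[i] <- match.arg(fallback, activity_categories())
    } else {
      stop(structure(
        class = c("diaryviz_unknown_code", "error", "condition"),
        list(message = paste0("activity code(s) not in crosswalk: ", code[i]),
             call = sys.call(-1), codes = code[i])))
    }
  }
  out
}

#' Load an activity crosswalk from a delimited file
#'
#' The file has two columns, `pattern` and `category` (header optional,
#' comma- or tab-delimited); lines starting with `#` are comments.
#' Categories must be among the eleven of [activity_categories()] and
#' patterns must be unique.
#'
#' @param path Path to the crosswalk file, or `NULL` (default) for the
#'   crosswalk bundled with the package.
#' @return An `activity_crosswalk`.
#' @export
load_crosswalk <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "crosswalk_default.csv",
                        package = "diaryviz", mustWork = TRUE)
    name <- "default"
  } else {
    name <- basename(path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("crosswalk file is empty: ", path)
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  tab <- utils::read.table(text = lines, sep = sep, header = FALSE,
                           colClasses = "character", strip.white = TRUE)
  if (ncol(tab) != 2L)
    stop("crosswalk file must have exactly two columns (pattern, category)")
  if (tolower(tab[1, 1]) == "pattern") tab <- tab[-1, , drop = FALSE]
  if (nrow(tab) == 0L) stop("crosswalk file has no entries: ", path)
  new_crosswalk(tab[[1]], tab[[2]], name = name)
}
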