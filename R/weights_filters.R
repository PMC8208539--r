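#' Normalize survey weights to sum to one
#'
#' Each selected subsample carries its raw survey weights; before any
#' weighted summary they are normalized, `w_j / sum(w)`, so the weights of
#' the analyzed diaries sum to exactly 1. Normalization is scale-invariant.
#'
#' @param weights Positive numeric vector.
#' @return Numeric vector of the same length summing to 1.
#' @export
#' @examples
#' normalize_weights(c(1, 3))  # 0.25 0.75
normalize_weights <- function(weights) {
  if (length(weights) == 0L) stop("no weights supplied")
  if (!is.numeric(weights) || any(!is.finite(weights)) || any(weights <= 0))
    stop("all weights must be positive finite numbers")
  weights / sum(weights)
}

#' Subgroup filter criteria
#'
#' Unset (`NULL`) fields match every diary; set fields match by equality.
#'
#' @param sex,day_type,marital,state Optional labels to match.
#' @param has_child_under_18 Optional logical to match.
#' @return A `filter_criteria` object.
#' @export
filter_criteria <- function(sex = NULL, day_type = NULL, marital = NULL,
                            has_child_under_18 = NULL, state = NULL) {
  if (!is.null(sex)) sex <- match.arg(sex, c("female", "male", "unknown"))
  if (!is.null(day_type)) day_type <- match.arg(day_type,
                                                c("weekday", "weekend"))
  structure(list(sex = sex, day_type = day_type, marital = marital,
                 has_child_under_18 = has_child_under_18, state = state),
            class = "filter_criteria")
}

#' Filter diaries by subgroup criteria
#'
#' Keeps, in original order, the diaries matching every set field of the
#' criteria (gender, weekday/weekend, marital status, parental status,
#' state). An empty result is legal and raises a warning; weights are
#' re-normalized downstream for each selected subsample.
#'
#' @param diaries List of `diary` objects.
#' @param criteria A `filter_criteria` (or arguments passed to it).
#' @return Order-preserving subset of `diaries`.
#' @export
filter_diaries <- function(diaries, criteria = filter_criteria()) {
  stopifnot(inherits(criteria, "filter_criteria"))
  keep <- vapply(diaries, function(d) {
    (is.null(criteria$sex) || d$sex == criteria$sex) &&
      (is.null(criteria$day_type) || d$day_type == criteria$day_type) &&
      (is.null(criteria$marital) || d$marital == criteria$marital) &&
      (is.null(criteria$has_child_under_18) ||
         d$has_child_under_18 == criteria$has_child_under_18) &&
      (is.null(criteria$state) || d$state == criteria$state)
  }, logical(1))
  out <- diaries[keep]
  if (length(out) == 0L) warning("no diaries match the filter criteria")
  out
}

#' Seeded random subsample of diaries for display
#'
#' Draws a simple random sample without replacement of
#' `min(n, length(diaries))` diaries. The seed is an explicit argument so
#' the same seed and input always yield the same subset (figures built on
#' the subsample are reproducible); the sample is uniform and unweighted -
#' the survey weights ride along untouched and are re-normalized by the
#' statistics, so weighting the draw would double-count them. The caller's
#' RNG state is left undisturbed.
#'
#' @param diaries List of `diary` objects.
#' @param n Target sample size (default 800, the display sample size).
#' @param seed Integer seed (default 20210616).
#' @return Subset of `diaries` of size `min(n, length(diaries))`, in
#'   original relative order.
#' @export
subsample_diaries <- function(diaries, n = 800L, seed = 20210616L) {
  stopifnot(n >= 1L)
  N <- length(diaries)
  if (N <= n) return(diaries)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  idx <- sort(sample.int(N, size = n, replace = FALSE))
  diaries[idx]
}
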