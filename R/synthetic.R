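#' Representative detailed activity codes per category
#'
#' One detailed 6-digit code for each of the eleven categories, chosen so
#' the default crosswalk resolves each to its category; the simulator
#' emits these so the crosswalk stage is exercised, never bypassed.
#'
#' @return Named character vector (names are the categories).
#' @export
representative_codes <- function() {
  c(sleep = "010101", personal_care = "010201", housework = "020101",
    childcare = "030101", adult_care = "030401", work = "050101",
    shopping = "070101", tv = "120303", eating = "110101",
    leisure = "120101", travel = "180101")
}

#' Define a diary simulation profile
#'
#' The simulator generates diaries as a semi-Markov process on the eleven
#' activity categories: at 4:00 am a category is drawn from
#' `initial_probs`; the spell's duration is geometric in fifteen-minute
#' units (support 15, 30, 45, ... minutes) with the category's mean; at
#' each spell end the next (different) category is drawn from the
#' corresponding row of `transition_probs`; the final spell is truncated
#' at the 4:00 am boundary, mimicking real capping. Geometric durations on
#' the fifteen-minute grid make the slot-level sequence exactly
#' first-order Markov, so transition recovery is analytic. Covariates and
#' log-normal weights are drawn independently.
#'
#' @param initial_probs Length-11 probability vector over categories at
#'   4:00 am (default: everyone asleep).
#' @param transition_probs 11 x 11 row-stochastic matrix with zero
#'   diagonal; rows of categories with zero probability of occurring may
#'   be left uniform.
#' @param mean_duration Length-11 positive vector of mean spell durations
#'   in minutes (each >= 15).
#' @param p_female,p_weekend,p_child Covariate marginals.
#' @param marital_levels,marital_probs Marital categories and marginals.
#' @param states,state_probs State labels and marginals.
#' @param weight_meanlog,weight_sdlog Log-normal weight parameters
#'   (`sdlog = 0` gives constant weights).
#' @return A `simulation_profile`.
#' @export
simulation_profile <- function(initial_probs = NULL, transition_probs = NULL,
                               mean_duration = NULL,
                               p_female = 0.5, p_weekend = 2 / 7,
                               p_child = 0.4,
                               marital_levels = c("married", "not_married"),
                               marital_probs = c(0.55, 0.45),
                               states = c("CA", "TX", "NY", "FL", "MN"),
                               state_probs = rep(0.2, 5),
                               weight_meanlog = 0, weight_sdlog = 0.5) {
  cats <- activity_categories()
  k <- length(cats)
  if (is.null(initial_probs)) {
    initial_probs <- c(sleep = 1, setNames(rep(0, k - 1L), cats[-1]))
  }
  if (is.null(transition_probs)) {
    transition_probs <- matrix(1 / (k - 1L), k, k,
                               dimnames = list(cats, cats))
    diag(transition_probs) <- 0
  }
  if (is.null(mean_duration))
    mean_duration <- setNames(rep(60, k), cats)
  initial_probs <- setNames(as.numeric(initial_probs), cats)
  mean_duration <- setNames(as.numeric(mean_duration), cats)
  if (abs(sum(initial_probs) - 1) > 1e-9 || any(initial_probs < 0))
    stop("initial_probs must be a probability vector over the 11 categories")
  if (!all(dim(transition_probs) == c(k, k)))
    stop("transition_probs must be 11 x 11")
  if (any(diag(transition_probs) != 0))
    stop("transition_probs must have a zero diagonal")
  if (any(transition_probs < 0) ||
      any(abs(rowSums(transition_probs) - 1) > 1e-9))
    stop("rows of transition_probs must sum to 1")
  if (any(mean_duration < 15))
    stop("mean durations must be at least 15 minutes")
  if (abs(sum(marital_probs) - 1) > 1e-9 || abs(sum(state_probs) - 1) > 1e-9)
    stop("marital_probs and state_probs must sum to 1")
  dimnames(transition_probs) <- list(cats, cats)
  structure(
    list(initial_probs = initial_probs, transition_probs = transition_probs,
         mean_duration = mean_duration, p_female = p_female,
         p_weekend = p_weekend, p_child = p_child,
         marital_levels = marital_levels, marital_probs = marital_probs,
         states = states, state_probs = state_probs,
         weight_meanlog = weight_meanlog, weight_sdlog = weight_sdlog),
    class = "simulation_profile"
  )
}

#' Simulate ATUS-like diaries from a profile
#'
#' Generates `n` fully synthetic respondent-days under the semi-Markov
#' model of [simulation_profile()]: contiguous episodes from minute 1,
#' detailed 6-digit activity codes (one representative per category),
#' exact 1440-minute coverage via boundary truncation, independent
#' covariates and weights. Byte-reproducible from the seed; the caller's
#' RNG state is left undisturbed.
#'
#' @param profile A `simulation_profile`.
#' @param n Number of diaries.
#' @param seed Integer seed.
#' @return List of `n` `diary` objects with ids `"sim00001"`, ...
#' @export
#' @examples
#' prof <- simulation_profile()
#' d <- simulate_diaries(prof, n = 3, seed = 1)
#' validate_diary(d[[1]])$is_valid
simulate_diaries <- function(profile, n = 100L, seed = 20210616L) {
  stopifnot(inherits(profile, "simulation_profile"), n >= 1L)
  cats <- activity_categories()
  codes <- representative_codes()
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  # geometric spell length in 15-min units: K >= 1, P(K = k) = p (1-p)^(k-1),
  # mean K = 1/p, so p = 15 / mean_duration
  p_geo <- pmin(1, 15 / profile$mean_duration)
  out <- vector("list", n)
  for (j in seq_len(n)) {
    cur <- sample.int(11L, 1L, prob = profile$initial_probs)
    start <- 1L
    acts <- integer(0); starts <- integer(0); durs <- integer(0)
    while (start <= 1440L) {
      dur <- 15L * (1L + stats::rgeom(1L, p_geo[cur]))
      if (start + dur > 1441L) dur <- 1441L - start   # truncate at 4:00 am
      acts <- c(acts, cur); starts <- c(starts, start); durs <- c(durs, dur)
      start <- start + dur
      if (start > 1440L) break
      cur <- sample.int(11L, 1L, prob = profile$transition_probs[cur, ])
    }
    out[[j]] <- new_diary(
      diary_id = sprintf("sim%05d", j),
      activity_code = unname(codes[cats[acts]]),
      start_min = starts, duration_min = durs,
      weight = stats::rlnorm(1, profile$weight_meanlog, profile$weight_sdlog),
      sex = if (stats::runif(1) < profile$p_female) "female" else "male",
      day_type = if (stats::runif(1) < profile$p_weekend) "weekend"
                 else "weekday",
      marital = sample(profile$marital_levels, 1L,
                       prob = profile$marital_probs),
      has_child_under_18 = stats::runif(1) < profile$p_child,
      state = sample(profile$states, 1L, prob = profile$state_probs)
    )
  }
  out
}

#' Write diaries as an episode/person fixture pair
#'
#' Writes the two delimited files of the default ingest dialect: an
#' episode file (one row per episode) and a person file (one row per
#' diary). The pair round-trips losslessly through [read_extract()].
#'
#' @param diaries Non-empty list of `diary` objects.
#' @param episode_path,person_path Output file paths.
#' @param dialect An `extract_dialect` (default dialect by default).
#' @return Invisibly, `c(episode_path, person_path)`.
#' @export
write_fixture <- function(diaries, episode_path, person_path,
                          dialect = extract_dialect()) {
  if (inherits(diaries, "diary")) diaries <- list(diaries)
  if (length(diaries) == 0L) stop("no diaries to write")
  ec <- dialect$episode_cols; pc <- dialect$person_cols
  ep <- do.call(rbind, lapply(diaries, function(d) {
    data.frame(id = d$diary_id, code = d$episodes$activity_code,
               start = d$episodes$start_min, dur = d$episodes$duration_min,
               stringsAsFactors = FALSE)
  }))
  names(ep) <- c(ec["diary_id"], ec["activity_code"], ec["start"],
                 ec["duration"])
  pers <- do.call(rbind, lapply(diaries, function(d) {
    sex_code <- names(dialect$sex_map)[match(d$sex, dialect$sex_map)]
    day_code <- names(dialect$day_map)[match(d$day_type, dialect$day_map)]
    data.frame(id = d$diary_id, wt = d$weight,
               sex = sex_code, day = day_code,
               marital = d$marital,
               kid = as.integer(d$has_child_under_18), state = d$state,
               stringsAsFactors = FALSE)
  }))
  names(pers) <- c(pc["diary_id"], pc["weight"], pc["sex"], pc["day"],
                   pc["marital"], pc["child"], pc["state"])
  utils::write.table(ep, episode_path, sep = dialect$delim,
                     row.names = FALSE, quote = FALSE)
  utils::write.table(pers, person_path, sep = dialect$delim,
                     row.names = FALSE, quote = FALSE)
  invisible(c(episode_path, person_path))
}
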