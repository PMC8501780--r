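# Dependency indicators: ADR, LFDR, PWLFDR, normalized trajectories, and
# pyramid summaries.

#' Age dependency ratio
#'
#' (weighted population under 15 + weighted population 65 and over) divided
#' by the weighted population aged 15-64.
#'
#' @param frame a [population_frame()].
#' @return nonnegative ratio.
#' @export
adr <- function(frame) {
  young <- frame$age < 15
  old <- frame$age >= 65
  denom <- sum(frame$weight[!young & !old])
  if (denom <= 0) stop("ADR undefined: no weighted population aged 15-64")
  sum(frame$weight[young | old]) / denom
}

# Weighted inactive total: the population out of the labor force
# irrespective of age, so children (not_applicable) count as inactive.
inactive_total <- function(frame) sum(frame$weight[frame$activity != "active"])

#' Labor force dependency ratio
#'
#' Weighted inactive population of all ages (children count as inactive)
#' divided by the weighted active population.
#'
#' @param frame a [population_frame()].
#' @return nonnegative ratio.
#' @export
lfdr <- function(frame) {
  act <- sum(frame$weight[frame$activity == "active"])
  if (act <= 0) stop("LFDR undefined: no weighted active population")
  inactive_total(frame) / act
}

#' Productivity-weighted labor force dependency ratio
#'
#' Divides the weighted inactive population (all ages) by the active
#' population weighted by the productivity factor of its education level:
#' PWLFDR = I / sum_e(W_e x A_e). A ratio of 1 means one inactive person per
#' productivity equivalent of a reference-level (upper secondary) worker.
#' Under unit weights this reduces exactly to [lfdr()].
#'
#' @param frame a [population_frame()].
#' @param weights a [derive_productivity_weights()] vector (named by
#'   education level).
#' @return nonnegative ratio.
#' @export
pwlfdr <- function(frame, weights) {
  act <- frame$activity == "active"
  if (!any(act)) stop("PWLFDR undefined: no active population")
  w_e <- weights[frame$education[act]]
  if (anyNA(w_e))
    stop("no productivity weight for education level(s): ",
         paste(unique(frame$education[act][is.na(w_e)]), collapse = ", "))
  denom <- sum(frame$weight[act] * w_e)
  if (denom <= 0) stop("PWLFDR undefined: zero weighted denominator")
  inactive_total(frame) / denom
}

#' Indicator series along a projection
#'
#' @param projection a [run_projection()] result (or a named list of frames).
#' @param weights productivity weights for the PWLFDR.
#' @return data.frame with columns `period`, `adr`, `lfdr`, `pwlfdr`.
#' @export
indicator_series <- function(projection, weights) {
  frames <- if (inherits(projection, "projection")) projection$frames
            else projection
  out <- data.frame(
    period = as.integer(names(frames)),
    adr = vapply(frames, adr, numeric(1)),
    lfdr = vapply(frames, lfdr, numeric(1)),
    pwlfdr = vapply(frames, function(f) pwlfdr(f, weights), numeric(1)),
    row.names = NULL
  )
  out
}

#' Normalize an indicator series to a base period
#'
#' Divides every indicator column by its own base-period value, so the base
#' period maps to exactly 1 and trajectories are comparable across
#' indicators and scenarios.
#'
#' @param series data.frame with a `period` column and numeric indicator
#'   columns.
#' @param base_period the period mapped to 1 (default: the earliest).
#' @return data.frame of the same shape with normalized indicator columns.
#' @export
normalize_series <- function(series, base_period = min(series$period)) {
  i <- match(base_period, series$period)
  if (is.na(i)) stop("base period ", base_period, " is not in the series")
  for (col in setdiff(names(series), "period")) {
    b <- series[[col]][i]
    if (!is.finite(b) || b <= 0)
      stop("cannot normalize '", col, "': nonpositive base-period value")
    series[[col]] <- series[[col]] / b
  }
  series
}

#' Age pyramid summary by education tier and activity
#'
#' Weighted counts by age band x sex x education tier (low = lower than
#' secondary, medium = upper secondary, high = postsecondary; children are
#' `not_applied`) x activity.
#'
#' @param frame a [population_frame()].
#' @param ladder the education ladder (defaults to the frame's).
#' @return data.frame with columns `age`, `sex`, `tier`, `activity`,
#'   `weight`; its weight column sums to the frame total.
#' @export
pyramid_summary <- function(frame, ladder = frame_ladder(frame)) {
  if (!nrow(frame))
    return(data.frame(age = integer(), sex = character(), tier = character(),
                      activity = character(), weight = numeric()))
  d <- data.frame(age = frame$age, sex = frame$sex,
                  tier = edu_tier(frame$education, ladder),
                  activity = frame$activity, weight = frame$weight,
                  stringsAsFactors = FALSE)
  out <- aggregate(weight ~ age + sex + tier + activity, d, sum)
  out[order(out$age, out$sex, out$tier, out$activity), , drop = FALSE]
}

#' Weighted active population by education tier over a projection
#'
#' Tracks how cohort replacement reshapes the labor force: per period, the
#' weighted active population in each education tier. Tier totals match the
#' LFDR denominator of the same frame.
#'
#' @param projection a [run_projection()] result (or named list of frames).
#' @param ladder the education ladder.
#' @return data.frame with columns `period`, `tier`, `active`.
#' @export
active_counts_by_education <- function(projection,
                                       ladder = education_ladder()) {
  frames <- if (inherits(projection, "projection")) projection$frames
            else projection
  if (!length(frames)) stop("empty trajectory")
  rows <- lapply(names(frames), function(p) {
    f <- frames[[p]]
    act <- f[f$activity == "active", , drop = FALSE]
    if (!nrow(act))
      return(data.frame(period = as.integer(p), tier = character(),
                        active = numeric()))
    d <- data.frame(tier = edu_tier(act$education, ladder),
                    active = act$weight)
    s <- aggregate(active ~ tier, d, sum)
    data.frame(period = as.integer(p), tier = s$tier, active = s$active)
  })
  do.call(rbind, rows)
}
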