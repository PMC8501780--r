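# Rate schedules: the period-indexed demographic assumption tables.

SCHEDULE_NAMES <- c("survival_ratios", "education_entry", "education_transitions",
                    "fertility_schedule", "emigration_rates",
                    "immigration_profile", "newborn_survival")

#' Bundle the demographic assumption tables
#'
#' Collects the period-indexed schedules driving the projection. Expected
#' columns (all `period` keys are the year at the start of the 5-year step):
#' \describe{
#'   \item{survival_ratios}{`period, age, sex, education, ratio` — 5-year
#'     survivorship in (0, 1]; rows for ages under 15 carry NA education.}
#'   \item{education_entry}{`period, sex, level, share` — the attainment
#'     distribution assigned when a cohort is broken down on reaching 15-19;
#'     shares sum to 1 per period and sex.}
#'   \item{education_transitions}{`period, age, sex, from_level, prob` —
#'     probability of advancing one ladder rung during the step, applied at
#'     ages 15-19 through 25-29 so attainment is final at 30-34.}
#'   \item{fertility_schedule}{`period, age, share` — the age shape of
#'     fertility, normalized so that 5 x sum(share) = 1; the age-specific
#'     fertility rate is TFR x share.}
#'   \item{emigration_rates}{`period, age, sex, rate` — probability of
#'     leaving the country during the step.}
#'   \item{immigration_profile}{`period, age, sex, education, count` —
#'     immigrant person counts added during the step.}
#'   \item{newborn_survival}{`period, sex, ratio` — survivorship of newborns
#'     over the partial period from birth to the end of the step.}
#' }
#'
#' @param survival_ratios,education_entry,education_transitions,fertility_schedule,emigration_rates,immigration_profile,newborn_survival
#'   data.frames as described above.
#' @return object of class `rate_schedules`.
#' @export
rate_schedules <- function(survival_ratios, education_entry,
                           education_transitions, fertility_schedule,
                           emigration_rates, immigration_profile,
                           newborn_survival) {
  s <- structure(list(survival_ratios = survival_ratios,
                      education_entry = education_entry,
                      education_transitions = education_transitions,
                      fertility_schedule = fertility_schedule,
                      emigration_rates = emigration_rates,
                      immigration_profile = immigration_profile,
                      newborn_survival = newborn_survival),
                 class = "rate_schedules")
  s
}

#' Validate schedule coverage and ranges for a scenario
#'
#' Checks, before any simulation starts, that every schedule covers every
#' step period of the scenario, that all probabilities are inside [0, 1]
#' (survival ratios inside (0, 1]), that the fertility shape is normalized
#' (5 x sum of shares = 1 per period), and that entry shares sum to 1.
#'
#' @param schedules a [rate_schedules()].
#' @param cfg a [scenario_config()].
#' @return invisibly TRUE; raises an error describing every gap found.
#' @export
validate_schedules <- function(schedules, cfg) {
  steps <- step_periods(cfg)
  probs <- character()
  need_periods <- function(df, what) {
    missing <- setdiff(steps, unique(df$period))
    if (length(missing))
      probs <<- c(probs, sprintf("%s lacks period(s) %s", what,
                                 paste(missing, collapse = ", ")))
  }
  sr <- schedules$survival_ratios
  need_periods(sr, "survival_ratios")
  if (any(sr$ratio <= 0 | sr$ratio > 1))
    probs <- c(probs, "survival ratios must lie in (0, 1]")

  ee <- schedules$education_entry
  need_periods(ee, "education_entry")
  sums <- aggregate(share ~ period + sex, ee, sum)
  if (any(abs(sums$share - 1) > 1e-8))
    probs <- c(probs, "education entry shares must sum to 1 per period and sex")

  et <- schedules$education_transitions
  need_periods(et, "education_transitions")
  if (any(et$prob < 0 | et$prob > 1))
    probs <- c(probs, "education transition probabilities must lie in [0, 1]")

  fs <- schedules$fertility_schedule
  need_periods(fs, "fertility_schedule")
  fsum <- aggregate(share ~ period, fs, sum)
  if (any(abs(5 * fsum$share - 1) > 1e-8))
    probs <- c(probs, "fertility shape must satisfy 5 x sum(share) = 1 per period")

  er <- schedules$emigration_rates
  need_periods(er, "emigration_rates")
  if (any(er$rate < 0 | er$rate > 1))
    probs <- c(probs, "emigration rates must lie in [0, 1]")

  ip <- schedules$immigration_profile
  if (nrow(ip) && any(ip$count < 0))
    probs <- c(probs, "immigration counts must be nonnegative")

  ns <- schedules$newborn_survival
  need_periods(ns, "newborn_survival")
  if (any(ns$ratio < 0 | ns$ratio > 1))
    probs <- c(probs, "newborn survival ratios must lie in [0, 1]")

  if (length(probs))
    stop("schedule validation failed:\n  - ", paste(probs, collapse = "\n  - "))
  invisible(TRUE)
}

# Step periods of a scenario: the years t at which a t -> t+5 step starts.
step_periods <- function(cfg) {
  if (cfg$horizon == cfg$start) integer() else
    seq(cfg$start, cfg$horizon - 5L, by = 5L)
}

# -- keyed lookups -----------------------------------------------------------

sched_key <- function(...) do.call(paste, c(list(...), sep = "\r"))

# Look up `value_col` for each row of keys; error naming the first missing
# stratum unless a default is supplied.
sched_lookup <- function(df, keys, key_cols, value_col, what, default = NULL) {
  tab_keys <- do.call(sched_key, unname(df[key_cols]))
  idx <- match(keys, tab_keys)
  if (anyNA(idx)) {
    if (!is.null(default)) {
      out <- df[[value_col]][idx]
      out[is.na(idx)] <- default
      return(out)
    }
    miss <- keys[which(is.na(idx))[1L]]
    stop("no ", what, " defined for occupied stratum [",
         gsub("\r", ", ", miss), "]")
  }
  df[[value_col]][idx]
}
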