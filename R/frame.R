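# Population frame: weighted individual records at one point in time.

FRAME_COLS <- c("id", "age", "sex", "education", "activity", "weight", "origin")
SEXES <- c("male", "female")
ACTIVITIES <- c("active", "inactive", "not_applicable")
ORIGINS <- c("baseline", "birth", "immigrant")

#' Construct a population frame
#'
#' A population frame is a data.frame of weighted individual cases — the unit
#' of the Monte Carlo experiments — observed at one 5-year period. Columns:
#' `id` (stable individual identifier, keys the random streams), `age`
#' (lower bound of the 5-year band, 0 to 100 with 100 open-ended), `sex`
#' ("male"/"female"), `education` (ladder level, NA for ages 0-14 where the
#' education variable is not applied), `activity` ("active"/"inactive", or
#' "not_applicable" for children under 15), `weight` (persons represented by
#' the case, positive), `origin` ("baseline"/"birth"/"immigrant").
#'
#' @param df data.frame with the columns above.
#' @param period calendar year of the 5-year step (2015, 2020, ...).
#' @param ladder the [education_ladder()] the education column refers to.
#' @return object of class `population_frame` (a data.frame).
#' @export
population_frame <- function(df, period, ladder = education_ladder()) {
  missing_cols <- setdiff(FRAME_COLS, names(df))
  if (length(missing_cols))
    stop("population frame lacks columns: ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[FRAME_COLS]
  df$age <- as.integer(df$age)
  attr(df, "period") <- as.integer(period)
  attr(df, "ladder") <- ladder
  class(df) <- c("population_frame", "data.frame")
  df
}

frame_period <- function(frame) attr(frame, "period")
frame_ladder <- function(frame) attr(frame, "ladder") %||% education_ladder()

`%||%` <- function(a, b) if (is.null(a)) b else a

# Re-attach frame attributes after a data.frame operation stripped them.
as_frame <- function(df, like) population_frame(df, frame_period(like), frame_ladder(like))

#' Total weighted population of a frame
#' @param frame a [population_frame()].
#' @return numeric scalar.
#' @export
frame_total <- function(frame) sum(frame$weight)

#' Check every individual- and frame-level invariant
#'
#' Reports (rather than raises) violations: positive weights, valid sex /
#' activity / origin codes, education on the ladder, the child rules
#' (activity is `not_applicable` exactly for ages under 15, and the education
#' variable is not applied below 15), and age bands on the 5-year grid.
#'
#' @param frame a [population_frame()].
#' @param ladder the education ladder to validate against.
#' @return character vector of violation messages; empty iff the frame is valid.
#' @export
validate_frame <- function(frame, ladder = frame_ladder(frame)) {
  v <- character()
  add <- function(cond, msg) if (any(cond, na.rm = TRUE))
    c(v, sprintf("%s (%d case(s))", msg, sum(cond, na.rm = TRUE))) else v

  v <- add(!is.finite(frame$weight) | frame$weight <= 0,
           "weight must be positive and finite")
  v <- add(!frame$sex %in% SEXES, "sex must be 'male' or 'female'")
  v <- add(!frame$activity %in% ACTIVITIES, "invalid activity code")
  v <- add(!frame$origin %in% ORIGINS, "invalid origin code")
  v <- add(!frame$age %in% age_bands(), "age must be a 5-year band lower bound")

  child <- frame$age < AGE_MIN_ADULT
  v <- add(child & frame$activity != "not_applicable",
           "children under 15 must have activity 'not_applicable'")
  v <- add(!child & frame$activity == "not_applicable",
           "activity 'not_applicable' is reserved for children under 15")
  v <- add(child & !is.na(frame$education),
           "education is not applied below age 15")
  v <- add(!child & !frame$education %in% ladder$levels,
           "adult education must be a ladder level")
  if (anyDuplicated(frame$id))
    v <- c(v, "individual ids must be unique")
  v
}

#' Scenario configuration
#'
#' Bundles the knobs of one projection scenario: the constant total fertility
#' rate applied from the start period onwards, the projection window, the
#' seed of the counter-based random streams, and the case-generation
#' constants (sampling fraction, the subgroup size below which oversampling
#' applies, the oversampled case floor) plus the sex ratio at birth.
#'
#' @param tfr total fertility rate, children per woman (constant over the
#'   projection).
#' @param start base period (calendar year).
#' @param horizon final period; `horizon - start` must be a multiple of 5.
#' @param seed integer seed for all random streams.
#' @param sampling_fraction fraction of persons represented as cases
#'   (default 0.05%).
#' @param oversample_threshold subgroup population size below which the
#'   oversampling floor applies (default 10,000).
#' @param floor_cases number of cases generated for an oversampled subgroup.
#' @param sex_ratio_at_birth male births per female birth (default 1.05).
#' @param ladder the [education_ladder()].
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(tfr, start = 2015L, horizon = 2070L, seed = 1L,
                            sampling_fraction = 5e-4,
                            oversample_threshold = 10000,
                            floor_cases = 20L,
                            sex_ratio_at_birth = 1.05,
                            ladder = education_ladder()) {
  if (!is.numeric(tfr) || length(tfr) != 1L || tfr < 0)
    stop("tfr must be a single nonnegative number")
  if (horizon < start) stop("horizon must not precede start")
  if ((horizon - start) %% 5 != 0)
    stop("horizon - start must be a multiple of the 5-year step")
  if (sampling_fraction <= 0 || sampling_fraction > 1)
    stop("sampling_fraction must be in (0, 1]")
  if (floor_cases < 1) stop("floor_cases must be at least 1")
  if (sex_ratio_at_birth <= 0) stop("sex_ratio_at_birth must be positive")
  structure(list(tfr = tfr, start = as.integer(start),
                 horizon = as.integer(horizon), seed = as.integer(seed),
                 sampling_fraction = sampling_fraction,
                 oversample_threshold = oversample_threshold,
                 floor_cases = as.integer(floor_cases),
                 sex_ratio_at_birth = sex_ratio_at_birth,
                 ladder = ladder),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario: TFR %.2f, %d-%d, seed %d, sampling %.4f%%\n",
              x$tfr, x$start, x$horizon, x$seed, 100 * x$sampling_fraction))
  invisible(x)
}
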