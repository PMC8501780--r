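# Synthesis of the weighted starting case file from aggregate estimates,
# and generation of immigrant cases by the same statistical rules.

# Deterministic round-half-up; base R round() rounds half to even.
round_half_up <- function(x) floor(x + 0.5)

# Case count and per-case weight for one population cell. Cells at or above
# the oversampling threshold get round(count x fraction) cases (at least 1);
# smaller cells get a fixed floor of cases with proportionally reduced
# weights, which curbs the Monte Carlo error of small subgroups. Weights are
# count / cases, so the weighted total reproduces the cell exactly.
cell_cases <- function(count, cfg) {
  n <- ifelse(count >= cfg$oversample_threshold,
              pmax(1, round_half_up(count * cfg$sampling_fraction)),
              cfg$floor_cases)
  as.integer(n)
}

#' Build the weighted base population from aggregate estimates
#'
#' Expands an age x sex x education table of person counts into individual
#' cases. Each cell with `count >= oversample_threshold` yields
#' `round(count x sampling_fraction)` cases; smaller nonempty cells are
#' oversampled to `floor_cases` cases. Every case in a cell carries weight
#' `count / cases`, so weighted totals match the aggregates cell by cell
#' exactly. Children under 15 enter with no education level and activity
#' `not_applicable`; everyone else starts `inactive` until the labor-force
#' model assigns a status.
#'
#' @param est data.frame with columns `age` (band lower bound), `sex`,
#'   `education` (NA for under-15 cells), `count`.
#' @param cfg a [scenario_config()].
#' @return a [population_frame()] at `cfg$start`.
#' @export
build_base_population <- function(est, cfg) {
  est <- as.data.frame(est)
  need <- c("age", "sex", "education", "count")
  if (!all(need %in% names(est)))
    stop("estimates need columns: ", paste(need, collapse = ", "))
  if (!nrow(est) || sum(est$count) == 0)
    stop("estimates are empty")
  if (any(est$count < 0)) stop("estimates contain negative counts")
  bad_edu <- !is.na(est$education) & !est$education %in% cfg$ladder$levels
  if (any(bad_edu))
    stop("unknown education level(s) in estimates: ",
         paste(unique(est$education[bad_edu]), collapse = ", "))
  est <- est[est$count > 0, , drop = FALSE]

  n_cases <- cell_cases(est$count, cfg)
  idx <- rep.int(seq_len(nrow(est)), n_cases)
  df <- data.frame(
    id = seq_along(idx),
    age = est$age[idx],
    sex = est$sex[idx],
    education = est$education[idx],
    activity = ifelse(est$age[idx] < AGE_MIN_ADULT, "not_applicable", "inactive"),
    weight = (est$count / n_cases)[idx],
    origin = "baseline",
    stringsAsFactors = FALSE
  )
  population_frame(df, cfg$start, cfg$ladder)
}

#' Generate immigrant cases for one period's profile
#'
#' Immigrant cases follow the same statistical rules as the base population:
#' per profile cell, the case count comes from the sampling fraction with the
#' oversampling floor for small cells, and weights conserve the cell count
#' exactly. Origin is `immigrant`; activity is assigned later by the
#' labor-force step like everyone else's.
#'
#' @param profile data.frame with columns `age`, `sex`, `education`, `count`
#'   (one period's slice of the immigration profile).
#' @param cfg a [scenario_config()].
#' @return data.frame of case rows (no ids; the engine assigns stable ids).
#' @export
make_immigrant_cases <- function(profile, cfg) {
  cols <- c("age", "sex", "education", "count")
  empty <- data.frame(age = integer(), sex = character(),
                      education = character(), activity = character(),
                      weight = numeric(), origin = character(),
                      stringsAsFactors = FALSE)
  if (is.null(profile) || !nrow(profile)) return(empty)
  if (!all(cols %in% names(profile)))
    stop("immigration profile needs columns: ", paste(cols, collapse = ", "))
  bad <- !is.na(profile$education) & !profile$education %in% cfg$ladder$levels
  if (any(bad))
    stop("unknown education level(s) in immigration profile: ",
         paste(unique(profile$education[bad]), collapse = ", "))
  profile <- profile[profile$count > 0, , drop = FALSE]
  if (!nrow(profile)) return(empty)

  n_cases <- cell_cases(profile$count, cfg)
  idx <- rep.int(seq_len(nrow(profile)), n_cases)
  data.frame(
    age = profile$age[idx],
    sex = profile$sex[idx],
    education = profile$education[idx],
    activity = ifelse(profile$age[idx] < AGE_MIN_ADULT,
                      "not_applicable", "inactive"),
    weight = (profile$count / n_cases)[idx],
    origin = "immigrant",
    stringsAsFactors = FALSE
  )
}
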