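# Discrete-time stochastic projection engine. Each 5-year step applies, in
# order: 1) mortality, 2) education transitions, 3) emigration (survivors
# only), 4) immigration, 5) fertility, 6) labor-force assignment, then the
# age increment. Every Monte Carlo transition compares its probability with
# a uniform draw from the counter stream keyed by (individual, event,
# period), so runs sharing a seed give common individuals identical
# outcomes across scenarios.

# id blocks: baseline cases take 1..N; immigrants and newborns get ids
# derived deterministically from the step index so that the same profile
# yields the same ids in every scenario.
IMMIGRANT_ID_BASE <- 1e9
NEWBORN_ID_BASE <- 2e9
ID_BLOCK <- 1e7

step_index <- function(period, cfg) (period - cfg$start) %/% 5L

#' Apply mortality over one 5-year step
#'
#' Each case survives with its stratum's survival ratio (by period, age,
#' sex, education) via the Monte Carlo rule: survive iff the ratio exceeds a
#' fresh uniform draw. Non-survivors are removed; deaths are tallied by
#' weight.
#'
#' @param frame a [population_frame()] at the step's start period.
#' @param schedules a [rate_schedules()].
#' @param cfg a [scenario_config()].
#' @return list with `frame` (survivors) and `deaths` (weighted).
#' @export
step_mortality <- function(frame, schedules, cfg) {
  period <- frame_period(frame)
  if (!nrow(frame)) return(list(frame = frame, deaths = 0))
  sr <- schedules$survival_ratios
  ratio <- sched_lookup(sr,
                        sched_key(period, frame$age, frame$sex, frame$education),
                        c("period", "age", "sex", "education"),
                        "ratio", "survival ratio")
  u <- event_uniform(cfg$seed, frame$id, "mortality", period)
  survive <- u < ratio
  list(frame = as_frame(frame[survive, , drop = FALSE], frame),
       deaths = sum(frame$weight[!survive]))
}

# Assign an initial attained level from the entry distribution to the given
# rows (draw keyed by the entry event at `period`).
assign_entry_education <- function(frame, rows, schedules, cfg, period) {
  if (!any(rows)) return(frame)
  ee <- schedules$education_entry
  ee <- ee[ee$period == period, , drop = FALSE]
  if (!nrow(ee)) stop("no education entry distribution for period ", period)
  u <- event_uniform(cfg$seed, frame$id[rows], "education_entry", period)
  lv <- frame$education[rows]
  for (s in unique(frame$sex[rows])) {
    es <- ee[ee$sex == s, , drop = FALSE]
    cum <- cumsum(es$share) / sum(es$share)
    i <- frame$sex[rows] == s
    lv[i] <- es$level[findInterval(u[i], cum) + 1L]
  }
  frame$education[rows] <- lv
  frame
}

#' Apply education transitions over one 5-year step
#'
#' Cohorts reaching 15-19 at the end of the step (currently 10-14) are
#' broken down by the period's entry distribution of attained levels.
#' Cases currently aged 15-19 through 25-29 may advance one ladder rung with
#' the transition probability of their (period, age, sex, current level)
#' stratum — never move down — so attainment is final on reaching 30-34.
#' Below 15 the education variable is not applied.
#'
#' @inheritParams step_mortality
#' @return the updated frame.
#' @export
step_education <- function(frame, schedules, cfg) {
  period <- frame_period(frame)
  ladder <- frame_ladder(frame)

  entering <- frame$age == 10L |
    (frame$age == AGE_MIN_ADULT & is.na(frame$education))
  frame <- assign_entry_education(frame, entering, schedules, cfg, period)

  et <- schedules$education_transitions
  rank <- edu_rank(frame$education, ladder)
  movable <- frame$age >= AGE_MIN_ADULT & frame$age <= 25L &
    !is.na(rank) & rank < length(ladder$levels) & !entering
  if (any(movable)) {
    prob <- sched_lookup(et,
                         sched_key(period, frame$age[movable],
                                   frame$sex[movable], frame$education[movable]),
                         c("period", "age", "sex", "from_level"),
                         "prob", "education transition", default = 0)
    if (any(prob < 0 | prob > 1))
      stop("education transition probabilities must lie in [0, 1]")
    u <- event_uniform(cfg$seed, frame$id[movable], "education_advance", period)
    up <- u < prob
    idx <- which(movable)[up]
    frame$education[idx] <- ladder$levels[rank[idx] + 1L]
  }
  frame
}

#' Apply emigration over one 5-year step
#'
#' Survivors of the mortality step are removed with the period's emigration
#' rate of their age x sex stratum (Bernoulli per case). Because the rates
#' are fixed but the standing population differs across fertility scenarios,
#' emigrant counts are scenario-dependent.
#'
#' @inheritParams step_mortality
#' @return list with `frame` (remaining) and `emigrants` (weighted).
#' @export
step_emigration <- function(frame, schedules, cfg) {
  period <- frame_period(frame)
  if (!nrow(frame)) return(list(frame = frame, emigrants = 0))
  er <- schedules$emigration_rates
  rate <- sched_lookup(er, sched_key(period, frame$age, frame$sex),
                       c("period", "age", "sex"), "rate", "emigration rate")
  u <- event_uniform(cfg$seed, frame$id, "emigration", period)
  leave <- u < rate
  list(frame = as_frame(frame[!leave, , drop = FALSE], frame),
       emigrants = sum(frame$weight[leave]))
}

#' Add the period's immigrant cases
#'
#' Immigrants, whose numbers and characteristics are set a priori in the
#' immigration profile, are generated by the same statistical rules as the
#' base population and appended with stable, scenario-invariant ids.
#'
#' @inheritParams step_mortality
#' @return list with `frame` and `immigrants` (weighted total added).
#' @export
step_immigration <- function(frame, schedules, cfg) {
  period <- frame_period(frame)
  ip <- schedules$immigration_profile
  prof <- ip[ip$period == period, , drop = FALSE]
  cases <- make_immigrant_cases(prof, cfg)
  if (!nrow(cases))
    return(list(frame = frame, immigrants = 0))
  cases$id <- IMMIGRANT_ID_BASE + step_index(period, cfg) * ID_BLOCK +
    seq_len(nrow(cases))
  out <- rbind(as.data.frame(frame), cases[FRAME_COLS])
  list(frame = as_frame(out, frame), immigrants = sum(cases$weight))
}

#' Generate births over one 5-year step
#'
#' For each woman of reproductive age, the number of births over the step is
#' Poisson with mean 5 x ASFR(age) = 5 x TFR x shape(age), drawn by
#' inverse-CDF from her keyed uniform so fertility draws stay individual-
#' specific. Each newborn inherits the mother's weight, receives a sex from
#' the sex ratio at birth, and survives the partial period to the end of the
#' step with the newborn survival ratio; survivors are appended at age 0-4
#' with activity `not_applicable` and origin `birth`.
#'
#' @inheritParams step_mortality
#' @return list with `frame` (newborns appended), `births` (weighted
#'   surviving), `births_total` (weighted including newborn deaths), and
#'   `newborn_ids` (ids appended this step, which the caller must exclude
#'   from the age increment).
#' @export
step_fertility <- function(frame, schedules, cfg) {
  period <- frame_period(frame)
  if (cfg$tfr < 0) stop("negative TFR")
  fs <- schedules$fertility_schedule
  fsp <- fs[fs$period == period, , drop = FALSE]
  if (abs(5 * sum(fsp$share) - 1) > 1e-8)
    stop("fertility shape is not normalized for period ", period)

  women <- frame$sex == "female" & frame$age %in% fsp$age
  res <- list(frame = frame, births = 0, births_total = 0,
              newborn_ids = numeric())
  if (!any(women) || cfg$tfr == 0) return(res)

  shape <- fsp$share[match(frame$age[women], fsp$age)]
  lambda <- 5 * cfg$tfr * shape
  u <- event_uniform(cfg$seed, frame$id[women], "fertility", period)
  nb <- qpois(u, lambda)
  if (!sum(nb)) return(res)

  midx <- which(women)[rep.int(seq_along(nb), nb)]
  birth_no <- sequence(nb[nb > 0])
  mother_id <- frame$id[midx]
  p_male <- cfg$sex_ratio_at_birth / (1 + cfg$sex_ratio_at_birth)
  us <- event_uniform(cfg$seed, mother_id, "birth_sex", period, rep = birth_no)
  sex <- ifelse(us < p_male, "male", "female")

  ns <- schedules$newborn_survival
  ratio <- sched_lookup(ns, sched_key(period, sex), c("period", "sex"),
                        "ratio", "newborn survival ratio")
  uv <- event_uniform(cfg$seed, mother_id, "newborn_survival", period,
                      rep = birth_no)
  alive <- uv < ratio

  w <- frame$weight[midx]
  births_total <- sum(w)
  births <- sum(w[alive])
  if (!any(alive)) {
    res$births_total <- births_total
    return(res)
  }
  newborns <- data.frame(
    id = NEWBORN_ID_BASE + step_index(period, cfg) * ID_BLOCK +
      seq_len(sum(alive)),
    age = 0L, sex = sex[alive], education = NA_character_,
    activity = "not_applicable", weight = w[alive], origin = "birth",
    stringsAsFactors = FALSE
  )
  out <- rbind(as.data.frame(frame), newborns)
  list(frame = as_frame(out, frame), births = births,
       births_total = births_total, newborn_ids = newborns$id)
}

#' Assign labor-force status from the participation model
#'
#' Every case aged 15+ is set active with its predicted participation
#' probability (Monte Carlo rule: active iff the probability exceeds a fresh
#' uniform); ages beyond the calibrated window receive rate 0 and children
#' stay `not_applicable`. Parameters are held constant across periods, so
#' aggregate participation changes only through population composition.
#'
#' @param frame a [population_frame()]; the draw is keyed by the frame's
#'   period.
#' @param lfp_params an [lfp_logit_params()].
#' @param cfg a [scenario_config()].
#' @return the frame with activity assigned.
#' @export
step_labor_force <- function(frame, lfp_params, cfg) {
  period <- frame_period(frame)
  adult <- frame$age >= AGE_MIN_ADULT
  if (any(adult)) {
    p <- predict_participation_rate(lfp_params, frame$sex[adult],
                                    frame$age[adult], frame$education[adult])
    u <- event_uniform(cfg$seed, frame$id[adult], "labor_force", period)
    frame$activity[adult] <- ifelse(u < p, "active", "inactive")
  }
  frame$activity[!adult] <- "not_applicable"
  frame
}

#' Run the full projection
#'
#' Starts from the base population frame, assigns the base period's
#' labor-force status, then repeats the six-event step (mortality,
#' education, emigration, immigration, fertility, labor force) with the age
#' increment through every 5-year step up to the horizon. Labor-force status
#' is drawn at end-of-step ages so that cohorts reaching 15-19 within the
#' step hold a status in the emitted frame. Fully reproducible from
#' `cfg$seed`; schedule coverage is validated before any simulation starts.
#'
#' @param base a [population_frame()] at `cfg$start` (ids assigned).
#' @param schedules a [rate_schedules()] covering `start` to `horizon`.
#' @param lfp_params an [lfp_logit_params()].
#' @param cfg a [scenario_config()].
#' @return object of class `projection`: list with `frames` (named list of
#'   frames per period, the base period first) and `tallies` (data.frame of
#'   weighted deaths, emigrants, immigrants, births per step).
#' @export
run_projection <- function(base, schedules, lfp_params, cfg) {
  validate_schedules(schedules, cfg)
  frame <- as_frame(as.data.frame(base), base)
  attr(frame, "period") <- cfg$start
  frame <- step_labor_force(frame, lfp_params, cfg)

  frames <- setNames(list(frame), cfg$start)
  tallies <- list()

  for (t in step_periods(cfg)) {
    attr(frame, "period") <- as.integer(t)

    m <- step_mortality(frame, schedules, cfg)
    frame <- step_education(m$frame, schedules, cfg)
    e <- step_emigration(frame, schedules, cfg)
    i <- step_immigration(e$frame, schedules, cfg)
    f <- step_fertility(i$frame, schedules, cfg)
    frame <- f$frame

    grown <- !frame$id %in% f$newborn_ids
    frame$age[grown] <- pmin(frame$age[grown] + 5L, AGE_TOP)

    # cohorts that reached 15-19 without an attained level (immigrant
    # children arriving after the education step) are broken down now
    frame <- assign_entry_education(
      frame, frame$age == AGE_MIN_ADULT & is.na(frame$education),
      schedules, cfg, as.integer(t))

    attr(frame, "period") <- as.integer(t + 5L)
    frame <- step_labor_force(frame, lfp_params, cfg)

    frames[[as.character(t + 5L)]] <- frame
    tallies[[length(tallies) + 1L]] <- data.frame(
      period = t, deaths = m$deaths, emigrants = e$emigrants,
      immigrants = i$immigrants, births = f$births,
      births_total = f$births_total)
  }

  structure(list(frames = frames,
                 tallies = if (length(tallies)) do.call(rbind, tallies)
                           else data.frame(period = integer(),
                                           deaths = numeric(),
                                           emigrants = numeric(),
                                           immigrants = numeric(),
                                           births = numeric(),
                                           births_total = numeric()),
                 config = cfg),
            class = "projection")
}

#' @export
print.projection <- function(x, ...) {
  ps <- names(x$frames)
  cat(sprintf("Projection %s-%s (%d frames), TFR %.2f\n",
              ps[1], ps[length(ps)], length(ps), x$config$tfr))
  invisible(x)
}
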