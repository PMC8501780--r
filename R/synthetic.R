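# Synthetic world: generates every input the pipeline needs with known
# ground truth — a stylized aging age x sex x education pyramid, complete
# rate schedules, and survey-like microdata drawn from known logit/Poisson
# coefficients — so the full system is testable without external data.

#' Specify a synthetic world
#'
#' Bundles the ground truth from which every synthetic input is generated.
#' The default pyramid is a stylized aging population (mid-age bulge, small
#' recent cohorts), not a copy of any country's; the education composition
#' steepens toward younger cohorts (the younger generation is already much
#' better educated), with `education_gradient` scaling that steepening
#' (0 = identical composition across adult cohorts). True participation
#' coefficients follow the inverse-U age pattern with later retirement for
#' the low-educated; true wage coefficients span productivity factors from
#' 0.36 (no education) to 2.03 (postsecondary) around the upper-secondary
#' reference.
#'
#' @param total_population persons in the base period (default 20 million,
#'   small enough for fast tests; scale up for production runs).
#' @param education_gradient steepness of the cohort education gradient in
#'   [0, 1].
#' @param immigration_volume_factor immigrant inflow per period as a
#'   fraction of the base period's expected emigrant outflow; the default
#'   0.4 keeps net migration negative.
#' @param wage_scale baseline mean wage at the reference category.
#' @param wage_dispersion variance-to-mean ratio of generated wages; 1 is
#'   Poisson, larger values generate overdispersed wages (negative
#'   binomial) to exercise estimator robustness.
#' @param survey_years calendar years the synthetic survey pools.
#' @param ladder the [education_ladder()].
#' @return object of class `synthetic_world_spec`.
#' @export
synthetic_world_spec <- function(total_population = 2e7,
                                 education_gradient = 1,
                                 immigration_volume_factor = 0.4,
                                 wage_scale = 2500,
                                 wage_dispersion = 1,
                                 survey_years = c(2010, 2012, 2015, 2017),
                                 ladder = education_ladder()) {
  if (total_population <= 0) stop("total_population must be positive")
  if (education_gradient < 0 || education_gradient > 1)
    stop("education_gradient must lie in [0, 1]")
  if (wage_dispersion < 1) stop("wage_dispersion must be >= 1")
  k <- length(ladder$levels)
  # attainment shares of the youngest adult cohorts vs. the oldest;
  # intermediate cohorts interpolate (see edu_shares_by_age)
  young <- prop_over_levels(c(0.03, 0.07, 0.28, 0.36, 0.26), k)
  old <- prop_over_levels(c(0.28, 0.27, 0.27, 0.13, 0.05), k)

  lv <- ladder$levels
  # pad to the ladder length and re-zero at the reference level, so the
  # coding contract (reference effects are 0) holds for any ladder size
  nm <- function(x) {
    y <- setNames(prop_pad(x, k), lv)
    y - y[[ladder$reference]]
  }
  true_lfp <- lfp_logit_params(
    male = list(b0 = 1.9, b_age = 0.05, b_age2 = -0.16,
                b_edu = nm(c(-0.9, -0.5, -0.25, 0, 0.45)),
                b_edu_age = nm(c(0.12, 0.08, 0.04, 0, -0.05)),
                b_edu_age2 = nm(c(0.04, 0.03, 0.015, 0, -0.01))),
    female = list(b0 = 1.1, b_age = -0.05, b_age2 = -0.20,
                  b_edu = nm(c(-1.1, -0.6, -0.3, 0, 0.8)),
                  b_edu_age = nm(c(0.15, 0.10, 0.05, 0, -0.05)),
                  b_edu_age2 = nm(c(0.05, 0.035, 0.02, 0, -0.005))),
    ladder = ladder)

  ages_survey <- seq(15, 70, 5)
  f_age <- 0.45 - 0.45 * ((age_mid(ages_survey) - 47.5) / 30)^2
  true_wage <- list(
    b0 = log(wage_scale),
    b_edu = nm(log(prop_pad(c(0.36, 0.55, 0.75, 1, 2.03), k))),
    b_age = setNames(f_age - f_age[1], ages_survey),
    b_sex_female = -0.18,
    b_year = setNames(seq(0, 0.18, length.out = length(survey_years)),
                      survey_years)
  )

  structure(list(total_population = total_population,
                 education_gradient = education_gradient,
                 immigration_volume_factor = immigration_volume_factor,
                 wage_scale = wage_scale, wage_dispersion = wage_dispersion,
                 survey_years = survey_years, ladder = ladder,
                 edu_young = setNames(young, lv), edu_old = setNames(old, lv),
                 true_lfp = true_lfp, true_wage = true_wage),
            class = "synthetic_world_spec")
}

# pad or trim a 5-vector of defaults to k levels, then renormalize
prop_pad <- function(x, k) {
  if (k == length(x)) return(x)
  stats::approx(seq(0, 1, length.out = length(x)), x,
                seq(0, 1, length.out = k))$y
}
prop_over_levels <- function(x, k) {
  y <- prop_pad(x, k)
  y / sum(y)
}

# Stylized aging pyramid: band share of total population, with a bulge at
# mid-ages and recent cohorts about half the size of the bulge cohorts.
pyramid_share <- function(age) {
  mid <- age_mid(age)
  raw <- dnorm(mid, 42, 18) + 0.30 * dnorm(mid, 65, 12)
  raw[mid < 25] <- raw[mid < 25] * (0.55 + 0.015 * mid[mid < 25])
  raw / sum(raw)
}

# Adult attainment shares as a function of age band: the youngest cohorts
# hold the `edu_young` composition, cohorts aged 60+ the `edu_old` one,
# scaled by the gradient; with gradient 0 every cohort holds `edu_old`.
edu_shares_by_age <- function(spec, age) {
  w <- pmin(pmax((60 - age_mid(age)) / (60 - 27.5), 0), 1)
  sh <- spec$edu_old + spec$education_gradient * w * (spec$edu_young - spec$edu_old)
  sh / sum(sh)
}

# Largest-remainder rounding: integer vector with the same total as
# round(sum(x)).
round_preserve_sum <- function(x) {
  total <- round(sum(x))
  f <- floor(x)
  rem <- total - sum(f)
  if (rem > 0) {
    ord <- order(x - f, decreasing = TRUE)
    f[ord[seq_len(rem)]] <- f[ord[seq_len(rem)]] + 1
  }
  f
}

#' Generate aggregate base-period estimates
#'
#' Builds the age x sex x education person-count table the base population
#' is synthesized from. Deterministic given the spec (the seed argument is
#' accepted for interface symmetry); counts are integers conserving the
#' spec's total population exactly.
#'
#' @param spec a [synthetic_world_spec()].
#' @param seed unused; generation is deterministic.
#' @return data.frame with columns `age`, `sex`, `education`, `count`.
#' @export
make_aggregate_estimates <- function(spec, seed = 1L) {
  bands <- age_bands()
  shares <- pyramid_share(bands)
  p_male <- pmax(0.45, 0.512 - 0.002 * pmax(0, age_mid(bands) - 65))

  rows <- list()
  for (i in seq_along(bands)) {
    a <- bands[i]
    tot <- spec$total_population * shares[i]
    for (s in SEXES) {
      stot <- tot * if (s == "male") p_male[i] else 1 - p_male[i]
      if (a < AGE_MIN_ADULT) {
        rows[[length(rows) + 1L]] <- data.frame(
          age = a, sex = s, education = NA_character_, count = stot)
      } else {
        sh <- edu_shares_by_age(spec, a)
        rows[[length(rows) + 1L]] <- data.frame(
          age = a, sex = s, education = names(sh), count = stot * sh)
      }
    }
  }
  est <- do.call(rbind, rows)
  est$count <- round_preserve_sum(est$count)
  rownames(est) <- NULL
  est
}

#' Generate the full set of rate schedules
#'
#' Builds validity-checked schedules for every step from `start` to
#' `horizon`: survival ratios improving slowly over periods and with
#' education; a bell-shaped fertility schedule over ages 15-49 normalized so
#' scaling by the scenario TFR yields age-specific rates; young-adult-peaked
#' emigration rates; a low-volume immigration profile sized so expected net
#' migration is negative under the defaults; entry and one-rung advancement
#' probabilities for education; and newborn survival.
#'
#' @param spec a [synthetic_world_spec()].
#' @param start,horizon projection window (calendar years, 5-year steps).
#' @return a [rate_schedules()].
#' @export
make_rate_schedules <- function(spec, start = 2015L, horizon = 2070L) {
  if (horizon <= start) stop("horizon must exceed start")
  steps <- seq(start, horizon - 5L, by = 5L)
  bands <- age_bands()
  lv <- spec$ladder$levels
  k <- length(lv)

  # survival: cubic-in-age decline on the logit scale, female advantage,
  # education gradient for adults, slow improvement over periods
  surv <- expand.grid(period = steps, age = bands, sex = SEXES,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  child <- surv$age < AGE_MIN_ADULT
  adult <- surv[!child, , drop = FALSE]
  adult <- adult[rep(seq_len(nrow(adult)), each = k), , drop = FALSE]
  adult$education <- rep(lv, times = sum(!child))
  kid <- surv[child, , drop = FALSE]
  kid$education <- NA_character_
  surv <- rbind(kid, adult)
  step_i <- (surv$period - start) / 5
  erank <- ifelse(is.na(surv$education), 0, edu_rank(surv$education, spec$ladder) - 1)
  surv$ratio <- plogis(7 - 8e-6 * age_mid(surv$age)^3 +
                         0.3 * (surv$sex == "female") + 0.12 * erank +
                         0.03 * step_i)
  rownames(surv) <- NULL

  # entry distribution: young-cohort composition, tilted slowly toward the
  # top of the ladder over periods (education expansion)
  entry <- do.call(rbind, lapply(steps, function(t) {
    tilt <- min(0.25, 0.02 * (t - start) / 5)
    sh <- spec$edu_young
    moved <- sh[seq_len(k - 1)] * tilt
    sh[seq_len(k - 1)] <- sh[seq_len(k - 1)] - moved
    sh[k] <- sh[k] + sum(moved)
    do.call(rbind, lapply(SEXES, function(s)
      data.frame(period = t, sex = s, level = lv, share = unname(sh))))
  }))
  rownames(entry) <- NULL

  # one-rung advancement probabilities at ages 15-19, 20-24, 25-29
  adv <- expand.grid(period = steps, age = c(15L, 20L, 25L), sex = SEXES,
                     from_level = lv[-k], KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  base_p <- setNames(prop_pad(c(0.25, 0.45, 0.55, 0.35), k - 1), lv[-k])
  age_f <- c(`15` = 1, `20` = 0.5, `25` = 0.15)
  adv$prob <- base_p[adv$from_level] * age_f[as.character(adv$age)]
  rownames(adv) <- NULL

  # fertility shape over reproductive ages, normalized to 5 x sum = 1
  fages <- seq(15L, 45L, 5L)
  raw <- dnorm(age_mid(fages), 27.5, 5.5)
  fert <- expand.grid(period = steps, age = fages, KEEP.OUT.ATTRS = FALSE)
  fert$share <- (raw / (5 * sum(raw)))[match(fert$age, fages)]

  # emigration peaking among young adults, constant across periods
  emig <- expand.grid(period = steps, age = bands, sex = SEXES,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  emig$rate <- 0.004 * exp(-0.5 * ((age_mid(emig$age) - 27.5) / 10)^2)

  # immigration: a fixed fraction of the base period's expected outflow,
  # spread over young-adult ages with a mid-to-high education profile
  est <- make_aggregate_estimates(spec)
  out_rate <- emig$rate[match(sched_key(start, est$age, est$sex),
                              sched_key(emig$period, emig$age, emig$sex))]
  expected_outflow <- sum(est$count * out_rate)
  volume <- spec$immigration_volume_factor * expected_outflow
  im_ages <- c(20L, 25L, 30L, 35L)
  im_age_sh <- c(0.35, 0.35, 0.2, 0.1)
  im_lv <- lv[max(1, k - 2):k]
  im_lv_sh <- prop_over_levels(c(0.2, 0.5, 0.3), length(im_lv))
  imm <- expand.grid(period = steps, age = im_ages, sex = SEXES,
                     education = im_lv, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  imm$count <- volume * im_age_sh[match(imm$age, im_ages)] * 0.5 *
    im_lv_sh[match(imm$education, im_lv)]

  newborn <- expand.grid(period = steps, sex = SEXES,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  newborn$ratio <- plogis(5.5 + 0.3 * (newborn$sex == "female") +
                            0.03 * (newborn$period - start) / 5)

  rate_schedules(survival_ratios = surv, education_entry = entry,
                 education_transitions = adv, fertility_schedule = fert,
                 emigration_rates = emig, immigration_profile = imm,
                 newborn_survival = newborn)
}

#' Generate survey-like microdata from known coefficients
#'
#' Draws `n` respondents aged 15-74: age bands weighted by the adult
#' pyramid, equal sexes, education from the cohort-specific composition,
#' activity from the spec's true participation logit, and wages for active
#' respondents from the true log-wage model (Poisson, or negative binomial
#' when `wage_dispersion > 1`). The generating parameters are returned
#' alongside the records so estimator recovery can be checked.
#'
#' @param spec a [synthetic_world_spec()].
#' @param n number of records.
#' @param seed RNG seed (the caller's RNG state is untouched).
#' @return list with `records` (data.frame: `age`, `sex`, `education`,
#'   `in_labor_force`, `wage`, `survey_year`) and `truth` (list with the
#'   generating `lfp` and `wage` parameter sets).
#' @export
make_survey_microdata <- function(spec, n = 57411L, seed = 1L) {
  if (n <= 0) stop("n must be positive")
  ages <- seq(15L, 70L, 5L)
  aw <- pyramid_share(age_bands())[match(ages, age_bands())]
  records <- with_local_seed(seed, {
    age <- sample(ages, n, replace = TRUE, prob = aw)
    sex <- sample(SEXES, n, replace = TRUE)
    education <- character(n)
    for (a in ages) {
      i <- age == a
      sh <- edu_shares_by_age(spec, a)
      education[i] <- sample(names(sh), sum(i), replace = TRUE, prob = sh)
    }
    p <- predict_participation_rate(spec$true_lfp, sex, age, education)
    in_lf <- runif(n) < p
    year <- sample(spec$survey_years, n, replace = TRUE)

    tw <- spec$true_wage
    mu <- exp(tw$b0 + tw$b_edu[education] + tw$b_age[as.character(age)] +
                tw$b_sex_female * (sex == "female") +
                tw$b_year[as.character(year)])
    wage <- rep(NA_real_, n)
    if (spec$wage_dispersion > 1) {
      wage[in_lf] <- stats::rnbinom(sum(in_lf), mu = mu[in_lf],
                                    size = mu[in_lf] / (spec$wage_dispersion - 1))
    } else {
      wage[in_lf] <- rpois(sum(in_lf), mu[in_lf])
    }
    data.frame(age = age, sex = sex, education = education,
               in_labor_force = in_lf, wage = wage, survey_year = year,
               stringsAsFactors = FALSE)
  })
  list(records = records,
       truth = list(lfp = spec$true_lfp, wage = spec$true_wage))
}
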