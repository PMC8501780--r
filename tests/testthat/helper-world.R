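# Shared fixtures: a small synthetic world, toy frames, and constant-rate
# schedules for deterministic engine checks. All randomness is keyed by
# fixed seeds chosen once.

TEST_SEED <- 42L

LADDER <- education_ladder()

tiny_spec <- function(total = 2e6, ...) {
  synthetic_world_spec(total_population = total, ...)
}

# Build a frame by recycling column values; ids are 1..n.
mk_frame <- function(age, sex = "female", education = "upper_secondary",
                     activity = "inactive", weight = 1, origin = "baseline",
                     period = 2015) {
  n <- max(length(age), length(sex), length(education), length(activity),
           length(weight))
  education <- rep_len(education, n)
  age <- rep_len(age, n)
  education[age < 15] <- NA_character_
  activity <- rep_len(activity, n)
  activity[age < 15] <- "not_applicable"
  population_frame(data.frame(
    id = seq_len(n), age = age, sex = rep_len(sex, n),
    education = education, activity = activity,
    weight = rep_len(weight, n), origin = rep_len(origin, n),
    stringsAsFactors = FALSE), period, LADDER)
}

# Constant schedules over the steps of `cfg`: survival ratio `surv`
# everywhere, one-rung advancement probability `adv`, emigration rate
# `emig`, no immigration, uniform entry shares, newborn survival `nb`.
const_schedules <- function(cfg, surv = 1, adv = 0, emig = 0, nb = 1) {
  steps <- seq(cfg$start, max(cfg$start, cfg$horizon - 5L), by = 5L)
  bands <- age_bands()
  lv <- cfg$ladder$levels
  k <- length(lv)

  sr <- expand.grid(period = steps, age = bands, sex = c("male", "female"),
                    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  child <- sr$age < 15
  ad <- sr[!child, ][rep(seq_len(sum(!child)), each = k), ]
  ad$education <- rep(lv, times = sum(!child))
  kid <- sr[child, ]
  kid$education <- NA_character_
  sr <- rbind(kid, ad)
  sr$ratio <- surv

  ee <- expand.grid(period = steps, sex = c("male", "female"), level = lv,
                    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  ee$share <- 1 / k

  et <- expand.grid(period = steps, age = c(15L, 20L, 25L),
                    sex = c("male", "female"), from_level = lv[-k],
                    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  et$prob <- adv

  fages <- seq(15L, 45L, 5L)
  fs <- expand.grid(period = steps, age = fages, KEEP.OUT.ATTRS = FALSE)
  fs$share <- 1 / (5 * length(fages))

  er <- expand.grid(period = steps, age = bands, sex = c("male", "female"),
                    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  er$rate <- emig

  ip <- data.frame(period = integer(), age = integer(), sex = character(),
                   education = character(), count = numeric(),
                   stringsAsFactors = FALSE)

  ns <- expand.grid(period = steps, sex = c("male", "female"),
                    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  ns$ratio <- nb

  rate_schedules(sr, ee, et, fs, er, ip, ns)
}

# Participation parameters with a flat rate p for everyone in the window.
flat_lfp <- function(p) {
  zero <- setNames(numeric(length(LADDER$levels)), LADDER$levels)
  b <- list(b0 = qlogis(p), b_age = 0, b_age2 = 0,
            b_edu = zero, b_edu_age = zero, b_edu_age2 = zero)
  lfp_logit_params(male = b, female = b, ladder = LADDER)
}

# Map structured lfp truth to the glm coefficient naming of fit_lfp_logit,
# for Wald-interval coverage checks.
lfp_truth_as_coef <- function(truth, sex) {
  b <- truth[[sex]]
  ref <- truth$reference
  lv <- setdiff(truth$ladder$levels, ref)
  out <- c("(Intercept)" = b$b0, x = b$b_age, "I(x^2)" = b$b_age2)
  for (l in lv) {
    out[paste0("edu", l)] <- b$b_edu[[l]]
    out[paste0("x:edu", l)] <- b$b_edu_age[[l]]
    out[paste0("I(x^2):edu", l)] <- b$b_edu_age2[[l]]
  }
  out
}

# Same for the wage model truth.
wage_truth_as_coef <- function(tw, ladder, reference) {
  out <- c("(Intercept)" = tw$b0)
  for (l in setdiff(ladder$levels, reference))
    out[paste0("edu", l)] <- tw$b_edu[[l]]
  ages <- names(tw$b_age)
  for (a in ages[-1]) out[paste0("age_f", a)] <- tw$b_age[[a]]
  out["sex_ffemale"] <- tw$b_sex_female
  yrs <- names(tw$b_year)
  for (y in yrs[-1]) out[paste0("year_f", y)] <- tw$b_year[[y]]
  out
}
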