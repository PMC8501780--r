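cfg_run <- function(tfr = 1.5, horizon = 2030, seed = TEST_SEED, ...)
  scenario_config(tfr = tfr, horizon = horizon, seed = seed, ...)

test_that("mortality follows the survival ratios at the extremes", {
  cfg <- cfg_run()
  f <- mk_frame(age = rep(c(30, 60), 50), sex = c("male", "female"))
  keep <- step_mortality(f, const_schedules(cfg, surv = 1), cfg)
  expect_identical(nrow(keep$frame), nrow(f))
  expect_identical(keep$deaths, 0)

  gone <- step_mortality(f, const_schedules(cfg, surv = 1e-12), cfg)
  expect_identical(nrow(gone$frame), 0L)
  expect_equal(gone$deaths, frame_total(f))
})

test_that("mortality realizations stay within the binomial envelope", {
  cfg <- cfg_run()
  n <- 100000
  f <- mk_frame(age = rep(40, n), sex = "male")
  sch <- const_schedules(cfg, surv = 0.8)
  out <- step_mortality(f, sch, cfg)
  expect_lt(abs(nrow(out$frame) - n * 0.8), 3 * sqrt(n * 0.8 * 0.2))
})

test_that("mortality errors on a missing stratum ratio", {
  cfg <- cfg_run()
  sch <- const_schedules(cfg, surv = 0.9)
  sch$survival_ratios <- sch$survival_ratios[sch$survival_ratios$age != 40, ]
  f <- mk_frame(age = 40)
  expect_error(step_mortality(f, sch, cfg), "no survival ratio.*40")
})

test_that("education transitions move up, never down, and freeze at 30-34", {
  cfg <- cfg_run()
  ages <- c(15, 20, 25, 30, 45)
  f <- mk_frame(age = rep(ages, 20), education = "primary")
  frozen <- step_education(f, const_schedules(cfg, adv = 0), cfg)
  expect_identical(frozen$education, f$education)

  certain <- step_education(f, const_schedules(cfg, adv = 1), cfg)
  moved <- certain$age <= 25
  expect_true(all(certain$education[moved] == "lower_secondary"))
  expect_true(all(certain$education[!moved] == "primary"))
})

test_that("education advancement respects the binomial envelope", {
  cfg <- cfg_run()
  n <- 40000
  f <- mk_frame(age = rep(20, n), education = "primary")
  out <- step_education(f, const_schedules(cfg, adv = 0.5), cfg)
  adv <- sum(out$education == "lower_secondary")
  expect_lt(abs(adv - n * 0.5), 3 * sqrt(n * 0.25))
})

test_that("cohorts reaching 15-19 are broken down by the entry distribution", {
  cfg <- cfg_run()
  n <- 5000
  f <- mk_frame(age = rep(10, n), sex = c("male", "female"))
  out <- step_education(f, const_schedules(cfg), cfg)
  tab <- table(out$education)
  expect_identical(sort(names(tab)), sort(LADDER$levels))
  expect_true(all(abs(tab - n / 5) < 3 * sqrt(n * 0.2 * 0.8)))
})

test_that("emigration removes at the age-sex rate and only survivors", {
  cfg <- cfg_run()
  f <- mk_frame(age = rep(c(25, 60), 100), sex = "male")
  none <- step_emigration(f, const_schedules(cfg, emig = 0), cfg)
  expect_identical(nrow(none$frame), nrow(f))

  sch <- const_schedules(cfg, emig = 0)
  sch$emigration_rates$rate[sch$emigration_rates$age == 25] <- 1
  some <- step_emigration(f, sch, cfg)
  expect_true(all(some$frame$age != 25))
  expect_equal(some$emigrants, sum(f$weight[f$age == 25]))

  n <- 50000
  big <- mk_frame(age = rep(30, n))
  env <- step_emigration(big, const_schedules(cfg, emig = 0.02), cfg)
  expect_lt(abs(env$emigrants - n * 0.02), 3 * sqrt(n * 0.02 * 0.98))
})

test_that("immigrant cases enter with the profile's weighted composition", {
  cfg <- cfg_run()
  sch <- const_schedules(cfg)
  sch$immigration_profile <- data.frame(
    period = 2015, age = 25, sex = "female", education = "postsecondary",
    count = 1e6)
  f <- mk_frame(age = rep(40, 10))
  out <- step_immigration(f, sch, cfg)
  expect_equal(out$immigrants, 1e6)
  imm <- out$frame[out$frame$origin == "immigrant", ]
  expect_equal(sum(imm$weight), 1e6)
  expect_false(any(imm$id %in% f$id))
})

test_that("fertility produces no births at TFR 0 and inherits weights", {
  cfg0 <- cfg_run(tfr = 0)
  women <- mk_frame(age = rep(seq(15, 45, 5), 30), weight = 7)
  sch <- const_schedules(cfg0)
  expect_identical(step_fertility(women, sch, cfg0)$births, 0)

  cfg <- cfg_run(tfr = 1.7)
  out <- step_fertility(women, const_schedules(cfg), cfg)
  newborns <- out$frame[out$frame$origin == "birth", ]
  expect_gt(nrow(newborns), 0)
  expect_true(all(newborns$weight == 7))   # same weight as the mother
  expect_true(all(newborns$age == 0))
  expect_true(all(newborns$activity == "not_applicable"))
})

test_that("weighted births match the expectation oracle within 3 SD", {
  cfg <- cfg_run(tfr = 1.7)
  n <- 70000
  women <- mk_frame(age = rep(seq(15, 45, 5), length.out = n))
  sch <- const_schedules(cfg)
  fs <- sch$fertility_schedule[sch$fertility_schedule$period == 2015, ]
  lambda <- 5 * cfg$tfr * fs$share[match(women$age, fs$age)]
  expected <- sum(lambda)          # deterministic expected-births oracle
  out <- step_fertility(women, sch, cfg)
  expect_lt(abs(out$births_total - expected), 3 * sqrt(expected))
})

test_that("newborn sex follows the configured sex ratio at birth", {
  cfg <- cfg_run(tfr = 5, sex_ratio_at_birth = 1.05)
  women <- mk_frame(age = rep(seq(20, 35, 5), 8000))
  out <- step_fertility(women, const_schedules(cfg), cfg)
  nb <- out$frame[out$frame$origin == "birth", ]
  p <- 1.05 / 2.05
  n <- nrow(nb)
  expect_lt(abs(sum(nb$sex == "male") - n * p), 3 * sqrt(n * p * (1 - p)))
})

test_that("labor-force assignment follows the participation probability", {
  cfg <- cfg_run()
  f <- mk_frame(age = rep(40, 100), period = 2015)
  sure <- step_labor_force(f, flat_lfp(1 - 1e-16), cfg)
  expect_true(all(sure$activity == "active"))

  n <- 30000
  big <- mk_frame(age = rep(c(0, 40), length.out = n))
  out <- step_labor_force(big, flat_lfp(0.6), cfg)
  expect_true(all(out$activity[out$age == 0] == "not_applicable"))
  adults <- out$activity[out$age == 40]
  m <- length(adults)
  expect_lt(abs(sum(adults == "active") - 0.6 * m), 3 * sqrt(m * 0.24))
})

test_that("a zero-length horizon returns the base frame with status assigned", {
  cfg <- cfg_run(horizon = 2015)
  base <- build_base_population(make_aggregate_estimates(tiny_spec()), cfg)
  sch <- const_schedules(cfg_run(horizon = 2020))
  proj <- run_projection(base, sch, flat_lfp(0.6), cfg)
  expect_length(proj$frames, 1L)
  f <- proj$frames[["2015"]]
  expect_true(all(f$activity[f$age >= 15] %in% c("active", "inactive")))
  expect_identical(nrow(proj$tallies), 0L)
})

test_that("with no events the population only ages; counts are conserved", {
  cfg <- cfg_run(tfr = 0, horizon = 2030)
  base <- mk_frame(age = rep(c(20, 40, 60), 30))
  sch <- const_schedules(cfg, surv = 1, adv = 0, emig = 0)
  proj <- run_projection(base, sch, flat_lfp(0.5), cfg)
  totals <- vapply(proj$frames, frame_total, numeric(1))
  expect_true(all(totals == frame_total(base)))
  expect_identical(sort(unique(proj$frames[["2030"]]$age)),
                   c(35L, 55L, 75L))
})

test_that("emigration applies only to mortality survivors", {
  cfg <- cfg_run(tfr = 0, horizon = 2020)
  base <- mk_frame(age = rep(40, 50))
  sch <- const_schedules(cfg, surv = 1e-12, emig = 1)
  proj <- run_projection(base, sch, flat_lfp(0.5), cfg)
  expect_equal(proj$tallies$deaths, frame_total(base))
  expect_identical(proj$tallies$emigrants, 0)
})

test_that("the weighted accounting identity holds exactly every period", {
  spec <- tiny_spec()
  cfg <- cfg_run(tfr = 1.2, horizon = 2035)
  base <- build_base_population(make_aggregate_estimates(spec), cfg)
  sch <- make_rate_schedules(spec, cfg$start, cfg$horizon)
  proj <- run_projection(base, sch, spec$true_lfp, cfg)
  N <- vapply(proj$frames, frame_total, numeric(1))
  ta <- proj$tallies
  lhs <- unname(N[-1])
  rhs <- unname(N[-length(N)]) - ta$deaths - ta$emigrants +
    ta$immigrants + ta$births
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_true(all(ta$deaths >= 0 & ta$emigrants >= 0 &
                    ta$immigrants >= 0 & ta$births >= 0))
  # every emitted frame satisfies the frame invariants
  for (f in proj$frames) expect_identical(validate_frame(f), character())
})

test_that("projection is reproducible from the seed", {
  spec <- tiny_spec()
  cfg <- cfg_run(tfr = 1.2, horizon = 2025)
  base <- build_base_population(make_aggregate_estimates(spec), cfg)
  sch <- make_rate_schedules(spec, cfg$start, cfg$horizon)
  p1 <- run_projection(base, sch, spec$true_lfp, cfg)
  p2 <- run_projection(base, sch, spec$true_lfp, cfg)
  expect_identical(p1$frames, p2$frames)
  cfg2 <- cfg_run(tfr = 1.2, horizon = 2025, seed = TEST_SEED + 1)
  p3 <- run_projection(base, sch, spec$true_lfp, cfg2)
  expect_false(identical(p1$frames, p3$frames))
})

test_that("schedule coverage gaps are reported before any simulation", {
  cfg <- cfg_run(horizon = 2030)
  sch <- const_schedules(cfg_run(horizon = 2025))  # one step short
  base <- mk_frame(age = 40)
  expect_error(run_projection(base, sch, flat_lfp(0.5), cfg),
               "lacks period")
})
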