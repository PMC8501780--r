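test_that("ADR matches hand arithmetic", {
  f <- mk_frame(age = c(5, 40, 70), weight = c(30, 60, 12))
  expect_equal(adr(f), (30 + 12) / 60)
  # 38 dependents per 100 working-age persons
  g <- mk_frame(age = c(5, 40, 70), weight = c(19, 100, 19))
  expect_equal(adr(g), 0.38)
  expect_identical(adr(mk_frame(age = c(20, 40), weight = 10)), 0)
  expect_error(adr(mk_frame(age = c(5, 70))), "undefined")
})

test_that("LFDR counts children among the inactive of all ages", {
  f <- mk_frame(age = c(5, 40, 40, 70),
                activity = c("x", "active", "active", "inactive"),
                weight = c(20, 50, 50, 30))
  expect_equal(lfdr(f), (20 + 30) / 100)
  all_active <- mk_frame(age = 40, activity = "active", weight = 10)
  expect_identical(lfdr(all_active), 0)
  expect_error(lfdr(mk_frame(age = 40)), "no weighted active")
})

test_that("PWLFDR matches the weighted-denominator formula", {
  w <- structure(setNames(c(0.36, 0.55, 0.75, 1, 2.03), LADDER$levels),
                 reference = "upper_secondary", class = "productivity_weights")
  f <- mk_frame(age = c(40, 40, 40),
                education = c("none", "postsecondary", "upper_secondary"),
                activity = c("active", "active", "inactive"),
                weight = c(50, 50, 60))
  expect_equal(pwlfdr(f, w), 60 / (50 * 0.36 + 50 * 2.03), tolerance = 1e-12)
  # one inactive per reference-productivity worker gives a ratio of 1
  g <- mk_frame(age = c(40, 40), education = "upper_secondary",
                activity = c("active", "inactive"), weight = 100)
  expect_equal(pwlfdr(g, w), 1)
  # homogeneity of degree -1 in the weights
  expect_equal(pwlfdr(f, 2 * w), pwlfdr(f, w) / 2)
  miss <- w[-1]
  expect_error(pwlfdr(f, miss), "no productivity weight")
})

test_that("PWLFDR reduces to LFDR under unit weights", {
  spec <- tiny_spec()
  cfg <- scenario_config(tfr = 1.2, horizon = 2025, seed = TEST_SEED)
  base <- build_base_population(make_aggregate_estimates(spec), cfg)
  f <- step_labor_force(base, spec$true_lfp, cfg)
  expect_identical(pwlfdr(f, unit_productivity_weights()), lfdr(f))
})

test_that("the three ratios are invariant to uniform weight scaling", {
  spec <- tiny_spec()
  cfg <- scenario_config(tfr = 1.2, horizon = 2025, seed = TEST_SEED)
  f <- step_labor_force(
    build_base_population(make_aggregate_estimates(spec), cfg),
    spec$true_lfp, cfg)
  g <- f; g$weight <- g$weight * 13
  w <- unit_productivity_weights()
  expect_equal(adr(g), adr(f))
  expect_equal(lfdr(g), lfdr(f))
  expect_equal(pwlfdr(g, w), pwlfdr(f, w))
})

test_that("ADR ignores education and activity; LFDR ignores adult ages", {
  f <- mk_frame(age = c(20, 40, 40, 70), education = "primary",
                activity = c("active", "inactive", "active", "inactive"),
                weight = c(10, 20, 30, 5))
  g <- f
  g$education <- "postsecondary"
  g$activity <- rev(f$activity)
  expect_equal(adr(g), adr(f))
  h <- f
  h$age <- c(50, 25, 60, 30)   # relabel adult ages only
  expect_equal(lfdr(h), lfdr(f))
})

test_that("normalization maps the base period to 1 and preserves ordering", {
  s <- data.frame(period = c(2015, 2040), adr = c(0.4, 0.6),
                  lfdr = c(2, 2), pwlfdr = c(1, 0.5))
  n <- normalize_series(s, 2015)
  expect_equal(n$adr, c(1, 1.5))
  expect_equal(n$lfdr, c(1, 1))
  expect_equal(n$pwlfdr, c(1, 0.5))
  expect_error(normalize_series(s, 2030), "not in the series")
  expect_error(normalize_series(data.frame(period = 2015, adr = 0), 2015),
               "nonpositive")
})

test_that("pyramid summary partitions the population by tier", {
  f <- mk_frame(age = c(5, 20, 40, 40, 70), sex = c("male", "female"),
                education = c(NA, "lower_secondary", "upper_secondary",
                              "postsecondary", "none"),
                activity = c("x", "active", "active", "inactive", "inactive"),
                weight = c(5, 10, 20, 30, 40))
  tab <- pyramid_summary(f)
  expect_equal(sum(tab$weight), frame_total(f))
  expect_identical(tab$tier[tab$age == 20], "low")     # lower secondary -> low
  expect_identical(tab$tier[tab$age == 5], "not_applied")
  expect_identical(nrow(pyramid_summary(f[0, ])), 0L)
})

test_that("active counts by tier track the LFDR denominator", {
  spec <- tiny_spec()
  cfg <- experiment_config(scenarios = c(one = 1.2), seed = TEST_SEED,
                           horizon = 2030)
  ex <- run_experiment_synthetic(spec, cfg, survey_n = 5000)
  proj <- ex$projections$one
  ac <- active_counts_by_education(proj)
  per_period <- aggregate(active ~ period, ac, sum)
  for (i in seq_len(nrow(per_period))) {
    f <- proj$frames[[as.character(per_period$period[i])]]
    expect_equal(per_period$active[i], sum(f$weight[f$activity == "active"]))
  }
})

test_that("education expansion grows high-tier actives as totals decline", {
  # constructed scenario: no mortality/migration/fertility, entry pushes all
  # new cohorts to postsecondary, so high-tier actives are nondecreasing
  # while the aging population's total actives shrink
  cfg <- scenario_config(tfr = 0, horizon = 2035, seed = TEST_SEED)
  sch <- const_schedules(cfg, surv = 1)
  sch$education_entry$share <-
    as.numeric(sch$education_entry$level == "postsecondary")
  base <- mk_frame(age = rep(c(10, 35, 55), c(200, 400, 400)),
                   education = "upper_secondary", sex = c("male", "female"))
  proj <- run_projection(base, sch, tiny_spec()$true_lfp, cfg)
  ac <- active_counts_by_education(proj)
  high <- ac[ac$tier == "high", ]
  high <- high$active[order(high$period)]
  tot <- aggregate(active ~ period, ac, sum)$active
  expect_true(all(diff(high) >= 0))
  expect_lt(tot[length(tot)], tot[1])
})
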