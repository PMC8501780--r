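test_that("predicted participation equals the closed-form inverse logit", {
  spec <- tiny_spec()
  params <- spec$true_lfp
  b <- params$male
  for (edu in LADDER$levels) {
    for (age in c(15, 30, 50, 70)) {
      x <- (age + 2.5 - 45) / 5
      eta <- b$b0 + b$b_age * x + b$b_age2 * x^2 + b$b_edu[[edu]] +
        b$b_edu_age[[edu]] * x + b$b_edu_age2[[edu]] * x^2
      expect_equal(predict_participation_rate(params, "male", age, edu),
                   exp(eta) / (1 + exp(eta)), tolerance = 1e-12)
    }
  }
})

test_that("participation predictions respect logistic structure", {
  expect_equal(predict_participation_rate(flat_lfp(0.5), "male", 40,
                                          "primary"), 0.5)
  # monotone in the education main effect at every age
  spec <- tiny_spec()
  lo <- spec$true_lfp
  hi <- lo
  hi$female$b_edu[["primary"]] <- hi$female$b_edu[["primary"]] + 0.5
  ages <- seq(15, 70, 5)
  expect_true(all(predict_participation_rate(hi, "female", ages, "primary") >
                    predict_participation_rate(lo, "female", ages, "primary")))
  # round trip: logit of the prediction reproduces the linear predictor
  p <- predict_participation_rate(lo, "male", 40, "postsecondary")
  b <- lo$male
  x <- agegr_code(40)
  eta <- b$b0 + b$b_age * x + b$b_age2 * x^2 + b$b_edu[["postsecondary"]] +
    b$b_edu_age[["postsecondary"]] * x + b$b_edu_age2[["postsecondary"]] * x^2
  expect_equal(qlogis(p), eta, tolerance = 1e-10)
  # outside the calibrated window the rate is 0; unknown levels are refused
  expect_identical(predict_participation_rate(lo, "male", 80, "primary"), 0)
  expect_error(predict_participation_rate(lo, "male", 40, "wizardry"),
               "unknown education")
})

test_that("participation logit raises on degenerate strata", {
  rec <- make_survey_microdata(tiny_spec(), n = 2000, seed = TEST_SEED)$records
  expect_error(fit_lfp_logit(rec[rec$sex == "male", ]), "missing")
  all_in <- rec; all_in$in_labor_force <- TRUE
  expect_error(fit_lfp_logit(all_in), "separation")
})

test_that("participation fits recover the generating rate surface", {
  spec <- tiny_spec()
  small <- make_survey_microdata(spec, n = 5000, seed = TEST_SEED)
  large <- make_survey_microdata(spec, n = 50000, seed = TEST_SEED)
  fit_s <- fit_lfp_logit(small$records)
  fit_l <- fit_lfp_logit(large$records)
  grid <- participation_rate_schedule(spec$true_lfp)
  err <- function(fit) max(abs(
    predict_participation_rate(fit, grid$sex, grid$age, grid$education) -
      grid$rate))
  expect_lt(err(fit_l), err(fit_s))   # estimates converge with n
  # max error over the whole surface is dominated by sparse extreme cells
  # (oldest bands x rarest levels); 50,000 records keep it under 0.075
  expect_lt(err(fit_l), 0.075)
  # diagnostics are attached for comparability with survey-based fits
  expect_true(all(c("r2_max_rescaled", "c_statistic") %in%
                    names(fit_l$diagnostics$male)))
  expect_gt(fit_l$diagnostics$male[["c_statistic"]], 0.5)
})

test_that("wage model recovers known education premia", {
  spec <- tiny_spec()
  survey <- make_survey_microdata(spec, n = 50000, seed = TEST_SEED)
  fit <- fit_wage_poisson(survey$records)
  w <- derive_productivity_weights(fit)
  truth <- exp(spec$true_wage$b_edu)
  expect_true(all(abs(w / truth - 1) < 0.05))
})

test_that("wage model degenerate inputs are refused", {
  rec <- make_survey_microdata(tiny_spec(), n = 2000, seed = TEST_SEED)$records
  inactive <- rec[!rec$in_labor_force, ]
  expect_error(fit_wage_poisson(inactive), "no wage-bearing")
})

test_that("flat wages across education give unit weights", {
  n <- 4000
  set.seed(TEST_SEED)
  rec <- data.frame(
    age = sample(seq(15, 70, 5), n, TRUE),
    sex = sample(c("male", "female"), n, TRUE),
    education = sample(LADDER$levels, n, TRUE),
    in_labor_force = TRUE,
    wage = rpois(n, 200),
    survey_year = sample(2010:2017, n, TRUE))
  w <- derive_productivity_weights(fit_wage_poisson(rec))
  expect_true(all(abs(w - 1) < 0.05))
})

test_that("productivity weights are the natural exponent of the premium", {
  params <- structure(list(
    b_edu = setNames(c(0, 0, 0, 0, log(2)), LADDER$levels),
    reference = "upper_secondary", ladder = LADDER),
    class = "wage_model_params")
  w <- derive_productivity_weights(params)
  expect_identical(unname(w[["upper_secondary"]]), 1)
  expect_equal(unname(w[["postsecondary"]]), 2)
  zero <- params; zero$b_edu[] <- 0
  expect_true(all(derive_productivity_weights(zero) == 1))
  expect_error(derive_productivity_weights(params, reference = "abacus"),
               "not on the ladder")
})

test_that("weights are invariant to relabeling survey years", {
  survey <- make_survey_microdata(tiny_spec(), n = 8000, seed = TEST_SEED)
  rec2 <- survey$records
  rec2$survey_year <- rec2$survey_year + 30
  w1 <- derive_productivity_weights(fit_wage_poisson(survey$records))
  w2 <- derive_productivity_weights(fit_wage_poisson(rec2))
  expect_equal(as.numeric(w1), as.numeric(w2), tolerance = 1e-10)
})
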