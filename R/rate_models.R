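# Calibration models: sex-specific logistic regression of labor-force
# participation on age (quadratic) and education (with full age
# interactions), and a Poisson log-link wage model whose education
# coefficients yield the productivity weights.

#' Construct labor-force participation logit parameters
#'
#' One full coefficient set per sex for the participation model
#' logit(P) = b0 + b1 AGE + b2 AGE^2 + b3[edu] + b4[edu] AGE + b5[edu] AGE^2,
#' where AGE is the band midpoint coded as `(mid - age_center) / age_scale`
#' and education is categorical with the given reference level absorbed into
#' the intercept (its main effect and interactions are zero by coding).
#'
#' @param male,female lists with elements `b0`, `b_age`, `b_age2` (scalars)
#'   and `b_edu`, `b_edu_age`, `b_edu_age2` (named vectors over ladder
#'   levels; the reference entry must be 0).
#' @param ladder the [education_ladder()].
#' @param reference education level absorbed in the intercept.
#' @param age_center,age_scale the age-group coding constants.
#' @param window inclusive age range (in years) over which the model is
#'   considered calibrated; ages above it receive participation 0.
#' @return object of class `lfp_logit_params`.
#' @export
lfp_logit_params <- function(male, female, ladder = education_ladder(),
                             reference = ladder$reference,
                             age_center = 45, age_scale = 5,
                             window = c(15, 74)) {
  check_sex <- function(b, sex) {
    for (nm in c("b_edu", "b_edu_age", "b_edu_age2")) {
      if (!all(ladder$levels %in% names(b[[nm]])))
        stop(sex, " ", nm, " must name every ladder level")
      if (abs(b[[nm]][[reference]]) > 0)
        stop(sex, " ", nm, " must be 0 at the reference level")
    }
    vals <- c(b$b0, b$b_age, b$b_age2, b$b_edu, b$b_edu_age, b$b_edu_age2)
    if (!all(is.finite(vals))) stop(sex, " coefficients must be finite")
    b
  }
  structure(list(male = check_sex(male, "male"),
                 female = check_sex(female, "female"),
                 ladder = ladder, reference = reference,
                 age_center = age_center, age_scale = age_scale,
                 window = window),
            class = "lfp_logit_params")
}

# Factor with the reference level first, remaining ladder order preserved.
edu_factor <- function(education, ladder, reference) {
  lv <- c(reference, setdiff(ladder$levels, reference))
  factor(education, levels = lv)
}

check_survey_records <- function(records) {
  need <- c("age", "sex", "education", "in_labor_force")
  if (!all(need %in% names(records)))
    stop("survey records need columns: ", paste(need, collapse = ", "))
  if (!all(records$sex %in% SEXES))
    stop("survey sex codes must be 'male'/'female'")
  invisible(records)
}

#' Fit the sex-specific participation logit
#'
#' Maximum-likelihood logistic regression of labor-force membership on the
#' quadratic age-group code and categorical education with full education x
#' age and education x age-squared interactions, fitted separately by sex.
#' Raises an error (naming the offending stratum) on missing sexes, on
#' education strata observed in only one activity state (complete
#' separation), or on non-convergence.
#'
#' @param records survey microdata: data.frame with `age` (5-year band lower
#'   bound, within the survey window), `sex`, `education`, `in_labor_force`
#'   (logical).
#' @param ladder the [education_ladder()].
#' @param age_center,age_scale age-group coding constants (recorded on the
#'   result so coefficients stay interpretable).
#' @param window inclusive calibrated age range in years.
#' @return an [lfp_logit_params()] object; per-sex coefficient covariance
#'   matrices and fit diagnostics (Nagelkerke max-rescaled R-squared and the
#'   c-statistic) are attached as `vcov` and `diagnostics`.
#' @export
fit_lfp_logit <- function(records, ladder = education_ladder(),
                          age_center = 45, age_scale = 5, window = c(15, 74)) {
  check_survey_records(records)
  if (!all(SEXES %in% records$sex))
    stop("records must include both sexes; missing: ",
         paste(setdiff(SEXES, records$sex), collapse = ", "))
  reference <- ladder$reference

  fit_one <- function(sub, sex) {
    tab <- table(sub$education, sub$in_labor_force)
    if (ncol(tab) < 2L || any(rowSums(tab > 0) < 2L)) {
      off <- if (ncol(tab) < 2L) "all levels" else
        paste(rownames(tab)[rowSums(tab > 0) < 2L], collapse = ", ")
      stop("complete separation for sex=", sex, ", education stratum(s): ", off)
    }
    d <- data.frame(
      y = sub$in_labor_force,
      x = agegr_code(sub$age, age_center, age_scale),
      edu = edu_factor(sub$education, ladder, reference)
    )
    fit <- glm(y ~ x + I(x^2) + edu + x:edu + I(x^2):edu,
               family = binomial(), data = d)
    if (!fit$converged)
      stop("participation logit did not converge for sex=", sex)
    if (any(abs(coef(fit)) > 15, na.rm = TRUE) || anyNA(coef(fit)))
      stop("quasi-separation detected for sex=", sex,
           " (unbounded coefficient)")
    fit
  }

  fits <- lapply(SEXES, function(s)
    fit_one(records[records$sex == s, , drop = FALSE], s))
  names(fits) <- SEXES

  unpack <- function(fit) {
    b <- coef(fit)
    zero <- setNames(numeric(length(ladder$levels)), ladder$levels)
    b_edu <- b_edu_age <- b_edu_age2 <- zero
    for (lv in setdiff(ladder$levels, reference)) {
      b_edu[lv] <- b[[paste0("edu", lv)]]
      b_edu_age[lv] <- b[[paste0("x:edu", lv)]]
      b_edu_age2[lv] <- b[[paste0("I(x^2):edu", lv)]]
    }
    list(b0 = b[["(Intercept)"]], b_age = b[["x"]], b_age2 = b[["I(x^2)"]],
         b_edu = b_edu, b_edu_age = b_edu_age, b_edu_age2 = b_edu_age2)
  }

  diagnostics <- lapply(fits, function(fit) {
    n <- length(fit$y)
    r2_cs <- 1 - exp(-(fit$null.deviance - fit$deviance) / n)
    r2_max <- 1 - exp(-fit$null.deviance / n)
    p <- fit$fitted.values
    y <- fit$y
    n1 <- sum(y == 1); n0 <- n - n1
    cstat <- (sum(rank(p)[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    c(r2_max_rescaled = r2_cs / r2_max, c_statistic = cstat)
  })

  out <- lfp_logit_params(unpack(fits$male), unpack(fits$female),
                          ladder = ladder, reference = reference,
                          age_center = age_center, age_scale = age_scale,
                          window = window)
  out$vcov <- lapply(fits, vcov)
  out$coef <- lapply(fits, coef)
  out$diagnostics <- diagnostics
  out
}

#' Predicted labor-force participation rate
#'
#' Inverse-logit of the linear predictor: P = exp(eta) / (1 + exp(eta)).
#' Within the calibrated age window the fitted value is used; band 75+ and
#' above receive 0 (the model is not extrapolated beyond the survey ages).
#'
#' @param params an [lfp_logit_params()].
#' @param sex,age,education vectors (recycled to a common length); `age` is
#'   the 5-year band lower bound.
#' @return participation probabilities in [0, 1); strictly inside (0, 1)
#'   within the calibrated window.
#' @export
predict_participation_rate <- function(params, sex, age, education) {
  n <- max(length(sex), length(age), length(education))
  sex <- rep_len(sex, n); age <- rep_len(age, n)
  education <- rep_len(education, n)
  bad <- !education %in% params$ladder$levels
  if (any(bad))
    stop("unknown education level(s): ",
         paste(unique(education[bad]), collapse = ", "))
  if (any(age < params$window[1]))
    stop("participation is undefined below age ", params$window[1])

  x <- agegr_code(age, params$age_center, params$age_scale)
  p <- numeric(n)
  for (s in SEXES) {
    i <- sex == s
    if (!any(i)) next
    b <- params[[s]]
    eta <- b$b0 + b$b_age * x[i] + b$b_age2 * x[i]^2 +
      b$b_edu[education[i]] + b$b_edu_age[education[i]] * x[i] +
      b$b_edu_age2[education[i]] * x[i]^2
    p[i] <- plogis(eta)
  }
  # bands lying beyond the calibrated window are assigned rate 0
  p[age + 4 > params$window[2]] <- 0
  p
}

#' Fit the Poisson log-wage model
#'
#' ln(E WAGE) = b0 + b1[edu] + b2[age band] + b3 sex + b4[survey year],
#' estimated by Poisson regression with log link on the wage of labor-force
#' members only (inactive records are excluded inside the operation). The
#' response is continuous, so the fit is the quasi-likelihood analogue with
#' identical point estimates. Education is coded with the ladder's reference
#' level at zero.
#'
#' @param records survey microdata including `wage` (positive, present for
#'   labor-force members) and `survey_year`.
#' @param ladder the [education_ladder()].
#' @return object of class `wage_model_params`: intercept `b0`, named
#'   education effects `b_edu` (reference 0), age-band effects `b_age`,
#'   `b_sex_female`, survey-year effects `b_year`, plus the coefficient
#'   covariance matrix.
#' @export
fit_wage_poisson <- function(records, ladder = education_ladder()) {
  check_survey_records(records)
  if (!"wage" %in% names(records)) stop("survey records need a wage column")
  act <- records[records$in_labor_force & !is.na(records$wage), , drop = FALSE]
  if (!nrow(act))
    stop("no wage-bearing labor-force records to fit the wage model on")
  bad <- !act$education %in% ladder$levels
  if (any(bad))
    stop("unknown education level(s): ",
         paste(unique(act$education[bad]), collapse = ", "))
  reference <- ladder$reference

  d <- data.frame(
    wage = act$wage,
    edu = edu_factor(act$education, ladder, reference),
    age_f = factor(act$age, levels = sort(unique(act$age))),
    sex_f = factor(act$sex, levels = SEXES),
    year_f = factor(act$survey_year, levels = sort(unique(act$survey_year)))
  )
  # drop constant factors (single survey year, single sex) from the formula
  terms <- c("edu", "age_f", "sex_f", "year_f")
  keep <- vapply(terms, function(v) nlevels(droplevels(d[[v]])) > 1L, logical(1))
  form <- stats::reformulate(terms[keep], response = "wage")
  fit <- suppressWarnings(glm(form, family = quasipoisson(link = "log"), data = d))
  if (!fit$converged) stop("wage model did not converge")
  b <- coef(fit)

  grab <- function(prefix, levels) {
    out <- setNames(numeric(length(levels)), levels)
    nm <- paste0(prefix, levels)
    hit <- nm %in% names(b)
    out[hit] <- b[nm[hit]]
    out
  }
  structure(list(
    b0 = b[["(Intercept)"]],
    b_edu = grab("edu", ladder$levels),
    b_age = grab("age_f", levels(d$age_f)),
    b_sex_female = if ("sex_ffemale" %in% names(b)) b[["sex_ffemale"]] else 0,
    b_year = grab("year_f", levels(d$year_f)),
    reference = reference, ladder = ladder,
    vcov = vcov(fit), coef = b, n = nrow(d)
  ), class = "wage_model_params")
}

#' Derive productivity weights from the wage model
#'
#' The productivity factor of an education level is the natural exponent of
#' its wage-model coefficient, W_e = exp(b1[e]); the reference category
#' (upper secondary by default) has W = 1 exactly. Survey-year effects are
#' absorbed by the year coefficients and never enter the weights.
#'
#' @param params a [fit_wage_poisson()] result.
#' @param reference education level fixed at weight 1; defaults to the
#'   reference used in the fit.
#' @return named numeric vector of class `productivity_weights`, one
#'   positive weight per ladder level.
#' @export
derive_productivity_weights <- function(params, reference = params$reference) {
  if (!reference %in% params$ladder$levels)
    stop("reference level '", reference, "' is not on the ladder")
  w <- exp(params$b_edu - params$b_edu[[reference]])
  w[reference] <- 1  # exact, not exp(0) subject to rounding of the difference
  structure(w[params$ladder$levels], reference = reference,
            class = "productivity_weights")
}

#' Unit productivity weights
#'
#' Convenience constructor: weight 1 for every ladder level, under which the
#' productivity-weighted dependency ratio reduces to the plain labor force
#' dependency ratio.
#'
#' @param ladder the [education_ladder()].
#' @return a `productivity_weights` vector of ones.
#' @export
unit_productivity_weights <- function(ladder = education_ladder()) {
  structure(setNames(rep(1, length(ladder$levels)), ladder$levels),
            reference = ladder$reference, class = "productivity_weights")
}

#' Predicted participation rate schedule
#'
#' Tabulates [predict_participation_rate()] over age x sex x education — the
#' rate surface the simulation applies each period.
#'
#' @param params an [lfp_logit_params()].
#' @param ages band lower bounds to tabulate (default: the calibrated window).
#' @return data.frame with columns `age`, `sex`, `education`, `rate`.
#' @export
participation_rate_schedule <- function(params,
                                        ages = seq(params$window[1],
                                                   params$window[2] - 4, 5)) {
  g <- expand.grid(age = ages, sex = SEXES,
                   education = params$ladder$levels,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$rate <- predict_participation_rate(params, g$sex, g$age, g$education)
  g
}
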