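Package: lfdemosim
Title: Demographic Microsimulation of Education and Labor Force Dependency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dynamic discrete-time Monte Carlo microsimulation for projecting
    a population by 5-year age group, sex, educational attainment, and
    labor-force status under alternative fertility scenarios. Includes
    calibration of sex-specific logistic labor-force participation models
    and a Poisson log-wage model yielding education-specific productivity
    weights; computes the age dependency ratio (ADR), the labor force
    dependency ratio (LFDR), and the productivity-weighted labor force
    dependency ratio (PWLFDR). Scenario pairs share counter-based random
    number streams so that projected differences reflect assumptions rather
    than Monte Carlo noise. Ships synthetic-input generators (base pyramid,
    rate schedules, survey microdata with known coefficients) so the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
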