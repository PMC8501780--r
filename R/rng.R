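# Counter-based random streams.
#
# Every stochastic event in the simulation draws its uniform from a hash of
# (seed, individual id, event code, period, repetition). Because the draw is
# a pure function of that key, two scenario runs sharing a seed give every
# individual present in both runs identical event outcomes: differences
# between scenarios are then attributable to the assumptions alone.

EVENT_CODES <- c(
  mortality        = 1L,
  education_entry  = 2L,
  education_advance = 3L,
  emigration       = 4L,
  fertility        = 5L,
  birth_sex        = 6L,
  newborn_survival = 7L,
  labor_force      = 8L
)

#' Uniform draws from a keyed counter stream
#'
#' @param seed scenario seed (integer-valued).
#' @param id numeric vector of individual ids.
#' @param event event name, one of `names(EVENT_CODES)`.
#' @param period integer period key (calendar year of the step).
#' @param rep repetition index for multiple draws per key (scalar or vector).
#' @return numeric vector of uniforms in (0, 1), one per id.
#' @keywords internal
event_uniform <- function(seed, id, event, period, rep = 0) {
  code <- EVENT_CODES[[event]]
  if (is.null(code)) stop("unknown event name: ", event)
  counter_uniform_cpp(as.double(seed), as.double(id), code,
                      as.integer(period), as.double(rep))
}

# Evaluate an expression under a temporary R RNG seed, restoring the caller's
# RNG state afterwards. Used by the synthetic-data generators.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
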