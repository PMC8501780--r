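# Education ladder and 5-year age band utilities.

#' Ordered education ladder
#'
#' The attainment scale used throughout the model. Levels are strictly
#' ordered from lowest to highest; one level is the designated reference for
#' productivity weights (upper secondary by default, which receives weight 1
#' exactly). The number of levels is configurable: the default ladder has
#' five categories (no education including incomplete primary, primary,
#' lower secondary, upper secondary, postsecondary), but a six-level variant
#' splitting postsecondary, say, is accepted as long as a reference is named.
#'
#' @param levels character vector of level names, lowest first.
#' @param reference the level whose productivity weight is fixed at 1.
#' @return an object of class `education_ladder`.
#' @export
#' @examples
#' lad <- education_ladder()
#' lad$levels
education_ladder <- function(levels = c("none", "primary", "lower_secondary",
                                        "upper_secondary", "postsecondary"),
                             reference = "upper_secondary") {
  levels <- as.character(levels)
  if (anyDuplicated(levels)) stop("education levels must be distinct")
  if (length(levels) < 2L) stop("education ladder needs at least two levels")
  if (!reference %in% levels)
    stop("reference level '", reference, "' is not on the ladder")
  structure(list(levels = levels, reference = reference),
            class = "education_ladder")
}

#' @export
print.education_ladder <- function(x, ...) {
  cat("Education ladder:", paste(x$levels, collapse = " < "),
      "\nReference level:", x$reference, "\n")
  invisible(x)
}

# Integer rank of a level on the ladder (1 = lowest); NA passes through
# (children aged 0-14 carry no education level).
edu_rank <- function(education, ladder) {
  match(education, ladder$levels)
}

#' Collapse the ladder into low/medium/high tiers
#'
#' Pyramid summaries group attainment into three tiers: everything below the
#' reference level (lower than secondary) is "low", the reference level is
#' "medium", anything above is "high". Children without an assigned level map
#' to "not_applied".
#'
#' @param education character vector of ladder levels (NA for children).
#' @param ladder an [education_ladder()].
#' @return character vector of tiers.
#' @export
edu_tier <- function(education, ladder = education_ladder()) {
  r <- edu_rank(education, ladder)
  ref <- match(ladder$reference, ladder$levels)
  out <- ifelse(is.na(r), "not_applied",
                ifelse(r < ref, "low", ifelse(r == ref, "medium", "high")))
  bad <- !is.na(education) & is.na(r)
  if (any(bad))
    stop("unknown education level(s): ",
         paste(unique(education[bad]), collapse = ", "))
  out
}

# -- age bands ---------------------------------------------------------------

AGE_MIN_ADULT <- 15L   # lower bound of the first band eligible for activity
AGE_TOP <- 100L        # open-ended top band 100+

#' Lower bounds of the 5-year age bands (0-4 ... 100+)
#' @return integer vector of band lower bounds.
#' @export
age_bands <- function() seq(0L, AGE_TOP, by = 5L)

#' Band labels ("0-4", ..., "100+") for band lower bounds
#' @param age integer vector of band lower bounds.
#' @return character labels.
#' @export
age_label <- function(age) {
  ifelse(age >= AGE_TOP, paste0(AGE_TOP, "+"), paste0(age, "-", age + 4L))
}

# Midpoint of a band; the top band uses 102.5 by convention.
age_mid <- function(age) pmin(age, AGE_TOP) + 2.5

# Numeric age-group coding used in the participation logit: band midpoint
# centered at 45 and scaled by the band width, so the quadratic term is well
# conditioned. Coding is recorded on fitted parameter objects.
agegr_code <- function(age, center = 45, scale = 5) (age_mid(age) - center) / scale
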