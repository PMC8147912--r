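#' Built-in rural-system parameter tables
#'
#' The package ships the illness families, age classes, and age-class-illness
#' mixing distributions of a rural German three-municipality primary care
#' system (seven aggregated ICD-10 families, three age classes). They are the
#' default inputs of the synthetic scenario generator.
#'
#' @return `default_families()`: a seven-row family table.
#' @export
default_families <- function() {
  dplyr::bind_rows(
    illness_family("high blood pressure", "I10", willingness = c(-10, 20),
                   followup = c(-20, 100), chronic = TRUE),
    illness_family("diabetes", "E11", willingness = c(-4, 14),
                   followup = c(-10, 90), chronic = TRUE),
    illness_family("ischemic heart disease", "I25", willingness = c(-4, 10),
                   followup = c(-30, 100), chronic = TRUE),
    illness_family("high cholesterol level", "E78", willingness = c(-5, 8),
                   duration = c(4, 8), followup = c(-2, 11)),
    illness_family("back pain", "M54", willingness = c(-3, 4),
                   duration = c(9, 5), followup = c(-4, 11)),
    illness_family("vaccination", "Z25", willingness = c(0, 40)),
    illness_family("cold", "J06", willingness = c(-2, 2),
                   duration = c(5, 4), followup = c(-1, 6))
  )
}

#' @rdname default_families
#' @return `default_age_classes()`: three age classes (16-24, 25-65, >65)
#'   with illness-rate functions, duration/willingness deviation factors,
#'   cancellation probabilities, and the generator's population share,
#'   session-availability and chronic-illness probabilities.
#' @export
default_age_classes <- function() {
  dplyr::bind_rows(
    age_class("16-24", c(6, 0), 0.8, 1.2, 0.95,
              share = 0.1196, avail_prob = 0.85, chronic_prob = 0.12),
    age_class("25-65", c(7, 1), 1.0, 1.0, 0.80,
              share = 0.6318, avail_prob = 0.55, chronic_prob = 0.33),
    age_class(">65", c(9, 1), 1.2, 0.8, 0.70,
              share = 0.2486, avail_prob = 0.95, chronic_prob = 0.52)
  )
}

#' @rdname default_families
#' @return `default_acute_mix()`: acute mixing matrix (rows: age classes,
#'   columns: the four acute families).
#' @export
default_acute_mix <- function() {
  illness_mix(
    c("16-24", "25-65", ">65"),
    c("high cholesterol level", "back pain", "vaccination", "cold"),
    c(0.02, 0.32, 0.14, 0.52,
      0.24, 0.38, 0.14, 0.24,
      0.36, 0.28, 0.27, 0.09)
  )
}

#' @rdname default_families
#' @return `default_chronic_mix()`: chronic mixing matrix (three chronic
#'   families).
#' @export
default_chronic_mix <- function() {
  illness_mix(
    c("16-24", "25-65", ">65"),
    c("high blood pressure", "diabetes", "ischemic heart disease"),
    c(0.17, 0.33, 0.50,
      0.65, 0.16, 0.19,
      0.61, 0.20, 0.19)
  )
}

#' Shifted age-class distributions for aging-population scenarios
#'
#' Projected age-class shares for a short-term and a medium-term shift,
#' used by [apply_aging()] to regenerate an aged patient population.
#'
#' @param horizon `"short"` or `"medium"`.
#' @return Named numeric vector of age-class shares summing to 1.
#' @export
aged_distribution <- function(horizon = c("short", "medium")) {
  horizon <- match.arg(horizon)
  if (horizon == "short") {
    c("16-24" = 0.1051, "25-65" = 0.6283, ">65" = 0.2666)
  } else {
    c("16-24" = 0.1025, "25-65" = 0.6033, ">65" = 0.2942)
  }
}
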