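#' Illness families, age classes, and illness sampling
#'
#' An illness family fixes the constant traits shared by all illnesses of its
#' kind: linear functions of the seriousness `s` in `[0, 1]` for the expected
#' duration `D(s)`, the expected willingness to wait `W(s)`, and the
#' (deterministic) follow-up interval `N(s)`, plus a chronic flag. An emerged
#' illness carries a sampled seriousness, a stochastic duration and
#' willingness whose means are the family values scaled by age-class factors,
#' and the exact follow-up interval `N(s)`.
#'
#' @name illness_model
NULL

#' Define an illness family
#'
#' Linear trait functions are given as `c(slope, intercept)` pairs; `NULL`
#' (stored as `NA`) marks a trait as not applicable. Chronic families must
#' not carry a duration (they neither develop nor heal); acute families
#' without a duration resolve upon their first treatment (e.g. a
#' vaccination).
#'
#' @param name Family name.
#' @param icd ICD-10 code (informational).
#' @param willingness `c(slope, intercept)` of `W(s)` in days.
#' @param duration `c(slope, intercept)` of `D(s)` in days, or `NULL`.
#' @param followup `c(slope, intercept)` of `N(s)` in days, or `NULL`.
#' @param chronic Chronic flag.
#' @return One-row tibble; bind rows to build a family table.
#' @examples
#' illness_family("common cold", "J00",
#'   duration = c(10, 3), willingness = c(-3, 3), followup = c(-2, 7))
#' @export
illness_family <- function(name, icd = NA_character_, willingness,
                           duration = NULL, followup = NULL, chronic = FALSE) {
  lin <- function(x) if (is.null(x)) c(NA_real_, NA_real_) else as.numeric(x)
  d <- lin(duration); w <- lin(willingness); nn <- lin(followup)
  if (anyNA(w)) rlang::abort("every family needs a willingness function")
  if (chronic && !anyNA(d)) {
    rlang::abort("chronic families must not define a duration")
  }
  tibble::tibble(
    name = name, icd = icd,
    d_slope = d[1], d_int = d[2],
    w_slope = w[1], w_int = w[2],
    n_slope = nn[1], n_int = nn[2],
    chronic = isTRUE(chronic)
  )
}

# evaluate slope * s + intercept, clamped at 0 (negative evaluations can only
# arise from coefficients used outside their sensible seriousness range)
eval_linfun <- function(slope, int, s) {
  v <- slope * s + int
  neg <- !is.na(v) & v < 0
  if (any(neg)) {
    rlang::warn("linear trait function evaluated negative; clamped at 0",
                .frequency = "once", .frequency_id = "primsim_linfun_clamp")
    v[neg] <- 0
  }
  v
}

#' Expected traits of a family at a given seriousness
#'
#' Evaluates the family's linear functions at `s`: a mild case (`s = 0.2`) of
#' a family with `D(s) = 10 s + 3`, `W(s) = -3 s + 3`, `N(s) = -2 s + 7` has
#' expected duration 5 days, expected willingness 2.4 days, and follow-up
#' interval 6.6 days. Not-applicable traits propagate as `NA`.
#'
#' @param family A one-row family tibble (see [illness_family()]).
#' @param s Seriousness in `[0, 1]` (vectorized).
#' @return Tibble with columns `duration`, `willingness`, `followup` (days).
#' @export
expected_traits <- function(family, s) {
  if (nrow(family) != 1) rlang::abort("`family` must be a single family row")
  if (any(s < 0 | s > 1)) rlang::abort("seriousness must lie in [0, 1]")
  tibble::tibble(
    duration = eval_linfun(family$d_slope, family$d_int, s),
    willingness = eval_linfun(family$w_slope, family$w_int, s),
    followup = eval_linfun(family$n_slope, family$n_int, s)
  )
}

#' Define an age class
#'
#' @param name Class label.
#' @param annual_illnesses `c(slope, intercept)` of the expected number of
#'   annual acute illnesses as a linear function of the health condition `c`.
#' @param duration_factor Multiplicative deviation (> 0) applied to expected
#'   illness durations.
#' @param willingness_factor Multiplicative deviation (>= 0) applied to the
#'   expected willingness to wait.
#' @param cancel_prob Probability to cancel an appointment after full
#'   recovery.
#' @param share Probability of the class in the population (generator).
#' @param avail_prob Per-session availability probability (generator).
#' @param chronic_prob Probability of carrying a chronic illness (generator).
#' @return One-row tibble; bind rows to build the age-class table.
#' @export
age_class <- function(name, annual_illnesses, duration_factor,
                      willingness_factor, cancel_prob,
                      share = NA_real_, avail_prob = NA_real_,
                      chronic_prob = NA_real_) {
  if (duration_factor <= 0) rlang::abort("`duration_factor` must be positive")
  if (willingness_factor < 0) rlang::abort("`willingness_factor` must be >= 0")
  if (cancel_prob < 0 || cancel_prob > 1) {
    rlang::abort("`cancel_prob` must lie in [0, 1]")
  }
  tibble::tibble(
    name = name,
    i_slope = annual_illnesses[1], i_int = annual_illnesses[2],
    duration_factor = duration_factor,
    willingness_factor = willingness_factor,
    cancel_prob = cancel_prob,
    share = share, avail_prob = avail_prob, chronic_prob = chronic_prob
  )
}

#' Expected annual acute illnesses for an age class
#'
#' Evaluates the class's linear rate function at health condition `c`; the
#' rate drives each patient's homogeneous Poisson onset process
#' (`rate / 365` per day).
#'
#' @param age A one-row age-class tibble.
#' @param c Health condition in `[0, 1]` (vectorized).
#' @return Expected illnesses per year (>= 0).
#' @examples
#' annual_rate(age_class(">65", c(9, 1), 1.2, 0.8, 0.7), c = 0.5) # 5.5
#' @export
annual_rate <- function(age, c) {
  if (nrow(age) != 1) rlang::abort("`age` must be a single age-class row")
  if (any(c < 0 | c > 1)) rlang::abort("health condition must lie in [0, 1]")
  eval_linfun(age$i_slope, age$i_int, c)
}

#' Age-class-illness mixing distribution
#'
#' Builds the matrix `pi(a, f)` of expected illness-family shares per age
#' class. Rows are age classes, columns families; every row must sum to 1.
#'
#' @param age_names,family_names Dimension names.
#' @param probs Matrix (or row-major vector) of probabilities.
#' @return A named probability matrix.
#' @export
illness_mix <- function(age_names, family_names, probs) {
  m <- matrix(probs, nrow = length(age_names), byrow = TRUE,
              dimnames = list(age_names, family_names))
  bad <- abs(rowSums(m) - 1) > 1e-9
  if (any(bad)) {
    rlang::abort(paste0("mixing rows must sum to 1; offending age class(es): ",
                        paste(age_names[bad], collapse = ", ")))
  }
  if (any(m < 0)) rlang::abort("mixing probabilities must be non-negative")
  m
}

# fast internal core: sample n illnesses given integer family indices into
# `fam` (a families tibble), age factors, and control. Returns plain vectors.
sample_illness_core <- function(fam, fam_idx, n, dur_factor, will_factor, ctl) {
  s <- rtriangular(n, mode = ctl$seriousness_mode,
                   lo = if (ctl$deterministic) ctl$seriousness_mode else 0,
                   hi = if (ctl$deterministic) ctl$seriousness_mode else 1)
  d_mean <- eval_linfun(fam$d_slope[fam_idx], fam$d_int[fam_idx], s) * dur_factor
  w_mean <- eval_linfun(fam$w_slope[fam_idx], fam$w_int[fam_idx], s) * will_factor
  nu <- eval_linfun(fam$n_slope[fam_idx], fam$n_int[fam_idx], s)
  dur <- rep(NA_real_, n)
  has_d <- !is.na(d_mean)
  if (any(has_d)) {
    dur[has_d] <- rlnorm_mean_cv(sum(has_d), pmax(d_mean[has_d], 1e-9),
                                 if (ctl$deterministic) 0 else ctl$duration_cv)
  }
  will <- rweibull_mean(n, w_mean,
                        if (ctl$deterministic) Inf else ctl$willingness_shape)
  list(fam_idx = fam_idx, s = s, duration = dur, willingness = will,
       followup = nu)
}

# draw family indices from a mixing row
sample_family_idx <- function(n, fam, mix_row) {
  idx <- match(names(mix_row), fam$name)
  if (anyNA(idx)) rlang::abort("mixing columns must name known families")
  idx[sample.int(length(mix_row), n, replace = TRUE, prob = mix_row)]
}

#' Sample acute illnesses for an age class
#'
#' Draws the family from the acute mixing row of the age class, the
#' seriousness from a triangular distribution, the duration from a log-normal
#' and the willingness to wait from a Weibull distribution whose means are
#' the age-adjusted family traits; the follow-up interval is the exact family
#' value `N(s)`.
#'
#' @param n Number of illnesses to draw.
#' @param age One-row age-class tibble.
#' @param families Family table (acute families must appear in `mix`).
#' @param mix Acute mixing matrix from [illness_mix()].
#' @param control A [sim_control()].
#' @return Tibble with columns `family`, `s`, `duration`, `willingness`,
#'   `followup` (durations in days; `NA` duration marks a one-visit illness).
#' @export
sample_acute_illness <- function(n, age, families, mix,
                                 control = sim_control()) {
  ctl <- as_sim_control(control)
  row <- stats::setNames(as.numeric(mix[age$name, ]), colnames(mix))
  fam_idx <- sample_family_idx(n, families, row)
  if (any(families$chronic[fam_idx])) {
    rlang::abort("acute mixing matrix assigns mass to a chronic family")
  }
  core <- sample_illness_core(families, fam_idx, n, age$duration_factor,
                              age$willingness_factor, ctl)
  tibble::tibble(
    family = families$name[core$fam_idx], s = core$s,
    duration = core$duration, willingness = core$willingness,
    followup = core$followup
  )
}

#' Sample chronic illnesses for an age class
#'
#' As [sample_acute_illness()], but over the chronic mixing matrix; chronic
#' illnesses never carry a duration and their follow-up interval spaces the
#' patient's perpetual regular appointments.
#'
#' @inheritParams sample_acute_illness
#' @param mix Chronic mixing matrix.
#' @return Tibble with columns `family`, `s`, `willingness`, `followup`.
#' @export
sample_chronic_illness <- function(n, age, families, mix,
                                   control = sim_control()) {
  if (is.null(mix)) {
    rlang::abort("no chronic mixing matrix configured for this scenario")
  }
  ctl <- as_sim_control(control)
  row <- stats::setNames(as.numeric(mix[age$name, ]), colnames(mix))
  fam_idx <- sample_family_idx(n, families, row)
  if (!all(families$chronic[fam_idx])) {
    rlang::abort("chronic mixing matrix assigns mass to an acute family")
  }
  core <- sample_illness_core(families, fam_idx, n, age$duration_factor,
                              age$willingness_factor, ctl)
  tibble::tibble(
    family = families$name[core$fam_idx], s = core$s,
    willingness = core$willingness, followup = core$followup
  )
}
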