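#' KPI aggregation, confidence intervals, warm-up testing, sensitivity
#'
#' Every simulation experiment repeats the modeled period over independent
#' runs and reports per-KPI means with Student-t confidence intervals. The
#' warm-up machinery applies an initialization-bias test to per-period KPI
#' series and searches for the smallest truncation at which no tracked
#' indicator rejects. The sensitivity harness varies one numeric input
#' relative to its base value over a grid and re-runs the experiment at each
#' grid point.
#'
#' @name kpi_stats
NULL

#' Utilization of a physician
#'
#' Service time divided by the available working time derived from the
#' opening hours over the (post-warm-up) measurement window; the buffer hour
#' is not part of the denominator, so heavy overtime can push utilization
#' above 1.
#'
#' @param service_h Total service time in hours.
#' @param available_h Total open-window time in hours.
#' @return The utilization fraction, or `NA` when no time was available.
#' @export
utilization <- function(service_h, available_h) {
  ifelse(available_h > 0, service_h / available_h, NA_real_)
}

#' Annual physician contacts per patient
#'
#' The mean number of treatments per physician, scaled to the whole system
#' and divided by the number of patients.
#'
#' @param treatments_per_pcp Mean number of treatments per physician.
#' @param n_pcps Number of physicians.
#' @param n_patients Number of patients.
#' @return Contacts per patient.
#' @export
contact_rate <- function(treatments_per_pcp, n_pcps, n_patients) {
  treatments_per_pcp * n_pcps / n_patients
}

#' Share of walk-ins among treatments
#'
#' @param walkins,treatments Counts (same scope: per physician or total).
#' @return The walk-in fraction of all treatments.
#' @export
walkin_share <- function(walkins, treatments) walkins / treatments

#' Run a replicated simulation experiment
#'
#' Repeats [sim_run()] with consecutive seeds and collects the per-run KPI
#' records.
#'
#' @inheritParams sim_run
#' @param runs Number of independent runs.
#' @param seed Base seed; run `i` uses `seed + i - 1`.
#' @return A `primsim_experiment`: `$runs` (tibble, one row per run),
#'   `$by_pcp`, `$meta`.
#' @export
sim_experiment <- function(sc, runs = 20, days = 91, warmup_days = 0,
                           seed = 1) {
  res <- vector("list", runs)
  for (i in seq_len(runs)) {
    res[[i]] <- sim_run(sc, days = days, warmup_days = warmup_days,
                        seed = seed + i - 1)
  }
  runs_tbl <- dplyr::bind_rows(lapply(seq_along(res), function(i) {
    dplyr::mutate(res[[i]]$kpis, run = i, seed = seed + i - 1,
                  .before = 1)
  }))
  by_pcp <- dplyr::bind_rows(lapply(seq_along(res), function(i) {
    dplyr::mutate(res[[i]]$by_pcp, run = i, .before = 1)
  }))
  structure(
    list(runs = runs_tbl, by_pcp = by_pcp,
         meta = list(scenario = sc$name, runs = runs, days = days,
                     warmup_days = warmup_days, seed = seed)),
    class = "primsim_experiment"
  )
}

#' Summarize an experiment with confidence intervals
#'
#' Per-KPI mean and two-sided Student-t confidence bounds over the
#' independent runs. With a single run the interval is undefined and reported
#' as `NA`.
#'
#' @param x A `primsim_experiment` or a tibble of per-run KPI rows.
#' @param level Confidence level.
#' @return A tibble with columns `kpi`, `mean`, `lower`, `upper`, `n`.
#' @export
summarize_runs <- function(x, level = 0.95) {
  tbl <- if (inherits(x, "primsim_experiment")) x$runs else x
  tbl <- dplyr::select(tbl, -dplyr::any_of(c("run", "seed")))
  long <- tidyr::pivot_longer(tbl, dplyr::everything(),
                              names_to = "kpi", values_to = "value")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$kpi),
    mean = mean(.data$value),
    sd = stats::sd(.data$value),
    n = dplyr::n(),
    .groups = "drop"
  )
  half <- ifelse(out$n >= 2,
                 stats::qt(1 - (1 - level) / 2, out$n - 1) *
                   out$sd / sqrt(out$n),
                 NA_real_)
  dplyr::select(
    dplyr::mutate(out, lower = .data$mean - half, upper = .data$mean + half),
    "kpi", "mean", "lower", "upper", "n"
  )
}

#' Initialization-bias (warm-up) test
#'
#' Two-sided Schruben-Singh-Tierney-type test for initialization bias on a
#' per-period KPI series. The statistic is the normalized area under the
#' standardized partial-sum bridge
#' \deqn{Z = \sqrt{12} \, n^{-3/2} \sum_{k=1}^{n} S_k / \hat\sigma,}
#' where \eqn{S_k = \sum_{i \le k} (\bar Y - Y_i)}; under no initialization
#' bias the partial sums behave like a Brownian bridge and `Z` is referred to
#' a t distribution whose degrees of freedom come from the batch-means
#' variance estimator (5 batches over the last half of the series, the part
#' least affected by any initial transient). An initial negative bias inflates
#' early partial sums and drives `Z` positive; an initial positive bias
#' drives it negative.
#'
#' @param series Numeric KPI series (one value per simulated period), already
#'   truncated by the candidate warm-up.
#' @param alpha Significance level of the two-sided test.
#' @param batches Number of batches for the variance estimator.
#' @return A list: `statistic`, `df`, `p_value`, `reject`.
#' @export
sst_warmup_test <- function(series, alpha = 0.05, batches = 5) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 2 * batches) {
    rlang::abort("series too short for the batch-means variance estimator")
  }
  half <- series[(n - floor(n / 2) + 1):n]
  bsize <- floor(length(half) / batches)
  half <- half[seq_len(bsize * batches)]
  bm <- colMeans(matrix(half, nrow = bsize))
  sigma2 <- bsize * stats::var(bm)          # estimates n * Var(mean) scale
  if (sigma2 <= 0) {
    return(list(statistic = 0, df = batches - 1, p_value = 1, reject = FALSE))
  }
  s <- cumsum(mean(series) - series)
  z <- sqrt(12) * sum(s) / (n^1.5 * sqrt(sigma2))
  df <- batches - 1
  p <- 2 * stats::pt(-abs(z), df)
  list(statistic = z, df = df, p_value = p, reject = p < alpha)
}

#' Find the warm-up truncation for a set of KPI series
#'
#' Increases the truncation in steps and returns the smallest multiple of
#' `step` at which the initialization-bias test does not reject for any of
#' the tracked series.
#'
#' @param series_list A named list of per-period KPI series (or a tibble of
#'   series columns, e.g. the `$series` of a [sim_run()]).
#' @param step Truncation step, in periods.
#' @param alpha Significance level.
#' @param max_frac Largest fraction of the series that may be truncated.
#' @param min_len Shortest series length the test is run on.
#' @return The truncation length in periods, or `NA` (with a warning) when no
#'   acceptable truncation exists within `max_frac`.
#' @export
find_warmup <- function(series_list, step = 5, alpha = 0.05,
                        max_frac = 0.5, min_len = 10) {
  if (is.data.frame(series_list)) {
    series_list <- as.list(series_list[setdiff(names(series_list), "period")])
  }
  if (step <= 0) rlang::abort("`step` must be positive")
  n <- length(series_list[[1]])
  for (trunc in seq(0, floor(n * max_frac), by = step)) {
    ok <- TRUE
    for (s in series_list) {
      s2 <- s[(trunc + 1):length(s)]
      s2 <- s2[!is.na(s2)]
      if (length(s2) < min_len) { ok <- FALSE; break }
      if (sst_warmup_test(s2, alpha = alpha)$reject) { ok <- FALSE; break }
    }
    if (ok) return(trunc)
  }
  rlang::warn("no acceptable warm-up truncation found within `max_frac`")
  NA_integer_
}

#' One-at-a-time sensitivity sweep
#'
#' Varies one numeric scenario input relative to its base value over a
#' `+/- range` grid and re-runs the experiment at every grid point with the
#' same seeds, so that the zero-delta point reproduces the base experiment
#' exactly.
#'
#' @param sc A `primsim_scenario`.
#' @param param Parameter path: either a control parameter name (e.g.
#'   `"service_mean_min"`) or an age-class column prefixed `"age_classes."`
#'   (e.g. `"age_classes.willingness_factor"`, scaled for every class).
#' @param range Relative half-width of the grid (0.2 = +/- 20 %).
#' @param increment Relative step between grid points (0.01 = 1 %).
#' @param runs,days,warmup_days,seed Experiment setup per grid point.
#' @param kpis KPI columns to summarize.
#' @return A `primsim_sweep`: tibble with `delta`, `kpi`, `mean`, `lower`,
#'   `upper`.
#' @export
sensitivity_sweep <- function(sc, param, range = 0.2, increment = 0.01,
                              runs = 5, days = 28, warmup_days = 7, seed = 1,
                              kpis = c("utilization", "rejected_walkins")) {
  deltas <- seq(-range, range, by = increment)
  apply_delta <- function(sc, delta) {
    f <- 1 + delta
    if (startsWith(param, "age_classes.")) {
      col <- sub("^age_classes\\.", "", param)
      if (!col %in% names(sc$age_classes) ||
          !is.numeric(sc$age_classes[[col]])) {
        rlang::abort(paste0("unknown or non-numeric age-class column: ", col))
      }
      sc$age_classes[[col]] <- sc$age_classes[[col]] * f
      if (col == "cancel_prob") {
        sc$age_classes[[col]] <- pmin(1, sc$age_classes[[col]])
      }
    } else if (param == "health_condition") {
      sc$patients$c <- pmin(1, pmax(0, sc$patients$c * f))
    } else if (param %in% names(sc$control) &&
               is.numeric(sc$control[[param]])) {
      sc$control[[param]] <- sc$control[[param]] * f
    } else {
      rlang::abort(paste0("unknown or non-numeric parameter path: ", param))
    }
    sc
  }
  rows <- vector("list", length(deltas))
  for (i in seq_along(deltas)) {
    ex <- sim_experiment(apply_delta(sc, deltas[i]), runs = runs, days = days,
                         warmup_days = warmup_days, seed = seed)
    sm <- summarize_runs(ex)
    sm <- sm[sm$kpi %in% kpis, ]
    rows[[i]] <- dplyr::mutate(sm, delta = deltas[i], .before = 1)
  }
  structure(
    dplyr::bind_rows(rows),
    class = c("primsim_sweep", "tbl_df", "tbl", "data.frame"),
    param = param
  )
}

#' @export
print.primsim_experiment <- function(x, ...) {
  cat(sprintf("<primsim_experiment> %s: %d runs x %d days (+%d warm-up)\n",
              x$meta$scenario, x$meta$runs, x$meta$days, x$meta$warmup_days))
  print(summarize_runs(x), n = 30)
  invisible(x)
}
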