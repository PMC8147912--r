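#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang %||% .data
NULL

#' Tidy a simulation run
#'
#' @param x A `primsim_run`.
#' @param ... Unused.
#' @return A long tibble with columns `kpi`, `value`.
#' @method tidy primsim_run
#' @export
tidy.primsim_run <- function(x, ...) {
  tidyr::pivot_longer(x$kpis, dplyr::everything(),
                      names_to = "kpi", values_to = "value")
}

#' Glance at a simulation run
#'
#' @param x A `primsim_run`.
#' @param ... Unused.
#' @return A one-row tibble with the headline indicators.
#' @method glance primsim_run
#' @export
glance.primsim_run <- function(x, ...) {
  dplyr::select(
    x$kpis, "treatments", "walkins", "walkin_share", "utilization",
    "weekly_overtime_min", "wait_appointment_min", "wait_walkin_min",
    "access_time_d", "access_distance_km"
  )
}

#' Tidy a simulation experiment
#'
#' @param x A `primsim_experiment`.
#' @param level Confidence level for the interval columns.
#' @param ... Unused.
#' @return A tibble with `kpi`, `mean`, `lower`, `upper`, `n`.
#' @method tidy primsim_experiment
#' @export
tidy.primsim_experiment <- function(x, level = 0.95, ...) {
  summarize_runs(x, level = level)
}

#' Glance at a simulation experiment
#'
#' @param x A `primsim_experiment`.
#' @param ... Unused.
#' @return A one-row tibble: scenario label, runs, days, warm-up.
#' @method glance primsim_experiment
#' @export
glance.primsim_experiment <- function(x, ...) {
  tibble::tibble(scenario = x$meta$scenario, runs = x$meta$runs,
                 days = x$meta$days, warmup_days = x$meta$warmup_days)
}

#' Plot an experiment summary
#'
#' Dot-and-interval plot of per-KPI means with their confidence intervals.
#'
#' @param object A `primsim_experiment`.
#' @param kpis Which KPI columns to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot primsim_experiment
#' @export
autoplot.primsim_experiment <- function(object,
                                        kpis = c("treatments", "walkins",
                                                 "utilization",
                                                 "wait_walkin_min"),
                                        ...) {
  sm <- summarize_runs(object)
  sm <- sm[sm$kpi %in% kpis, ]
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$mean, y = .data$kpi)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lower, xmax = .data$upper), height = 0.2) +
    ggplot2::facet_wrap(~kpi, scales = "free", ncol = 1) +
    ggplot2::labs(x = "mean and 95% CI", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity sweep
#'
#' Mean KPI values (with confidence ribbons) against the relative input
#' variation.
#'
#' @param object A `primsim_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot primsim_sweep
#' @export
autoplot.primsim_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$delta, y = .data$mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper), alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~kpi, scales = "free_y") +
    ggplot2::scale_x_continuous(labels = function(x) sprintf("%+.0f%%", 100 * x)) +
    ggplot2::labs(x = sprintf("relative change in %s", attr(object, "param")),
                  y = "mean and 95% CI") +
    ggplot2::theme_minimal()
}

#' Plot per-period KPI series of a run
#'
#' The visual companion of the warm-up analysis: per-period series of access
#' time, walk-in waiting time, and overtime.
#'
#' @param object A `primsim_run` produced with `series_period_days`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot primsim_run
#' @export
autoplot.primsim_run <- function(object, ...) {
  if (is.null(object$series)) {
    rlang::abort("run has no per-period series; set `series_period_days`")
  }
  long <- tidyr::pivot_longer(object$series, -"period",
                              names_to = "kpi", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$period, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~kpi, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "simulated period", y = NULL) +
    ggplot2::theme_minimal()
}
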