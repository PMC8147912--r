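#' Simulation control parameters
#'
#' Collects every tunable knob of the simulator with its default. All values
#' travel inside the scenario, so a scenario file fully determines a run.
#'
#' @param seriousness_mode Mode of the triangular seriousness distribution on
#'   `[0, 1]`.
#' @param duration_cv Coefficient of variation of the log-normal illness
#'   duration around its age-adjusted family mean.
#' @param willingness_shape Weibull shape `k` of the willingness to wait.
#' @param service_mean_min Mean service time in minutes (log-normal).
#' @param service_cv Coefficient of variation of service times.
#' @param slot_min Appointment slot length in minutes (one patient per slot);
#'   by convention the mean service time rounded up to 5 minutes.
#' @param congestion_queue Queue length above which the physician speeds up.
#' @param speed_factor Multiplier (< 1) on the mean service time under
#'   congestion.
#' @param punctuality_sd_min SD (minutes) of the appointment punctuality
#'   offset; arrivals are clamped into the session window.
#' @param walkin_beta Two beta shape parameters positioning walk-in arrivals
#'   within the open window.
#' @param theta0_min,theta_step_min,theta_min_min,theta_max_min Admission
#'   threshold (minutes): initial value, additive learning step, bounds.
#' @param theta_emergency_bonus_min Extra threshold slack for emergencies.
#' @param idle_learn_min Idle minutes within a session above which the
#'   threshold loosens.
#' @param buffer_hours Post-session buffer during which admitted work
#'   continues without counting as overtime.
#' @param w_dist,w_match Weights of the distance kernel and the
#'   availability/opening-hour overlap in initial ratings.
#' @param dist_scale_km Half-rating distance `d0` of the kernel
#'   `1 / (1 + d / d0)`.
#' @param rating_factors Named multiplicative update factors for the five
#'   experience kinds.
#' @param long_wait_min Waiting time (minutes) above which a visit counts as
#'   a negative experience.
#' @param switch_margin Relative rating advantage a challenger needs before a
#'   chronic patient switches family physician.
#' @param n_consider Size of each patient's consideration set (nearest PCPs).
#' @param followup_tol_frac Follow-up bookings are sought within
#'   `target +/- followup_tol_frac * interval`.
#' @param regular_retry_days Retry delay when no regular-care slot is found.
#' @param ontime_min Treatment starting within this many minutes of the
#'   scheduled time counts as on time.
#' @param deterministic If `TRUE`, every sampler collapses to its mean (the
#'   hand-checkable zero-variance mode).
#' @return A named list of class `sim_control`.
#' @export
sim_control <- function(seriousness_mode = 0.3,
                        duration_cv = 0.25,
                        willingness_shape = 2,
                        service_mean_min = 7,
                        service_cv = 0.25,
                        slot_min = 10,
                        congestion_queue = 4,
                        speed_factor = 0.8,
                        punctuality_sd_min = 5,
                        walkin_beta = c(2, 2),
                        theta0_min = 0,
                        theta_step_min = 5,
                        theta_min_min = -60,
                        theta_max_min = 60,
                        theta_emergency_bonus_min = 30,
                        idle_learn_min = 30,
                        buffer_hours = 1,
                        w_dist = 1,
                        w_match = 1,
                        dist_scale_km = 5,
                        rating_factors = c(
                          request_granted = 1.1,
                          request_failed = 0.8,
                          short_wait = 1.05,
                          long_wait = 0.9,
                          rejected_at_door = 0.6
                        ),
                        long_wait_min = 30,
                        switch_margin = 0.2,
                        n_consider = 5,
                        followup_tol_frac = 0.25,
                        regular_retry_days = 7,
                        ontime_min = 5,
                        deterministic = FALSE) {
  ctl <- as.list(environment())
  need <- c("request_granted", "request_failed", "short_wait", "long_wait",
            "rejected_at_door")
  if (!all(need %in% names(ctl$rating_factors))) {
    rlang::abort("`rating_factors` must name all five experience kinds")
  }
  if (ctl$theta_min_min > ctl$theta_max_min) {
    rlang::abort("threshold bounds must satisfy theta_min <= theta_max")
  }
  structure(ctl, class = c("sim_control", "list"))
}

# merge user-supplied values (e.g. from a scenario file) over the defaults
as_sim_control <- function(x) {
  if (inherits(x, "sim_control")) return(x)
  base <- sim_control()
  if (!is.null(x)) {
    for (nm in intersect(names(x), names(base))) {
      v <- x[[nm]]
      if (nm == "rating_factors") v <- unlist(v)
      if (nm == "walkin_beta") v <- as.numeric(unlist(v))
      base[[nm]] <- v
    }
  }
  sim_control(
    seriousness_mode = base$seriousness_mode, duration_cv = base$duration_cv,
    willingness_shape = base$willingness_shape,
    service_mean_min = base$service_mean_min, service_cv = base$service_cv,
    slot_min = base$slot_min, congestion_queue = base$congestion_queue,
    speed_factor = base$speed_factor,
    punctuality_sd_min = base$punctuality_sd_min,
    walkin_beta = base$walkin_beta, theta0_min = base$theta0_min,
    theta_step_min = base$theta_step_min, theta_min_min = base$theta_min_min,
    theta_max_min = base$theta_max_min,
    theta_emergency_bonus_min = base$theta_emergency_bonus_min,
    idle_learn_min = base$idle_learn_min, buffer_hours = base$buffer_hours,
    w_dist = base$w_dist, w_match = base$w_match,
    dist_scale_km = base$dist_scale_km, rating_factors = base$rating_factors,
    long_wait_min = base$long_wait_min, switch_margin = base$switch_margin,
    n_consider = base$n_consider, followup_tol_frac = base$followup_tol_frac,
    regular_retry_days = base$regular_retry_days, ontime_min = base$ontime_min,
    deterministic = isTRUE(base$deterministic)
  )
}
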