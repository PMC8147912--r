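#' Physician strategies: scheduling, treatment order, admission
#'
#' Each physician runs three interchangeable strategies. The case-study set
#' implemented here comprises: an individual-block/fixed-interval appointment
#' scheduling strategy (a fixed slot grid inside the opening hours, one
#' patient per slot, earliest free slot offered); a priority
#' first-come-first-served (PFCFS) treatment strategy (appointment holders
#' strictly before walk-ins, emergencies before ordinary walk-ins, FCFS
#' within class) with demand-dependent log-normal service times; and a
#' priority-threshold admission strategy whose threshold adapts by
#' end-of-buffer learning. Alternative strategies can be plugged in by
#' replacing these functions in the scenario's strategy registry.
#'
#' @name strategies
NULL

#' Appointment slot grid of a session
#'
#' @param open,close Decimal times of the session window.
#' @param slot_min Slot length in minutes.
#' @return Numeric vector of slot start times (decimal time); one patient
#'   per slot, all slots inside the opening hours.
#' @export
slot_grid <- function(open, close, slot_min) {
  len <- slot_min / 1440
  n <- floor(((close - open) + 1e-12) / len)
  if (n <= 0) return(numeric(0))
  open + (seq_len(n) - 1) * len
}

#' Create an empty appointment calendar
#'
#' A calendar stores, per physician and session, which grid slots are taken
#' and by whom. It is a mutable environment shared by the booking functions.
#'
#' @return An empty calendar object.
#' @export
new_calendar <- function() {
  structure(new.env(parent = emptyenv()), class = "primsim_calendar")
}

cal_key <- function(pcp, day, half) paste0(pcp, ".", day, ".", half)

cal_get <- function(cal, pcp, day, half, n_slots) {
  k <- cal_key(pcp, day, half)
  v <- get0(k, envir = cal, inherits = FALSE)
  if (is.null(v)) v <- integer(n_slots)
  v
}

#' Offer (and book) the earliest feasible appointment slot
#'
#' Searches the physician's slot grid for the earliest free slot strictly
#' after `after` and no later than `until`, restricted to sessions in which
#' the patient is available. Returns `NULL` when no such slot exists (the
#' request fails); otherwise books the slot for `patient` and returns it.
#'
#' @param cal Calendar from [new_calendar()].
#' @param pcp Physician id.
#' @param hours The physician's 14 x 2 opening-hours matrix.
#' @param avail The patient's 14-long logical availability vector (use
#'   `rep(TRUE, 14)` for an always-available patient).
#' @param after Scalar time; offered slots must satisfy `t > after`.
#' @param until Scalar time; offered slots must satisfy `t <= until`.
#' @param slot_min Slot length in minutes.
#' @param patient Patient id to book (0 books anonymously).
#' @param book If `FALSE`, only probe without booking.
#' @return A list `(time, day, half, slot)`, or `NULL`.
#' @export
offer_slot <- function(cal, pcp, hours, avail, after, until, slot_min,
                       patient = 0L, book = TRUE) {
  if (until <= after) return(NULL)
  d0 <- floor(after + 1e-12)
  d1 <- floor(until + 1e-12)
  for (d in d0:d1) {
    for (g in 0:1) {
      cid <- weekly_class_id(d, g)
      if (!avail[cid]) next
      op <- hours[cid, 1]
      if (is.na(op)) next
      cl <- hours[cid, 2]
      if (d + op > until + .time_eps) next        # session starts too late
      if (d + cl <= after) next                   # session already over
      starts <- d + slot_grid(op, cl, slot_min)
      if (length(starts) == 0) next
      taken <- cal_get(cal, pcp, d, g, length(starts))
      ok <- which(taken == 0L & starts > after + .time_eps &
                    starts <= until + .time_eps)
      if (length(ok) > 0) {
        i <- ok[1]
        if (book) {
          # 0 books anonymously; occupied slots are always non-zero
          taken[i] <- if (patient == 0) -1L else as.integer(patient)
          assign(cal_key(pcp, d, g), taken, envir = cal)
        }
        return(list(time = starts[i], day = d, half = g, slot = i))
      }
    }
  }
  NULL
}

#' Free a previously booked slot
#'
#' @inheritParams offer_slot
#' @param day,half,slot Slot coordinates as returned by [offer_slot()].
#' @return Invisibly, the calendar.
#' @export
free_slot <- function(cal, pcp, day, half, slot) {
  k <- cal_key(pcp, day, half)
  v <- get0(k, envir = cal, inherits = FALSE)
  if (!is.null(v) && slot <= length(v)) {
    v[slot] <- 0L
    assign(k, v, envir = cal)
  }
  invisible(cal)
}

# booked appointments of a session that are still ahead of `now_frac`
booked_after <- function(cal, pcp, day, half, hours, slot_min, now_frac) {
  cid <- weekly_class_id(day, half)
  op <- hours[cid, 1]
  if (is.na(op)) return(0L)
  starts <- slot_grid(op, hours[cid, 2], slot_min)
  if (length(starts) == 0) return(0L)
  taken <- cal_get(cal, pcp, day, half, length(starts))
  sum(taken != 0L & starts > now_frac)
}

#' Select the next patient under priority FCFS
#'
#' Appointment holders are treated strictly before walk-ins, emergency
#' walk-ins before ordinary walk-ins, and first-come-first-served (by
#' arrival) within each class.
#'
#' @param room Tibble of present patients with columns `patient`,
#'   `class` (1 = appointment, 2 = emergency walk-in, 3 = walk-in), and
#'   `arrival` (arrival order/time).
#' @return The row index of the patient to treat next.
#' @export
next_patient_pfcfs <- function(room) {
  if (nrow(room) == 0) rlang::abort("waiting room is empty")
  order(room$class, room$arrival, room$patient)[1]
}

#' Draw a demand-dependent service time
#'
#' Log-normal service times around the configured mean; when the queue
#' exceeds the congestion threshold the physician consciously speeds up and
#' the mean shrinks by the speed factor.
#'
#' @param n Number of draws.
#' @param queue_len Patients currently waiting (excluding the one entering
#'   service).
#' @param control A [sim_control()].
#' @return Service durations in days (strictly positive).
#' @export
service_time <- function(n = 1, queue_len = 0, control = sim_control()) {
  ctl <- as_sim_control(control)
  mean_min <- ctl$service_mean_min *
    ifelse(queue_len > ctl$congestion_queue, ctl$speed_factor, 1)
  rlnorm_mean_cv(n, mean_min, if (ctl$deterministic) 0 else ctl$service_cv) /
    1440
}

#' Priority-threshold admission decision
#'
#' Appointment holders are always admitted (admitted patients must be
#' treated). A walk-in is admitted iff the predicted completion time of all
#' present plus still-booked work fits within the session buffer plus the
#' physician's admission threshold; emergencies enjoy a relaxed threshold.
#'
#' @param kind `"appointment"` or `"walkin"`.
#' @param emergency Is the arriving walk-in flagged as an emergency?
#' @param now Scalar arrival time.
#' @param n_present Patients present (waiting plus in service).
#' @param booked_remaining Booked appointments of the session still ahead.
#' @param theta_min Current admission threshold in minutes.
#' @param buffer_end Scalar time at which the session's buffer ends.
#' @param control A [sim_control()].
#' @return `TRUE` (admit) or `FALSE` (reject).
#' @export
admit <- function(kind, emergency, now, n_present, booked_remaining,
                  theta_min, buffer_end, control = sim_control()) {
  if (kind == "appointment") return(TRUE)
  ctl <- as_sim_control(control)
  mean_min <- ctl$service_mean_min *
    if (n_present > ctl$congestion_queue) ctl$speed_factor else 1
  predicted <- now + (n_present + 1 + booked_remaining) * mean_min / 1440
  slack <- theta_min + if (emergency) ctl$theta_emergency_bonus_min else 0
  predicted <= buffer_end + slack / 1440 + .time_eps
}

#' End-of-buffer threshold learning
#'
#' After each session the physician reevaluates: realized overtime tightens
#' the admission threshold by one additive step, substantial idle time
#' loosens it; the threshold stays inside its configured bounds.
#'
#' @param theta_min Current threshold in minutes.
#' @param overtime_min Minutes worked past the buffer end this session.
#' @param idle_min Idle minutes within the opening hours this session.
#' @param control A [sim_control()].
#' @return The updated threshold in minutes.
#' @export
learn_threshold <- function(theta_min, overtime_min, idle_min,
                            control = sim_control()) {
  ctl <- as_sim_control(control)
  if (overtime_min > 0) {
    theta_min <- theta_min - ctl$theta_step_min
  } else if (idle_min >= ctl$idle_learn_min) {
    theta_min <- theta_min + ctl$theta_step_min
  }
  min(max(theta_min, ctl$theta_min_min), ctl$theta_max_min)
}
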