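#' Discrete-event simulation engine
#'
#' A run processes a sequential event queue in chronological order up to the
#' horizon. Patients' illness onsets trigger care-seeking (up to two
#' appointment requests in rating order, walk-in fallback), physicians open
#' and close weekly-recurring sessions with a post-session buffer, admit
#' patients under the priority-threshold strategy, treat them in PFCFS order
#' with demand-dependent service times, and adapt their admission threshold
#' at the end of each buffer. Key performance indicators are accumulated only
#' after the warm-up period (empty-state initialization). Identical scenario,
#' horizon, and seed give bit-identical results; the run seed feeds separate
#' substreams per stochastic concern (onsets, illness traits, service times,
#' arrivals, behavioral choices) so that changing one model component leaves
#' unrelated draws untouched.
#'
#' @name engine
NULL

# event kinds
EV_ONSET <- 1L; EV_RECOVERY <- 2L; EV_APPT_ARR <- 3L; EV_WALK_ARR <- 4L
EV_SESS_OPEN <- 5L; EV_SESS_CLOSE <- 6L; EV_BUFFER_END <- 7L
EV_TREAT_DONE <- 8L; EV_REG_DUE <- 9L

EV_NAMES <- c("onset", "recovery", "appointment_arrival", "walkin_arrival",
              "session_open", "session_close", "buffer_end",
              "treatment_complete", "regular_due")

# simultaneous-event priority: session_open < onsets/recoveries/due <
# arrivals < treatment_complete < session_close < buffer_end; then kind,
# then first payload id (reproducible total order)
EV_PRIO <- c(2L, 2L, 3L, 3L, 1L, 5L, 6L, 4L, 2L)

# The queue stores one packed payload double per event
# (a + b*1e7 + c*1e9 + kind*1e15; all components are small non-negative
# integers, so the packing is exact in doubles) plus a sort key
# time + priority * 1e-11. Free capacity is padded with Inf so the pop is a
# single which.min over the full vector, no subsetting, no reallocation.

ev_push <- function(st, time, kind, a = 0, b = 0, c = 0) {
  n <- st$ev_n + 1L
  if (n > st$ev_cap) {
    grow <- st$ev_cap
    st$ev_key <- c(st$ev_key, rep(Inf, grow))
    st$ev_pay <- c(st$ev_pay, numeric(grow))
    st$ev_cap <- st$ev_cap + grow
  }
  st$ev_key[n] <- time + EV_PRIO[kind] * 1e-11
  st$ev_pay[n] <- a + b * 1e7 + c * 1e9 + kind * 1e15
  st$ev_n <- n
  invisible(NULL)
}

# the event time is recovered as key - priority * 1e-11 (round-trip error is
# below 1e-13 days, far inside the 1e-9 comparison tolerance)
ev_pop <- function(st) {
  i <- which.min(st$ev_key)
  key <- st$ev_key[i]; pay <- st$ev_pay[i]
  n <- st$ev_n
  if (i != n) {
    st$ev_key[i] <- st$ev_key[n]
    st$ev_pay[i] <- st$ev_pay[n]
  }
  st$ev_key[n] <- Inf
  st$ev_n <- n - 1L
  c(key, pay)
}

# independent RNG substreams derived from the root seed
stream_init <- function(st, seed) {
  names <- c("onset", "illness", "service", "arrival", "choice")
  st$streams <- stats::setNames(vector("list", length(names)), names)
  for (i in seq_along(names)) {
    sub <- (as.numeric(seed) * 48271 + i * 7919) %% 2147483629
    set.seed(as.integer(sub))
    st$streams[[i]] <- get(".Random.seed", envir = .GlobalEnv)
  }
}

stream_eval <- function(st, name, fun) {
  assign(".Random.seed", st$streams[[name]], envir = .GlobalEnv)
  out <- fun()
  st$streams[[name]] <- get(".Random.seed", envir = .GlobalEnv)
  out
}

# ---- run-state construction ------------------------------------------------

build_run_state <- function(sc, horizon, warmup, seed, series_period = NA) {
  ctl <- sc$control
  st <- new.env(parent = emptyenv())
  st$ctl <- ctl; st$horizon <- horizon; st$warmup <- warmup
  st$now <- 0
  np <- nrow(sc$patients); ng <- nrow(sc$pcps)
  st$np <- np; st$ng <- ng
  stream_init(st, seed)

  # patients
  p <- sc$patients
  ac <- sc$age_classes
  st$p_age <- match(p$age, ac$name)
  st$p_rate <- eval_linfun(ac$i_slope[st$p_age], ac$i_int[st$p_age], p$c)
  st$p_dfac <- ac$duration_factor[st$p_age]
  st$p_wfac <- ac$willingness_factor[st$p_age]
  st$p_cancel <- ac$cancel_prob[st$p_age]
  st$p_avail <- matrix(unlist(p$avail), nrow = np, byrow = TRUE)
  st$p_chronic <- p$chronic
  st$emergency <- logical(np)
  st$acute_appt <- integer(np)
  st$reg_appt <- integer(np)
  st$p_nact <- integer(np)
  st$p_ills <- vector("list", np)
  st$p_deadline <- numeric(np)
  st$p_retries <- integer(np)

  # physicians
  st$hours <- sc$pcps$hours
  st$g_id <- sc$pcps$id
  st$cal <- new_calendar()
  st$g_theta <- rep(ctl$theta0_min, ng)
  st$g_busy <- logical(ng)
  st$g_busy_pat <- integer(ng); st$g_busy_role <- integer(ng)
  st$g_serv_start <- numeric(ng); st$g_busy_until <- numeric(ng)
  st$g_open_t <- rep(-1, ng); st$g_close_t <- rep(-1, ng)
  st$g_buffer_t <- rep(-1, ng)
  st$g_sess_day <- integer(ng); st$g_sess_half <- integer(ng)
  st$g_in_session <- logical(ng); st$g_learn_pending <- logical(ng)
  st$g_idle_from <- rep(-1, ng); st$g_idle_acc <- numeric(ng)
  st$room_pat <- rep(list(integer(0)), ng)
  st$room_class <- rep(list(integer(0)), ng)
  st$room_arr <- rep(list(numeric(0)), ng)
  st$room_appt <- rep(list(integer(0)), ng)
  st$room_arrt <- rep(list(numeric(0)), ng)
  st$arr_counter <- 0

  # distances, consideration sets, ratings
  dm <- matrix(0, np, ng)
  for (g in seq_len(ng)) {
    dm[, g] <- distance_km(p$lat, p$lon, sc$pcps$lat[g], sc$pcps$lon[g])
  }
  st$dist <- dm
  k <- min(ctl$n_consider, ng)
  cons <- t(apply(dm, 1, function(d) sort.int(order(d)[seq_len(k)])))
  if (k == 1) cons <- matrix(cons, ncol = 1)
  st$consider <- cons
  open_m <- vapply(st$hours, open_classes, logical(14))   # 14 x ng
  kernel <- ctl$w_dist * dist_kernel(dm, ctl$dist_scale_km)
  match_m <- (st$p_avail %*% open_m) / 14                 # np x ng
  base <- kernel + ctl$w_match * match_m
  considered <- matrix(FALSE, np, ng)
  considered[cbind(rep(seq_len(np), k), as.integer(cons))] <- TRUE
  st$r_app <- base * considered
  walk <- array(0, c(np, ng, 14))
  for (cid in 1:14) {
    feas <- considered & outer(st$p_avail[, cid], open_m[cid, ], `&`)
    walk[, , cid] <- base * feas
  }
  st$r_walk <- walk

  # chronic traits
  fam <- sc$families
  st$fam <- fam
  st$p_cfam <- match(p$chronic_family, fam$name)
  st$p_cs <- p$chronic_s
  st$p_cnu <- ifelse(is.na(st$p_cfam), NA_real_,
                     eval_linfun(fam$n_slope[st$p_cfam],
                                 fam$n_int[st$p_cfam], st$p_cs))
  st$p_cwill <- ifelse(is.na(st$p_cfam), NA_real_,
                       eval_linfun(fam$w_slope[st$p_cfam],
                                   fam$w_int[st$p_cfam], st$p_cs) * st$p_wfac)
  st$fam_phys <- integer(np)

  # per-age acute mixing (cumulative) for fast family draws
  mixm <- sc$acute_mix[ac$name, , drop = FALSE]
  st$mix_fam_idx <- match(colnames(mixm), fam$name)
  st$mix_cum <- matrix(t(apply(mixm, 1, cumsum)), nrow = nrow(mixm))

  # illness store
  cap <- 1024L
  st$ill_n <- 0L
  st$ill_pat <- integer(cap); st$ill_fam <- integer(cap)
  st$ill_s <- numeric(cap); st$ill_dur <- numeric(cap)
  st$ill_nu <- numeric(cap); st$ill_end <- numeric(cap)
  st$ill_onset <- numeric(cap); st$ill_active <- logical(cap)

  # appointment store
  acap <- 1024L
  st$ap_n <- 0L
  st$ap_time <- numeric(acap); st$ap_pcp <- integer(acap)
  st$ap_pat <- integer(acap); st$ap_role <- integer(acap)
  st$ap_day <- integer(acap); st$ap_half <- integer(acap)
  st$ap_slot <- integer(acap); st$ap_status <- integer(acap)

  # event queue
  st$ev_cap <- 4096L
  st$ev_key <- rep(Inf, 4096L)
  st$ev_pay <- numeric(4096L)
  st$ev_n <- 0L

  # accumulators
  zg <- numeric(ng)
  st$k_treat <- zg; st$k_walk <- zg; st$k_appt_acute <- zg
  st$k_appt_reg <- zg; st$k_serv <- zg; st$k_over <- zg
  st$k_rej_walk <- zg; st$k_rej_appt <- zg; st$k_open <- zg
  st$k_attended <- 0; st$k_ontime <- 0
  st$k_acc_acute <- 0; st$k_acc_acute_n <- 0
  st$k_acc_reg <- 0; st$k_acc_reg_n <- 0
  st$k_dist <- 0; st$k_dist_n <- 0
  st$k_wait_appt <- 0; st$k_wait_appt_n <- 0
  st$k_wait_walk <- 0; st$k_wait_walk_n <- 0
  st$k_onsets <- 0; st$k_forgone <- 0; st$k_cancel <- 0
  st$k_arrivals <- 0; st$k_admit <- 0; st$k_reject <- 0

  # optional per-period series
  st$series_period <- series_period
  if (!is.na(series_period)) {
    st$se_n <- ceiling(horizon / series_period)
    st$se_acc <- matrix(0, st$se_n, 6)
  }

  st$do_trace <- FALSE
  st$trace_lines <- NULL
  st$audit_double <- 0L
  st
}

# ---- stores ----------------------------------------------------------------

register_illness <- function(st, pat, fam_idx, s, dur, will, nu, onset) {
  n <- st$ill_n + 1L
  if (n > length(st$ill_pat)) {
    g <- length(st$ill_pat)
    st$ill_pat <- c(st$ill_pat, integer(g)); st$ill_fam <- c(st$ill_fam, integer(g))
    st$ill_s <- c(st$ill_s, numeric(g)); st$ill_dur <- c(st$ill_dur, numeric(g))
    st$ill_nu <- c(st$ill_nu, numeric(g)); st$ill_end <- c(st$ill_end, numeric(g))
    st$ill_onset <- c(st$ill_onset, numeric(g))
    st$ill_active <- c(st$ill_active, logical(g))
  }
  st$ill_pat[n] <- pat; st$ill_fam[n] <- fam_idx; st$ill_s[n] <- s
  st$ill_dur[n] <- dur; st$ill_nu[n] <- nu; st$ill_onset[n] <- onset
  st$ill_end[n] <- if (is.na(dur)) Inf else onset + dur
  st$ill_active[n] <- TRUE
  st$ill_n <- n
  st$p_nact[pat] <- st$p_nact[pat] + 1L
  st$p_ills[[pat]] <- c(st$p_ills[[pat]], n)
  n
}

register_appt <- function(st, time, g, pat, role, day, half, slot) {
  n <- st$ap_n + 1L
  if (n > length(st$ap_time)) {
    gr <- length(st$ap_time)
    st$ap_time <- c(st$ap_time, numeric(gr)); st$ap_pcp <- c(st$ap_pcp, integer(gr))
    st$ap_pat <- c(st$ap_pat, integer(gr)); st$ap_role <- c(st$ap_role, integer(gr))
    st$ap_day <- c(st$ap_day, integer(gr)); st$ap_half <- c(st$ap_half, integer(gr))
    st$ap_slot <- c(st$ap_slot, integer(gr)); st$ap_status <- c(st$ap_status, integer(gr))
  }
  st$ap_time[n] <- time; st$ap_pcp[n] <- g; st$ap_pat[n] <- pat
  st$ap_role[n] <- role; st$ap_day[n] <- as.integer(day)
  st$ap_half[n] <- as.integer(half)
  st$ap_slot[n] <- as.integer(slot); st$ap_status[n] <- 0L
  st$ap_n <- n
  n
}

# schedule the physical arrival for a booked appointment (punctuality offset,
# clamped into the session's open window and after the booking instant)
schedule_appt_arrival <- function(st, ap, booked_at) {
  ctl <- st$ctl
  off <- stream_eval(st, "arrival", function() {
    rpunctuality(1, if (ctl$deterministic) 0 else ctl$punctuality_sd_min)
  })
  g <- st$ap_pcp[ap]
  cid <- weekly_class_id(st$ap_day[ap], st$ap_half[ap])
  h <- st$hours[[g]]
  lo <- st$ap_day[ap] + h[cid, 1]
  hi <- st$ap_day[ap] + h[cid, 2]
  arr <- min(max(st$ap_time[ap] + off, lo), hi - .time_eps)
  arr <- max(arr, booked_at + .time_eps)
  ev_push(st, arr, EV_APPT_ARR, ap)
}

# ---- care-seeking ----------------------------------------------------------

book_acute <- function(st, pat, g, slot, request_time) {
  # a patient can never hold two acute appointments; audited per run
  if (st$acute_appt[pat] != 0L) st$audit_double <- st$audit_double + 1L
  apid <- register_appt(st, slot$time, g, pat, 1L, slot$day, slot$half,
                        slot$slot)
  st$acute_appt[pat] <- apid
  if (request_time >= st$warmup) {
    st$k_appt_acute[g] <- st$k_appt_acute[g] + 1
    st$k_acc_acute <- st$k_acc_acute + (slot$time - request_time)
    st$k_acc_acute_n <- st$k_acc_acute_n + 1
    series_acc(st, request_time, 1, slot$time - request_time)
  }
  schedule_appt_arrival(st, apid, request_time)
  apid
}

# up to two appointment requests in rating order; walk-in fallback
seek_initial_care <- function(st, pat, t, will) {
  ctl <- st$ctl
  ap <- st$acute_appt[pat]
  if (ap != 0L && st$ap_status[ap] == 0L &&
      st$ap_time[ap] <= t + will + .time_eps) {
    return(invisible(NULL))   # existing acute appointment is reused
  }
  st$p_deadline[pat] <- t + will
  st$p_retries[pat] <- 0L
  if (ap == 0L) {
    cons <- st$consider[pat, ]
    r <- st$r_app[pat, cons]
    ord <- order(-r, cons)
    targets <- cons[ord][seq_len(min(2L, length(cons)))]
    for (g in targets) {
      slot <- offer_slot(st$cal, g, st$hours[[g]], st$p_avail[pat, ],
                         after = t, until = t + will, slot_min = ctl$slot_min,
                         patient = pat)
      if (!is.null(slot)) {
        st$r_app[pat, g] <- st$r_app[pat, g] *
          ctl$rating_factors[["request_granted"]]
        book_acute(st, pat, g, slot, t)
        return(invisible(NULL))
      }
      st$r_app[pat, g] <- st$r_app[pat, g] *
        ctl$rating_factors[["request_failed"]]
    }
  }
  # both requests failed (or the held appointment is too late):
  # forgo an appointment and visit as a walk-in
  plan_walkin(st, pat, t, st$p_deadline[pat])
}

# choose the best feasible (physician, session) walk-in pair and schedule the
# arrival; forgo care when nothing is feasible within the window
plan_walkin <- function(st, pat, t, deadline, skip_g = 0L, skip_sess = -1L) {
  ctl <- st$ctl
  cons <- st$consider[pat, ]
  best_r <- -1; best_g <- 0L; best_key <- -1L
  best_lo <- 0; best_hi <- 0
  d1 <- floor(deadline + 1e-12)
  for (d in floor(t + 1e-12):d1) {
    for (hf in 0:1) {
      cid <- weekly_class_id(d, hf)
      if (!st$p_avail[pat, cid]) next
      sess_key <- d * 2L + hf
      for (g in cons) {
        if (g == skip_g && sess_key == skip_sess) next
        h <- st$hours[[g]]
        op <- h[cid, 1]
        if (is.na(op)) next
        cl <- h[cid, 2]
        if (d + cl <= t + .time_eps) next      # session already over
        if (d + op > deadline + .time_eps) next
        r <- st$r_walk[pat, g, cid]
        if (r > best_r + 1e-12) {
          best_r <- r; best_g <- g; best_key <- sess_key
          best_lo <- d + op; best_hi <- d + cl
        }
      }
    }
  }
  if (best_g == 0L) {
    # no session inside the willingness window: patients always seek
    # treatment, so the visit targets the next feasible session (best rating
    # within the earliest day that offers one); only a fortnight without any
    # feasible session makes the patient forgo care for this cycle
    d <- floor(t + 1e-12)
    while (best_g == 0L && d <= floor(t) + 14L) {
      for (hf in 0:1) {
        cid <- weekly_class_id(d, hf)
        if (!st$p_avail[pat, cid]) next
        sess_key <- d * 2L + hf
        for (g in cons) {
          if (g == skip_g && sess_key == skip_sess) next
          h <- st$hours[[g]]
          op <- h[cid, 1]
          if (is.na(op)) next
          if (d + h[cid, 2] <= t + .time_eps) next
          r <- st$r_walk[pat, g, cid]
          if (best_g == 0L || sess_key < best_key ||
              (sess_key == best_key && r > best_r + 1e-12)) {
            if (best_g != 0L && sess_key > best_key) next
            best_r <- r; best_g <- g; best_key <- sess_key
            best_lo <- d + op; best_hi <- d + h[cid, 2]
          }
        }
        if (best_g != 0L) break
      }
      d <- d + 1L
    }
  }
  if (best_g == 0L) {
    if (t >= st$warmup) st$k_forgone <- st$k_forgone + 1
    st$emergency[pat] <- FALSE
    return(invisible(NULL))
  }
  lo <- max(best_lo, t + .time_eps)
  frac <- stream_eval(st, "arrival", function() {
    rarrival_fraction(1, ctl$walkin_beta[1], ctl$walkin_beta[2],
                      degenerate = ctl$deterministic)
  })
  arr <- lo + frac * (best_hi - lo - .time_eps)
  ev_push(st, arr, EV_WALK_ARR, pat, best_g, best_key)
  invisible(NULL)
}

# book the next regular (chronic-care) appointment targeted at `target`
book_regular <- function(st, pat, t, target) {
  ctl <- st$ctl
  g <- st$fam_phys[pat]
  lo <- max(t, target)
  slot <- offer_slot(st$cal, g, st$hours[[g]], st$p_avail[pat, ],
                     after = lo, until = lo + max(st$p_cwill[pat], 1),
                     slot_min = ctl$slot_min, patient = pat)
  if (!is.null(slot)) {
    apid <- register_appt(st, slot$time, g, pat, 2L, slot$day, slot$half,
                          slot$slot)
    st$reg_appt[pat] <- apid
    st$r_app[pat, g] <- st$r_app[pat, g] *
      ctl$rating_factors[["request_granted"]]
    if (t >= st$warmup) {
      st$k_appt_reg[g] <- st$k_appt_reg[g] + 1
      st$k_acc_reg <- st$k_acc_reg + (slot$time - lo)
      st$k_acc_reg_n <- st$k_acc_reg_n + 1
    }
    schedule_appt_arrival(st, apid, t)
  } else {
    st$r_app[pat, g] <- st$r_app[pat, g] *
      ctl$rating_factors[["request_failed"]]
    reeval_fam(st, pat)
    ev_push(st, t + ctl$regular_retry_days, EV_REG_DUE, pat)
  }
  invisible(NULL)
}

reeval_fam <- function(st, pat) {
  ctl <- st$ctl
  cons <- st$consider[pat, ]
  r <- st$r_app[pat, cons]
  ord <- order(-r, cons)
  top <- cons[ord][1]
  cur <- st$fam_phys[pat]
  if (top != cur && r[ord][1] > (1 + ctl$switch_margin) * st$r_app[pat, cur]) {
    st$fam_phys[pat] <- top
  }
  invisible(NULL)
}

# ---- waiting room / service ------------------------------------------------

enter_room <- function(st, g, pat, class, t, appt) {
  st$arr_counter <- st$arr_counter + 1
  st$room_pat[[g]] <- c(st$room_pat[[g]], pat)
  st$room_class[[g]] <- c(st$room_class[[g]], class)
  st$room_arr[[g]] <- c(st$room_arr[[g]], st$arr_counter)
  st$room_appt[[g]] <- c(st$room_appt[[g]], appt)
  st$room_arrt[[g]] <- c(st$room_arrt[[g]], t)
  invisible(NULL)
}

series_acc <- function(st, t, col, val) {
  if (is.na(st$series_period)) return(invisible(NULL))
  p <- min(st$se_n, 1L + floor(t / st$series_period))
  st$se_acc[p, col] <- st$se_acc[p, col] + val
  st$se_acc[p, col + 1] <- st$se_acc[p, col + 1] + 1
  invisible(NULL)
}

start_service <- function(st, g, t) {
  if (st$g_busy[g] || length(st$room_pat[[g]]) == 0L) return(invisible(NULL))
  ctl <- st$ctl
  cls <- st$room_class[[g]]
  i <- order(cls, st$room_arr[[g]], st$room_pat[[g]])[1]
  pat <- st$room_pat[[g]][i]
  class <- cls[i]
  apid <- st$room_appt[[g]][i]
  arrival_time <- st$room_arrt[[g]][i]
  st$room_pat[[g]] <- st$room_pat[[g]][-i]
  st$room_class[[g]] <- st$room_class[[g]][-i]
  st$room_arr[[g]] <- st$room_arr[[g]][-i]
  st$room_appt[[g]] <- st$room_appt[[g]][-i]
  st$room_arrt[[g]] <- st$room_arrt[[g]][-i]

  # close out an idle spell inside the open window
  if (st$g_idle_from[g] >= 0) {
    a <- max(st$g_idle_from[g], st$g_open_t[g])
    b <- min(t, st$g_close_t[g])
    if (b > a) st$g_idle_acc[g] <- st$g_idle_acc[g] + (b - a)
    st$g_idle_from[g] <- -1
  }

  in_window <- t >= st$warmup
  role <- 0L
  if (class == 1L) {
    sched <- st$ap_time[apid]
    role <- st$ap_role[apid]
    st$ap_status[apid] <- 1L
    if (role == 1L) st$acute_appt[pat] <- 0L else st$reg_appt[pat] <- 0L
    wait <- max(0, t - max(arrival_time, sched))
    if (in_window) {
      st$k_attended <- st$k_attended + 1
      if (t - sched <= ctl$ontime_min / 1440 + .time_eps) {
        st$k_ontime <- st$k_ontime + 1
      }
      st$k_wait_appt <- st$k_wait_appt + wait
      st$k_wait_appt_n <- st$k_wait_appt_n + 1
    }
    exp_kind <- if (wait > ctl$long_wait_min / 1440) "long_wait" else "short_wait"
    st$r_app[pat, g] <- st$r_app[pat, g] * ctl$rating_factors[[exp_kind]]
  } else {
    wait <- t - arrival_time
    if (in_window) {
      st$k_walk[g] <- st$k_walk[g] + 1
      st$k_wait_walk <- st$k_wait_walk + wait
      st$k_wait_walk_n <- st$k_wait_walk_n + 1
      series_acc(st, t, 3, wait)
    }
    cid <- weekly_class_id(st$g_sess_day[g], st$g_sess_half[g])
    exp_kind <- if (wait > ctl$long_wait_min / 1440) "long_wait" else "short_wait"
    st$r_walk[pat, g, cid] <- st$r_walk[pat, g, cid] *
      ctl$rating_factors[[exp_kind]]
  }
  if (in_window) {
    st$k_treat[g] <- st$k_treat[g] + 1
    st$k_dist <- st$k_dist + st$dist[pat, g]
    st$k_dist_n <- st$k_dist_n + 1
  }
  queue_after <- length(st$room_pat[[g]])
  mean_min <- ctl$service_mean_min *
    if (queue_after > ctl$congestion_queue) ctl$speed_factor else 1
  cv <- if (ctl$deterministic) 0 else ctl$service_cv
  dur <- stream_eval(st, "service", function() {
    rlnorm_mean_cv(1, mean_min, cv) / 1440
  })
  st$g_busy[g] <- TRUE
  st$g_busy_pat[g] <- pat
  st$g_busy_role[g] <- role
  st$g_serv_start[g] <- t
  st$g_busy_until[g] <- t + dur
  ev_push(st, t + dur, EV_TREAT_DONE, g)
  invisible(NULL)
}

# ---- event handlers --------------------------------------------------------

handle_onset <- function(st, t) {
  ctl <- st$ctl
  i <- st$on_i
  pat <- st$on_pat[i]
  st$on_i <- i + 1L
  if (st$on_i <= length(st$on_t)) {
    ev_push(st, st$on_t[st$on_i], EV_ONSET)   # one rolling onset event
  }
  draw <- stream_eval(st, "illness", function() {
    u <- stats::runif(1)
    j <- min(findInterval(u, st$mix_cum[st$p_age[pat], ], left.open = TRUE) + 1L,
             length(st$mix_fam_idx))
    sample_illness_core(st$fam, st$mix_fam_idx[j], 1L, st$p_dfac[pat],
                        st$p_wfac[pat], ctl)
  })
  ill <- register_illness(st, pat, draw$fam_idx, draw$s, draw$duration,
                          draw$willingness, draw$followup, t)
  if (t >= st$warmup) st$k_onsets <- st$k_onsets + 1
  if (!is.na(draw$duration)) ev_push(st, t + draw$duration, EV_RECOVERY, ill)
  seek_initial_care(st, pat, t, draw$willingness)
  invisible(NULL)
}

handle_recovery <- function(st, ill, t) {
  if (!st$ill_active[ill]) return(invisible(NULL))
  st$ill_active[ill] <- FALSE
  pat <- st$ill_pat[ill]
  st$p_nact[pat] <- st$p_nact[pat] - 1L
  if (st$p_nact[pat] == 0L) {
    ap <- st$acute_appt[pat]
    if (ap != 0L && st$ap_status[ap] == 0L) {
      cancel <- stream_eval(st, "choice", function() {
        stats::runif(1) < st$p_cancel[pat]
      })
      if (cancel) {
        st$ap_status[ap] <- 2L
        free_slot(st$cal, st$ap_pcp[ap], st$ap_day[ap], st$ap_half[ap],
                  st$ap_slot[ap])
        st$acute_appt[pat] <- 0L
        if (t >= st$warmup) st$k_cancel <- st$k_cancel + 1
      }
    }
    st$emergency[pat] <- FALSE
  }
  invisible(NULL)
}

handle_appt_arrival <- function(st, ap, t) {
  if (st$ap_status[ap] != 0L) return(invisible(NULL))   # cancelled
  g <- st$ap_pcp[ap]; pat <- st$ap_pat[ap]
  if (t >= st$warmup) {
    st$k_arrivals <- st$k_arrivals + 1
    st$k_admit <- st$k_admit + 1    # appointment holders are always admitted
  }
  st$emergency[pat] <- FALSE
  enter_room(st, g, pat, 1L, t, ap)
  start_service(st, g, t)
  invisible(NULL)
}

handle_walkin_arrival <- function(st, pat, g, sess, t) {
  ctl <- st$ctl
  if (st$p_nact[pat] == 0L) return(invisible(NULL))     # recovered meanwhile
  day <- sess %/% 2L; hf <- sess %% 2L
  if (!st$g_in_session[g] || st$g_sess_day[g] != day ||
      st$g_sess_half[g] != hf) {
    return(invisible(NULL))                             # stale session
  }
  if (t >= st$warmup) st$k_arrivals <- st$k_arrivals + 1
  emerg <- st$emergency[pat]
  n_present <- length(st$room_pat[[g]]) + as.integer(st$g_busy[g])
  booked <- booked_after(st$cal, g, day, hf, st$hours[[g]], ctl$slot_min,
                         t - day)
  mean_min <- ctl$service_mean_min *
    if (n_present > ctl$congestion_queue) ctl$speed_factor else 1
  slack <- st$g_theta[g] + if (emerg) ctl$theta_emergency_bonus_min else 0
  ok <- t + (n_present + 1 + booked) * mean_min / 1440 <=
    st$g_buffer_t[g] + slack / 1440 + .time_eps
  if (ok) {
    if (t >= st$warmup) st$k_admit <- st$k_admit + 1
    st$emergency[pat] <- FALSE
    enter_room(st, g, pat, if (emerg) 2L else 3L, t, 0L)
    start_service(st, g, t)
  } else {
    if (t >= st$warmup) {
      st$k_reject <- st$k_reject + 1
      st$k_rej_walk[g] <- st$k_rej_walk[g] + 1
    }
    cid <- weekly_class_id(day, hf)
    st$r_walk[pat, g, cid] <- st$r_walk[pat, g, cid] *
      ctl$rating_factors[["rejected_at_door"]]
    st$emergency[pat] <- TRUE
    st$p_retries[pat] <- st$p_retries[pat] + 1L
    if (st$p_retries[pat] <= 3L * ncol(st$consider) &&
        t < st$p_deadline[pat]) {
      plan_walkin(st, pat, t, st$p_deadline[pat], skip_g = g, skip_sess = sess)
    } else {
      if (t >= st$warmup) st$k_forgone <- st$k_forgone + 1
      st$emergency[pat] <- FALSE
    }
  }
  invisible(NULL)
}

handle_treat_done <- function(st, g, t) {
  ctl <- st$ctl
  pat <- st$g_busy_pat[g]
  role <- st$g_busy_role[g]
  dur <- t - st$g_serv_start[g]
  st$g_busy[g] <- FALSE
  if (st$g_serv_start[g] >= st$warmup) {
    st$k_serv[g] <- st$k_serv[g] + dur
    if (t > st$g_buffer_t[g] && st$g_buffer_t[g] > 0) {
      ot <- t - max(st$g_serv_start[g], st$g_buffer_t[g])
      st$k_over[g] <- st$k_over[g] + ot
      series_acc(st, t, 5, ot)
    }
  }

  # every visit treats all acute illnesses
  ills <- st$p_ills[[pat]]
  if (length(ills) > 0) {
    act <- ills[st$ill_active[ills]]
    need_follow <- FALSE
    follow_nu <- Inf
    for (i in act) {
      if (is.na(st$ill_dur[i])) {
        # one-visit illness (no duration): resolved by this treatment
        st$ill_active[i] <- FALSE
        st$p_nact[pat] <- st$p_nact[pat] - 1L
      } else if (!is.na(st$ill_nu[i]) &&
                 st$ill_end[i] > t + st$ill_nu[i] + .time_eps) {
        need_follow <- TRUE
        follow_nu <- min(follow_nu, st$ill_nu[i])
      }
    }
    if (need_follow && st$acute_appt[pat] == 0L) {
      tol <- follow_nu * ctl$followup_tol_frac
      target <- t + follow_nu
      slot <- offer_slot(st$cal, g, st$hours[[g]], st$p_avail[pat, ],
                         after = max(t, target - tol), until = target + tol,
                         slot_min = ctl$slot_min, patient = pat)
      if (!is.null(slot)) {
        book_acute(st, pat, g, slot, t)
      } else {
        st$p_deadline[pat] <- target + tol
        st$p_retries[pat] <- 0L
        plan_walkin(st, pat, max(t, target - tol), target + tol)
      }
    }
  }

  # chronic care: after a regular visit, rebook with the family physician
  if (role == 2L && st$p_chronic[pat]) {
    reeval_fam(st, pat)
    book_regular(st, pat, t, t + st$p_cnu[pat])
  }

  if (length(st$room_pat[[g]]) > 0) {
    start_service(st, g, t)
  } else {
    st$g_idle_from[g] <- t
    if (st$g_learn_pending[g] && !st$g_in_session[g] &&
        t >= st$g_buffer_t[g]) {
      do_learning(st, g, overtime_min = (t - st$g_buffer_t[g]) * 1440)
    }
  }
  invisible(NULL)
}

do_learning <- function(st, g, overtime_min) {
  st$g_theta[g] <- learn_threshold(st$g_theta[g], overtime_min,
                                   st$g_idle_acc[g] * 1440, st$ctl)
  st$g_learn_pending[g] <- FALSE
  invisible(NULL)
}

handle_session_open <- function(st, g, day, hf, t) {
  cid <- weekly_class_id(day, hf)
  h <- st$hours[[g]]
  st$g_sess_day[g] <- day; st$g_sess_half[g] <- hf
  st$g_open_t[g] <- day + h[cid, 1]
  st$g_close_t[g] <- day + h[cid, 2]
  st$g_buffer_t[g] <- st$g_close_t[g] + st$ctl$buffer_hours / 24
  st$g_in_session[g] <- TRUE
  st$g_learn_pending[g] <- TRUE
  st$g_idle_acc[g] <- 0
  if (!st$g_busy[g]) st$g_idle_from[g] <- t
  ev_push(st, st$g_close_t[g], EV_SESS_CLOSE, g)
  # recurring sessions keep the queue alive up to the horizon
  nxt <- next_open_session(st, g, day, hf)
  if (!is.null(nxt) && nxt$time <= st$horizon + 7) {
    ev_push(st, nxt$time, EV_SESS_OPEN, nxt$day * 2L + nxt$half, g)
  }
  invisible(NULL)
}

next_open_session <- function(st, g, day, hf) {
  h <- st$hours[[g]]
  d <- day; f <- hf
  for (step in 1:16) {
    if (f == 0L) f <- 1L else { f <- 0L; d <- d + 1L }
    cid <- weekly_class_id(d, f)
    if (!is.na(h[cid, 1])) {
      return(list(time = d + h[cid, 1], day = d, half = f))
    }
  }
  NULL
}

handle_session_close <- function(st, g, t) {
  st$g_in_session[g] <- FALSE
  if (st$g_open_t[g] >= st$warmup) {
    st$k_open[g] <- st$k_open[g] + (st$g_close_t[g] - st$g_open_t[g])
  }
  if (!st$g_busy[g] && st$g_idle_from[g] >= 0) {
    a <- max(st$g_idle_from[g], st$g_open_t[g])
    if (t > a) st$g_idle_acc[g] <- st$g_idle_acc[g] + (t - a)
    st$g_idle_from[g] <- -1
  }
  ev_push(st, st$g_buffer_t[g], EV_BUFFER_END, g)
  invisible(NULL)
}

handle_buffer_end <- function(st, g, t) {
  if (st$g_learn_pending[g] && !st$g_busy[g] &&
      length(st$room_pat[[g]]) == 0L) {
    do_learning(st, g, overtime_min = 0)
  }
  invisible(NULL)
}

handle_regular_due <- function(st, pat, t) {
  if (st$reg_appt[pat] != 0L && st$ap_status[st$reg_appt[pat]] == 0L) {
    return(invisible(NULL))
  }
  book_regular(st, pat, t, t)
  invisible(NULL)
}

# ---- the run ---------------------------------------------------------------

#' Run one simulation
#'
#' Processes the scenario's event stream from an empty initial state over
#' `warmup_days + days` simulated days; indicators are accumulated over the
#' final `days` only.
#'
#' @param sc A `primsim_scenario`.
#' @param days Length of the measurement period in days.
#' @param warmup_days Warm-up period discarded before measurement.
#' @param seed Integer seed; identical `(scenario, days, warmup, seed)` give
#'   bit-identical results.
#' @param series_period_days If set, also record per-period series of access
#'   time, walk-in waiting time, and overtime (for warm-up analysis).
#' @param trace If `TRUE`, keep a textual event trace (`$trace`), one line
#'   per processed event.
#' @return A `primsim_run` object: `$kpis` (one-row aggregate tibble),
#'   `$by_pcp` (per-physician tibble), `$series` (or `NULL`), `$meta`.
#' @export
sim_run <- function(sc, days = 91, warmup_days = 0, seed = 1,
                    series_period_days = NULL, trace = FALSE) {
  stopifnot(inherits(sc, "primsim_scenario"))
  old_seed <- get0(".Random.seed", envir = .GlobalEnv)
  horizon <- warmup_days + days
  st <- build_run_state(sc, horizon, warmup_days, seed,
                        series_period = series_period_days %||% NA)
  st$do_trace <- isTRUE(trace)
  if (st$do_trace) st$trace_lines <- character(0)
  init_events(st)
  loop_events(st)
  out <- finalize_run(st, sc, days, warmup_days, seed)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = .GlobalEnv)
  out
}

init_events <- function(st) {
  ctl <- st$ctl
  # every patient's acute onsets form a homogeneous Poisson process; the
  # whole process is drawn up front (counts + sorted uniform positions are
  # exactly the order statistics of the process) and consumed through a
  # single rolling onset event
  horizon <- st$horizon
  if (ctl$deterministic) {
    times <- pats <- list()
    for (pat in seq_len(st$np)) {
      gap <- if (st$p_rate[pat] > 0) 365 / st$p_rate[pat] else Inf
      if (gap <= horizon) {
        tt <- seq(gap, horizon, by = gap)
        times[[length(times) + 1L]] <- tt
        pats[[length(pats) + 1L]] <- rep(pat, length(tt))
      }
    }
    tt <- unlist(times) %||% numeric(0)
    pp <- unlist(pats) %||% integer(0)
  } else {
    draw <- stream_eval(st, "onset", function() {
      n_i <- stats::rpois(st$np, st$p_rate * horizon / 365)
      list(n = n_i, u = stats::runif(sum(n_i)) * horizon)
    })
    pp <- rep(seq_len(st$np), draw$n)
    tt <- draw$u
  }
  ord <- order(tt)
  st$on_t <- tt[ord]
  st$on_pat <- pp[ord]
  st$on_i <- 1L
  if (length(st$on_t) > 0) ev_push(st, st$on_t[1], EV_ONSET)
  # chronic patients: family physician and phase-staggered first regular due
  chron <- which(st$p_chronic)
  if (length(chron) > 0) {
    u <- stream_eval(st, "choice", function() stats::runif(length(chron)))
    for (j in seq_along(chron)) {
      pat <- chron[j]
      cons <- st$consider[pat, ]
      r <- st$r_app[pat, cons]
      st$fam_phys[pat] <- cons[order(-r, cons)][1]
      ev_push(st, u[j] * st$p_cnu[pat], EV_REG_DUE, pat)
    }
  }
  # first session of every physician
  for (g in seq_len(st$ng)) {
    h <- st$hours[[g]]
    found <- FALSE
    for (d in 0:6) {
      for (f in 0:1) {
        cid <- weekly_class_id(d, f)
        if (!is.na(h[cid, 1])) {
          ev_push(st, d + h[cid, 1], EV_SESS_OPEN, d * 2L + f, g)
          found <- TRUE
          break
        }
      }
      if (found) break
    }
  }
  invisible(NULL)
}

loop_events <- function(st) {
  horizon <- st$horizon
  while (st$ev_n > 0L) {
    ev <- ev_pop(st)
    pay <- ev[2]
    k <- pay %/% 1e15; pay <- pay - k * 1e15
    t <- ev[1] - EV_PRIO[k] * 1e-11
    if (t > horizon) break
    st$now <- t
    cc <- pay %/% 1e9; pay <- pay - cc * 1e9
    b <- pay %/% 1e7; a <- pay - b * 1e7
    if (st$do_trace) {
      st$trace_lines <- c(st$trace_lines,
                          paste(decode_time(t)$label, EV_NAMES[k], a, b, cc))
    }
    if (k == EV_ONSET) handle_onset(st, t)
    else if (k == EV_RECOVERY) handle_recovery(st, a, t)
    else if (k == EV_APPT_ARR) handle_appt_arrival(st, a, t)
    else if (k == EV_WALK_ARR) handle_walkin_arrival(st, a, b, cc, t)
    else if (k == EV_SESS_OPEN) handle_session_open(st, b, a %/% 2, a %% 2, t)
    else if (k == EV_SESS_CLOSE) handle_session_close(st, a, t)
    else if (k == EV_BUFFER_END) handle_buffer_end(st, a, t)
    else if (k == EV_TREAT_DONE) handle_treat_done(st, a, t)
    else if (k == EV_REG_DUE) handle_regular_due(st, a, t)
  }
  invisible(NULL)
}

finalize_run <- function(st, sc, days, warmup_days, seed) {
  ng <- st$ng
  weeks <- days / 7
  by_pcp <- tibble::tibble(
    pcp = st$g_id,
    treatments = st$k_treat,
    walkins = st$k_walk,
    acute_appointments = st$k_appt_acute,
    regular_appointments = st$k_appt_reg,
    service_h = st$k_serv * 24,
    overtime_min = st$k_over * 1440,
    rejected_walkins = st$k_rej_walk,
    rejected_appointments = st$k_rej_appt,
    capacity_h = st$k_open * 24,
    utilization = ifelse(st$k_open > 0, st$k_serv / st$k_open, NA_real_)
  )
  agg <- tibble::tibble(
    treatments = mean(by_pcp$treatments),
    walkins = mean(by_pcp$walkins),
    acute_appointments = mean(by_pcp$acute_appointments),
    regular_appointments = mean(by_pcp$regular_appointments),
    utilization = sum(st$k_serv) / max(sum(st$k_open), .time_eps),
    weekly_overtime_min = sum(st$k_over) * 1440 / ng / weeks,
    rejected_walkins = mean(by_pcp$rejected_walkins),
    rejected_appointments = mean(by_pcp$rejected_appointments),
    access_time_d = st$k_acc_acute / max(st$k_acc_acute_n, 1),
    access_time_regular_d = st$k_acc_reg / max(st$k_acc_reg_n, 1),
    access_distance_km = st$k_dist / max(st$k_dist_n, 1),
    wait_appointment_min = st$k_wait_appt * 1440 / max(st$k_wait_appt_n, 1),
    wait_walkin_min = st$k_wait_walk * 1440 / max(st$k_wait_walk_n, 1),
    ontime_fraction = st$k_ontime / max(st$k_attended, 1),
    attended_appointments = st$k_attended,
    acute_illnesses = st$k_onsets,
    chronic_patients = sum(st$p_chronic),
    capacity_h = sum(by_pcp$capacity_h),
    arrivals = st$k_arrivals,
    admissions = st$k_admit,
    rejections = st$k_reject,
    cancellations = st$k_cancel,
    forgone = st$k_forgone,
    walkin_share = sum(st$k_walk) / max(sum(st$k_treat), 1),
    n_patients = st$np,
    n_pcps = ng
  )
  series <- NULL
  if (!is.na(st$series_period)) {
    m <- st$se_acc
    series <- tibble::tibble(
      period = seq_len(nrow(m)),
      access_time_d = ifelse(m[, 2] > 0, m[, 1] / m[, 2], NA_real_),
      wait_walkin_min = ifelse(m[, 4] > 0, m[, 3] * 1440 / m[, 4], NA_real_),
      overtime_min = m[, 5] * 1440
    )
  }
  structure(
    list(kpis = agg, by_pcp = by_pcp, series = series,
         trace = st$trace_lines,
         meta = list(scenario = sc$name, days = days,
                     warmup_days = warmup_days, seed = seed,
                     double_acute_bookings = st$audit_double)),
    class = "primsim_run"
  )
}

#' @export
print.primsim_run <- function(x, ...) {
  cat(sprintf("<primsim_run> %s: %d days (+%d warm-up), seed %d\n",
              x$meta$scenario, x$meta$days, x$meta$warmup_days,
              x$meta$seed))
  df <- tidyr::pivot_longer(x$kpis, dplyr::everything(),
                            names_to = "kpi", values_to = "value")
  print(df, n = 30)
  invisible(x)
}
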