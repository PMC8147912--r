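test_that("slot grids tile the opening hours, one patient per slot", {
  g <- slot_grid(8 / 24, 12 / 24, 10)
  expect_length(g, 24)                       # 4 h / 10 min
  expect_equal(g[1], 8 / 24)
  expect_true(all(diff(g) * 1440 - 10 < 1e-9))
  expect_true(all(g + 10 / 1440 <= 12 / 24 + 1e-9))
  expect_length(slot_grid(8 / 24, 8.1 / 24, 10), 0)
})

test_that("offer_slot returns the earliest feasible free slot (grid oracle)", {
  cal <- new_calendar()
  h <- weekday_hours(c(8, 12), NULL)         # weekday mornings
  avail <- rep(TRUE, 14)
  # empty calendar, Monday 00:00 request, willingness 2 days
  s <- offer_slot(cal, "p1", h, avail, after = 0, until = 2, slot_min = 10)
  expect_equal(s$time, 8 / 24)               # first Monday-morning slot
  # the slot is now occupied: the next offer is the following slot
  s2 <- offer_slot(cal, "p1", h, avail, after = 0, until = 2, slot_min = 10)
  expect_equal(s2$time, 8 / 24 + 10 / 1440)
  # zero willingness -> nothing
  expect_null(offer_slot(cal, "p1", h, avail, after = 0, until = 0,
                         slot_min = 10))
  # a fully booked horizon -> nothing
  cal2 <- new_calendar()
  for (i in 1:24) offer_slot(cal2, "p1", h, avail, 0, 1, 10)
  expect_null(offer_slot(cal2, "p1", h, avail, 0, 8 / 24 + 23.9 * 10 / 1440, 10))
  # freeing a slot makes it available again
  free_slot(cal, "p1", s$day, s$half, s$slot)
  s3 <- offer_slot(cal, "p1", h, avail, after = 0, until = 2, slot_min = 10)
  expect_equal(s3$time, s$time)
  # brute-force oracle over random feasibility patterns
  set.seed(401)
  for (rep in 1:10) {
    calx <- new_calendar()
    av <- rep(FALSE, 14); av[sample(1:14, 6)] <- TRUE
    after <- runif(1, 0, 3); until <- after + runif(1, 0.5, 4)
    got <- offer_slot(calx, "p", h, av, after, until, 10, book = FALSE)
    # oracle: enumerate all slots in the window
    alld <- floor(after):floor(until)
    cand <- c()
    for (d in alld) for (g in 0:1) {
      cid <- weekly_class_id(d, g)
      if (!av[cid] || is.na(h[cid, 1])) next
      st <- d + slot_grid(h[cid, 1], h[cid, 2], 10)
      cand <- c(cand, st[st > after + 1e-9 & st <= until + 1e-9])
    }
    if (length(cand) == 0) expect_null(got) else {
      expect_equal(got$time, min(cand))
    }
  }
})

test_that("PFCFS treats appointments first, then emergencies, FCFS within", {
  room <- tibble::tibble(patient = c(10L, 11L),
                         class = c(3L, 1L), arrival = c(1, 2))
  expect_equal(next_patient_pfcfs(room), 2L)   # appointment before walk-in
  walkers <- tibble::tibble(patient = c(5L, 6L), class = c(3L, 3L),
                            arrival = c(2, 1))
  expect_equal(next_patient_pfcfs(walkers), 2L)  # FCFS among walk-ins
  mixed <- tibble::tibble(patient = c(1L, 2L), class = c(3L, 2L),
                          arrival = c(1, 5))
  expect_equal(next_patient_pfcfs(mixed), 2L)    # emergency beats ordinary
  expect_error(next_patient_pfcfs(room[0, ]), "empty")
})

test_that("service times are log-normal around the demand-dependent mean", {
  set.seed(402)
  ctl <- sim_control(service_mean_min = 10, service_cv = 0.25,
                     congestion_queue = 4, speed_factor = 0.8)
  calm <- service_time(1e5, queue_len = 0, control = ctl) * 1440
  expect_true(all(calm > 0))
  se <- sd(calm) / sqrt(1e5)
  expect_lt(abs(mean(calm) - 10), 3 * se)
  busy <- service_time(1e5, queue_len = 5, control = ctl) * 1440
  expect_lt(abs(mean(busy) - 8), 3 * sd(busy) / sqrt(1e5))
})

test_that("priority-threshold admission follows the workload predictor", {
  ctl <- sim_control(service_mean_min = 10, theta_emergency_bonus_min = 30)
  buffer_end <- 13 / 24
  # appointment holders are always admitted
  expect_true(admit("appointment", FALSE, 12 / 24, 50, 10, -60, buffer_end,
                    ctl))
  # empty practice mid-session -> admit
  expect_true(admit("walkin", FALSE, 10 / 24, 0, 0, 0, buffer_end, ctl))
  # predicted completion far past the buffer at theta = 0 -> reject
  expect_false(admit("walkin", FALSE, 12.9 / 24, 12, 0, 0, buffer_end, ctl))
  # the emergency bonus relaxes the threshold
  expect_true(admit("walkin", TRUE, 12.9 / 24, 2, 0, 0, buffer_end, ctl))
})

test_that("end-of-buffer learning tightens on overtime, loosens on idle", {
  th <- learn_threshold(10, overtime_min = 30, idle_min = 0)
  expect_equal(th, 5)
  th2 <- learn_threshold(10, overtime_min = 0, idle_min = 60)
  expect_equal(th2, 15)
  expect_equal(learn_threshold(10, 0, 0), 10)    # on target: unchanged
  # bounded under arbitrary outcome sequences
  set.seed(403)
  th <- 0
  for (i in 1:200) {
    th <- learn_threshold(th, sample(c(0, 45), 1), sample(c(0, 45), 1))
    expect_gte(th, -60); expect_lte(th, 60)
  }
})
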