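test_that("an empty patient load produces all-zero indicators", {
  sc <- tiny_scenario(n_patients = 1, annual_rate = 0)  # never falls ill
  r <- sim_run(sc, days = 14, seed = 1)
  expect_equal(r$kpis$treatments, 0)
  expect_equal(r$kpis$utilization, 0)
  expect_equal(r$kpis$acute_illnesses, 0)
  expect_equal(r$kpis$arrivals, 0)
})

test_that("a zero-variance 1-patient/1-PCP run matches the hand oracle", {
  # Setup: one PCP, Monday-Friday mornings 08:00-12:00, 10-min slots, 10-min
  # deterministic service; one always-available patient at the practice,
  # onset rate 36.5/yr -> deterministic onsets every 10 days; illness family
  # D = 5 d, W = 2 d, N = 7 d.
  #
  # Hand-derived sequence: onset at day 10 (Thursday) 00:00; the top-rated
  # (only) PCP offers the earliest free slot within 2 days: Thursday 08:00;
  # punctual arrival 08:00; idle physician starts service immediately
  # (wait 0, on time); completion 08:10; d = 5 < nu = 7 so no follow-up is
  # booked; recovery day 15; second onset (day 20) lies beyond the horizon.
  sc <- tiny_scenario()
  r <- sim_run(sc, days = 16, warmup_days = 0, seed = 5, trace = TRUE)
  k <- r$kpis
  expect_equal(k$treatments, 1)
  expect_equal(k$walkins, 0)
  expect_equal(k$acute_appointments, 1)
  expect_equal(k$attended_appointments, 1)
  expect_equal(k$acute_illnesses, 1)
  expect_equal(k$access_time_d, 8 / 24, tolerance = 1e-9)
  expect_equal(k$wait_appointment_min, 0, tolerance = 1e-6)
  expect_equal(k$ontime_fraction, 1)
  # utilization: 10 min service over 12 weekday mornings x 4 h
  expect_equal(k$utilization, (10 / 60) / 48, tolerance = 1e-9)
  expect_equal(k$weekly_overtime_min, 0)
  expect_equal(k$rejections, 0)
  # the non-session trace lines reproduce the hand-derived event list
  ev <- grep("session|buffer", r$trace, invert = TRUE, value = TRUE)
  expect_equal(sub(" [0-9 ]+$", "", ev),
               c("d10 00:00 onset", "d10 08:00 appointment_arrival",
                 "d10 08:10 treatment_complete", "d15 00:00 recovery"))
})

test_that("identical seeds give bit-identical results", {
  sc <- small_preset()
  r1 <- sim_run(sc, days = 21, warmup_days = 7, seed = 9)
  r2 <- sim_run(sc, days = 21, warmup_days = 7, seed = 9)
  expect_identical(r1$kpis, r2$kpis)
  expect_identical(r1$by_pcp, r2$by_pcp)
  r3 <- sim_run(sc, days = 21, warmup_days = 7, seed = 10)
  expect_false(identical(r1$kpis, r3$kpis))
})

test_that("conservation identities hold on arbitrary seeds", {
  sc <- small_preset()
  for (seed in c(1, 2, 3)) {
    r <- sim_run(sc, days = 28, warmup_days = 7, seed = seed)
    k <- r$kpis
    # admissions + rejections = arrivals
    expect_equal(k$admissions + k$rejections, k$arrivals)
    # treatments = attended appointments + admitted walk-ins
    expect_equal(sum(r$by_pcp$treatments),
                 k$attended_appointments + sum(r$by_pcp$walkins))
    # no patient ever held two acute appointments
    expect_equal(r$meta$double_acute_bookings, 0)
    # non-negativity of all counters and waits
    expect_true(all(r$by_pcp$treatments >= 0))
    expect_gte(k$wait_appointment_min, 0)
    expect_gte(k$wait_walkin_min, 0)
    expect_gte(k$access_time_d, 0)
  }
})

test_that("recovery cancels a now-pointless appointment with probability p_a", {
  # 300 co-located patients, one PCP open Monday 08:00-16:00 only with
  # 1-min slots (480 slots); onsets hit on day 10 (Thursday); every booked
  # slot (Monday, day 14) lies after the recovery on day 12, so every
  # appointment faces exactly one Bernoulli(p_a) cancellation draw
  mk <- function(p_cancel) {
    tiny_scenario(
      n_patients = 300,
      hours = hours_only(0, 0, open = 8, close = 16),   # Monday only
      family = illness_family("short", "S01", duration = c(0, 2),
                              willingness = c(0, 30), followup = NULL),
      cancel_prob = p_cancel,
      control = sim_control(deterministic = TRUE, service_mean_min = 1,
                            slot_min = 1)
    )
  }
  r1 <- sim_run(mk(1), days = 13, seed = 3)   # horizon before any Monday slot
  expect_equal(r1$kpis$cancellations, 300)
  expect_equal(r1$kpis$attended_appointments, 0)
  r0 <- sim_run(mk(0), days = 16, seed = 3)   # never cancelled: all attend
  expect_equal(r0$kpis$cancellations, 0)
  expect_equal(r0$kpis$attended_appointments, 300)
  r7 <- sim_run(mk(0.7), days = 13, seed = 4)
  frac <- r7$kpis$cancellations / 300
  se <- sqrt(0.7 * 0.3 / 300)
  expect_lt(abs(frac - 0.7), 3 * se)
})

test_that("a persisting illness books a follow-up; a short one does not", {
  # D = 40 d > N = 7 d: after the initial treatment the illness still has
  # > nu remaining, so a follow-up acute appointment is booked
  sc <- tiny_scenario(
    family = illness_family("lingering", "L01", duration = c(0, 40),
                            willingness = c(0, 2), followup = c(0, 7))
  )
  r <- sim_run(sc, days = 28, seed = 2)
  expect_gte(r$kpis$acute_appointments, 2)     # initial + follow-up(s)
  # the worked-example property: d < nu books no follow-up
  sc2 <- tiny_scenario()                       # D = 5 < N = 7
  r2 <- sim_run(sc2, days = 14, seed = 2)
  expect_equal(r2$kpis$acute_appointments, 1)
})

test_that("one-visit illnesses resolve at first treatment", {
  sc <- tiny_scenario(
    family = illness_family("jab", "Z99", willingness = c(0, 30))
  )
  r <- sim_run(sc, days = 14, seed = 2)
  expect_equal(r$kpis$treatments, 1)
  expect_equal(r$kpis$acute_appointments, 1)   # no follow-up, no recurrence
})

test_that("chronic patients hold regular appointments with their family physician", {
  fam <- dplyr::bind_rows(
    illness_family("test flu", "T00", duration = c(0, 5),
                   willingness = c(0, 2), followup = c(0, 7)),
    illness_family("chronic c", "C01", willingness = c(0, 10),
                   followup = c(0, 21), chronic = TRUE)
  )
  ages <- age_class("uniform", c(0, 0), 1, 1, 0, share = 1, avail_prob = 1,
                    chronic_prob = 1)
  pcps <- tibble::tibble(id = "pcp01", lat = 50.5, lon = 6.25,
                         hours = list(weekday_hours(c(8, 12), NULL)))
  patients <- tibble::tibble(
    id = 1L, cell = 1L, lat = 50.5, lon = 6.25, c = 0.5, age = "uniform",
    avail = list(rep(TRUE, 14)), chronic = TRUE,
    chronic_family = "chronic c", chronic_s = 0.5
  )
  sc <- scenario(pcps, patients, families = fam, age_classes = ages,
                 acute_mix = illness_mix("uniform", "test flu", 1),
                 chronic_mix = illness_mix("uniform", "chronic c", 1),
                 control = sim_control(deterministic = TRUE), name = "chronic")
  r <- sim_run(sc, days = 84, seed = 6)
  # regular care recurs roughly every nu = 21 days after the staggered start
  expect_gte(r$kpis$regular_appointments, 3)
  expect_equal(r$kpis$treatments, r$kpis$attended_appointments)
  expect_equal(r$kpis$chronic_patients, 1)
  expect_gte(r$kpis$access_time_regular_d, 0)
})

test_that("per-period series are recorded for warm-up analysis", {
  sc <- small_preset()
  r <- sim_run(sc, days = 28, warmup_days = 0, seed = 1,
               series_period_days = 7)
  expect_equal(nrow(r$series), 4)
  expect_true(all(c("access_time_d", "wait_walkin_min", "overtime_min") %in%
                    names(r$series)))
})
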