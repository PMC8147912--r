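mk_patient <- function(avail = rep(TRUE, 14), lat = 50.5, lon = 6.25) {
  tibble::tibble(lat = lat, lon = lon, avail = list(avail))
}

mk_pcp <- function(id, lat = 50.5, lon = 6.25, hours = weekday_hours()) {
  tibble::tibble(id = id, lat = lat, lon = lon, hours = list(hours))
}

test_that("haversine distances are sane", {
  # one degree of latitude is ~111.2 km
  expect_equal(distance_km(50, 6, 51, 6), 111.2, tolerance = 0.01)
  expect_equal(distance_km(50, 6, 50, 6), 0)
})

test_that("initial ratings reward opening-hour overlap at equal distance", {
  p <- mk_patient()
  many <- mk_pcp("a")                                      # open 10 sessions
  few <- mk_pcp("b", hours = hours_only(0, 0))             # open Mon AM only
  r <- initial_ratings(p, dplyr::bind_rows(many, few))
  ra <- r$appointment$rating
  expect_gt(ra[1], ra[2])
  # identical PCPs get identical ratings
  r2 <- initial_ratings(p, dplyr::bind_rows(mk_pcp("a"), mk_pcp("b")))
  expect_equal(r2$appointment$rating[1], r2$appointment$rating[2])
  expect_true(all(r$appointment$rating > 0))
})

test_that("walk-in ratings vanish where PCP closed or patient unavailable", {
  avail <- rep(FALSE, 14); avail[1] <- TRUE                # Mon AM only
  p <- mk_patient(avail = avail)
  g <- mk_pcp("a", hours = hours_only(1, 0))               # Tue AM only
  r <- initial_ratings(p, g)
  expect_true(all(r$walkin$rating == 0))                   # disjoint
  g2 <- mk_pcp("a", hours = hours_only(0, 0))              # Mon AM
  r2 <- initial_ratings(p, g2)
  expect_gt(r2$walkin$rating[r2$walkin$class_id == 1], 0)
  expect_true(all(r2$walkin$rating[r2$walkin$class_id != 1] == 0))
})

test_that("rating updates are monotone, multiplicative, and floored", {
  expect_equal(update_rating(1.0, "request_failed"), 0.8)
  expect_equal(update_rating(0, "rejected_at_door"), 0)
  expect_gt(update_rating(1.0, "request_granted"), 1.0)
  expect_gt(update_rating(1.0, "short_wait"), 1.0)
  expect_lt(update_rating(1.0, "long_wait"), 1.0)
  expect_error(update_rating(1.0, "mystery"), "unknown experience")
  # inverse factors round-trip
  ctl <- sim_control(rating_factors = c(request_granted = 1.25,
                                        request_failed = 0.8,
                                        short_wait = 1.05, long_wait = 0.9,
                                        rejected_at_door = 0.6))
  r <- update_rating(update_rating(1, "request_granted", ctl),
                     "request_failed", ctl)
  expect_equal(r, 1, tolerance = 1e-12)
})

test_that("appointment targets are the top-two ratings with id tie-break", {
  r <- tibble::tibble(pcp = c("A", "B", "C"), rating = c(3, 2, 1))
  expect_equal(choose_appointment_targets(r), c("A", "B"))
  expect_equal(choose_appointment_targets(r[1, ]), "A")
  tie <- tibble::tibble(pcp = c("B", "A"), rating = c(2, 2))
  expect_equal(choose_appointment_targets(tie), c("A", "B"))
  # agreement with a sort oracle on random instances
  set.seed(301)
  for (i in 1:20) {
    n <- sample(1:6, 1)
    rt <- tibble::tibble(pcp = sample(LETTERS[1:6], n),
                         rating = round(runif(n, 0, 3), 1))
    oracle <- rt$pcp[order(-rt$rating, rt$pcp)][seq_len(min(2, n))]
    expect_equal(choose_appointment_targets(rt), oracle)
  }
})

test_that("walk-in target maximizes rating with earliest-session tie-break", {
  one <- tibble::tibble(pcp = "A", day = 3, half = 0, rating = 1)
  expect_equal(choose_walkin_target(one)$pcp, "A")
  tie <- tibble::tibble(pcp = c("A", "A"), day = c(4, 3), half = c(0, 0),
                        rating = c(1, 1))
  expect_equal(choose_walkin_target(tie)$day, 3)
  expect_null(choose_walkin_target(tie[0, ]))
  # exhaustive-max oracle on random candidate sets
  set.seed(302)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    cand <- tibble::tibble(pcp = sample(LETTERS[1:4], n, TRUE),
                           day = sample(0:6, n, TRUE),
                           half = sample(0:1, n, TRUE),
                           rating = sample(seq(0, 1, 0.25), n, TRUE))
    pick <- choose_walkin_target(cand)
    expect_equal(pick$rating, max(cand$rating))
    best <- cand[cand$rating == max(cand$rating), ]
    expect_equal(pick$day + pick$half / 2, min(best$day + best$half / 2))
  }
})

test_that("family physician switches only past the relative margin", {
  r <- tibble::tibble(pcp = c("A", "B"), rating = c(1.1, 1.0))
  expect_equal(reevaluate_family_physician("B", r), "B")   # 10% < 20% margin
  r$rating[1] <- 1.3
  expect_equal(reevaluate_family_physician("B", r), "A")   # 30% > margin
  expect_equal(reevaluate_family_physician("A", r), "A")   # incumbent on top
})
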