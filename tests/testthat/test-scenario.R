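test_that("minor exclusion conserves adults exactly for any seed", {
  totals <- c(M1 = 8000, M2 = 16000, M3 = 11542)
  kids <- c(M1 = 1390, M2 = 2383, M3 = 1794)
  cells <- make_cells(totals, c(M1 = 620, M2 = 1240,
                                M3 = 894))
  expect_equal(nrow(cells), 2754)
  expect_equal(sum(cells$count), 35542)
  for (seed in c(1, 99)) {
    set.seed(seed)
    out <- exclude_minors(cells, kids)
    expect_equal(sum(out$adults), 29975)       # 35542 - 5567
    expect_true(all(out$adults >= 1))          # one fixed adult per cell
  }
  # zero children: population unchanged
  out0 <- exclude_minors(cells, c(M1 = 0, M2 = 0, M3 = 0))
  expect_equal(out0$adults, out0$count)
  # infeasible: one resident per cell, any children requested
  solo <- tibble::tibble(municipality = "X", lat = 50, lon = 6, count = 1L)
  expect_error(exclude_minors(solo, c(X = 1)), "exceeds")
})

test_that("generated patients match the configured distributions", {
  set.seed(501)
  cells <- make_cells(c(A = 60000, B = 50000), c(A = 500, B = 400))
  cells <- dplyr::mutate(cells[1:200, ], adults = 500L)
  p <- generate_patients(cells)
  n <- nrow(p)
  expect_equal(n, 1e5)
  # health conditions: beta(25, 25), mean 0.5
  se_c <- sd(p$c) / sqrt(n)
  expect_lt(abs(mean(p$c) - 0.5), 3 * se_c)
  expect_true(all(p$c >= 0 & p$c <= 1))
  # age-class shares
  shares <- c(`16-24` = 0.1196, `25-65` = 0.6318, `>65` = 0.2486)
  for (a in names(shares)) {
    se <- sqrt(shares[a] * (1 - shares[a]) / n)
    expect_lt(abs(mean(p$age == a) - shares[a]), 3 * se)
  }
  # chronic fraction within each age class
  probs <- c(`16-24` = 0.12, `25-65` = 0.33, `>65` = 0.52)
  for (a in names(probs)) {
    sub <- p[p$age == a, ]
    se <- sqrt(probs[a] * (1 - probs[a]) / nrow(sub))
    expect_lt(abs(mean(sub$chronic) - probs[a]), 3 * se)
  }
  # chronic patients carry a chronic family and a seriousness
  chr <- p[p$chronic, ]
  expect_true(all(!is.na(chr$chronic_family)))
  expect_true(all(chr$chronic_s >= 0 & chr$chronic_s <= 1))
  # availability probability per age class (14 Bernoulli trials each)
  av <- vapply(p$avail, sum, numeric(1))
  for (a in c("16-24", "25-65", ">65")) {
    pr <- default_age_classes()$avail_prob[default_age_classes()$name == a]
    m <- mean(av[p$age == a]) / 14
    se <- sqrt(pr * (1 - pr) / (14 * sum(p$age == a)))
    expect_lt(abs(m - pr), 3 * se)
  }
})

test_that("generator and preset are deterministic given a seed", {
  s1 <- scenario_preset(n_pcps = 2, patients_per_pcp = 100, seed = 3)
  s2 <- scenario_preset(n_pcps = 2, patients_per_pcp = 100, seed = 3)
  expect_identical(s1$patients, s2$patients)
  expect_identical(s1$pcps, s2$pcps)
  s3 <- scenario_preset(n_pcps = 2, patients_per_pcp = 100, seed = 4)
  expect_false(identical(s1$patients, s3$patients))
  # patients-per-PCP ratio preserved
  expect_equal(nrow(s1$patients) / nrow(s1$pcps), 100)
})

test_that("scenario validation reports all violations, not just the first", {
  sc <- small_preset()
  bad <- unclass(sc)
  bad$acute_mix["16-24", 1] <- bad$acute_mix["16-24", 1] + 0.1   # row sum 1.1
  bad$pcps$hours[[1]][1, ] <- c(0.5, 0.3)                        # open > close
  v <- validate_scenario(bad)
  expect_length(v, 2)
  expect_match(v[1], "16-24")
  expect_match(v[2], "open < close")
  # a well-formed generated scenario validates cleanly
  expect_length(validate_scenario(sc), 0)
})

test_that("PCP decline keeps patients and rebuilds downstream state", {
  sc <- small_preset()
  red <- apply_pcp_decline(sc, "pcp01")
  expect_equal(nrow(red$pcps), 1)
  expect_equal(nrow(red$patients), nrow(sc$patients))
  expect_error(apply_pcp_decline(sc, character(0)), "non-empty")
  expect_error(apply_pcp_decline(sc, "nope"), "subset")
  # identity: retaining everything changes nothing but the label
  same <- apply_pcp_decline(sc, sc$pcps$id)
  expect_identical(same$pcps, sc$pcps)
  # runs on the reduced roster work (family physicians reassigned at init)
  r <- sim_run(red, days = 7, seed = 1)
  expect_gte(r$kpis$treatments, 0)
})

test_that("aging regenerates age-dependent attributes, keeps locations", {
  sc <- small_preset()
  aged <- apply_aging(sc, aged_distribution("medium"), seed = 8)
  expect_identical(aged$patients$lat, sc$patients$lat)
  expect_identical(aged$patients$c, sc$patients$c)
  # medium-term elderly share 0.2942 within sampling error
  n <- nrow(aged$patients)
  se <- sqrt(0.2942 * (1 - 0.2942) / n)
  expect_lt(abs(mean(aged$patients$age == ">65") - 0.2942), 3 * se + 0.02)
  expect_error(apply_aging(sc, c(0.5, 0.2)), "probability")
  # composes with the PCP decline (combined what-if scenario)
  both <- apply_pcp_decline(aged, sc$pcps$id[1])
  expect_equal(nrow(both$pcps), 1)
  expect_equal(nrow(both$patients), n)
})

test_that("scenario JSON round-trips structurally", {
  sc <- small_preset(n_pcps = 2, patients_per_pcp = 40)
  path <- withr::local_tempfile(fileext = ".json")
  write_scenario(sc, path)
  sc2 <- read_scenario(path)
  expect_equal(sc2$families, sc$families)
  expect_equal(sc2$age_classes, sc$age_classes)
  expect_equal(sc2$acute_mix, sc$acute_mix)
  expect_equal(sc2$chronic_mix, sc$chronic_mix)
  expect_equal(sc2$patients, sc$patients)
  expect_equal(sc2$pcps$id, sc$pcps$id)
  expect_equal(sc2$pcps$hours, sc$pcps$hours)
  expect_equal(unclass(sc2$control), unclass(sc$control))
  # and the round-tripped scenario simulates equivalently (floats re-read
  # from JSON text can differ in the last ulp)
  r1 <- sim_run(sc, days = 7, seed = 2)
  r2 <- sim_run(sc2, days = 7, seed = 2)
  expect_equal(r1$kpis, r2$kpis, tolerance = 1e-9)
})
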