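test_that("family trait evaluation reproduces the worked mild-cold example", {
  fam <- example_cold_family()
  tr <- expected_traits(fam, 0.2)
  expect_equal(tr$duration, 5)       # 10 * 0.2 + 3
  expect_equal(tr$willingness, 2.4)  # -3 * 0.2 + 3
  expect_equal(tr$followup, 6.6)     # -2 * 0.2 + 7
})

test_that("trait evaluation handles printed coefficients and NA traits", {
  fams <- default_families()
  back_pain <- fams[fams$icd == "M54", ]
  expect_equal(expected_traits(back_pain, 1)$willingness, 1)  # -3 + 4
  hbp <- fams[fams$icd == "I10", ]
  expect_true(is.na(expected_traits(hbp, 0.5)$duration))      # chronic: no D
  diabetes <- fams[fams$icd == "E11", ]
  expect_equal(expected_traits(diabetes, 0)$followup, 90)     # -10 * 0 + 90
  vac <- fams[fams$icd == "Z25", ]
  expect_true(is.na(expected_traits(vac, 0.3)$followup))
  expect_equal(expected_traits(vac, 0.3)$willingness, 40)
  expect_error(expected_traits(back_pain, 1.5), "\\[0, 1\\]")
})

test_that("chronic families must not define a duration", {
  expect_error(
    illness_family("bad", willingness = c(0, 1), duration = c(1, 1),
                   chronic = TRUE),
    "chronic"
  )
})

test_that("annual illness rate evaluates the age-class linear function", {
  old <- age_class(">65", c(9, 1), 1.2, 0.8, 0.7)
  expect_equal(annual_rate(old, 0.5), 5.5)
  young <- age_class("16-24", c(6, 0), 0.8, 1.2, 0.95)
  expect_equal(annual_rate(young, 0), 0)
  expect_error(annual_rate(old, -0.1), "\\[0, 1\\]")
})

test_that("onset counts over a patient-year match the Poisson-process rate", {
  set.seed(201)
  # oracle: the number of exponential(rate) gaps within a year is Pois(rate)
  n <- 1e4
  counts <- vapply(seq_len(n), function(i) {
    t <- 0; k <- 0
    repeat {
      t <- t + ronset_gap(1, 5.5)
      if (t > 365) break
      k <- k + 1
    }
    k
  }, numeric(1))
  se <- sd(counts) / sqrt(n)
  expect_lt(abs(mean(counts) - 5.5), 3 * se)
})

test_that("mixing rows must sum to one", {
  expect_error(illness_mix(c("a"), c("f1", "f2"), c(0.5, 0.4)), "sum to 1")
  m <- default_acute_mix()
  expect_equal(unname(rowSums(m)), rep(1, 3))
  expect_equal(unname(rowSums(default_chronic_mix())), rep(1, 3))
  expect_equal(unname(m["16-24", ]), c(0.02, 0.32, 0.14, 0.52))
})

test_that("acute sampling follows the configured stochastic machinery", {
  set.seed(202)
  fams <- default_families()
  ages <- default_age_classes()
  old <- ages[ages$name == ">65", ]
  n <- 2e4
  draws <- sample_acute_illness(n, old, fams, default_acute_mix())
  # family frequencies match the mixing row within 3 SE
  freq <- table(factor(draws$family, levels = colnames(default_acute_mix())))
  p <- default_acute_mix()[">65", ]
  for (f in names(p)) {
    se <- sqrt(p[f] * (1 - p[f]) / n)
    expect_lt(abs(freq[[f]] / n - p[f]), 3 * se + 1e-12)
  }
  # non-negative durations/willingness; one-visit families have NA duration
  expect_true(all(is.na(draws$duration) | draws$duration >= 0))
  expect_true(all(draws$willingness >= 0))
  expect_true(all(is.na(draws$duration[draws$family == "vaccination"])))
  # follow-up interval is the exact deterministic family value
  cold <- draws[draws$family == "cold", ]
  expect_equal(cold$followup, -1 * cold$s + 6)
  # empirical duration mean tracks the age-adjusted family mean at fixed s
  ctl <- sim_control(seriousness_mode = 0.2)
  ctl$seriousness_mode <- 0.2
  one_fam <- fams[fams$icd == "J06", ]
  mix1 <- illness_mix(">65", "cold", 1)
  d2 <- sample_acute_illness(1e5, old, fams, mix1,
                             control = sim_control(seriousness_mode = 0.2))
  mu <- mean(d2$duration)
  target <- mean((5 * d2$s + 4) * old$duration_factor)
  se <- sd(d2$duration) / sqrt(1e5)
  expect_lt(abs(mu - target), 3 * se)
})

test_that("repeated sampling never varies the follow-up of a given (f, s)", {
  fam <- example_cold_family()
  set.seed(203)
  nus <- replicate(50, {
    core <- expected_traits(fam, 0.2)
    core$followup
  })
  expect_true(all(nus == 6.6))
})

test_that("chronic sampling uses the chronic mix and never has a duration", {
  set.seed(204)
  fams <- default_families()
  ages <- default_age_classes()
  young <- ages[ages$name == "16-24", ]
  n <- 2e4
  draws <- sample_chronic_illness(n, young, fams, default_chronic_mix())
  p <- default_chronic_mix()["16-24", ]   # (0.17, 0.33, 0.50)
  freq <- table(factor(draws$family, levels = names(p)))
  for (f in names(p)) {
    se <- sqrt(p[f] * (1 - p[f]) / n)
    expect_lt(abs(freq[[f]] / n - p[f]), 3 * se)
  }
  expect_true(all(fams$chronic[match(draws$family, fams$name)]))
  expect_false("duration" %in% names(draws))
  expect_error(sample_chronic_illness(1, young, fams, NULL), "chronic")
})

test_that("misconfigured mixing matrices are rejected at sampling time", {
  fams <- default_families()
  ages <- default_age_classes()
  a <- ages[1, ]
  bad_acute <- illness_mix(a$name, "diabetes", 1)   # chronic family as acute
  expect_error(sample_acute_illness(10, a, fams, bad_acute), "chronic")
  bad_chronic <- illness_mix(a$name, "cold", 1)
  expect_error(sample_chronic_illness(10, a, fams, bad_chronic), "acute")
})
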