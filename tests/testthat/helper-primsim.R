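# Shared fixtures: tiny hand-built scenarios for engine-level tests.

# the worked-example family: D(s) = 10s + 3, W(s) = -3s + 3, N(s) = -2s + 7
example_cold_family <- function() {
  illness_family("common cold", "J00",
                 duration = c(10, 3), willingness = c(-3, 3),
                 followup = c(-2, 7))
}

# hours matrix with only the named weekday sessions open
hours_only <- function(days = 0, halves = 0, open = 8, close = 12) {
  m <- matrix(NA_real_, 14, 2,
              dimnames = list(weekly_class_labels(), c("open", "close")))
  for (i in seq_along(days)) {
    m[1 + 2 * days[i] + halves[i], ] <- c(open, close) / 24
  }
  m
}

# a single-family, single-age-class scenario with explicit agents:
# every patient is always available, co-located with the physician(s)
tiny_scenario <- function(n_patients = 1, n_pcps = 1,
                          hours = weekday_hours(c(8, 12), NULL),
                          family = illness_family("test flu", "T00",
                                                  duration = c(0, 5),
                                                  willingness = c(0, 2),
                                                  followup = c(0, 7)),
                          annual_rate = 36.5, cancel_prob = 0,
                          control = sim_control(deterministic = TRUE,
                                                service_mean_min = 10,
                                                slot_min = 10)) {
  ages <- age_class("uniform", c(0, annual_rate), 1, 1, cancel_prob,
                    share = 1, avail_prob = 1, chronic_prob = 0)
  pcps <- tibble::tibble(
    id = sprintf("pcp%02d", seq_len(n_pcps)),
    lat = 50.5 + 0.01 * (seq_len(n_pcps) - 1), lon = 6.25,
    hours = replicate(n_pcps, hours, simplify = FALSE)
  )
  patients <- tibble::tibble(
    id = seq_len(n_patients), cell = 1L,
    lat = 50.5, lon = 6.25, c = 0.5, age = "uniform",
    avail = replicate(n_patients, rep(TRUE, 14), simplify = FALSE),
    chronic = FALSE, chronic_family = NA_character_, chronic_s = NA_real_
  )
  scenario(pcps, patients, families = family, age_classes = ages,
           acute_mix = illness_mix("uniform", family$name, 1),
           chronic_mix = NULL, control = control, name = "tiny")
}

# small random-but-seeded synthetic scenario for property-style suites
small_preset <- function(n_pcps = 2, patients_per_pcp = 150, seed = 11) {
  scenario_preset(n_pcps = n_pcps, patients_per_pcp = patients_per_pcp,
                  seed = seed)
}
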