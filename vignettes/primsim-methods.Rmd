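---
title: "Methods: an agent-based discrete-event model of primary care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an agent-based discrete-event model of primary care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primsim)
```

# The model

`primsim` couples an agent-based representation of a primary care system —
every patient and every primary care physician (PCP) is an individual with
state and preferences — with a discrete-event engine that advances time from
event to event. The model is a closed system: a fixed population of patients
interacts with a fixed roster of physicians; there are no referrals,
hospitals, no-shows, seasonality, holidays, or infection dynamics, and
treatments do not alter illness durations. These are deliberate scope
limits, not accidents: the model targets the macro-level interplay of
demand (illness burden in an aging population) and supply (physician
capacity and operating strategies), not clinical detail.

## Time

Time is measured in days with a fractional *decimal time* part: `(38, 0.55)`
is day 38 at `0.55 * 1440 = 792` minutes, 13:12. The same pair encodes
durations. Every time object maps to the scalar `day + frac`, and all
internal comparisons use that scalar with a tolerance of 1e-9 days (86 µs) —
coarse enough to absorb float noise, fine enough that no two distinct
clinical instants collide. Days split into a morning and an afternoon
session; sessions recur weekly, so there are 14 weekly session classes. Day
0 is a Monday by convention, which pins down which classes are weekend
classes for closed practices.

## Illnesses

An illness family fixes linear functions of the seriousness `s` on `[0, 1]`:
the expected duration `D(s)` and expected willingness to wait `W(s)` in
days, the deterministic follow-up interval `N(s)`, and a chronic flag.
Chronic families never carry a duration (they neither develop nor heal);
acute families without a duration model one-visit concerns such as
vaccinations and resolve upon their first treatment. Emerged illnesses draw

* the family from the age-class-specific mixing distribution,
* the seriousness from a triangular distribution on `[0, 1]` (default mode
  0.3 — most cases are mild),
* the duration from a log-normal with mean `Δ^d_a · D(s)` and coefficient of
  variation 0.25,
* the willingness to wait from a Weibull with mean `Δ^ω_a · W(s)` and shape
  `k = 2`,

while the follow-up interval is always exactly `N(s)`. The dispersion
parameters (triangular mode, log-normal CV, Weibull shape) are modeling
choices — only the distribution families and their means are pinned down by
the trait functions — and all of them live in `sim_control()`. Negative
evaluations of a trait function are clamped at zero with a one-time warning;
with the shipped coefficient tables this cannot occur inside `[0, 1]`.
Illness onsets per patient form a homogeneous Poisson process with annual
rate `I_a(c)`, a linear function of the health condition `c`; the whole
process per run is pre-drawn as Poisson counts plus sorted uniform
positions, which is exactly the order-statistics construction of the
process.

## Patients and ratings

Patients have a fixed location, health condition, age class, weekly session
availabilities, and a consideration set of the `n_consider = 5` nearest
physicians (the distance submodel is great-circle distance; the kernel
`1 / (1 + d / d0)` with `d0 = 5` km halves at 5 km). Ratings start at
`w_dist · kernel + w_match · overlap`, where `overlap` is the fraction of
the 14 weekly classes in which the physician is open *and* the patient
available; walk-in ratings are additionally zero wherever a visit is
impossible. Updates are multiplicative — granted request ×1.1, failed
request ×0.8, short wait ×1.05, wait above 30 minutes ×0.9, rejection at the
door ×0.6 — floored at zero. Only monotone directions are structurally
meaningful; the factors are configurable. Chronic patients keep a family
physician and switch only when a challenger's rating exceeds the
incumbent's by more than 20% (`switch_margin`), modeling continuity of
care.

Care-seeking after an onset: an acute appointment already booked within the
new illness's willingness window is reused (patients never hold two acute
appointments). Otherwise up to two appointment requests go to the top-rated
considered physicians; each request asks for the earliest free slot after
the request and within the willingness to wait, in a session the patient
can attend. If both fail, the patient walks in at the best-rated feasible
(physician, session) pair, arrival placed at a Beta(2, 2) fraction of the
open window. When *no* session lies inside the willingness window the
patient targets the next feasible session instead (earliest day, best
rating): patients always seek treatment, and a care-forgone event is
recorded only when a full fortnight offers no feasible session (or a
rejection cascade exhausts `3 × n_consider` retries). This always-seek rule
matters: making such patients abandon care creates a large artificial
channel in which a *larger* willingness to wait recovers forgone patients
and *raises* utilization, inverting the substitution-and-cancellation
mechanism the sensitivity analysis is meant to expose.

## Physicians and strategies

Physicians run three interchangeable strategies, pluggable per scenario:

* **Scheduling** — individual-block/fixed-interval: a fixed grid of
  `slot_min` -minute slots (default 10, the mean service time rounded up to
  5 minutes) inside the opening hours, one patient per slot, earliest free
  slot offered.
* **Treatment** — priority first-come-first-served: appointment holders
  strictly before walk-ins, emergency walk-ins before ordinary ones, FCFS
  within class. Service times are log-normal with mean `service_mean_min`
  (default 7 minutes, CV 0.25); a queue longer than 4 shrinks the mean by
  the speed factor 0.8 (physicians consciously speed up under load).
* **Admission** — priority threshold with end-of-buffer learning:
  appointment holders are always admitted (admitted patients must be
  treated); a walk-in is admitted iff the predicted completion of present
  plus still-booked work, at the current mean service time, fits within the
  session's one-hour buffer plus a threshold θ (minutes). Emergencies get
  θ + 30. After each session θ moves by ±5 minutes — down after realized
  overtime, up after ≥30 idle minutes — clamped to [−60, 60].

Punctuality of appointment holders is normal with SD 5 minutes, clamped
into the session window. Overtime is work performed after the buffer end;
work inside the buffer is neither idle nor overtime, and the utilization
denominator counts published opening hours only.

## The event engine

Events (onset, recovery, appointment/walk-in arrival, session open/close,
buffer end, treatment completion, regular-care due) sit in a queue keyed by
time plus a small kind-priority increment (session openings before
arrivals, arrivals before completions, completions before closings), so
simultaneous events resolve in a fixed order; within identical keys the
insertion order — itself deterministic — decides. The queue is a flat
pair of preallocated vectors (sort key, packed integer payload) padded with
`Inf`, popped by `which.min` with swap-delete; at desk scale the live queue
stays in the low thousands and the engine processes tens of thousands of
events per second. One root seed per run feeds five named RNG substreams
(onsets, illness traits, service times, arrivals, behavioral choices), so a
change in one model component leaves unrelated draws untouched, and
identical inputs give bit-identical results.

Initialization is empty-state: no illnesses, no bookings, neutral ratings,
θ = 0. Indicators are accumulated only after the warm-up period. The one
exception to strict emptiness is chronic care: each chronic patient's first
regular-care due time is uniform in `[0, ν)`, the stationary phase of a
periodic regime — an all-at-once day-0 stampede is precisely the
initialization bias the warm-up machinery exists to remove, and staggering
shortens the warm-up a desk-scale experiment needs. Follow-up and regular
appointments are booked at treatment time (target `now + ν`, tolerance
±ν/4 for follow-ups; regular bookings search forward over the chronic
illness's willingness window and retry after 7 days when full, because
chronic illnesses are treated only in regular appointments and must not
fall back to walk-ins).

## Indicators and statistics

Per run the engine reports, per physician and aggregated: treatments,
walk-ins, arranged acute and regular appointments, service hours, overtime
minutes, rejected patients, capacity hours, and utilization; per patient
side: access time (scheduled minus request, days) for acute and regular
bookings, access distance (km per attended visit), waiting time by visit
type (appointment waits measured from the later of arrival and scheduled
time), the fraction of appointments starting within 5 minutes of schedule,
illness and cancellation counts, and the conservation counters (arrivals =
admissions + rejections; treatments = attended appointments + admitted
walk-ins, all counted at service start so the identity is exact at any
horizon). Replicated experiments summarize each KPI with a two-sided
Student-t interval.

The warm-up test is a standardized-partial-sum (Brownian bridge area)
statistic: with `S_k = Σ_{i≤k}(Ȳ − Y_i)`,
`Z = √12 · Σ_k S_k / (n^{3/2} σ̂)`, where `σ̂²` comes from batch means — 5
batches over the last half of the series, the part least affected by any
transient — and `Z` is referred to a t distribution with 4 degrees of
freedom, two-sided at 5%. Only the test's name, sidedness, level, and
variance estimator are externally fixed; the normalization is our choice,
and the test suite therefore verifies its operating characteristics by
Monte Carlo (type-I error within sampling error of 5% on i.i.d. series;
power above 0.8 against a 2-SD bias over the first 15 of 70 points) rather
than trusting the construction. `find_warmup()` raises the truncation in
steps until no tracked per-period series rejects.

`sensitivity_sweep()` varies one numeric input relative to its base value
over a ±range grid, re-running the experiment at each point with the same
seeds, so the zero-delta point reproduces the base experiment exactly and
curves are smooth in the common-random-numbers sense.

# The synthetic scenario generator

No real physician register or census extract ships with the package; the
generator reconstructs a rural three-municipality system of the same shape.
Population cells are one-hectare squares on 100 m grids (one block per
municipality, blocks a few km apart); each municipality's population
spreads multinomially over its cells with at least one resident each.
Children under 16, recorded per municipality, are excluded by fixing one
adult per cell and removing the child count uniformly from the remainder —
so the adult total equals population minus children exactly, for any seed.
Patients then draw: location uniform in their cell, health condition
Beta(25, 25) (mean 0.5), age class categorical (shares 0.1196 / 0.6318 /
0.2486 for 16–24 / 25–65 / >65), fourteen Bernoulli session availabilities
(0.85 / 0.55 / 0.95), chronic status Bernoulli (0.12 / 0.33 / 0.52), and —
if chronic — one chronic illness from the chronic mixing table. Physician
locations are uniform over the cell bounding box; all practices share
Monday–Friday hours 08:00–12:00 and 14:00–16:15 and the case-study strategy
set.

Two anchor choices deserve note. The weekly opening time (31.25 h) matches
the per-physician capacity implied by the reference system's printed annual
capacity, and the 7-minute mean service time is what that capacity, its
utilization, and its treatment volume jointly imply; both were fixed from
those printed quantities before any acceptance run. The
`scenario_preset()` keeps the reference ratio of roughly 1500 patients per
physician and scales the absolute size through `n_pcps`.

What the generator does *not* emulate: real spatial clustering of practices
and population, heterogeneous opening hours, empirically estimated
consideration sets and family-physician assignments (both are derived from
distance and ratings at run initialization), and correlated availabilities.
Tests passing on synthetic scenarios therefore validate the mechanics and
the qualitative regime behavior, not point predictions for any real
system.

# Study conditions used by the test suite

Problem sizes are the package's own desk-scale choices: the what-if
comparison uses the 3-physician / 4500-patient preset, removes one
physician (a 33% capacity loss), and averages 20 replications of a 63-day
measurement window after a 21-day warm-up; the sensitivity direction check
runs a 1-physician / 2250-patient configuration — the near-capacity
operating point at which the reference system operates, where the
walk-in-to-appointment substitution dominates — over a ±20% grid in 10%
steps with 3 paired-seed replications; generator moments are checked at
10⁵ patients; statistical calibration uses 1000 (type-I) and 400 (power)
Monte-Carlo replications. The hand-checkable engine oracle zeroes every
variance (`deterministic = TRUE` collapses each sampler to its mean) in a
1-patient/1-physician scenario and compares the full event trace and every
indicator against a paper-and-pencil derivation.

# Known limitations

* Waiting rooms are uncapacitated and patient travel is instantaneous;
  access distance is recorded but does not delay arrivals.
* Appointment requests resolve instantaneously (no phone-queue dynamics).
* Walk-in retry chains exclude only the just-rejected (physician, session)
  pair and are capped, so pathological ping-pong between two overloaded
  practices within one session is truncated rather than modeled.
* The per-run KPI attribution counts a treatment at service start and its
  service time at completion; a treatment spanning the horizon end
  contributes its count but not its final minutes.
* Rating dynamics are internal to each patient; there is no word of mouth,
  and rating scales are only meaningful relative to the configured update
  factors.
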