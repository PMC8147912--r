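#' Temporal algebra: decimal time, sessions, weekly session classes
#'
#' The simulator measures time in days with a fractional *decimal time*
#' component: a time object is a pair `(day, frac)` with `day` a non-negative
#' integer and `frac` in `[0, 1)`. The same encoding serves both points in
#' time and durations; context decides which. Every time object is associated
#' with the scalar `day + frac`, and all internal comparisons use that scalar
#' (tolerance 1e-9 days).
#'
#' Each day splits into a morning (`half = 0`) and an afternoon (`half = 1`)
#' clinical session. Sessions recur weekly, giving 14 weekly session classes
#' (Monday morning ... Sunday afternoon). Day 0 is a Monday, so weekday
#' classes are `weekday` 0--4 and weekend classes 5--6.
#'
#' @name timebase
NULL

#' Construct a time point (or duration)
#'
#' @param day Non-negative integer day component.
#' @param frac Decimal-time fraction in `[0, 1)`.
#' @return A tibble with columns `day`, `frac` and the scalar `value
#'   = day + frac`. Vectorized over both arguments.
#' @examples
#' time_point(38, 0.55)
#' @export
time_point <- function(day, frac = 0) {
  n <- max(length(day), length(frac))
  day <- rep_len(as.numeric(day), n)
  frac <- rep_len(as.numeric(frac), n)
  if (any(day < 0) || any(day != floor(day))) {
    rlang::abort("`day` must be a non-negative integer")
  }
  if (any(frac < 0 | frac >= 1)) {
    rlang::abort("`frac` must lie in [0, 1)")
  }
  tibble::tibble(day = day, frac = frac, value = day + frac)
}

#' Scalar value of a time point
#'
#' Collapses `(day, frac)` to the non-negative scalar `day + frac`; the total
#' order on time points agrees with this value.
#'
#' @param t A tibble from [time_point()], or a numeric scalar value already.
#' @return Numeric vector of day-valued scalars.
#' @export
time_scalar <- function(t) {
  if (is.data.frame(t)) t$day + t$frac else as.numeric(t)
}

#' Decode a time point into day and minutes-of-day
#'
#' `(38, 0.55)` decodes to day 38 and `24 * 60 * 0.55 = 792` minutes,
#' i.e. 13:12.
#'
#' @param t A tibble from [time_point()] or a numeric scalar time.
#' @return A tibble with columns `day`, `minutes` and a formatted `label`
#'   (`"d<day> HH:MM"`), the serialization used in trace output.
#' @examples
#' decode_time(time_point(38, 0.55))
#' @export
decode_time <- function(t) {
  if (is.data.frame(t)) {
    day <- t$day
    frac <- t$frac
  } else {
    v <- as.numeric(t)
    day <- floor(v + 1e-12)
    frac <- v - day
  }
  minutes <- 24 * 60 * frac
  hh <- floor(minutes / 60)
  mm <- floor(minutes - 60 * hh + 1e-9)
  tibble::tibble(
    day = day, minutes = minutes,
    label = sprintf("d%d %02d:%02d", as.integer(day), as.integer(hh), as.integer(mm))
  )
}

#' Encode a day and minutes-of-day as a time point
#'
#' Inverse of [decode_time()]: `encode_time(38, 792)` gives `(38, 0.55)`.
#'
#' @param day Non-negative integer day.
#' @param minutes Minutes of day in `[0, 1440)`.
#' @return A [time_point()] tibble.
#' @export
encode_time <- function(day, minutes) {
  if (any(minutes < 0 | minutes >= 1440)) {
    rlang::abort("`minutes` must lie in [0, 1440)")
  }
  time_point(day, minutes / (24 * 60))
}

#' Construct a session
#'
#' @param day Non-negative integer day.
#' @param half 0 for the morning session, 1 for the afternoon session.
#' @return A tibble with columns `day`, `half`.
#' @export
session <- function(day, half) {
  n <- max(length(day), length(half))
  day <- rep_len(as.integer(day), n)
  half <- rep_len(as.integer(half), n)
  if (any(day < 0)) rlang::abort("`day` must be non-negative")
  if (!all(half %in% c(0L, 1L))) rlang::abort("`half` must be 0 or 1")
  tibble::tibble(day = day, half = half)
}

#' Weekly session class of a session
#'
#' Sessions `(d1, g1)` and `(d2, g2)` are equivalent iff `d1 = d2 (mod 7)` and
#' `g1 = g2`; there are exactly 14 classes. Classes are indexed
#' `1 + 2 * weekday + half` in `1..14` (day 0 being a Monday), the layout used
#' for availability and opening-hour tables throughout the package.
#'
#' @param s A session tibble from [session()].
#' @return A tibble with columns `weekday` (0--6), `half`, and the linear
#'   `class_id` in 1..14.
#' @examples
#' weekly_class(session(c(0, 7, 3), c(0, 0, 1)))
#' @export
weekly_class <- function(s) {
  wd <- s$day %% 7L
  tibble::tibble(weekday = wd, half = s$half, class_id = 1L + 2L * wd + s$half)
}

#' @rdname weekly_class
#' @param day,half Session components (vectorized); bare-integer fast path.
#' @export
weekly_class_id <- function(day, half) {
  1L + 2L * (as.integer(day) %% 7L) + as.integer(half)
}

#' Labels of the 14 weekly session classes
#'
#' @return Character vector of length 14, e.g. `"Mon-AM"`, in `class_id` order.
#' @export
weekly_class_labels <- function() {
  days <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
  paste0(rep(days, each = 2), c("-AM", "-PM"))
}

# scalar comparison tolerance, in days
.time_eps <- 1e-9
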