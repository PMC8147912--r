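#' Patients, physicians, ratings, and care-seeking choices
#'
#' Patients track their satisfaction with each considered physician through
#' non-negative internal ratings: one appointment rating per physician and one
#' walk-in rating per physician and weekly session class. Ratings start from
#' the physician's geographic proximity and the overlap between the
#' physician's opening hours and the patient's session availabilities, and
#' are then updated multiplicatively by experiences. All care-seeking choices
#' (appointment requests, walk-in targeting, family-physician switching) rank
#' physicians by the relevant rating with deterministic lexicographic
#' tie-breaks.
#'
#' @name agents
NULL

#' Great-circle distance in kilometres
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (WGS84).
#' @return Haversine distances in km (vectorized).
#' @export
distance_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2)) / 1000
}

# distance kernel: 1 at distance 0, 1/2 at d0, -> 0 far away
dist_kernel <- function(d_km, d0_km) 1 / (1 + d_km / d0_km)

#' Opening-hours helper: which weekly classes is a PCP open?
#'
#' @param hours A 14 x 2 matrix of `(open, close)` decimal times per weekly
#'   session class (`NA` row = closed).
#' @return Logical vector of length 14.
#' @export
open_classes <- function(hours) !is.na(hours[, 1])

#' Initial ratings of considered physicians
#'
#' Every considered physician starts with the appointment rating
#' `w_dist / (1 + d / d0) + w_match * overlap`, where `overlap` is the
#' fraction of the 14 weekly session classes in which the physician is open
#' *and* the patient is available. Walk-in ratings start from the same value
#' per session class but are zero wherever the physician is closed or the
#' patient unavailable (such sessions are never chosen).
#'
#' @param patient One-row patient tibble (columns `lat`, `lon`, and a 14-long
#'   logical availability in `avail[[1]]`).
#' @param pcps Physician roster tibble (columns `id`, `lat`, `lon`, and
#'   list-column `hours` of 14 x 2 matrices).
#' @param control A [sim_control()].
#' @return A list with tibbles `appointment` (`pcp`, `rating`) and `walkin`
#'   (`pcp`, `class_id`, `rating`).
#' @export
initial_ratings <- function(patient, pcps, control = sim_control()) {
  ctl <- as_sim_control(control)
  if (nrow(pcps) == 0) rlang::abort("consideration set must be non-empty")
  avail <- patient$avail[[1]]
  d <- distance_km(patient$lat, patient$lon, pcps$lat, pcps$lon)
  open <- vapply(pcps$hours, open_classes, logical(14))    # 14 x npcp
  both <- open & avail
  base <- ctl$w_dist * dist_kernel(d, ctl$dist_scale_km) +
    ctl$w_match * colSums(both) / 14
  walk <- matrix(rep(base, each = 14), nrow = 14) * both
  list(
    appointment = tibble::tibble(pcp = pcps$id, rating = base),
    walkin = tibble::tibble(
      pcp = rep(pcps$id, each = 14),
      class_id = rep(1:14, times = nrow(pcps)),
      rating = as.numeric(walk)
    )
  )
}

#' Update a rating after an experience
#'
#' Negative experiences (a failed appointment request, an excessive wait, a
#' rejection at the door) strictly decrease the rating; positive experiences
#' (a granted request, a short wait) strictly increase it. Updates are
#' multiplicative with configurable factors and floored at zero.
#'
#' @param rating Current non-negative rating (vectorized).
#' @param experience One of `"request_granted"`, `"request_failed"`,
#'   `"short_wait"`, `"long_wait"`, `"rejected_at_door"`.
#' @param control A [sim_control()].
#' @return Updated rating(s).
#' @export
update_rating <- function(rating, experience, control = sim_control()) {
  ctl <- as_sim_control(control)
  if (!experience %in% names(ctl$rating_factors)) {
    rlang::abort(paste0("unknown experience kind: ", experience))
  }
  pmax(0, rating * ctl$rating_factors[[experience]])
}

#' Choose appointment-request targets
#'
#' Patients make up to two appointment requests in descending order of the
#' appointment rating; ties break on the lexicographically smaller physician
#' identifier.
#'
#' @param ratings Tibble with columns `pcp` and `rating`.
#' @return Character/integer vector of at most two physician ids.
#' @export
choose_appointment_targets <- function(ratings) {
  if (nrow(ratings) == 0) rlang::abort("at least one considered PCP required")
  ord <- order(-ratings$rating, ratings$pcp)
  ratings$pcp[ord][seq_len(min(2, nrow(ratings)))]
}

#' Choose a walk-in target
#'
#' Maximizes the walk-in rating over feasible (physician, session) pairs;
#' among equal ratings the earlier session wins, then the smaller physician
#' id.
#'
#' @param candidates Tibble with columns `pcp`, `day`, `half`, `rating`
#'   (already restricted to sessions where the physician is open and the
#'   patient available and willing to wait).
#' @return One-row tibble (`pcp`, `day`, `half`, `rating`), or `NULL` when no
#'   candidate exists (the patient forgoes care for this cycle).
#' @export
choose_walkin_target <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0) return(NULL)
  ord <- order(-candidates$rating, candidates$day + candidates$half / 2,
               candidates$pcp)
  candidates[ord[1], ]
}

#' Reevaluate the family physician
#'
#' A chronic patient switches to the top-rated considered physician only if
#' its appointment rating exceeds the incumbent's by more than the configured
#' relative margin; otherwise the incumbent is kept (continuity of care).
#'
#' @param current Id of the incumbent family physician.
#' @param ratings Tibble with columns `pcp`, `rating`.
#' @param control A [sim_control()].
#' @return The id of the (possibly unchanged) family physician.
#' @export
reevaluate_family_physician <- function(current, ratings,
                                        control = sim_control()) {
  ctl <- as_sim_control(control)
  top <- choose_appointment_targets(ratings)[1]
  if (identical(top, current)) return(current)
  r_top <- ratings$rating[ratings$pcp == top]
  r_cur <- ratings$rating[ratings$pcp == current]
  if (length(r_cur) == 0) return(top)  # incumbent left the roster
  if (r_top > (1 + ctl$switch_margin) * r_cur) top else current
}
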