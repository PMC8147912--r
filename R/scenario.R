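#' Simulation scenarios
#'
#' A scenario bundles everything a run needs: the illness families, age
#' classes, and mixing distributions; the physician roster with locations,
#' weekly opening hours, and strategy parameters; the patient population; and
#' the control parameters. Populations are generated from census-style
#' hectare population cells: one adult is fixed per cell, under-16-year-olds
#' are removed uniformly per municipality, and patient attributes are drawn
#' from the age-class tables.
#'
#' @name scenario_io
NULL

#' Build a weekly opening-hours matrix
#'
#' @param morning,afternoon `c(open, close)` in hours of day, or `NULL` for
#'   closed; applied Monday--Friday. Weekends are closed.
#' @return A 14 x 2 matrix of decimal times (`NA` = closed), rows in weekly
#'   class order.
#' @export
weekday_hours <- function(morning = c(8, 12), afternoon = c(14, 16.25)) {
  m <- matrix(NA_real_, 14, 2, dimnames = list(weekly_class_labels(),
                                               c("open", "close")))
  for (wd in 0:4) {
    if (!is.null(morning)) m[1 + 2 * wd, ] <- morning / 24
    if (!is.null(afternoon)) m[2 + 2 * wd, ] <- afternoon / 24
  }
  m
}

#' Synthetic census-style population cells
#'
#' Lays out one-hectare cells on 100 m grids (one compact block per
#' municipality, blocks a few kilometres apart) and distributes each
#' municipality's population over its cells, at least one resident per cell.
#'
#' @param municipality_totals Named vector of municipality populations.
#' @param n_cells Named vector of cell counts per municipality.
#' @param center `c(lat, lon)` of the region.
#' @return Tibble with columns `municipality`, `lat`, `lon`, `count`.
#' @export
make_cells <- function(municipality_totals, n_cells,
                       center = c(50.55, 6.25)) {
  stopifnot(length(municipality_totals) == length(n_cells))
  munis <- names(municipality_totals)
  if (is.null(munis)) munis <- paste0("M", seq_along(municipality_totals))
  offs <- cbind(c(0, 0.045, 0.01), c(0, 0.01, 0.055))  # ~ 4-6 km apart
  out <- vector("list", length(munis))
  for (k in seq_along(munis)) {
    n <- n_cells[k]
    side <- ceiling(sqrt(n))
    idx <- seq_len(n) - 1L
    lat0 <- center[1] + offs[(k - 1) %% 3 + 1, 1]
    lon0 <- center[2] + offs[(k - 1) %% 3 + 1, 2]
    lat <- lat0 + (idx %/% side) * (100 / 111320)
    lon <- lon0 + (idx %% side) * (100 / (111320 * cos(lat0 * pi / 180)))
    total <- municipality_totals[k]
    if (total < n) rlang::abort("each cell needs at least one resident")
    extra <- stats::rmultinom(1, total - n, rep(1, n))[, 1]
    out[[k]] <- tibble::tibble(municipality = munis[k], lat = lat, lon = lon,
                               count = as.integer(1L + extra))
  }
  dplyr::bind_rows(out)
}

#' Exclude under-16-year-olds from a cell population
#'
#' Children are recorded per municipality while the population is recorded
#' per cell. One adult is fixed in every cell (children do not live on their
#' own); the municipality's child count is then removed by uniform sampling
#' without replacement from the remaining residents of its cells. The total
#' number of adults equals total population minus total children, exactly and
#' for any seed.
#'
#' @param cells Cell tibble from [make_cells()] (columns `municipality`,
#'   `lat`, `lon`, `count`).
#' @param child_counts Named vector of under-16 counts per municipality.
#' @return The cell tibble with an added `adults` column (>= 1 everywhere).
#' @export
exclude_minors <- function(cells, child_counts) {
  cells$adults <- NA_integer_
  for (m in unique(cells$municipality)) {
    sel <- which(cells$municipality == m)
    cnt <- cells$count[sel]
    kids <- child_counts[[m]]
    if (is.null(kids) || is.na(kids)) kids <- 0L
    remaining <- cnt - 1L
    if (kids > sum(remaining)) {
      rlang::abort(paste0("municipality ", m, ": child count ", kids,
                          " exceeds population minus fixed adults ",
                          sum(remaining)))
    }
    removed <- integer(length(sel))
    if (kids > 0) {
      pool <- rep(seq_along(sel), remaining)
      hit <- pool[sample.int(length(pool), kids)]
      tb <- tabulate(hit, nbins = length(sel))
      removed <- tb
    }
    cells$adults[sel] <- as.integer(1L + remaining - removed)
  }
  cells
}

#' Generate a patient population from adult cell counts
#'
#' Per patient: the location is uniform within the (one-hectare) cell, the
#' health condition is Beta(p, q) distributed (default `p = q = 25`, mean
#' 0.5), the age class is categorical, each of the 14 weekly session
#' availabilities is an independent Bernoulli draw with the age class's
#' availability probability, chronic status is Bernoulli with the age class's
#' chronic probability, and chronic patients receive their unique chronic
#' illness from the chronic mixing distribution.
#'
#' @param cells Cell tibble with an `adults` column (see [exclude_minors()]).
#' @param age_classes Age-class table with `share`, `avail_prob`,
#'   `chronic_prob` columns.
#' @param families Family table.
#' @param chronic_mix Chronic mixing matrix (may be `NULL` if no age class
#'   has a positive chronic probability).
#' @param age_dist Optional age-class distribution overriding the `share`
#'   column (named or in table order).
#' @param beta_shape `c(p, q)` of the health-condition beta distribution.
#' @param control A [sim_control()].
#' @return Patient tibble: `id`, `cell`, `lat`, `lon`, `c`, `age`, `avail`
#'   (list of 14 logicals), `chronic`, `chronic_family`, `chronic_s`.
#' @export
generate_patients <- function(cells, age_classes = default_age_classes(),
                              families = default_families(),
                              chronic_mix = default_chronic_mix(),
                              age_dist = NULL, beta_shape = c(25, 25),
                              control = sim_control()) {
  ctl <- as_sim_control(control)
  if (is.null(cells$adults)) rlang::abort("cells need an `adults` column")
  if (is.null(age_dist)) {
    age_dist <- stats::setNames(age_classes$share, age_classes$name)
  }
  if (!is.null(names(age_dist))) {
    age_dist <- age_dist[age_classes$name]
  }
  if (abs(sum(age_dist) - 1) > 1e-9 || any(age_dist < 0)) {
    rlang::abort("age-class distribution must be a probability vector")
  }
  n <- sum(cells$adults)
  cell_idx <- rep(seq_len(nrow(cells)), cells$adults)
  lat <- cells$lat[cell_idx] + stats::runif(n, -50, 50) / 111320
  lon <- cells$lon[cell_idx] +
    stats::runif(n, -50, 50) / (111320 * cos(cells$lat[cell_idx] * pi / 180))
  cc <- stats::rbeta(n, beta_shape[1], beta_shape[2])
  age_i <- sample.int(nrow(age_classes), n, replace = TRUE, prob = age_dist)
  avail_m <- matrix(stats::runif(n * 14) < age_classes$avail_prob[age_i],
                    nrow = n)
  chronic <- stats::runif(n) < age_classes$chronic_prob[age_i]
  chronic_family <- rep(NA_character_, n)
  chronic_s <- rep(NA_real_, n)
  for (k in seq_len(nrow(age_classes))) {
    sel <- which(chronic & age_i == k)
    if (length(sel) > 0) {
      draw <- sample_chronic_illness(length(sel), age_classes[k, ], families,
                                     chronic_mix, ctl)
      chronic_family[sel] <- draw$family
      chronic_s[sel] <- draw$s
    }
  }
  tibble::tibble(
    id = seq_len(n), cell = cell_idx, lat = lat, lon = lon, c = cc,
    age = age_classes$name[age_i],
    avail = lapply(asplit(avail_m, 1), as.logical),
    chronic = chronic, chronic_family = chronic_family, chronic_s = chronic_s
  )
}

#' Generate a synthetic physician roster
#'
#' Physicians are placed uniformly over the bounding box of the population
#' cells, open Monday--Friday with a morning and an afternoon session, and
#' all run the case-study strategy set (fixed-interval scheduling, PFCFS
#' treatment, priority-threshold admission).
#'
#' @param n Number of physicians.
#' @param cells Cell tibble (for the bounding box).
#' @param morning,afternoon Session windows in hours of day.
#' @return Physician tibble: `id`, `lat`, `lon`, `hours` (list of 14 x 2
#'   matrices).
#' @export
make_pcps <- function(n, cells, morning = c(8, 12), afternoon = c(14, 16.25)) {
  h <- weekday_hours(morning, afternoon)
  tibble::tibble(
    id = sprintf("pcp%02d", seq_len(n)),
    lat = stats::runif(n, min(cells$lat), max(cells$lat)),
    lon = stats::runif(n, min(cells$lon), max(cells$lon)),
    hours = replicate(n, h, simplify = FALSE)
  )
}

#' Assemble a scenario
#'
#' @param pcps Physician tibble (see [make_pcps()]).
#' @param patients Patient tibble (see [generate_patients()]).
#' @param families,age_classes,acute_mix,chronic_mix Parameter tables.
#' @param control A [sim_control()].
#' @param cells Optional cell tibble kept for provenance/transformers.
#' @param name Scenario label.
#' @return An object of class `primsim_scenario`.
#' @export
scenario <- function(pcps, patients, families = default_families(),
                     age_classes = default_age_classes(),
                     acute_mix = default_acute_mix(),
                     chronic_mix = default_chronic_mix(),
                     control = sim_control(), cells = NULL,
                     name = "scenario") {
  sc <- structure(
    list(name = name, families = families, age_classes = age_classes,
         acute_mix = acute_mix, chronic_mix = chronic_mix, pcps = pcps,
         patients = patients, cells = cells,
         control = as_sim_control(control)),
    class = "primsim_scenario"
  )
  bad <- validate_scenario(sc)
  if (length(bad) > 0) {
    rlang::abort(c("invalid scenario", stats::setNames(bad, rep("x", length(bad)))))
  }
  sc
}

#' Validate a scenario
#'
#' Checks every structural invariant (probability rows summing to one,
#' resolvable names, well-formed opening hours, chronic consistency, at least
#' one physician and patient) and returns all violations, not just the first.
#'
#' @param sc A `primsim_scenario` (or a bare list with the same fields).
#' @return Character vector of violations; empty when the scenario is valid.
#' @export
validate_scenario <- function(sc) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  fam <- sc$families; ac <- sc$age_classes
  if (is.null(sc$pcps) || nrow(sc$pcps) == 0) add("at least one PCP required")
  if (is.null(sc$patients) || nrow(sc$patients) == 0) {
    add("at least one patient required")
  }
  if (any(fam$chronic & !is.na(fam$d_slope))) {
    add("chronic families must not define a duration")
  }
  for (mx_name in c("acute_mix", "chronic_mix")) {
    mx <- sc[[mx_name]]
    if (is.null(mx)) next
    bad <- abs(rowSums(mx) - 1) > 1e-9
    if (any(bad)) {
      add(paste0(mx_name, " rows do not sum to 1 for age class(es): ",
                 paste(rownames(mx)[bad], collapse = ", ")))
    }
    if (!all(rownames(mx) %in% ac$name)) {
      add(paste0(mx_name, " references unknown age classes"))
    }
    unknown <- setdiff(colnames(mx), fam$name)
    if (length(unknown) > 0) {
      add(paste0(mx_name, " references unknown families: ",
                 paste(unknown, collapse = ", ")))
    }
    chronic_cols <- fam$chronic[match(colnames(mx), fam$name)]
    want <- mx_name == "chronic_mix"
    if (!anyNA(chronic_cols) && !all(chronic_cols == want)) {
      add(paste0(mx_name, " mixes acute and chronic families"))
    }
  }
  if (!is.null(sc$pcps) && nrow(sc$pcps) > 0) {
    for (i in seq_len(nrow(sc$pcps))) {
      h <- sc$pcps$hours[[i]]
      op <- h[, 1]; cl <- h[, 2]
      if (any(!is.na(op) & (op >= cl | op < 0 | cl >= 1))) {
        add(paste0("PCP ", sc$pcps$id[i],
                   ": opening hours must satisfy 0 <= open < close < 1"))
      }
    }
    if (anyDuplicated(sc$pcps$id)) add("duplicate PCP ids")
  }
  p <- sc$patients
  if (!is.null(p) && nrow(p) > 0) {
    if (!all(p$age %in% ac$name)) add("patients reference unknown age classes")
    if (any(p$c < 0 | p$c > 1)) add("health conditions must lie in [0, 1]")
    if (any(lengths(p$avail) != 14)) {
      add("availabilities must cover the 14 weekly session classes")
    }
    chr <- p$chronic
    if (any(chr & is.na(p$chronic_family))) {
      add("chronic patients need a chronic illness family")
    }
    known_chronic <- fam$name[fam$chronic]
    if (!all(p$chronic_family[chr] %in% known_chronic)) {
      add("chronic patients reference unknown or acute families")
    }
  }
  v
}

#' Scaled synthetic baseline scenario
#'
#' Reconstructs the case-study build at desk scale: a three-municipality cell
#' grid, the under-16 exclusion, the default family/age-class tables, and a
#' roster of identically configured physicians. The patients-per-physician
#' ratio of roughly 1500 : 1 is preserved; the absolute size scales with
#' `n_pcps`.
#'
#' @param n_pcps Number of physicians.
#' @param patients_per_pcp Target adults per physician.
#' @param seed Seed for the generator.
#' @param control A [sim_control()].
#' @return A `primsim_scenario`.
#' @export
scenario_preset <- function(n_pcps = 3, patients_per_pcp = 1500, seed = 1,
                            control = sim_control()) {
  set.seed(seed)
  adults_total <- n_pcps * patients_per_pcp
  shr <- c(0.22, 0.44, 0.34)                # rough municipality size split
  adults <- floor(adults_total * shr)
  adults[1] <- adults[1] + (adults_total - sum(adults))
  children <- round(0.1857 * adults)        # children per adult, census-like
  totals <- adults + children
  names(totals) <- names(children) <- c("Nordwald", "Mittelbach", "Suedhoehe")
  n_cells <- pmax(1L, round(totals / 12.9)) # ~12.9 residents per hectare cell
  cells <- make_cells(totals, n_cells)
  cells <- exclude_minors(cells, children)
  pcps <- make_pcps(n_pcps, cells)
  patients <- generate_patients(cells, control = control)
  scenario(pcps, patients, control = control, cells = cells,
           name = sprintf("synthetic baseline (%d PCPs)", n_pcps))
}

#' Remove physicians from a scenario (declining-roster variant)
#'
#' Keeps only the retained roster; the patient population is unchanged.
#' Consideration sets, ratings, and family physicians are derived from the
#' roster at run initialization, so patients whose family physician retired
#' are reassigned to their then top-rated remaining physician.
#'
#' @param sc A `primsim_scenario`.
#' @param retained Ids of the physicians that remain.
#' @return The reduced scenario.
#' @export
apply_pcp_decline <- function(sc, retained) {
  if (length(retained) == 0) rlang::abort("retained roster must be non-empty")
  if (!all(retained %in% sc$pcps$id)) {
    rlang::abort("retained roster must be a subset of the baseline roster")
  }
  sc$pcps <- sc$pcps[sc$pcps$id %in% retained, , drop = FALSE]
  sc$name <- paste0(sc$name, " [decline]")
  sc
}

#' Age the patient population (shifted age-class distribution)
#'
#' Redraws every patient's age class from the shifted distribution and
#' regenerates the age-dependent attributes (availabilities, chronic status,
#' chronic illness); locations, cells, and health conditions are preserved.
#'
#' @param sc A `primsim_scenario`.
#' @param age_dist New age-class distribution (named vector summing to 1),
#'   e.g. [aged_distribution()].
#' @param seed Seed for the regeneration.
#' @return The aged scenario.
#' @export
apply_aging <- function(sc, age_dist, seed = 1) {
  if (abs(sum(age_dist) - 1) > 1e-9 || any(age_dist < 0)) {
    rlang::abort("`age_dist` must be a probability distribution")
  }
  set.seed(seed)
  ac <- sc$age_classes
  if (!is.null(names(age_dist))) age_dist <- age_dist[ac$name]
  p <- sc$patients
  n <- nrow(p)
  age_i <- sample.int(nrow(ac), n, replace = TRUE, prob = age_dist)
  p$age <- ac$name[age_i]
  avail_m <- matrix(stats::runif(n * 14) < ac$avail_prob[age_i], nrow = n)
  p$avail <- lapply(asplit(avail_m, 1), as.logical)
  p$chronic <- stats::runif(n) < ac$chronic_prob[age_i]
  p$chronic_family <- NA_character_
  p$chronic_s <- NA_real_
  for (k in seq_len(nrow(ac))) {
    sel <- which(p$chronic & age_i == k)
    if (length(sel) > 0) {
      draw <- sample_chronic_illness(length(sel), ac[k, ], sc$families,
                                     sc$chronic_mix, sc$control)
      p$chronic_family[sel] <- draw$family
      p$chronic_s[sel] <- draw$s
    }
  }
  sc$patients <- p
  sc$name <- paste0(sc$name, " [aged]")
  sc
}

#' Write / read a scenario as JSON
#'
#' One self-contained JSON document; all probabilities and control values are
#' explicit, so a file fully determines the scenario.
#'
#' @param sc A `primsim_scenario`.
#' @param path File path.
#' @return `read_scenario()` returns the scenario; `write_scenario()` its
#'   path, invisibly.
#' @export
write_scenario <- function(sc, path) {
  ser <- list(
    name = sc$name,
    families = sc$families,
    age_classes = sc$age_classes,
    acute_mix = list(age = rownames(sc$acute_mix),
                     family = colnames(sc$acute_mix),
                     probs = unname(sc$acute_mix)),
    chronic_mix = if (!is.null(sc$chronic_mix)) {
      list(age = rownames(sc$chronic_mix), family = colnames(sc$chronic_mix),
           probs = unname(sc$chronic_mix))
    },
    pcps = list(
      id = sc$pcps$id, lat = sc$pcps$lat, lon = sc$pcps$lon,
      hours = lapply(sc$pcps$hours, function(h) unname(h))
    ),
    patients = list(
      id = sc$patients$id, cell = sc$patients$cell, lat = sc$patients$lat,
      lon = sc$patients$lon, c = sc$patients$c, age = sc$patients$age,
      avail = lapply(sc$patients$avail, as.integer),
      chronic = sc$patients$chronic,
      chronic_family = sc$patients$chronic_family,
      chronic_s = sc$patients$chronic_s
    ),
    cells = sc$cells,
    control = {
      ctl <- unclass(sc$control)
      ctl$rating_factors <- as.list(ctl$rating_factors)  # keep names in JSON
      ctl
    }
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk_mix <- function(m) {
    if (is.null(m) || is.null(m$age)) return(NULL)
    matrix(as.numeric(t(m$probs)), nrow = length(m$age), byrow = TRUE,
           dimnames = list(m$age, m$family))
  }
  hraw <- j$pcps$hours
  hours <- if (is.array(hraw) && length(dim(hraw)) == 3) {
    lapply(seq_len(dim(hraw)[1]), function(i) hraw[i, , ])
  } else {
    lapply(hraw, function(h) {
      if (!is.matrix(h)) h <- matrix(as.numeric(unlist(h)), ncol = 2,
                                     byrow = TRUE)
      h
    })
  }
  hours <- lapply(hours, function(m) {
    dimnames(m) <- list(weekly_class_labels(), c("open", "close"))
    m
  })
  pcps <- tibble::tibble(id = j$pcps$id, lat = j$pcps$lat, lon = j$pcps$lon,
                         hours = hours)
  pt <- j$patients
  araw <- pt$avail
  avail <- if (is.matrix(araw)) {
    lapply(asplit(araw, 1), function(a) as.logical(as.integer(a)))
  } else {
    lapply(araw, function(a) as.logical(as.integer(a)))
  }
  patients <- tibble::tibble(
    id = as.integer(pt$id), cell = as.integer(pt$cell), lat = pt$lat,
    lon = pt$lon, c = pt$c, age = pt$age,
    avail = avail,
    chronic = as.logical(pt$chronic),
    chronic_family = as.character(pt$chronic_family),
    chronic_s = as.numeric(pt$chronic_s)
  )
  cells <- if (!is.null(j$cells)) tibble::as_tibble(j$cells)
  scenario(pcps, patients, families = tibble::as_tibble(j$families),
           age_classes = tibble::as_tibble(j$age_classes),
           acute_mix = mk_mix(j$acute_mix),
           chronic_mix = mk_mix(j$chronic_mix),
           control = as_sim_control(j$control), cells = cells,
           name = j$name)
}

#' @export
print.primsim_scenario <- function(x, ...) {
  cat(sprintf(
    "<primsim_scenario> %s\n  %d PCPs, %d patients (%d chronic), %d families, %d age classes\n",
    x$name, nrow(x$pcps), nrow(x$patients), sum(x$patients$chronic),
    nrow(x$families), nrow(x$age_classes)))
  invisible(x)
}
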