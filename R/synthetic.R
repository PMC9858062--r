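# Synthetic study generator. Emulates the statistical structure the pipeline
# assumes: users whose trajectories contain planted stationary episodes
# separated by long-range transit, geospatial units whose daily footfall
# follows one of a small set of temporal archetypes with phase-level volume
# shifts, and urban-feature tables in which designated features carry
# archetype-dependent means.

#' Temporal activity archetype
#'
#' The expected number of stays a unit of this archetype receives on a given
#' day is `base_rate * weekday-or-weekend multiplier * phase multiplier`.
#' Archetypes emulate the temporal clusters observed in urban footfall:
#' commuter areas busy on weekdays, leisure areas busy at weekends, flat
#' low-activity areas, and areas that recover between lockdowns.
#'
#' @param name Archetype label.
#' @param base_rate Expected stays/unit/day before multipliers (>= 0).
#' @param weekday_multiplier,weekend_multiplier Positive factors applied
#'   Mon-Fri / Sat-Sun.
#' @param phase_multipliers Named positive numeric vector keyed by phase name;
#'   days in phases absent from the vector (or outside any phase) get 1.
#' @return An object of class `archetype_spec`.
#' @export
archetype_spec <- function(name, base_rate, weekday_multiplier = 1,
                           weekend_multiplier = 1, phase_multipliers = NULL) {
  stopifnot(base_rate >= 0, weekday_multiplier > 0, weekend_multiplier > 0)
  if (!is.null(phase_multipliers)) {
    stopifnot(is.numeric(phase_multipliers), all(phase_multipliers > 0),
              !is.null(names(phase_multipliers)))
  }
  structure(list(name = name, base_rate = base_rate,
                 weekday_multiplier = weekday_multiplier,
                 weekend_multiplier = weekend_multiplier,
                 phase_multipliers = phase_multipliers),
            class = "archetype_spec")
}

#' Default archetype set for a phase calendar
#'
#' Four archetypes spanning the canonical temporal patterns — busy-weekday,
#' busy-weekend, flat, recovering — with phase multipliers that collapse
#' activity at the first lockdown and (for the recovering archetype) climb
#' back between restrictions.
#'
#' @param calendar Phase calendar (list of [restriction_phase()]); multipliers
#'   are keyed to its phase names. Defaults to [default_calendar()].
#' @param base_rates Named base rates per archetype, stays/unit/day.
#' @return List of [archetype_spec()] objects.
#' @export
default_archetypes <- function(calendar = default_calendar(),
                               base_rates = c("busy-weekday" = 6, "busy-weekend" = 4,
                                              "flat" = 1.5, "recovering" = 2.5)) {
  nm <- vapply(calendar, `[[`, character(1), "name")
  k <- length(nm)
  ramp <- function(v) stats::setNames(v[seq_len(k)], nm)
  # post-lockdown collapse profiles; the recovering archetype climbs back
  drop_hard <- ramp(c(1, 0.35, 0.50, 0.45, 0.40, 0.35, 0.35, 0.30)[seq_len(max(k, 1))])
  drop_soft <- ramp(c(1, 0.45, 0.60, 0.55, 0.50, 0.45, 0.50, 0.40)[seq_len(max(k, 1))])
  recover <- ramp(c(1, 0.30, 0.70, 0.90, 0.85, 0.60, 0.70, 0.55)[seq_len(max(k, 1))])
  list(
    archetype_spec("busy-weekday", base_rates[["busy-weekday"]], 1.5, 0.5, drop_hard),
    archetype_spec("busy-weekend", base_rates[["busy-weekend"]], 0.6, 1.8, drop_soft),
    archetype_spec("flat", base_rates[["flat"]], 1.0, 1.0, drop_hard),
    archetype_spec("recovering", base_rates[["recovering"]], 1.0, 1.0, recover)
  )
}

#' Synthetic scenario definition
#'
#' Bundles everything the generators need; regeneration under a fixed seed is
#' deterministic.
#'
#' @param archetypes List of [archetype_spec()].
#' @param n_units Named integer vector: units per archetype (names must match
#'   archetype names; order gives the unit-to-archetype assignment).
#' @param n_users Number of synthetic panel users (>= 0).
#' @param calendar Phase calendar; also fixes the simulated date span.
#' @param feature_effect Named list keyed by archetype name; each element a
#'   named numeric vector of mean shifts for land-use columns (e.g.
#'   `list("busy-weekday" = c(lu_5 = 3))`). `NULL` plants no association.
#' @param noise_sd Nonnegative noise standard deviation for feature columns.
#' @param seed Integer seed driving all generators.
#' @param jitter_m Stay-point jitter radius, metres (strictly below the 50 m
#'   detection radius so planted stays always satisfy the detector contract).
#' @param stay_duration_s Planted stay duration, seconds (strictly above the
#'   300 s detection minimum).
#' @param points_per_stay GPS points emitted per planted stay (>= 3).
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(archetypes, n_units, n_users,
                               calendar = default_calendar(),
                               feature_effect = NULL, noise_sd = 0.5, seed = 1L,
                               jitter_m = 20, stay_duration_s = 600,
                               points_per_stay = 5L) {
  anames <- vapply(archetypes, `[[`, character(1), "name")
  stopifnot(all(names(n_units) %in% anames), n_users >= 0, noise_sd >= 0,
            jitter_m > 0, stay_duration_s > 0, points_per_stay >= 3L)
  validate_calendar(calendar)
  structure(list(archetypes = archetypes, n_units = n_units, n_users = n_users,
                 calendar = calendar, feature_effect = feature_effect,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 jitter_m = jitter_m, stay_duration_s = stay_duration_s,
                 points_per_stay = as.integer(points_per_stay)),
            class = "synthetic_scenario")
}

#' Generate a rectangular grid of geospatial units
#'
#' Cells are laid out in a local metric frame (metres east/north of `origin`)
#' and converted to WGS84 lon/lat, so nominal cell sizes stay consistent with
#' haversine distances at city latitudes. Cells tile the grid without overlap;
#' ids are stable (row-major).
#'
#' @param rows,cols Grid dimensions (>= 1).
#' @param cell_size_m Cell edge length in metres (> 0).
#' @param origin Numeric `c(lon, lat)` of the grid's south-west corner.
#' @return An object of class `haz_units`: a unit table plus polygon rings.
#' @export
generate_units <- function(rows, cols, cell_size_m = 500,
                           origin = c(-0.1278, 51.5074)) {
  stopifnot(rows >= 1, cols >= 1, cell_size_m > 0, length(origin) == 2)
  ids <- character(rows * cols)
  rings <- vector("list", rows * cols)
  rr <- integer(rows * cols); cc <- integer(rows * cols)
  k <- 0L
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      k <- k + 1L
      x0 <- (c - 1L) * cell_size_m; x1 <- c * cell_size_m
      y0 <- (r - 1L) * cell_size_m; y1 <- r * cell_size_m
      ring <- local_to_lonlat(c(x0, x1, x1, x0, x0), c(y0, y0, y1, y1, y0), origin)
      ids[k] <- sprintf("u%04d", k); rr[k] <- r; cc[k] <- c
      rings[[k]] <- ring
    }
  }
  structure(list(unit_id = ids, row = rr, col = cc, rings = rings,
                 origin = origin, cell_size_m = cell_size_m,
                 grid_rows = rows, grid_cols = cols),
            class = "haz_units")
}

#' @export
print.haz_units <- function(x, ...) {
  cat(sprintf("<haz_units> %d units (%s grid, %g m cells)\n",
              length(x$unit_id),
              if (!is.null(x$grid_rows)) paste0(x$grid_rows, "x", x$grid_cols) else "irregular",
              x$cell_size_m %||% NA))
  invisible(x)
}

#' @export
length.haz_units <- function(x) length(x$unit_id)

#' Assign archetypes to units
#'
#' Units (in id order) are assigned to archetypes block-wise according to the
#' scenario's `n_units` counts.
#'
#' @param units A [generate_units()] object.
#' @param scenario A [synthetic_scenario()].
#' @return Named character vector: unit_id -> archetype name.
#' @export
unit_archetype_map <- function(units, scenario) {
  m <- length(units$unit_id)
  if (sum(scenario$n_units) != m) {
    stop("scenario n_units (", sum(scenario$n_units),
         ") must total the number of units (", m, ")", call. = FALSE)
  }
  stats::setNames(rep(names(scenario$n_units), scenario$n_units), units$unit_id)
}

# Expected stays/unit/day under the archetype rate model, over the calendar's
# full date span: lambda = base_rate * weekday/weekend mult * phase mult.
expected_rate_matrix <- function(scenario, units) {
  cal <- scenario$calendar
  dates <- seq(cal[[1L]]$start_date, cal[[length(cal)]]$end_date, by = "day")
  amap <- unit_archetype_map(units, scenario)
  arch <- scenario$archetypes
  names(arch) <- vapply(arch, `[[`, character(1), "name")
  wkend <- format(dates, "%u") %in% c("6", "7")
  phase_of <- rep(NA_character_, length(dates))
  for (p in cal) phase_of[in_phase(dates, p)] <- p$name
  lam <- matrix(0, nrow = length(amap), ncol = length(dates),
                dimnames = list(names(amap), format(dates)))
  for (a in names(arch)) {
    sp <- arch[[a]]
    daily <- sp$base_rate * ifelse(wkend, sp$weekend_multiplier, sp$weekday_multiplier)
    if (!is.null(sp$phase_multipliers)) {
      pm <- ifelse(is.na(phase_of), 1,
                   ifelse(phase_of %in% names(sp$phase_multipliers),
                          sp$phase_multipliers[phase_of], 1))
      daily <- daily * pm
    }
    lam[amap == a, ] <- matrix(daily, nrow = sum(amap == a), ncol = length(dates),
                               byrow = TRUE)
  }
  lam
}

#' Generate daily footfall counts directly from the rate model
#'
#' Draws independent Poisson counts around the archetype rate model for every
#' unit-day — the aggregated-level counterpart of [generate_trajectories()],
#' used where the trajectory layer is not under study (e.g. clustering
#' experiments at larger unit counts).
#'
#' @param scenario A [synthetic_scenario()].
#' @param units A [generate_units()] object.
#' @return A [footfall_matrix()] with the archetype map attached as attribute
#'   `"archetype"`.
#' @export
generate_footfall_counts <- function(scenario, units) {
  set.seed(scenario$seed)
  lam <- expected_rate_matrix(scenario, units)
  counts <- matrix(stats::rpois(length(lam), lam), nrow = nrow(lam),
                   dimnames = dimnames(lam))
  out <- footfall_matrix(counts, rownames(lam), as.Date(colnames(lam)))
  attr(out, "archetype") <- unit_archetype_map(units, scenario)
  out
}

#' Generate synthetic GPS trajectories with planted stays
#'
#' Every planted stay emits `points_per_stay` points jittered within
#' `jitter_m` of a stay centre (strictly inside one grid cell) over
#' `stay_duration_s` seconds; consecutive stays of a user are separated by two
#' transit points placed far outside the grid and spaced hundreds of metres
#' apart, so transit can neither merge into a spurious stay nor extend a
#' planted one. Planted stay counts per unit-day are Poisson draws from the
#' archetype rate model. The returned ledger is therefore an exact oracle for
#' downstream stay detection and unit assignment.
#'
#' @param scenario A [synthetic_scenario()].
#' @param units A [generate_units()] grid.
#' @return List of class `synthetic_trajectories`: `points` (user_id, time,
#'   lon, lat; per-user time-sorted), `ledger` (one row per planted stay:
#'   user_id, unit_id, date, centre coords, start_time, duration_s).
#' @export
generate_trajectories <- function(scenario, units) {
  set.seed(scenario$seed)
  empty_pts <- data.frame(user_id = character(0),
                          time = as.POSIXct(character(0), tz = "UTC"),
                          lon = numeric(0), lat = numeric(0))
  empty_led <- data.frame(user_id = character(0), unit_id = character(0),
                          date = as.Date(character(0)), centre_lon = numeric(0),
                          centre_lat = numeric(0),
                          start_time = as.POSIXct(character(0), tz = "UTC"),
                          duration_s = numeric(0))
  if (scenario$n_users == 0L) {
    return(structure(list(points = empty_pts, ledger = empty_led),
                     class = "synthetic_trajectories"))
  }
  if (is.null(units$grid_rows)) stop("trajectory generator needs a grid", call. = FALSE)
  lam <- expected_rate_matrix(scenario, units)
  counts <- matrix(stats::rpois(length(lam), lam), nrow = nrow(lam),
                   dimnames = dimnames(lam))
  dates <- as.Date(colnames(lam))
  users <- sprintf("user%04d", seq_len(scenario$n_users))
  cell <- units$cell_size_m
  margin <- scenario$jitter_m + 5  # stay centre clear of cell edges
  stopifnot(cell > 2 * margin)
  grid_xmax <- units$grid_cols * cell
  grid_ymax <- units$grid_rows * cell
  dur <- scenario$stay_duration_s
  npts <- scenario$points_per_stay

  # allocate each planted stay to (user, day) round-robin over a per-day
  # shuffled user order, then lay stays out in disjoint time slots per user-day
  led <- list()
  for (j in seq_along(dates)) {
    day_counts <- counts[, j]
    total <- sum(day_counts)
    if (total == 0L) next
    uidx <- rep(seq_along(users), length.out = total)
    uidx <- uidx[sample.int(total)]
    unit_of <- rep(seq_len(nrow(counts)), day_counts)
    led[[length(led) + 1L]] <- data.frame(
      user = users[uidx], unit = rownames(counts)[unit_of], day = dates[j],
      stringsAsFactors = FALSE)
  }
  if (!length(led)) {
    return(structure(list(points = empty_pts, ledger = empty_led),
                     class = "synthetic_trajectories"))
  }
  led <- do.call(rbind, led)
  led <- led[order(led$user, led$day), , drop = FALSE]

  # per user-day slot layout: k stays get k equal slots of the 86400 s day
  key <- paste(led$user, led$day)
  slot_n <- ave(seq_along(key), key, FUN = length)
  slot_i <- ave(seq_along(key), key, FUN = seq_along)
  slot_len <- 86400 / slot_n
  pad <- 300  # seconds kept clear at both slot ends for transit separation
  stopifnot(all(slot_len >= dur + 2 * pad))
  start_s <- (slot_i - 1) * slot_len + pad +
    stats::runif(nrow(led)) * (slot_len - dur - 2 * pad)
  day0 <- as.POSIXct(paste0(format(led$day), " 00:00:00"), tz = "UTC")
  start_time <- day0 + start_s

  # stay centres uniform inside the unit's cell, clear of the edges
  ucol <- units$col[match(led$unit, units$unit_id)]
  urow <- units$row[match(led$unit, units$unit_id)]
  cx <- (ucol - 1) * cell + margin + stats::runif(nrow(led)) * (cell - 2 * margin)
  cy <- (urow - 1) * cell + margin + stats::runif(nrow(led)) * (cell - 2 * margin)
  cen <- local_to_lonlat(cx, cy, units$origin)

  # emit stay points: npts points spanning exactly dur seconds, jittered in a
  # disc of radius jitter_m around the centre
  ns <- nrow(led)
  rel_t <- seq(0, dur, length.out = npts)
  ang <- matrix(stats::runif(ns * npts, 0, 2 * pi), ns)
  rad <- scenario$jitter_m * sqrt(matrix(stats::runif(ns * npts), ns))
  px <- cx + rad * cos(ang)
  py <- cy + rad * sin(ang)
  stay_pts <- data.frame(
    user_id = rep(led$user, each = npts),
    time = rep(start_time, each = npts) + rep(rel_t, times = ns),
    lon = numeric(ns * npts), lat = numeric(ns * npts),
    stay_row = rep(seq_len(ns), each = npts))
  ll <- local_to_lonlat(as.vector(t(px)), as.vector(t(py)), units$origin)
  stay_pts$lon <- ll[, 1]; stay_pts$lat <- ll[, 2]

  # transit between consecutive stays of each user: two points far east of the
  # grid (>= 1 km from any cell) and >= 300 m from each other
  ord <- order(led$user, start_time)
  trans <- list()
  for (k in seq_len(ns - 1L)) {
    a <- ord[k]; b <- ord[k + 1L]
    if (led$user[a] != led$user[b]) next
    t0 <- start_time[a] + dur; t1 <- start_time[b]
    ty <- stats::runif(2, 0, grid_ymax)
    tl <- local_to_lonlat(c(grid_xmax + 1000, grid_xmax + 1300), ty, units$origin)
    trans[[length(trans) + 1L]] <- data.frame(
      user_id = led$user[a],
      time = t0 + as.numeric(t1 - t0, units = "secs") * c(1 / 3, 2 / 3),
      lon = tl[, 1], lat = tl[, 2], stay_row = NA_integer_)
  }
  pts <- rbind(stay_pts, if (length(trans)) do.call(rbind, trans))
  pts <- pts[order(pts$user_id, pts$time), c("user_id", "time", "lon", "lat")]
  rownames(pts) <- NULL

  ledger <- data.frame(user_id = led$user, unit_id = led$unit, date = led$day,
                       centre_lon = cen[, 1], centre_lat = cen[, 2],
                       start_time = start_time, duration_s = dur,
                       stringsAsFactors = FALSE)
  ledger <- ledger[order(ledger$user_id, ledger$start_time), , drop = FALSE]
  rownames(ledger) <- NULL
  structure(list(points = pts, ledger = ledger), class = "synthetic_trajectories")
}

#' Generate a static urban-feature table with planted associations
#'
#' Ten nonnegative continuous land-use acreage columns (`lu_0` .. `lu_9`) plus
#' one categorical socio-demographic supergroup column with eight levels.
#' Columns designated in the scenario's `feature_effect` get
#' archetype-dependent means; all other columns are archetype-independent
#' noise, so a downstream classifier can only learn from the planted effects.
#'
#' @param units A [generate_units()] object.
#' @param archetype_map Named unit_id -> archetype vector
#'   (see [unit_archetype_map()]).
#' @param scenario A [synthetic_scenario()].
#' @return data.frame: `unit_id`, `lu_0` .. `lu_9`, `supergroup` (factor).
#' @export
generate_urban_features <- function(units, archetype_map, scenario) {
  set.seed(scenario$seed + 1L)
  ids <- units$unit_id
  stopifnot(all(ids %in% names(archetype_map)))
  arch <- archetype_map[ids]
  m <- length(ids)
  lu_names <- paste0("lu_", 0:9)
  base <- 1  # baseline acreage mean, same for every column
  X <- matrix(pmax(0, base + stats::rnorm(m * 10, sd = scenario$noise_sd)),
              nrow = m, dimnames = list(NULL, lu_names))
  if (!is.null(scenario$feature_effect)) {
    for (a in names(scenario$feature_effect)) {
      eff <- scenario$feature_effect[[a]]
      sel <- arch == a
      for (f in names(eff)) {
        X[sel, f] <- pmax(0, X[sel, f] + eff[[f]])
      }
    }
  }
  supergroups <- c("rural residents", "cosmopolitans", "ethnic mix",
                   "blue collar neighbourhoods", "multicultural metropolitan",
                   "suburbanites", "hard-pressed households", "urbanites")
  sg <- factor(sample(supergroups, m, replace = TRUE), levels = supergroups)
  out <- data.frame(unit_id = ids, X, supergroup = sg, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
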