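# Independent oracles and small fixture builders shared across tests.

# Exhaustive-window stay oracle: enumerate every window [i, j], keep those
# whose members all lie within d_max of the window's first point and whose
# span is at least t_min, then select maximal non-overlapping windows left to
# right (smallest start; ties broken toward the largest end). Kept free of
# the scanning logic used by detect_stays().
oracle_stays <- function(points, d_max = 50, t_min = 300) {
  n <- nrow(points)
  tt <- as.numeric(points$time)
  if (n < 2L) return(data.frame(start = integer(0), end = integer(0)))
  valid <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dmax_ij <- max(great_circle_distance(points$lon[i], points$lat[i],
                                           points$lon[i:j], points$lat[i:j]))
      if (dmax_ij <= d_max && tt[j] - tt[i] >= t_min) {
        valid[[length(valid) + 1L]] <- c(i, j)
      }
    }
  }
  sel <- list()
  pos <- 1L
  while (length(valid)) {
    starts <- vapply(valid, `[`, integer(1), 1L)
    ends <- vapply(valid, `[`, integer(1), 2L)
    ok <- starts >= pos
    if (!any(ok)) break
    s <- min(starts[ok])
    e <- max(ends[ok & starts == s])
    sel[[length(sel) + 1L]] <- c(s, e)
    pos <- e + 1L
  }
  if (!length(sel)) return(data.frame(start = integer(0), end = integer(0)))
  out <- do.call(rbind, sel)
  data.frame(start = out[, 1L], end = out[, 2L])
}

# Random short trajectory: a walk whose steps are either small (stays can
# form) or large (window breaks), with irregular sampling intervals.
random_walk_points <- function(n, seed, p_small = 0.6) {
  set.seed(seed)
  step <- ifelse(stats::runif(n - 1) < p_small, 10, 200)  # metres
  ang <- stats::runif(n - 1, 0, 2 * pi)
  x <- cumsum(c(0, step * cos(ang)))
  y <- cumsum(c(0, step * sin(ang)))
  deg_lat <- 1 / 111194.9
  deg_lon <- deg_lat / cos(51.5 * pi / 180)
  data.frame(
    user_id = "u1",
    time = as.POSIXct("2020-01-01 08:00:00", tz = "UTC") +
      cumsum(c(0, stats::runif(n - 1, 30, 240))),
    lon = -0.1 + x * deg_lon,
    lat = 51.5 + y * deg_lat)
}

# Build a points data.frame at one location with given offsets (metres east)
# and times (seconds from an epoch).
points_at <- function(offsets_m, times_s, user = "u1",
                      lon0 = -0.1, lat0 = 51.5) {
  deg_lon <- 1 / (111194.9 * cos(lat0 * pi / 180))
  data.frame(
    user_id = user,
    time = as.POSIXct("2020-06-01 12:00:00", tz = "UTC") + times_s,
    lon = lon0 + offsets_m * deg_lon,
    lat = lat0)
}

# Two-phase toy calendar used across synthetic tests.
toy_calendar <- function() {
  list(restriction_phase("open", "2020-01-01", "2020-01-28"),
       restriction_phase("closed", "2020-01-29", "2020-02-25"))
}

# Frozen clustering study conditions (see the methods vignette): two cleanly
# separated archetypes, and four archetypes at busy-urban volumes where
# Poisson noise is moderate relative to profile shape.
two_archetype_scenario <- function(seed = 3L) {
  cal <- list(restriction_phase("p1", "2020-01-01", "2020-02-25"))
  arch <- list(archetype_spec("busy-weekday", 50, 1.5, 0.5),
               archetype_spec("busy-weekend", 50, 0.5, 1.5))
  synthetic_scenario(arch, c("busy-weekday" = 20L, "busy-weekend" = 20L),
                     n_users = 0L, calendar = cal, seed = seed)
}

four_archetype_scenario <- function(seed = 11L) {
  cal <- default_calendar()
  arch <- default_archetypes(cal, base_rates = c(
    "busy-weekday" = 150, "busy-weekend" = 90, "flat" = 40, "recovering" = 60))
  synthetic_scenario(
    arch,
    c("busy-weekday" = 15L, "busy-weekend" = 15L, "flat" = 15L, "recovering" = 15L),
    n_users = 0L, calendar = cal, seed = seed)
}

# Association study conditions: two archetypes distinguished by one strongly
# informative land-use column among ten.
association_fixture <- function(seed = 3L, effect = 3, noise_sd = 0.5) {
  scen <- two_archetype_scenario(seed)
  scen$feature_effect <- list("busy-weekday" = c(lu_3 = effect))
  scen$noise_sd <- noise_sd
  units <- generate_units(5, 8, 500)
  mat <- generate_footfall_counts(scen, units)
  amap <- attr(mat, "archetype")
  part <- delineate_hazs(standardize_rows(mat), mat, 2, 8)
  feats <- generate_urban_features(units, amap, scen)
  list(scenario = scen, units = units, matrix = mat, archetype = amap,
       partition = part, features = feats)
}
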