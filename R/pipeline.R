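# End-to-end orchestration: simulate inputs, detect stays, aggregate
# footfall, compute the recovery index, delineate HAZs per phase, compare
# partitions across phases, and attribute membership to urban features.
# Every artefact is plain text; the manifest hashes them all, so two runs
# from the same config and seed produce identical manifests.

#' Pipeline configuration
#'
#' Collects everything a full run needs; fully serialisable, and a run is
#' reproducible from config + seed alone (inputs are simulated).
#'
#' @param scenario A [synthetic_scenario()].
#' @param grid List with `rows`, `cols`, `cell_size_m`, `origin` for
#'   [generate_units()].
#' @param stay A [stay_params()].
#' @param benchmark Character `c(start, end)` of the recovery benchmark
#'   window (ISO dates).
#' @param n_min,n_max,linkage Clustering options (see [delineate_hazs()]).
#' @param cv_folds,n_param_draws Association options (see
#'   [fit_classifier()]).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario,
                            grid = list(rows = 3L, cols = 3L, cell_size_m = 500,
                                        origin = c(-0.1278, 51.5074)),
                            stay = stay_params(),
                            benchmark = c("2020-01-01", "2020-02-29"),
                            n_min = 2L, n_max = NULL, linkage = "ward",
                            cv_folds = 10L, n_param_draws = 15L) {
  stopifnot(inherits(scenario, "synthetic_scenario"), inherits(stay, "stay_params"))
  structure(list(scenario = scenario, grid = grid, stay = stay,
                 benchmark = benchmark, n_min = n_min, n_max = n_max,
                 linkage = linkage, cv_folds = cv_folds,
                 n_param_draws = n_param_draws),
            class = "pipeline_config")
}

#' Demo configuration: 3x3 grid, 20 users, the packaged 8-phase calendar
#'
#' @param seed Integer seed for the scenario.
#' @return A [pipeline_config()].
#' @export
demo_config <- function(seed = 1L) {
  cal <- default_calendar()
  arch <- default_archetypes(cal)
  scen <- synthetic_scenario(
    archetypes = arch,
    n_units = c("busy-weekday" = 3L, "busy-weekend" = 2L,
                "flat" = 2L, "recovering" = 2L),
    n_users = 20L, calendar = cal,
    feature_effect = list("busy-weekday" = c(lu_5 = 3)),
    noise_sd = 0.5, seed = seed)
  pipeline_config(scen)
}

#' Simulate the synthetic input bundle
#'
#' Writes trajectories, unit polygons, the urban feature table, the planted-
#' truth ledger and the phase calendar under `dir`.
#'
#' @param config A [pipeline_config()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the files written, invisibly.
#' @export
simulate_inputs <- function(config, dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- config$grid
  units <- generate_units(g$rows, g$cols, g$cell_size_m, g$origin)
  traj <- generate_trajectories(config$scenario, units)
  amap <- unit_archetype_map(units, config$scenario)
  feats <- generate_urban_features(units, amap, config$scenario)
  paths <- c(
    units = file.path(dir, "units.geojson"),
    trajectories = file.path(dir, "trajectories.csv"),
    features = file.path(dir, "features.csv"),
    ledger = file.path(dir, "ledger.csv"),
    calendar = file.path(dir, "calendar.yaml"))
  write_units_geojson(units, paths[["units"]])
  write_trajectories(traj, paths[["trajectories"]])
  write_feature_table(feats, paths[["features"]])
  led <- traj$ledger
  led$start_time <- format(led$start_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(led, paths[["ledger"]], row.names = FALSE)
  write_calendar(config$scenario$calendar, paths[["calendar"]])
  invisible(paths)
}

#' Run the full pipeline
#'
#' Simulates inputs (unless `dir` already holds a bundle and
#' `resimulate = FALSE`), then runs: stay detection -> unit assignment ->
#' footfall matrix -> recovery index -> per-phase HAZ delineation -> pairwise
#' partition comparison -> per-phase urban association. All artefacts are
#' written under `dir`; the returned manifest lists every artefact with its
#' MD5 content hash, stage-level record counts, and the effective config.
#'
#' @param config A [pipeline_config()].
#' @param dir Working directory for artefacts.
#' @param resimulate Regenerate the input bundle even if present.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, dir, resimulate = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- c(units = file.path(dir, "units.geojson"),
              trajectories = file.path(dir, "trajectories.csv"),
              features = file.path(dir, "features.csv"),
              ledger = file.path(dir, "ledger.csv"),
              calendar = file.path(dir, "calendar.yaml"))
  if (resimulate || !all(file.exists(inputs))) {
    missing <- inputs[!file.exists(inputs)]
    if (!resimulate && length(missing)) {
      stop("missing input file(s): ", paste(missing, collapse = ", "), call. = FALSE)
    }
    simulate_inputs(config, dir)
  }
  log_stage <- function(...) message("[hazsense] ", sprintf(...))

  units <- read_units_geojson(inputs[["units"]])
  trajectories <- read_trajectories(inputs[["trajectories"]])
  features <- read_feature_table(inputs[["features"]])
  calendar <- read_calendar(inputs[["calendar"]])
  n_points <- sum(vapply(trajectories, nrow, integer(1)))
  log_stage("read %d trajectory points from %d users", n_points, length(trajectories))

  stays <- detect_stays_all(trajectories, config$stay)
  log_stage("detected %d stays", nrow(stays))
  write_stays(stays, file.path(dir, "stays.csv"))

  assigned <- assign_stays_to_units(stays, units)
  n_unassigned <- attr(assigned, "n_unassigned")
  log_stage("assigned %d stays to units (%d unassigned)",
            nrow(assigned) - n_unassigned, n_unassigned)

  span <- c(calendar[[1L]]$start_date, calendar[[length(calendar)]]$end_date)
  mat <- build_footfall_matrix(assigned, units$unit_id, span)
  write_footfall_matrix(mat, file.path(dir, "footfall_matrix.csv"))

  rec <- recovery_index(mat, config$benchmark[1L], config$benchmark[2L])
  utils::write.csv(
    data.frame(date = format(rec$date), daily_index = rec$daily_index,
               rolling_index = rec$rolling_index),
    file.path(dir, "recovery_index.csv"), row.names = FALSE)
  log_stage("recovery index computed against benchmark %s..%s",
            config$benchmark[1L], config$benchmark[2L])

  partitions <- delineate_per_phase(mat, calendar, config$n_min, config$n_max,
                                    config$linkage)
  dir.create(file.path(dir, "hazs"), showWarnings = FALSE)
  part_files <- character(0)
  for (nm in names(partitions)) {
    f <- file.path(dir, "hazs", paste0("partition_", gsub("[^A-Za-z0-9]+", "_", nm), ".csv"))
    write_partition(partitions[[nm]], f)
    part_files <- c(part_files, f)
  }
  log_stage("delineated %d partitions (selected n: %s)", length(partitions),
            paste(vapply(partitions, `[[`, integer(1), "n"), collapse = ", "))

  cmp <- pairwise_contingency(partitions)
  utils::write.csv(data.frame(period = rownames(cmp), cmp, check.names = FALSE),
                   file.path(dir, "phase_contingency.csv"), row.names = FALSE)

  assoc <- suppressWarnings(per_phase_association(
    features, partitions, config$cv_folds, config$n_param_draws,
    seed = config$scenario$seed))
  utils::write.csv(
    data.frame(period = names(assoc$accuracy), cv_accuracy = assoc$accuracy),
    file.path(dir, "association_accuracy.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(feature = rownames(assoc$importance_matrix),
               assoc$importance_matrix, check.names = FALSE),
    file.path(dir, "association_importance.csv"), row.names = FALSE)
  if (length(assoc$failures)) {
    log_stage("association failures: %s",
              paste(names(assoc$failures), assoc$failures, sep = ": ",
                    collapse = "; "))
  }

  artefacts <- c(unname(inputs),
                 file.path(dir, c("stays.csv", "footfall_matrix.csv",
                                  "recovery_index.csv", "phase_contingency.csv",
                                  "association_accuracy.csv",
                                  "association_importance.csv")),
                 part_files)
  manifest <- list(
    config = config_as_list(config),
    counts = list(points_read = n_points, stays_detected = nrow(stays),
                  stays_assigned = nrow(assigned) - n_unassigned,
                  stays_unassigned = n_unassigned,
                  partitions = length(partitions),
                  association_results = length(assoc$results),
                  association_failures = length(assoc$failures)),
    artefacts = stats::setNames(as.vector(tools::md5sum(artefacts)),
                                basename(artefacts)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Serialisable echo of the effective configuration.
config_as_list <- function(config) {
  sc <- config$scenario
  list(
    grid = config$grid,
    stay = list(d_max = config$stay$d_max, t_min = config$stay$t_min),
    benchmark = as.character(config$benchmark),
    clustering = list(n_min = config$n_min, n_max = config$n_max,
                      linkage = config$linkage),
    association = list(cv_folds = config$cv_folds,
                       n_param_draws = config$n_param_draws),
    scenario = list(
      n_units = as.list(sc$n_units), n_users = sc$n_users,
      noise_sd = sc$noise_sd, seed = sc$seed, jitter_m = sc$jitter_m,
      stay_duration_s = sc$stay_duration_s, points_per_stay = sc$points_per_stay,
      archetypes = lapply(sc$archetypes, function(a) {
        list(name = a$name, base_rate = a$base_rate,
             weekday_multiplier = a$weekday_multiplier,
             weekend_multiplier = a$weekend_multiplier,
             phase_multipliers = as.list(a$phase_multipliers))
      }),
      calendar = lapply(sc$calendar, function(p) {
        list(name = p$name, start = format(p$start_date), end = format(p$end_date))
      })))
}
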