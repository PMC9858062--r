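test_that("row standardisation reproduces the direct evaluation", {
  dates <- as.Date("2020-01-01") + 0:2
  m <- footfall_matrix(matrix(c(1, 2, 3,
                                5, 5, 5), nrow = 2, byrow = TRUE),
                       c("varying", "constant"), dates)
  std <- standardize_rows(m)
  # (x - mean) / population sd with sd = sqrt(2/3)
  expect_equal(as.numeric(std$values["varying", ]),
               c(-1.2247, 0, 1.2247), tolerance = 1e-3)
  expect_identical(std$excluded_units, "constant")
  expect_identical(std$unit_ids, "varying")

  all_flat <- footfall_matrix(matrix(2L, 2, 3), c("a", "b"), dates)
  expect_error(standardize_rows(all_flat), "degenerate")
})

test_that("every retained standardised row has mean 0 and population sd 1", {
  scen <- four_archetype_scenario(seed = 23L)
  units <- generate_units(6, 10, 500)
  mat <- generate_footfall_counts(scen, units)
  std <- standardize_rows(mat)
  mu <- rowMeans(std$values)
  sd_pop <- sqrt(rowMeans(std$values^2) - mu^2)
  expect_true(all(abs(mu) < 1e-9))
  expect_true(all(abs(sd_pop - 1) < 1e-9))
})

test_that("two clean archetypes are recovered exactly with n = 2", {
  scen <- two_archetype_scenario(seed = 3L)
  units <- generate_units(5, 8, 500)
  mat <- generate_footfall_counts(scen, units)
  part <- delineate_hazs(standardize_rows(mat), mat, 2, 8)
  amap <- attr(mat, "archetype")
  expect_identical(part$n, 2L)
  expect_equal(mclust::adjustedRandIndex(part$labels[names(amap)], amap), 1)
  expect_true(part$silhouette >= -1 && part$silhouette <= 1)
})

test_that("four archetypes at busy-urban volumes are recovered with ARI >= 0.9", {
  scen <- four_archetype_scenario(seed = 11L)
  units <- generate_units(6, 10, 500)
  mat <- generate_footfall_counts(scen, units)
  part <- delineate_hazs(standardize_rows(mat), mat, 2, 8)
  amap <- attr(mat, "archetype")
  expect_identical(part$n, 4L)
  expect_gte(mclust::adjustedRandIndex(part$labels[names(amap)], amap), 0.9)
})

test_that("labels are ranked by mean daily footfall and rank only permutes", {
  scen <- four_archetype_scenario(seed = 29L)
  units <- generate_units(6, 10, 500)
  mat <- generate_footfall_counts(scen, units)
  std <- standardize_rows(mat)
  part <- delineate_hazs(std, mat, 2, 8)
  # busiest label first, non-increasing
  expect_true(all(diff(part$mean_daily_footfall) <= 0))
  expect_identical(names(part$mean_daily_footfall), as.character(0:(part$n - 1L)))
  # the ranking step only permutes labels: memberships match the raw cutree
  d <- stats::dist(std$values)
  hc <- stats::hclust(d, method = "ward.D2")
  raw_cl <- stats::cutree(hc, k = part$n)
  expect_equal(mclust::adjustedRandIndex(part$labels[std$unit_ids], raw_cl), 1)
  # label 0 really is the busiest by raw mean daily footfall
  lab <- part$labels[std$unit_ids]
  busiest <- tapply(rowMeans(mat)[std$unit_ids], lab, mean)
  expect_true(all(diff(busiest[order(as.integer(names(busiest)))]) <= 0))
})

test_that("delineation is deterministic and validates its cluster range", {
  scen <- two_archetype_scenario(seed = 13L)
  units <- generate_units(5, 8, 500)
  mat <- generate_footfall_counts(scen, units)
  std <- standardize_rows(mat)
  p1 <- delineate_hazs(std, mat, 2, 8)
  p2 <- delineate_hazs(std, mat, 2, 8)
  expect_identical(p1, p2)
  m <- nrow(std$values)
  expect_error(delineate_hazs(std, mat, 2, m), "below the number")
  expect_error(delineate_hazs(std, mat, 5, 3), "n_min")
})

test_that("per-phase delineation re-standardises within each slice", {
  cal <- toy_calendar()
  arch <- list(archetype_spec("busy-weekday", 40, 1.5, 0.5, c(open = 1, closed = 0.5)),
               archetype_spec("busy-weekend", 40, 0.5, 1.5, c(open = 1, closed = 0.5)))
  scen <- synthetic_scenario(arch, c("busy-weekday" = 10L, "busy-weekend" = 10L),
                             n_users = 0L, calendar = cal, seed = 41L)
  units <- generate_units(4, 5, 500)
  mat <- generate_footfall_counts(scen, units)
  parts <- delineate_per_phase(mat, cal, 2, 8)
  expect_named(parts, c("all", "open", "closed"))

  # 8-phase calendar -> 9 partitions
  scen8 <- four_archetype_scenario(seed = 11L)
  units8 <- generate_units(6, 10, 500)
  mat8 <- generate_footfall_counts(scen8, units8)
  parts8 <- delineate_per_phase(mat8, scen8$calendar, 2, 8)
  expect_length(parts8, 9L)

  # a unit all-zero in one phase only is excluded there, clustered elsewhere
  mat0 <- mat
  closed_cols <- footfall_dates(mat0) >= cal[[2]]$start_date
  mat0["u0001", closed_cols] <- 0L
  parts0 <- delineate_per_phase(mat0, cal, 2, 8)
  expect_identical(unname(parts0[["closed"]]$labels["u0001"]), HAZ_SENTINEL)
  expect_true(parts0[["open"]]$labels["u0001"] != HAZ_SENTINEL)

  # short phases are rejected
  tiny <- list(restriction_phase("blip", "2020-01-01", "2020-01-01"))
  expect_error(delineate_per_phase(mat, tiny, 2, 8), "fewer than 2 days")
})

test_that("phase-level degeneracy collapses the selected cluster count", {
  # two weekday-shaped archetypes distinguished only by their phase ramp plus
  # one weekend-shaped archetype: within the first phase the ramp is a scalar
  # that standardisation removes, so the two weekday archetypes coincide there
  # and the first-phase partition needs fewer clusters than the full period
  cal <- toy_calendar()
  arch <- list(
    archetype_spec("weekday-early", 40, 1.5, 0.4, c(open = 1, closed = 0.2)),
    archetype_spec("weekday-late", 40, 1.5, 0.4, c(open = 0.2, closed = 1)),
    archetype_spec("weekend", 40, 0.4, 1.5, c(open = 1, closed = 1)))
  scen <- synthetic_scenario(arch, c("weekday-early" = 8L, "weekday-late" = 8L,
                                     "weekend" = 8L),
                             n_users = 0L, calendar = cal, seed = 43L)
  units <- generate_units(4, 6, 500)
  mat <- generate_footfall_counts(scen, units)
  parts <- delineate_per_phase(mat, cal, 2, 8)
  expect_lt(parts[["open"]]$n, parts[["all"]]$n)
})
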