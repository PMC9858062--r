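make_stay <- function(lon, lat, time = "2020-01-01 09:00:00", user = "u1") {
  data.frame(user_id = user, centroid_lon = lon, centroid_lat = lat,
             start_time = as.POSIXct(time, tz = "UTC"),
             end_time = as.POSIXct(time, tz = "UTC") + 600,
             duration_s = 600, n_points = 5L)
}

test_that("stay centroids are assigned to the containing cell, once", {
  units <- generate_units(2, 2, 500, origin = c(0, 51.5))
  deg_lon <- 1 / (111194.9 * cos(51.5 * pi / 180))
  deg_lat <- 1 / 111194.9

  inside <- make_stay(0 + 250 * deg_lon, 51.5 + 750 * deg_lat)  # cell row 2, col 1
  asg <- assign_stays_to_units(inside, units)
  expect_identical(asg$unit_id, units$unit_id[units$row == 2 & units$col == 1])

  outside <- make_stay(0 - 100 * deg_lon, 51.5)
  asg2 <- assign_stays_to_units(outside, units)
  expect_true(is.na(asg2$unit_id))
  expect_identical(attr(asg2, "n_unassigned"), 1L)

  # points on shared edges land in exactly one cell
  edge_pts <- rbind(
    make_stay(0 + 500 * deg_lon, 51.5 + 250 * deg_lat),  # vertical shared edge
    make_stay(0 + 250 * deg_lon, 51.5 + 500 * deg_lat),  # horizontal shared edge
    make_stay(0 + 500 * deg_lon, 51.5 + 500 * deg_lat))  # interior corner
  for (k in 1:3) {
    hits <- vapply(units$rings, function(r) {
      hazsense:::point_in_ring(edge_pts$centroid_lon[k], edge_pts$centroid_lat[k], r)
    }, logical(1))
    expect_identical(sum(hits), 1L, label = paste("edge point", k))
  }

  # overlapping units are a fatal validation error
  bad <- units
  bad$rings[[2]] <- bad$rings[[1]]
  expect_error(assign_stays_to_units(inside, bad), "overlap")
})

test_that("footfall matrix counts assigned stays by unit and start date", {
  units <- generate_units(2, 2, 500, origin = c(0, 51.5))
  dates <- c(as.Date("2020-01-01"), as.Date("2020-01-05"))

  empty <- assign_stays_to_units(make_stay(1, 0)[0, ], units)
  m0 <- build_footfall_matrix(empty, units$unit_id, dates)
  expect_identical(dim(m0), c(4L, 5L))
  expect_true(all(m0 == 0))

  deg <- 1 / (111194.9 * cos(51.5 * pi / 180))
  one <- assign_stays_to_units(make_stay(0 + 250 * deg, 51.50101,
                                         time = "2020-01-03 23:50:00"), units)
  m1 <- build_footfall_matrix(one, units$unit_id, dates)
  expect_identical(sum(m1), 1L)
  expect_identical(as.integer(m1[one$unit_id, "2020-01-03"]), 1L)

  # a stay spanning midnight counts wholly on its start date
  expect_identical(sum(m1[, "2020-01-04"]), 0L)

  # out-of-range stays: fatal in strict mode, clipped otherwise
  late <- assign_stays_to_units(make_stay(0 + 250 * deg, 51.50101,
                                          time = "2020-02-01 10:00:00"), units)
  expect_error(build_footfall_matrix(late, units$unit_id, dates), "outside")
  expect_warning(m2 <- build_footfall_matrix(late, units$unit_id, dates, strict = FALSE),
                 "clipped")
  expect_identical(sum(m2), 0L)
})

test_that("stays-vs-unique-users counting differ exactly on repeat visits", {
  units <- generate_units(1, 1, 500, origin = c(0, 51.5))
  deg <- 1 / (111194.9 * cos(51.5 * pi / 180))
  two <- rbind(make_stay(250 * deg, 51.5021, "2020-01-01 09:00:00"),
               make_stay(250 * deg, 51.5021, "2020-01-01 15:00:00"))
  asg <- assign_stays_to_units(two, units)
  dates <- as.Date(c("2020-01-01", "2020-01-02"))
  expect_identical(sum(build_footfall_matrix(asg, units$unit_id, dates)), 2L)
  expect_identical(sum(build_footfall_matrix(asg, units$unit_id, dates,
                                             unique_users = TRUE)), 1L)
})

test_that("footfall conservation against the generator ledger", {
  cal <- toy_calendar()
  arch <- list(archetype_spec("busy-weekday", 2.5, 1.5, 0.5, c(open = 1, closed = 0.4)),
               archetype_spec("flat", 1.2))
  scen <- synthetic_scenario(arch, c("busy-weekday" = 5L, flat = 4L),
                             n_users = 10L, calendar = cal, seed = 31L)
  units <- generate_units(3, 3, 500)
  traj <- generate_trajectories(scen, units)
  stays <- detect_stays_all(split(traj$points, traj$points$user_id))
  asg <- assign_stays_to_units(stays, units)
  expect_identical(nrow(asg) - attr(asg, "n_unassigned") + attr(asg, "n_unassigned"),
                   nrow(stays))
  mat <- build_footfall_matrix(asg, units$unit_id,
                               c(cal[[1]]$start_date, cal[[2]]$end_date))
  expect_identical(sum(mat), nrow(traj$ledger))
  led_per_day <- table(factor(format(traj$ledger$date), levels = colnames(mat)))
  expect_identical(as.integer(colSums(mat)), as.integer(led_per_day))
})

test_that("recovery index is 100 for constant totals and tracks halving", {
  dates <- seq(as.Date("2020-01-01"), by = "day", length.out = 90)
  m <- footfall_matrix(matrix(5L, nrow = 3, ncol = 90), paste0("u", 1:3), dates)
  rec <- recovery_index(m, "2020-01-01", "2020-02-29")
  expect_true(all(abs(rec$daily_index - 100) < 1e-12))
  expect_true(all(abs(rec$rolling_index - 100) < 1e-12))

  counts <- matrix(10L, nrow = 2, ncol = 90)
  counts[, dates > as.Date("2020-02-29")] <- 5L
  m2 <- footfall_matrix(counts, c("a", "b"), dates)
  rec2 <- recovery_index(m2, "2020-01-01", "2020-02-29")
  expect_true(all(abs(rec2$daily_index[rec2$date > as.Date("2020-02-29")] - 50) < 1e-12))

  # the default benchmark window spans exactly 60 days
  expect_length(seq(as.Date("2020-01-01"), as.Date("2020-02-29"), by = "day"), 60L)

  # scale invariance
  rec3 <- recovery_index(footfall_matrix(counts * 7L, c("a", "b"), dates),
                         "2020-01-01", "2020-02-29")
  expect_equal(rec3$daily_index, rec2$daily_index)

  zero <- footfall_matrix(matrix(0L, 2, 90), c("a", "b"), dates)
  expect_error(recovery_index(zero, "2020-01-01", "2020-02-29"), "zero")
})

test_that("footfall matrices round-trip through delimited text", {
  dates <- seq(as.Date("2020-01-01"), by = "day", length.out = 5)
  m <- footfall_matrix(matrix(rpois(15, 4), 3), paste0("u", 1:3), dates)
  path <- withr::local_tempfile(fileext = ".csv")
  write_footfall_matrix(m, path)
  back <- read_footfall_matrix(path)
  expect_identical(unclass(back), unclass(m))
})
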