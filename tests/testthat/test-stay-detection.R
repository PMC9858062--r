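test_that("great-circle distance has the closed-form meridian value", {
  expect_identical(great_circle_distance(-0.1, 51.5, -0.1, 51.5), 0)
  # one degree of latitude = pi * 6371000 / 180 metres
  expect_equal(great_circle_distance(0, 0, 0, 1), 111194.9, tolerance = 0.1 / 111194.9)
  set.seed(1)
  a <- cbind(runif(20, -180, 180), runif(20, -80, 80))
  b <- cbind(runif(20, -180, 180), runif(20, -80, 80))
  expect_equal(great_circle_distance(a[, 1], a[, 2], b[, 1], b[, 2]),
               great_circle_distance(b[, 1], b[, 2], a[, 1], a[, 2]))
})

test_that("colocated points spanning t_min form one stay; fast movers none", {
  pts <- points_at(c(0, 0, 0), c(0, 180, 360))
  st <- detect_stays(pts)
  expect_identical(nrow(st), 1L)
  expect_identical(st$duration_s, 360)
  expect_identical(st$n_points, 3L)
  expect_equal(st$centroid_lon, pts$lon[1])

  movers <- points_at(seq(0, 9000, by = 1000), seq(0, 540, by = 60))
  expect_identical(nrow(detect_stays(movers)), 0L)

  expect_identical(nrow(detect_stays(points_at(0, 0))), 0L)
  expect_identical(nrow(detect_stays(points_at(0, 0)[0, ])), 0L)
})

test_that("a toy trajectory with two planted clusters matches the exhaustive oracle", {
  # two stations 500 m apart with transit points between and around them
  pts <- points_at(c(0, 5, -5, 2, 200, 500, 498, 503, 501, 900),
                   c(0, 200, 400, 600, 700, 800, 1000, 1200, 1500, 1600))
  st <- detect_stays(pts)
  orc <- oracle_stays(pts)
  expect_identical(nrow(st), nrow(orc))
  expect_identical(st$n_points, orc$end - orc$start + 1L)
  expect_equal(as.numeric(st$start_time), as.numeric(pts$time[orc$start]))
  expect_equal(as.numeric(st$end_time), as.numeric(pts$time[orc$end]))
})

test_that("detector agrees with the exhaustive-window oracle on random walks", {
  for (seed in 1:60) {
    n <- 4L + (seed %% 9L)
    pts <- random_walk_points(n, seed = 1000L + seed)
    st <- detect_stays(pts)
    orc <- oracle_stays(pts)
    expect_identical(nrow(st), nrow(orc), label = paste("seed", seed))
    if (nrow(orc)) {
      expect_equal(as.numeric(st$start_time), as.numeric(pts$time[orc$start]))
      expect_equal(as.numeric(st$end_time), as.numeric(pts$time[orc$end]))
    }
  }
})

test_that("stay counts are monotone in the thresholds", {
  for (seed in 1:20) {
    pts <- random_walk_points(12, seed = 2000L + seed)
    base <- nrow(detect_stays(pts, stay_params(50, 300)))
    expect_gte(nrow(detect_stays(pts, stay_params(120, 300))), base)
    expect_gte(nrow(detect_stays(pts, stay_params(50, 120))), base)
  }
})

test_that("every emitted stay satisfies both thresholds on its members", {
  params <- stay_params(50, 300)
  for (seed in 1:20) {
    pts <- random_walk_points(12, seed = 3000L + seed)
    st <- detect_stays(pts, params)
    if (!nrow(st)) next
    expect_true(all(st$duration_s >= params$t_min))
    for (k in seq_len(nrow(st))) {
      idx <- which(pts$time >= st$start_time[k] & pts$time <= st$end_time[k])
      anchor <- idx[1]
      d <- great_circle_distance(pts$lon[anchor], pts$lat[anchor],
                                 pts$lon[idx], pts$lat[idx])
      expect_true(all(d <= params$d_max))
    }
  }
})

test_that("haversine and planar distance options agree at stay scales", {
  pts <- random_walk_points(12, seed = 99)
  st_h <- detect_stays(pts, distance = "haversine")
  st_p <- detect_stays(pts, distance = "planar")
  expect_identical(st_h$n_points, st_p$n_points)
  expect_equal(st_h$centroid_lon, st_p$centroid_lon)
})

test_that("trajectory reader groups, sorts, deduplicates and validates", {
  path <- withr::local_tempfile(fileext = ".csv")
  rows <- c("user_id,timestamp,longitude,latitude",
            "b,2020-01-01T10:05:00,-0.10,51.50",
            "a,2020-01-01T09:00:00,-0.11,51.51",
            "b,2020-01-01T10:00:00,-0.10,51.50",
            "a,2020-01-01T08:00:00,-0.11,51.51",
            "a,2020-01-01T08:00:00,-0.11,51.51")  # exact duplicate
  writeLines(rows, path)
  expect_message(seqs <- read_trajectories(path), "1 exact-duplicate")
  expect_named(seqs, c("a", "b"))
  expect_identical(vapply(seqs, nrow, integer(1)), c(a = 2L, b = 2L))
  expect_true(all(vapply(seqs, function(s) !is.unsorted(s$time, strictly = TRUE), logical(1))))

  writeLines(rows[1], path)
  expect_length(read_trajectories(path), 0L)

  writeLines(c(rows[1], "a,not-a-time,-0.1,51.5"), path)
  expect_error(read_trajectories(path, strict = TRUE), "line")
  expect_warning(bad <- read_trajectories(path, strict = FALSE), "line")
  expect_length(bad, 0L)
})

test_that("stays round-trip through delimited text", {
  pts <- points_at(c(0, 1, 2), c(0, 200, 400))
  st <- detect_stays(pts)
  path <- withr::local_tempfile(fileext = ".csv")
  write_stays(st, path)
  back <- read_stays(path)
  expect_identical(back$n_points, st$n_points)
  expect_equal(as.numeric(back$start_time), as.numeric(st$start_time))
})
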