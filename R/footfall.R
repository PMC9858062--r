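# Footfall aggregation: stays -> units x days count matrix, and the daily
# recovery index against a pre-pandemic benchmark window.

#' Construct a footfall matrix
#'
#' Units x days matrix of nonnegative integer stay counts. Dates must be
#' strictly increasing and gap-free.
#'
#' @param counts m x t numeric matrix of nonnegative integers.
#' @param unit_ids Character vector, length m.
#' @param dates `Date` vector, length t, consecutive.
#' @return Matrix of class `footfall_matrix` with unit ids as rownames and ISO
#'   dates as colnames.
#' @export
footfall_matrix <- function(counts, unit_ids, dates) {
  counts <- as.matrix(counts)
  dates <- as.Date(dates)
  stopifnot(nrow(counts) == length(unit_ids), ncol(counts) == length(dates),
            all(counts >= 0))
  if (length(dates) > 1L && !all(diff(dates) == 1)) {
    stop("footfall dates must be consecutive calendar days", call. = FALSE)
  }
  dimnames(counts) <- list(unit_ids, format(dates))
  class(counts) <- c("footfall_matrix", class(counts))
  counts
}

#' @export
print.footfall_matrix <- function(x, ...) {
  cat(sprintf("<footfall_matrix> %d units x %d days (%s .. %s), total %d stays\n",
              nrow(x), ncol(x), colnames(x)[1L], colnames(x)[ncol(x)], sum(x)))
  invisible(x)
}

#' Dates of a footfall matrix
#' @param mat A [footfall_matrix()].
#' @return `Date` vector of its columns.
#' @export
footfall_dates <- function(mat) as.Date(colnames(mat))

# `[` keeps the class when the result is still a matrix with dimnames
#' @export
`[.footfall_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out) && !is.null(dimnames(out))) {
    class(out) <- c("footfall_matrix", "matrix", "array")
  }
  out
}

# Crossing-number (ray cast) point-in-polygon, vectorised over points. Its
# half-open edge handling assigns a point lying on the shared edge of two
# adjacent cells of a tiling to exactly one of them.
point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

validate_units_disjoint <- function(units) {
  # sampled-interior check: another unit containing this unit's centre means
  # overlap; exact geometric intersection is out of scope for these tilings
  m <- length(units$unit_id)
  cen <- t(vapply(units$rings, function(r) colMeans(r[-nrow(r), , drop = FALSE]),
                  numeric(2)))
  for (k in seq_len(m)) {
    hit <- which(point_in_ring(cen[, 1], cen[, 2], units$rings[[k]]))
    hit <- setdiff(hit, k)
    if (length(hit)) {
      stop("units overlap: ", units$unit_id[k], " and ", units$unit_id[hit[1L]],
           call. = FALSE)
    }
  }
  invisible(units)
}

#' Assign stays to geospatial units
#'
#' Each stay goes to the unit whose polygon contains its centroid. The ray-
#' cast containment test's fixed edge convention puts a centroid on a shared
#' cell boundary in exactly one unit; centroids outside all units stay
#' unassigned and are counted.
#'
#' @param stays Stay data.frame (see [detect_stays()]).
#' @param units A `haz_units` object with non-overlapping polygons.
#' @return `stays` with an added `unit_id` column (`NA` = unassigned), plus
#'   attribute `"n_unassigned"`.
#' @export
assign_stays_to_units <- function(stays, units) {
  validate_units_disjoint(units)
  uid <- rep(NA_character_, nrow(stays))
  if (nrow(stays)) {
    todo <- rep(TRUE, nrow(stays))
    for (i in seq_along(units$unit_id)) {
      if (!any(todo)) break
      hit <- point_in_ring(stays$centroid_lon[todo], stays$centroid_lat[todo],
                           units$rings[[i]])
      uid[which(todo)[hit]] <- units$unit_id[i]
      todo[todo] <- !hit
    }
  }
  out <- stays
  out$unit_id <- uid
  attr(out, "n_unassigned") <- sum(is.na(uid))
  out
}

#' Build the units x days footfall matrix
#'
#' Counts assigned stays per unit and calendar day; a stay is attributed
#' wholly to the date its start time falls on. Units with no stays appear as
#' all-zero rows. By default, counts stays (a user with two stays in a
#' unit-day contributes 2); `unique_users = TRUE` counts distinct users
#' instead.
#'
#' @param assignments Output of [assign_stays_to_units()].
#' @param unit_ids All unit ids (row universe, in order).
#' @param date_range `Date` vector `c(first, last)` (inclusive span).
#' @param strict If `TRUE` (default) an assigned stay outside `date_range` is
#'   an error; otherwise it is clipped with a warning.
#' @param unique_users Count distinct users per unit-day instead of stays.
#' @return A [footfall_matrix()].
#' @export
build_footfall_matrix <- function(assignments, unit_ids, date_range,
                                  strict = TRUE, unique_users = FALSE) {
  date_range <- as.Date(date_range)
  dates <- seq(min(date_range), max(date_range), by = "day")
  a <- assignments[!is.na(assignments$unit_id), , drop = FALSE]
  sdate <- as.Date(format(a$start_time, "%Y-%m-%d", tz = "UTC"))
  outside <- sdate < dates[1L] | sdate > dates[length(dates)]
  if (any(outside)) {
    msg <- paste0(sum(outside), " assigned stay(s) fall outside the date range")
    if (strict) stop(msg, call. = FALSE)
    warning(msg, "; clipped", call. = FALSE)
    a <- a[!outside, , drop = FALSE]; sdate <- sdate[!outside]
  }
  if (!all(a$unit_id %in% unit_ids)) {
    stop("assignments reference unit ids missing from unit_ids", call. = FALSE)
  }
  if (unique_users) {
    keep <- !duplicated(data.frame(a$unit_id, sdate, a$user_id))
    a <- a[keep, , drop = FALSE]; sdate <- sdate[keep]
  }
  counts <- table(factor(a$unit_id, levels = unit_ids),
                  factor(format(sdate), levels = format(dates)))
  footfall_matrix(matrix(as.integer(counts), nrow = length(unit_ids)),
                  unit_ids, dates)
}

#' Daily recovery index against a benchmark window
#'
#' The benchmark is the mean, over the benchmark days, of the citywide daily
#' total footfall (sum over all units). Each day's index is its citywide
#' total as a percentage of that benchmark; a trailing 7-day rolling mean
#' (shorter at the series head, where fewer days are available) smooths the
#' weekly cycle.
#'
#' @param mat A [footfall_matrix()].
#' @param benchmark_start,benchmark_end Benchmark window (inclusive), within
#'   the matrix dates.
#' @return data.frame of class `recovery_series`: `date`, `daily_index`,
#'   `rolling_index` (percentages).
#' @export
recovery_index <- function(mat, benchmark_start = "2020-01-01",
                           benchmark_end = "2020-02-29") {
  b0 <- as.Date(benchmark_start); b1 <- as.Date(benchmark_end)
  dates <- footfall_dates(mat)
  stopifnot(b0 <= b1)
  if (b0 < dates[1L] || b1 > dates[length(dates)]) {
    stop("benchmark window must lie within the matrix dates", call. = FALSE)
  }
  total <- colSums(mat)
  bench <- mean(total[dates >= b0 & dates <= b1])
  if (bench == 0) stop("benchmark daily total is zero", call. = FALSE)
  daily <- 100 * total / bench
  roll <- vapply(seq_along(daily), function(i) {
    mean(daily[max(1L, i - 6L):i])
  }, numeric(1))
  out <- data.frame(date = dates, daily_index = unname(daily),
                    rolling_index = roll)
  class(out) <- c("recovery_series", class(out))
  out
}
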