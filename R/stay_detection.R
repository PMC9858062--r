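#' Stay-detection parameters
#'
#' A stay (stationary episode) is a maximal run of consecutive GPS points that
#' all remain within `d_max` metres of the run's first point (the anchor) and
#' whose time span is at least `t_min` seconds. The defaults — 50 m and 5
#' minutes — are the standard thresholds for capturing significant visiting
#' behaviour from mobile-phone trajectories.
#'
#' @param d_max Maximum distance from the anchor point, metres (> 0).
#' @param t_min Minimum duration of the episode, seconds (> 0).
#' @return An object of class `stay_params`.
#' @export
stay_params <- function(d_max = 50, t_min = 300) {
  stopifnot(is.numeric(d_max), d_max > 0, is.numeric(t_min), t_min > 0)
  structure(list(d_max = d_max, t_min = t_min), class = "stay_params")
}

#' Detect stays in one user's GPS point sequence
#'
#' Greedy anchor-based scan: the anchor sits at point i and the window extends
#' through point j while `distance(p_i, p_j) <= d_max`. On the first violation
#' (or at the end of the sequence) the window `p_i .. p_{j-1}` becomes a stay
#' iff its time span is at least `t_min`; the anchor then restarts at j after
#' an emitted stay, or advances by one point otherwise (so stays beginning
#' inside a failed window are not skipped). Stay centroids are arithmetic
#' means of the member coordinates; stays are non-overlapping and time-ordered.
#'
#' @param points data.frame with columns `user_id`, `time` (POSIXct),
#'   `lon`, `lat`, time-sorted, single user.
#' @param params A [stay_params()].
#' @param distance `"haversine"` (default; sphere radius 6,371,000 m) or
#'   `"planar"` (equirectangular approximation).
#' @return data.frame of stays: `user_id`, `centroid_lon`, `centroid_lat`,
#'   `start_time`, `end_time`, `duration_s`, `n_points`.
#' @export
detect_stays <- function(points, params = stay_params(),
                         distance = c("haversine", "planar")) {
  distance <- match.arg(distance)
  stopifnot(inherits(params, "stay_params"))
  empty <- data.frame(
    user_id = character(0), centroid_lon = numeric(0), centroid_lat = numeric(0),
    start_time = as.POSIXct(character(0), tz = "UTC"),
    end_time = as.POSIXct(character(0), tz = "UTC"),
    duration_s = numeric(0), n_points = integer(0),
    stringsAsFactors = FALSE
  )
  n <- nrow(points)
  if (is.null(n) || n < 2L) return(empty)
  if (length(unique(points$user_id)) > 1L) {
    stop("detect_stays expects a single user's sequence", call. = FALSE)
  }
  tt <- as.numeric(points$time)
  if (is.unsorted(tt)) stop("points must be time-sorted", call. = FALSE)
  dfun <- if (distance == "haversine") great_circle_distance else planar_distance
  lon <- points$lon
  lat <- points$lat

  out <- list()
  i <- 1L
  while (i < n) {
    # extend in chunks; the first index with distance-to-anchor > d_max ends
    # the window (violations are typically found in the first chunk)
    j <- i + 1L
    viol <- NA_integer_
    while (j <= n) {
      hi <- min(n, j + 31L)
      d <- dfun(lon[i], lat[i], lon[j:hi], lat[j:hi])
      bad <- which(d > params$d_max)
      if (length(bad)) { viol <- j + bad[1L] - 1L; break }
      j <- hi + 1L
    }
    last <- if (is.na(viol)) n else viol - 1L
    if (tt[last] - tt[i] >= params$t_min) {
      idx <- i:last
      out[[length(out) + 1L]] <- data.frame(
        user_id = points$user_id[i],
        centroid_lon = mean(lon[idx]), centroid_lat = mean(lat[idx]),
        start_time = points$time[i], end_time = points$time[last],
        duration_s = tt[last] - tt[i], n_points = length(idx),
        stringsAsFactors = FALSE
      )
      if (is.na(viol)) break
      i <- viol
    } else {
      i <- i + 1L
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Detect stays for every user in a trajectory set
#'
#' @param trajectories Named list of per-user point data.frames, as returned
#'   by [read_trajectories()].
#' @inheritParams detect_stays
#' @return One data.frame of stays across all users (see [detect_stays()]).
#' @export
detect_stays_all <- function(trajectories, params = stay_params(),
                             distance = c("haversine", "planar")) {
  distance <- match.arg(distance)
  res <- lapply(trajectories, detect_stays, params = params, distance = distance)
  res <- res[vapply(res, nrow, integer(1)) > 0L]
  if (!length(res)) return(detect_stays(NULL, params))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Read per-user GPS trajectories from delimited text
#'
#' Expects a header `user_id, timestamp, longitude, latitude` with ISO-8601
#' UTC timestamps. Rows are grouped by user and sorted by timestamp within
#' user; exact-duplicate records are dropped and the drop count reported.
#'
#' @param path Path to the delimited file.
#' @param strict If `TRUE` (default) unparseable timestamps or coordinates
#'   abort with the offending line numbers; otherwise such rows are dropped
#'   with a warning.
#' @return Named list (by user id) of data.frames with columns `user_id`,
#'   `time` (POSIXct UTC), `lon`, `lat`, each strictly time-ordered.
#' @export
read_trajectories <- function(path, strict = TRUE) {
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("user_id", "timestamp", "longitude", "latitude")
  if (!all(need %in% names(raw))) {
    stop("trajectory file must have header: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) return(structure(list(), names = character(0)))

  dup <- duplicated(raw[need])
  if (any(dup)) {
    message(sum(dup), " exact-duplicate trajectory record(s) dropped")
    raw <- raw[!dup, , drop = FALSE]
  }
  time <- parse_utc_time(raw$timestamp)
  lon <- suppressWarnings(as.numeric(raw$longitude))
  lat <- suppressWarnings(as.numeric(raw$latitude))
  bad <- is.na(time) | is.na(lon) | is.na(lat) |
    abs(lon) > 180 | abs(lat) > 90
  if (any(bad)) {
    lines <- which(bad) + 1L  # +1 for the header line
    msg <- paste0("malformed trajectory row(s) at line(s): ",
                  paste(utils::head(lines, 20L), collapse = ", "),
                  if (length(lines) > 20L) " ..." else "")
    if (strict) stop(msg, call. = FALSE)
    warning(msg, "; dropped", call. = FALSE)
    keep <- !bad
    raw <- raw[keep, , drop = FALSE]; time <- time[keep]
    lon <- lon[keep]; lat <- lat[keep]
  }
  pts <- data.frame(user_id = raw$user_id, time = time, lon = lon, lat = lat,
                    stringsAsFactors = FALSE)
  pts <- pts[order(pts$user_id, pts$time), , drop = FALSE]
  split(pts, pts$user_id)
}

#' Write stays to delimited text
#'
#' @param stays data.frame of stays from [detect_stays_all()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stays <- function(stays, path) {
  out <- stays
  out$start_time <- format(out$start_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  out$end_time <- format(out$end_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read stays written by [write_stays()]
#'
#' @param path Input path.
#' @return data.frame of stays.
#' @export
read_stays <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$start_time <- parse_utc_time(out$start_time)
  out$end_time <- parse_utc_time(out$end_time)
  out
}

# ISO-8601 (T- or space-separated) -> POSIXct UTC; NA where unparseable.
parse_utc_time <- function(x) {
  t1 <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))
  t2 <- as.POSIXct(strptime(x, "%Y-%m-%d %H:%M:%OS", tz = "UTC"))
  t1[is.na(t1)] <- t2[is.na(t1)]
  t1
}
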