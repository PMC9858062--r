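#' Construct a restriction phase
#'
#' A phase is a named, contiguous interval of calendar dates during which a
#' single policy regime applied. Phases are the observation periods over which
#' footfall matrices are sliced and activity zones delineated.
#'
#' @param name Text label of the phase.
#' @param start_date,end_date First and last calendar day (inclusive), as
#'   `Date` or ISO-8601 strings.
#' @param days_printed Optional day count carried as metadata (see
#'   [default_calendar()]); not used in computation.
#' @return An object of class `restriction_phase`.
#' @export
restriction_phase <- function(name, start_date, end_date, days_printed = NA_integer_) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  stopifnot(is.character(name), length(name) == 1L, !is.na(start_date), !is.na(end_date))
  if (start_date > end_date) {
    stop("phase '", name, "': start_date is after end_date", call. = FALSE)
  }
  structure(
    list(name = name, start_date = start_date, end_date = end_date,
         days_printed = as.integer(days_printed)),
    class = "restriction_phase"
  )
}

#' @export
print.restriction_phase <- function(x, ...) {
  cat(sprintf("<phase> %s: %s .. %s (%d days)\n",
              x$name, format(x$start_date), format(x$end_date), phase_duration(x)))
  invisible(x)
}

#' The packaged eight-phase policy restriction calendar
#'
#' Eight COVID-19 policy restriction phases for Greater London,
#' 2020-01-01 to 2021-02-27, ordered and non-overlapping. Day counts as
#' originally published are attached as `days_printed` metadata; note the final
#' phase's published count (51) disagrees with inclusive date arithmetic (53) —
#' the dates are authoritative here and the printed count is retained only as
#' provenance.
#'
#' @return A list of eight [restriction_phase()] objects sorted by start date.
#' @export
default_calendar <- function() {
  rows <- list(
    list("Before lockdown",               "2020-01-01", "2020-03-22", 82L),
    list("First national lockdown",       "2020-03-23", "2020-07-03", 103L),
    list("Minimal lockdown restrictions", "2020-07-04", "2020-09-13", 72L),
    list("Reimposing restrictions",       "2020-09-14", "2020-10-13", 30L),
    list("Three-tire restrictions",       "2020-10-14", "2020-11-04", 22L),
    list("Second national lockdown",      "2020-11-05", "2020-12-02", 28L),
    list("Four-tier restrictions",        "2020-12-03", "2021-01-05", 34L),
    list("Third national lockdown",       "2021-01-06", "2021-02-27", 51L)
  )
  lapply(rows, function(r) restriction_phase(r[[1]], r[[2]], r[[3]], r[[4]]))
}

#' Inclusive duration of a phase in days
#'
#' @param phase A [restriction_phase()].
#' @return Integer day count, `end_date - start_date + 1`.
#' @export
phase_duration <- function(phase) {
  stopifnot(inherits(phase, "restriction_phase"))
  as.integer(phase$end_date - phase$start_date) + 1L
}

#' Calendar as a data frame
#'
#' @param calendar List of [restriction_phase()] objects.
#' @return data.frame with columns name, start_date, end_date, days,
#'   days_printed.
#' @export
calendar_table <- function(calendar) {
  validate_calendar(calendar)
  data.frame(
    name = vapply(calendar, `[[`, character(1), "name"),
    start_date = as.Date(vapply(calendar, function(p) format(p$start_date), character(1))),
    end_date = as.Date(vapply(calendar, function(p) format(p$end_date), character(1))),
    days = vapply(calendar, phase_duration, integer(1)),
    days_printed = vapply(calendar, function(p) p$days_printed, integer(1)),
    stringsAsFactors = FALSE
  )
}

validate_calendar <- function(calendar) {
  stopifnot(is.list(calendar), length(calendar) >= 1L)
  ok <- vapply(calendar, inherits, logical(1), "restriction_phase")
  if (!all(ok)) stop("calendar must be a list of restriction_phase objects", call. = FALSE)
  starts <- as.Date(vapply(calendar, function(p) format(p$start_date), character(1)))
  ends <- as.Date(vapply(calendar, function(p) format(p$end_date), character(1)))
  if (is.unsorted(starts)) stop("calendar phases must be sorted by start_date", call. = FALSE)
  if (length(calendar) > 1L && any(starts[-1L] <= ends[-length(ends)])) {
    stop("calendar phases must not overlap", call. = FALSE)
  }
  invisible(calendar)
}

#' Dates covered by a phase
#'
#' @param phase A [restriction_phase()].
#' @return Vector of consecutive `Date`s from start to end, inclusive.
#' @export
phase_dates <- function(phase) {
  stopifnot(inherits(phase, "restriction_phase"))
  seq(phase$start_date, phase$end_date, by = "day")
}

#' Restrict a daily-indexed structure to one phase
#'
#' Generic over structures keyed by calendar dates: `Date` vectors, data frames
#' with a `date` column, footfall matrices (date columns), and vectors/lists
#' named by ISO dates. The result contains exactly the input entries whose date
#' falls in `[start_date, end_date]`, input order preserved. An empty overlap
#' is signalled with a warning, not an error.
#'
#' @param x Daily-indexed structure.
#' @param phase A [restriction_phase()].
#' @param ... Passed to methods.
#' @return Same kind of structure, restricted to the phase.
#' @export
slice_by_phase <- function(x, phase, ...) UseMethod("slice_by_phase")

in_phase <- function(dates, phase) {
  dates >= phase$start_date & dates <= phase$end_date
}

warn_if_empty <- function(keep, phase) {
  if (!any(keep)) {
    warning("no dates overlap phase '", phase$name, "'", call. = FALSE)
  }
  keep
}

#' @export
slice_by_phase.Date <- function(x, phase, ...) {
  x[warn_if_empty(in_phase(x, phase), phase)]
}

#' @export
slice_by_phase.data.frame <- function(x, phase, date_col = "date", ...) {
  stopifnot(date_col %in% names(x))
  x[warn_if_empty(in_phase(as.Date(x[[date_col]]), phase), phase), , drop = FALSE]
}

#' @export
slice_by_phase.footfall_matrix <- function(x, phase, ...) {
  keep <- warn_if_empty(in_phase(footfall_dates(x), phase), phase)
  x[, keep, drop = FALSE]
}

#' @export
slice_by_phase.default <- function(x, phase, ...) {
  if (is.null(names(x))) stop("slice_by_phase needs a date-keyed structure", call. = FALSE)
  x[warn_if_empty(in_phase(as.Date(names(x)), phase), phase)]
}

#' Read / write a phase calendar as a YAML config
#'
#' Each entry has fields `name`, `start`, `end` (ISO dates) and optionally
#' `days_printed`.
#'
#' @param path File path.
#' @param calendar List of [restriction_phase()] objects (for writing).
#' @return `read_calendar()` returns a calendar list; `write_calendar()`
#'   returns `path` invisibly.
#' @export
read_calendar <- function(path) {
  raw <- yaml::read_yaml(path)
  cal <- lapply(raw, function(r) {
    restriction_phase(r$name, r$start, r$end,
                      if (is.null(r$days_printed)) NA_integer_ else r$days_printed)
  })
  validate_calendar(cal)
}

#' @rdname read_calendar
#' @export
write_calendar <- function(calendar, path) {
  validate_calendar(calendar)
  entries <- lapply(calendar, function(p) {
    e <- list(name = p$name, start = format(p$start_date), end = format(p$end_date))
    if (!is.na(p$days_printed)) e$days_printed <- p$days_printed
    e
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}
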