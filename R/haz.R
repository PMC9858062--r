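# Human activity zone (HAZ) delineation: row-standardise the footfall matrix,
# cluster units by their standardised temporal profiles (agglomerative, Ward
# linkage on Euclidean distances), pick the cluster count by maximising the
# mean silhouette, and rank zone labels by raw mean daily footfall.

#' Row-standardise a footfall matrix
#'
#' Each retained row is centred by its mean and scaled by its population
#' standard deviation (divisor t, not t-1), so the clustering compares the
#' shape of each unit's temporal profile rather than its volume. Rows with
#' zero variance have no defined standardised pattern and are excluded.
#'
#' @param mat A [footfall_matrix()] with at least 2 date columns.
#' @return List of class `standardized_matrix`: `values` (m' x t matrix, rows
#'   mean 0 / population sd 1), `unit_ids`, `dates`, `excluded_units`.
#' @export
standardize_rows <- function(mat) {
  stopifnot(ncol(mat) >= 2L)
  mu <- rowMeans(mat)
  sigma <- sqrt(rowMeans((mat - mu)^2))  # population sd, divisor t
  keep <- sigma > 0
  if (!any(keep)) stop("all rows are degenerate (zero variance)", call. = FALSE)
  B <- (mat[keep, , drop = FALSE] - mu[keep]) / sigma[keep]
  structure(list(values = unclass(B), unit_ids = rownames(mat)[keep],
                 dates = footfall_dates(mat),
                 excluded_units = rownames(mat)[!keep]),
            class = "standardized_matrix")
}

#' @export
print.standardized_matrix <- function(x, ...) {
  cat(sprintf("<standardized_matrix> %d units x %d days (%d excluded)\n",
              nrow(x$values), ncol(x$values), length(x$excluded_units)))
  invisible(x)
}

#' Label for units excluded from clustering
#' @export
HAZ_SENTINEL <- -1L

#' Delineate HAZs for one observation period
#'
#' Fits agglomerative clustering (Euclidean distance; Ward linkage by
#' default) on the standardised rows, computes the mean silhouette for every
#' candidate cluster count in `[n_min, n_max]`, and keeps the count with the
#' highest silhouette (ties broken toward the smallest count). Cluster labels
#' are then re-indexed 0, 1, ... by descending mean daily raw footfall of
#' their member units, so label 0 is always the busiest zone. Units excluded
#' at standardisation get the sentinel label [HAZ_SENTINEL].
#'
#' @param std A [standardize_rows()] result.
#' @param raw The raw [footfall_matrix()] for the same period (used only for
#'   the ranking step).
#' @param n_min,n_max Candidate cluster-count range, `2 <= n_min <= n_max <
#'   m'` (m' = retained units); `n_max` >= m' is an error. `n_max = NULL`
#'   picks `min(15, m' - 1)`.
#' @param linkage Agglomeration method: `"ward"` (Ward on Euclidean
#'   distances, via `hclust`'s `ward.D2`), `"average"` or `"complete"`.
#' @param period Label attached to the partition.
#' @return Object of class `haz_partition`: `period`, `labels` (named
#'   integer vector over all units, sentinel = excluded), `n`,
#'   `mean_daily_footfall` (per label, non-increasing), `silhouette`, and the
#'   per-candidate `silhouette_profile`.
#' @export
delineate_hazs <- function(std, raw, n_min = 2L, n_max = 15L,
                           linkage = c("ward", "average", "complete"),
                           period = "all") {
  linkage <- match.arg(linkage)
  stopifnot(inherits(std, "standardized_matrix"))
  m <- nrow(std$values)
  if (is.null(n_max)) n_max <- min(15L, m - 1L)
  if (n_max >= m) {
    stop("n_max (", n_max, ") must be below the number of clustered units (", m, ")",
         call. = FALSE)
  }
  if (!(2L <= n_min && n_min <= n_max)) {
    stop("need 2 <= n_min <= n_max < number of clustered units (", m, ")",
         call. = FALSE)
  }
  d <- stats::dist(std$values, method = "euclidean")
  hc <- stats::hclust(d, method = switch(linkage, ward = "ward.D2", linkage))
  cand <- n_min:n_max
  sil <- vapply(cand, function(n) {
    cl <- stats::cutree(hc, k = n)
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  }, numeric(1))
  best <- cand[which.max(sil)]  # which.max takes the first maximum: smallest n
  cl <- stats::cutree(hc, k = best)

  # rank labels by mean daily raw footfall of member units, busiest first
  row_mean <- rowMeans(raw)[std$unit_ids]
  cl_mean <- tapply(row_mean, cl, mean)
  rank_of <- stats::setNames(seq_along(cl_mean) - 1L,
                             names(sort(cl_mean, decreasing = TRUE)))
  labels <- stats::setNames(rep(HAZ_SENTINEL, nrow(raw)), rownames(raw))
  labels[std$unit_ids] <- rank_of[as.character(cl)]
  mdf <- sort(as.numeric(cl_mean), decreasing = TRUE)
  structure(list(period = period, labels = labels, n = best,
                 mean_daily_footfall = stats::setNames(mdf, seq_along(mdf) - 1L),
                 silhouette = max(sil),
                 silhouette_profile = stats::setNames(sil, cand)),
            class = "haz_partition")
}

#' @export
print.haz_partition <- function(x, ...) {
  cat(sprintf("<haz_partition> period '%s': n = %d zones over %d units (%d excluded), silhouette %.3f\n",
              x$period, x$n, length(x$labels), sum(x$labels == HAZ_SENTINEL),
              x$silhouette))
  invisible(x)
}

#' Delineate HAZs per phase and for the full period
#'
#' For each calendar phase the footfall matrix is sliced to the phase dates
#' and re-standardised within the slice — the zone structure of a phase
#' reflects only that phase's temporal profiles — then clustered and ranked
#' exactly as in [delineate_hazs()]. A unit constant within one phase is
#' excluded from that phase's partition only.
#'
#' @param mat Full-period [footfall_matrix()].
#' @param calendar Phase calendar (phases must lie within the matrix dates
#'   and span at least 2 days each).
#' @param n_min,n_max,linkage Passed to [delineate_hazs()].
#' @param include_all_period Also cluster the full date span (partition named
#'   `"all"`, first in the result).
#' @return Named list of `haz_partition` objects.
#' @export
delineate_per_phase <- function(mat, calendar = default_calendar(),
                                n_min = 2L, n_max = NULL, linkage = "ward",
                                include_all_period = TRUE) {
  validate_calendar(calendar)
  out <- list()
  if (include_all_period) {
    out[["all"]] <- delineate_hazs(standardize_rows(mat), mat,
                                   n_min, n_max, linkage, period = "all")
  }
  for (p in calendar) {
    if (phase_duration(p) < 2L) {
      stop("phase '", p$name, "' spans fewer than 2 days", call. = FALSE)
    }
    slice <- slice_by_phase(mat, p)
    out[[p$name]] <- delineate_hazs(standardize_rows(slice), slice,
                                    n_min, n_max, linkage, period = p$name)
  }
  out
}
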