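# Agreement between HAZ partitions from different phases: cross-tabulation
# over jointly clustered units and Pearson's contingency coefficient
# C = sqrt(chi2 / (chi2 + N)).

#' Cross-tabulate two HAZ partitions
#'
#' Counts units by their (label in A, label in B) pair, over units with a
#' non-sentinel label in both partitions; units excluded in either partition
#' are dropped and the drop count attached.
#'
#' @param pa,pb `haz_partition` objects over a shared unit universe.
#' @return Contingency table (class `table`) with attribute `"n_dropped"`.
#' @export
haz_crosstab <- function(pa, pb) {
  common <- intersect(names(pa$labels), names(pb$labels))
  if (!length(common)) stop("partitions share no units", call. = FALSE)
  la <- pa$labels[common]
  lb <- pb$labels[common]
  keep <- la != HAZ_SENTINEL & lb != HAZ_SENTINEL
  if (!any(keep)) stop("no units clustered in both partitions", call. = FALSE)
  tab <- table(a = la[keep], b = lb[keep])
  attr(tab, "n_dropped") <- sum(!keep)
  tab
}

#' Pearson's contingency coefficient
#'
#' `C = sqrt(chi2 / (chi2 + N))` with the plain Pearson chi-square statistic
#' (no continuity correction; expected counts from the product of margins).
#' Rows/columns with zero margins are dropped before computing expectations.
#' `C` lies in `[0, 1)` and is 0 exactly when the table is independent; it is
#' used descriptively, so small expected counts only raise a warning.
#'
#' @param tab Nonnegative count matrix/table with total >= 1.
#' @return The coefficient, a single number in `[0, 1)`.
#' @export
contingency_coefficient <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(tab >= 0), sum(tab) >= 1)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(0)
  N <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / N
  if (any(E < 5)) {
    warning("expected counts below 5; C is reported uncorrected", call. = FALSE)
  }
  chi2 <- sum((tab - E)^2 / E)
  sqrt(chi2 / (chi2 + N))
}

#' Pairwise contingency coefficients across partitions
#'
#' @param partitions Named list of `haz_partition` objects (>= 2).
#' @return Symmetric k x k matrix of C values, phase names as dimnames; the
#'   diagonal is each partition's C with itself.
#' @export
pairwise_contingency <- function(partitions) {
  k <- length(partitions)
  stopifnot(k >= 2L)
  nm <- names(partitions) %||% paste0("partition", seq_len(k))
  out <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) {
    for (j in i:k) {
      cij <- tryCatch(
        contingency_coefficient(haz_crosstab(partitions[[i]], partitions[[j]])),
        error = function(e) {
          stop("pair (", nm[i], ", ", nm[j], "): ", conditionMessage(e),
               call. = FALSE)
        })
      out[i, j] <- cij
      out[j, i] <- cij
    }
  }
  out
}
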