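# Attribution of HAZ membership to static urban characteristics: a random-
# forest classifier per observation period, tuned by randomised search with
# stratified k-fold cross-validation. Accuracy summarises the global
# relationship; normalised Gini importance (total decrease in Gini impurity
# over all splits and trees, scaled to sum to 1) the per-feature one.

#' Build the design matrix and label vector for one partition
#'
#' One row per unit with a non-sentinel HAZ label, ordered by sorted unit id.
#' The supergroup is integer-coded as a single column, preserving the
#' 11-column design (10 land-use acreages + 1 socio-demographic category).
#'
#' @param features Urban feature table (see [generate_urban_features()]).
#' @param partition A `haz_partition`.
#' @return List: `x` (numeric matrix, 11 columns), `y` (factor of HAZ
#'   labels), `unit_id`.
#' @export
build_design <- function(features, partition) {
  ids <- intersect(features$unit_id, names(partition$labels))
  lab <- partition$labels[ids]
  ids <- sort(ids[lab[ids] != HAZ_SENTINEL])
  if (length(unique(partition$labels[ids])) < 2L) {
    stop("fewer than 2 distinct HAZ labels among usable units", call. = FALSE)
  }
  f <- features[match(ids, features$unit_id), , drop = FALSE]
  x <- cbind(as.matrix(f[, paste0("lu_", 0:9), drop = FALSE]),
             supergroup = as.integer(factor(f$supergroup)))
  rownames(x) <- ids
  list(x = x, y = factor(partition$labels[ids]), unit_id = ids)
}

# Stratified fold assignment: each class's rows are spread round-robin over
# folds so every fold sees (near-)proportional class shares. Singleton-class
# rows simply land in one fold.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx[sample.int(length(idx))]] <- rep_len(sample.int(k), length(idx))
  }
  fold
}

#' Fit the tuned random-forest classifier for one period
#'
#' Randomised hyper-parameter search: `n_param_draws` configurations sampled
#' over tree count, features-per-split (mtry) and minimum node size, each
#' scored by stratified k-fold cross-validated accuracy on a shared fold
#' assignment; the best configuration is refit on all rows. If the rarest
#' class has fewer members than `cv_folds`, the fold count is reduced with a
#' warning. All randomness (folds, search, forests) flows from `seed`.
#'
#' @param design Output of [build_design()] (or any list with `x`, `y`).
#' @param cv_folds Number of CV folds (>= 2; default 10).
#' @param n_param_draws Number of sampled configurations (default 15).
#' @param seed Integer seed.
#' @param period Label carried into the result.
#' @return Object of class `association_result`: `period`, `cv_accuracy`
#'   (best mean CV accuracy), `importances` (nonnegative, sum 1), `params`
#'   (selected hyper-parameters), `n_units`, `seed`, and the fitted `forest`.
#' @export
fit_classifier <- function(design, cv_folds = 10L, n_param_draws = 15L,
                           seed = 1L, period = NA_character_) {
  x <- design$x; y <- droplevels(design$y)
  stopifnot(cv_folds >= 2L, n_param_draws >= 1L, nrow(x) == length(y))
  set.seed(seed)
  min_class <- min(table(y))
  k <- cv_folds
  if (min_class < k) {
    k <- max(2L, min_class)
    warning("rarest class has ", min_class, " member(s); folds reduced to ", k,
            call. = FALSE)
  }
  fold <- stratified_folds(y, k)
  p <- ncol(x)
  grid <- data.frame(
    ntree = sample(c(100L, 200L, 300L, 500L), n_param_draws, replace = TRUE),
    mtry = sample.int(p, n_param_draws, replace = TRUE),
    nodesize = sample(c(1L, 3L, 5L, 10L), n_param_draws, replace = TRUE))
  cv_acc <- numeric(n_param_draws)
  for (g in seq_len(n_param_draws)) {
    correct <- 0L
    for (f in seq_len(k)) {
      test <- fold == f
      if (!any(test) || length(unique(y[!test])) < 2L) next
      fit <- randomForest::randomForest(
        x[!test, , drop = FALSE], droplevels(y[!test]),
        ntree = grid$ntree[g], mtry = grid$mtry[g], nodesize = grid$nodesize[g])
      pred <- stats::predict(fit, x[test, , drop = FALSE])
      correct <- correct + sum(as.character(pred) == as.character(y[test]))
    }
    cv_acc[g] <- correct / length(y)
  }
  best <- which.max(cv_acc)
  forest <- randomForest::randomForest(
    x, y, ntree = grid$ntree[best], mtry = grid$mtry[best],
    nodesize = grid$nodesize[best], importance = FALSE)
  imp <- forest$importance[, "MeanDecreaseGini"]
  imp <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / length(imp), length(imp))
  structure(list(period = period, cv_accuracy = cv_acc[best],
                 importances = stats::setNames(as.numeric(imp), colnames(x)),
                 params = as.list(grid[best, ]), n_units = nrow(x),
                 seed = seed, cv_folds = k, forest = forest),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("<association_result> period '%s': CV accuracy %.3f (%d-fold, n = %d)\n",
              x$period, x$cv_accuracy, x$cv_folds, x$n_units))
  top <- sort(x$importances, decreasing = TRUE)[1:3]
  cat("  top importances:",
      paste(sprintf("%s = %.3f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Normalised Gini importances of a fitted classifier
#'
#' Per-feature total decrease in Gini impurity accumulated over all splits of
#' all trees, normalised so the importances sum to 1.
#'
#' @param result An [fit_classifier()] result.
#' @return Named nonnegative numeric vector summing to 1.
#' @export
gini_importance <- function(result) {
  stopifnot(inherits(result, "association_result"))
  result$importances
}

#' Fit one classifier per HAZ partition
#'
#' @param features Urban feature table.
#' @param partitions Named list of `haz_partition` objects.
#' @param cv_folds,n_param_draws,seed Passed to [fit_classifier()].
#' @return List: `results` (one `association_result` per partition that could
#'   be fitted), `accuracy` (named vector), `importance_matrix` (features x
#'   periods, columns summing to 1), `failures` (named error messages for
#'   partitions that could not be fitted).
#' @export
per_phase_association <- function(features, partitions, cv_folds = 10L,
                                  n_param_draws = 15L, seed = 1L) {
  stopifnot(length(partitions) >= 1L)
  nm <- names(partitions) %||% paste0("partition", seq_along(partitions))
  results <- list(); failures <- character(0)
  for (i in seq_along(partitions)) {
    res <- tryCatch(
      fit_classifier(build_design(features, partitions[[i]]),
                     cv_folds = cv_folds, n_param_draws = n_param_draws,
                     seed = seed + i, period = nm[i]),
      error = function(e) conditionMessage(e))
    if (is.character(res)) failures[nm[i]] <- res else results[[nm[i]]] <- res
  }
  if (!length(results)) stop("no partition could be fitted", call. = FALSE)
  acc <- vapply(results, `[[`, numeric(1), "cv_accuracy")
  imp <- do.call(cbind, lapply(results, `[[`, "importances"))
  list(results = results, accuracy = acc,
       importance_matrix = imp, failures = failures)
}
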