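# The evaluation metric family: MSE, group-balanced MSE over target subsets,
# and signed / absolute group-difference errors that reveal whether one
# confound group is predicted better than the other across the target range.

#' Mean squared error
#'
#' @param y,yhat Numeric vectors of equal length.
#' @return Mean of squared residuals.
#' @export
mse <- function(y, yhat) {
  if (length(y) != length(yhat))
    abort("y and yhat lengths differ", class = "deconfound_shape_error")
  mean((y - yhat)^2)
}

#' Partition subjects into low/high-target subsets
#'
#' Assigns each subject to subset 1 (`y <= threshold`) or subset 2. The
#' threshold should be computed once over the full pool (its median by
#' default), not per fold, so subsets are comparable across folds; ties at
#' the threshold fall in subset 1.
#'
#' @param y Numeric targets of the subjects to partition.
#' @param threshold Partition threshold; defaults to `median(y)`.
#' @return An integer vector of 1s and 2s with attribute `threshold`. Errors
#'   if either subset would be empty.
#' @export
partition_by_target <- function(y, threshold = NULL) {
  if (length(unique(y)) < 2 && is.null(threshold))
    abort("all targets identical: degenerate partition",
          class = "deconfound_domain_error")
  threshold <- threshold %||% median(y)
  part <- ifelse(y <= threshold, 1L, 2L)
  if (length(unique(part)) < 2)
    abort("one target subset is empty at this threshold",
          class = "deconfound_domain_error")
  structure(part, threshold = threshold)
}

# per-subset group-wise MSEs; the common kernel of the balanced and
# difference metrics. Returns a tibble: subset, n, mse_0, mse_1.
subset_group_mse <- function(y, yhat, group, part) {
  lev <- sort(unique(group))
  if (length(lev) != 2)
    abort("group must have exactly two levels", class = "deconfound_domain_error")
  purrr::map_dfr(sort(unique(as.integer(part))), function(l) {
    sel <- part == l
    m <- vapply(lev, function(q) {
      cell <- sel & group == q
      if (!any(cell))
        abort(sprintf("empty cell: subset %d, group level %s", l, q),
              class = "deconfound_metric_error")
      mean((y[cell] - yhat[cell])^2)
    }, numeric(1))
    tibble(subset = l, n = sum(sel), mse_0 = m[1], mse_1 = m[2])
  })
}

#' Group-balanced mean squared error
#'
#' For each target subset, the unweighted average of the two confound-group
#' MSEs (so each group counts equally regardless of size); overall, the
#' subset values averaged with weights `n_l / |fold|`. Equals the plain MSE
#' when the two groups are predicted equally well.
#'
#' @param y,yhat Observed and predicted targets for one test fold.
#' @param group Two-level confound labels for the fold.
#' @param partition Subset assignment from [partition_by_target()].
#' @return A list with `per_subset` (tibble: subset, n, value) and `overall`.
#' @export
balanced_mse <- function(y, yhat, group, partition) {
  gm <- subset_group_mse(y, yhat, group, partition)
  per <- dplyr::mutate(gm, value = (.data$mse_0 + .data$mse_1) / 2)
  list(per_subset = dplyr::select(per, "subset", "n", "value"),
       overall = sum(per$n / length(y) * per$value))
}

#' Signed and absolute group-difference errors
#'
#' For each target subset, the signed difference between the first and second
#' group's MSE (`mse_0 - mse_1`); positive values mean the second group is
#' predicted better. The summary is the subset-size-weighted average of the
#' absolute values, preventing opposite-signed subsets from cancelling.
#'
#' @inheritParams balanced_mse
#' @return A list with `per_subset` (tibble: subset, n, signed) and
#'   `overall` (absolute summary).
#' @export
signed_group_difference <- function(y, yhat, group, partition) {
  gm <- subset_group_mse(y, yhat, group, partition)
  per <- dplyr::mutate(gm, signed = .data$mse_0 - .data$mse_1)
  list(per_subset = dplyr::select(per, "subset", "n", "signed"),
       overall = sum(per$n / length(y) * abs(per$signed)))
}

# one tidy row of metrics for a single train/test run; `which` restricts the
# computation (group-wise metrics need every subset x group cell non-empty)
prediction_metrics <- function(y, yhat, group, partition,
                               which = c("mse", "balanced_mse", "diff_mse")) {
  out <- tibble(mse = mse(y, yhat))
  if ("balanced_mse" %in% which)
    out$balanced_mse <- balanced_mse(y, yhat, group, partition)$overall
  if ("diff_mse" %in% which) {
    s <- signed_group_difference(y, yhat, group, partition)
    out$diff_mse <- s$overall
    out$signed_diff_low <- s$per_subset$signed[1]
    out$signed_diff_high <- s$per_subset$signed[2]
  }
  out
}
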