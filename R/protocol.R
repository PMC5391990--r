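# Evaluation protocol: half-split the population-of-interest into two
# unbiased folds, draw biased (or unbiased) training samples from one fold,
# predict the opposite fold, and summarise the metric family over all runs.
# A restricted permutation test (targets shuffled within confound level)
# assesses whether a model learns from the features beyond the confound.

#' Split a pool into two disjoint half folds
#'
#' @param n Number of subjects (or a [confound_dataset()]).
#' @param seed Optional seed for the split substream.
#' @return A list with integer index vectors `f1`, `f2` (sizes differing by
#'   at most one when `n` is odd).
#' @export
half_split <- function(n, seed = NULL) {
  if (inherits(n, "confound_dataset")) n <- nrow(n$G)
  perm <- with_seed(seed, sample.int(n))
  h <- ceiling(n / 2)
  list(f1 = sort(perm[seq_len(h)]), f2 = sort(perm[seq(h + 1, n)]))
}

#' Draw a biased (or unbiased) sample from a fold
#'
#' Samples `size` subjects without replacement with selection probabilities
#' proportional to \eqn{\exp(\lambda \, z(y_i) \, \tilde c_i)}, where `z` is
#' the within-fold standardization of the target and \eqn{\tilde c \in
#' \{-1, +1\}} encodes the two confound levels (the higher level is `+1`).
#' With `lambda > 0` and `direction = +1`, high-target subjects of the higher
#' confound level are preferentially chosen, planting a confound–target
#' association. The draw is repeated until a two-sided equal-variance
#' two-sample t-test of the target across confound levels is significant
#' (`p < accept_p`) for biased draws, or non-significant (`p >= accept_p`)
#' for unbiased draws (`lambda = 0`).
#'
#' @param y Fold targets.
#' @param confound Two-level confound values for the fold.
#' @param size Sample size (must be smaller than the fold).
#' @param lambda Bias strength; `0` gives uniform sampling.
#' @param direction `+1` or `-1`, the sign of the planted association.
#' @param accept_p Significance level of the acceptance rule (default 0.05).
#' @param biased If `TRUE`, accept when `p < accept_p`; if `FALSE`, accept
#'   when `p >= accept_p`.
#' @param max_tries Maximum redraws before failing.
#' @param seed Optional seed for this draw's substream.
#' @param tilt Values whose within-fold standardization drives the selection
#'   probabilities; defaults to the target `y`. Passing a feature instead
#'   plants the association through the predictors (covariate shift proper,
#'   preserving the conditional distribution of the target given the
#'   predictors); the acceptance t-test is always on `y`.
#' @return A list with `indices` (into the fold), `p_value` (achieved t-test
#'   p), and `tries`.
#' @export
draw_biased_sample <- function(y, confound, size, lambda = 1.5, direction = 1,
                               accept_p = 0.05, biased = lambda > 0,
                               max_tries = 200, seed = NULL, tilt = y) {
  lev <- sort(unique(confound))
  if (length(lev) != 2)
    abort("fold must contain both confound levels", class = "deconfound_domain_error")
  if (size >= length(y))
    abort("sample size must be smaller than the fold", class = "deconfound_domain_error")
  ctil <- ifelse(confound == lev[2], 1, -1)
  z <- as.numeric(scale(tilt))
  prob <- exp(lambda * direction * z * ctil)
  with_seed(seed, {
    best_p <- NA_real_
    for (try in seq_len(max_tries)) {
      idx <- sample.int(length(y), size, prob = prob)
      if (length(unique(confound[idx])) < 2) next
      p <- t.test(y[idx] ~ ctil[idx], var.equal = TRUE)$p.value
      ok <- if (biased) p < accept_p else p >= accept_p
      if (ok) return(list(indices = sort(idx), p_value = p, tries = try))
      if (is.na(best_p) || (biased && p < best_p) || (!biased && p > best_p))
        best_p <- p
    }
    abort(sprintf("acceptance rule not met in %d tries (best p = %.4f)",
                  max_tries, best_p),
          class = "deconfound_sampling_error")
  })
}

#' Run the biased-training / unbiased-testing evaluation protocol
#'
#' Half-splits the pool into folds `F1`, `F2`; for each fold draws `J`
#' training samples (biased via [draw_biased_sample()], or unbiased); trains
#' every requested strategy on each sample and predicts the opposite fold;
#' and computes the metric family ([mse()], [balanced_mse()],
#' [signed_group_difference()]) with the target partition thresholded at the
#' pool median. All randomness derives from `seed` through named substreams,
#' so any stage is independently replayable.
#'
#' @param pool A [confound_dataset()] representative of the
#'   population-of-interest (target and confound independent).
#' @param strategies Character vector of strategy names
#'   (see [train_strategy()]).
#' @param J Training samples drawn per fold.
#' @param sample_size Size of each training sample.
#' @param lambda,direction,accept_p,max_tries Passed to
#'   [draw_biased_sample()].
#' @param biased Draw biased (`TRUE`) or unbiased (`FALSE`) training samples.
#' @param rounding Optional integer bounds passed to [train_strategy()].
#' @param check_pool If `TRUE`, error when the pool itself shows a
#'   significant confound–target association (`p < accept_p`), since it is
#'   then not a valid population-of-interest.
#' @param seed Master seed.
#' @param confound Column index of the (two-level) confound used for biasing
#'   and metrics.
#' @param ... Passed to [train_strategy()] / [fit_gp()].
#' @return An object of class `protocol_result`: list with `metrics` (tibble:
#'   one row per strategy x fold x sample), `summary` (per-strategy means),
#'   `predictions` (per-subject tibble), `threshold`, `splits` and `samples`
#'   metadata.
#' @examples
#' \donttest{
#' pop <- simulate_population(n = 80, d_features = 15, seed = 2)
#' pr <- run_protocol(pop, "images_only", J = 1, sample_size = 30,
#'                    seed = 7, n_restarts = 1)
#' pr$summary
#' }
#' @export
run_protocol <- function(pool, strategies = "images_only", J = 4,
                         sample_size = floor(nrow(pool$G) / 4), lambda = 1.5,
                         direction = 1, accept_p = 0.05, biased = TRUE,
                         rounding = NULL, check_pool = FALSE, seed = 1,
                         max_tries = 200, confound = 1, ...) {
  stopifnot(inherits(pool, "confound_dataset"), ncol(pool$C) >= confound)
  conf_all <- pool$C[, confound]
  if (check_pool) {
    p_pool <- t.test(pool$y ~ factor(conf_all), var.equal = TRUE)$p.value
    if (p_pool < accept_p)
      abort(sprintf("pool shows a significant confound-target association (p = %.4f); not a population-of-interest",
                    p_pool), class = "deconfound_domain_error")
  }
  threshold <- median(pool$y)
  split <- half_split(nrow(pool$G), seed = substream_seed(seed, "split"))
  folds <- list(split$f1, split$f2)
  metrics <- list(); preds <- list(); samples <- list()
  for (k in 1:2) {
    train_fold <- folds[[k]]; test_fold <- folds[[3 - k]]
    test_ds <- pool[test_fold]
    test_part <- partition_by_target(test_ds$y, threshold)
    test_group <- test_ds$C[, confound]
    for (j in seq_len(J)) {
      draw <- draw_biased_sample(pool$y[train_fold], conf_all[train_fold],
                                 size = sample_size, lambda = if (biased) lambda else 0,
                                 direction = direction, accept_p = accept_p,
                                 biased = biased, max_tries = max_tries,
                                 seed = substream_seed(seed, "draw", k * 1000 + j))
      train_ds <- pool[train_fold[draw$indices]]
      samples[[length(samples) + 1]] <-
        tibble(fold = k, j = j, p_value = draw$p_value, tries = draw$tries,
               indices = list(train_fold[draw$indices]))
      for (s in strategies) {
        model <- train_strategy(train_ds, s, test = if (s == "adjusted_images") test_ds,
                                rounding = rounding, ...)
        yhat <- predict(model, test_ds)
        metrics[[length(metrics) + 1]] <- dplyr::bind_cols(
          tibble(strategy = s, fold = k, j = j, bias_p = draw$p_value),
          prediction_metrics(test_ds$y, yhat, test_group, test_part))
        preds[[length(preds) + 1]] <-
          tibble(strategy = s, fold = k, j = j,
                 subject_id = test_ds$subject_ids, y_true = test_ds$y,
                 y_pred = yhat, group = test_group, subset = as.integer(test_part))
      }
    }
  }
  metrics <- dplyr::bind_rows(metrics)
  summary <- metrics |>
    dplyr::group_by(.data$strategy) |>
    dplyr::summarise(dplyr::across(c("mse", "balanced_mse", "diff_mse",
                                     "signed_diff_low", "signed_diff_high"), mean),
                     n_runs = dplyr::n(), .groups = "drop")
  structure(list(metrics = metrics, summary = summary,
                 predictions = dplyr::bind_rows(preds),
                 samples = dplyr::bind_rows(samples),
                 threshold = threshold, splits = split, seed = seed,
                 biased = biased, lambda = lambda),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("<protocol_result> %s training samples, %d runs, partition threshold %.3g\n",
              if (x$biased) "biased" else "unbiased", nrow(x$metrics), x$threshold))
  print(x$summary)
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.protocol_result <- function(x, ...) x$metrics

#' @rdname tidiers
#' @export
glance.protocol_result <- function(x, ...) x$summary

# permute targets within confound level (one permutation), preserving each
# level's multiset of targets exactly
permute_within_levels <- function(y, group) {
  out <- y
  for (g in unique(group)) {
    idx <- which(group == g)
    out[idx] <- y[idx[sample.int(length(idx))]]
  }
  out
}

#' Restricted permutation test for predictive performance under confounding
#'
#' Tests whether a model learns information from the features beyond what the
#' confound carries, by re-running training/prediction with targets permuted
#' *within confound level* — separately within each training sample and each
#' test fold — which preserves the confound–target association while breaking
#' the feature–target link. The p-value for each metric is the proportion of
#' permutations (the unpermuted labelling included) whose metric is less than
#' or equal to the observed one.
#'
#' @inheritParams run_protocol
#' @param strategy A single strategy name.
#' @param n_perm Total number of permutations including the identity
#'   (default 500).
#' @param fixed_hyperparameters If `TRUE`, kernel hyperparameters and noise
#'   scale are estimated once on the observed targets and reused for every
#'   permutation (only the linear solve is redone), making large `n_perm`
#'   cheap. If `FALSE`, the full fit is repeated per permutation.
#' @param metrics Which metrics to compute p-values for.
#' @return An object of class `permutation_result`: list with `observed`
#'   (named metric values), `null` (tibble of permuted metric values),
#'   `p_values` (named, each in `[1/n_perm, 1]`), `n_perm`.
#' @export
restricted_permutation_test <- function(pool, strategy = "images_only", J = 4,
                                        sample_size = floor(nrow(pool$G) / 4),
                                        lambda = 1.5, direction = 1,
                                        accept_p = 0.05, biased = TRUE,
                                        rounding = NULL, n_perm = 500, seed = 1,
                                        fixed_hyperparameters = FALSE,
                                        metrics = c("mse", "balanced_mse"),
                                        confound = 1, max_tries = 200, ...) {
  stopifnot(length(strategy) == 1, n_perm >= 2)
  threshold <- median(pool$y)
  conf_all <- pool$C[, confound]
  split <- half_split(nrow(pool$G), seed = substream_seed(seed, "split"))
  folds <- list(split$f1, split$f2)

  # fixed training/test pairs, as in the observed protocol
  runs <- list()
  for (k in 1:2) for (j in seq_len(J)) {
    train_fold <- folds[[k]]
    draw <- draw_biased_sample(pool$y[train_fold], conf_all[train_fold],
                               size = sample_size, lambda = if (biased) lambda else 0,
                               direction = direction, accept_p = accept_p,
                               biased = biased, max_tries = max_tries,
                               seed = substream_seed(seed, "draw", k * 1000 + j))
    runs[[length(runs) + 1]] <- list(k = k, train = train_fold[draw$indices],
                                     test = folds[[3 - k]])
  }

  # per-run fixed pieces: design matrices and (optionally) the hat matrix
  prep <- lapply(runs, function(r) {
    train_ds <- pool[r$train]; test_ds <- pool[r$test]
    out <- list(train_ds = train_ds, test_ds = test_ds,
                part = partition_by_target(test_ds$y, threshold),
                group_train = train_ds$C[, confound],
                group_test = test_ds$C[, confound])
    if (fixed_hyperparameters) {
      model <- train_strategy(train_ds, strategy,
                              test = if (strategy == "adjusted_images") test_ds,
                              rounding = NULL, ...)
      gp <- model$gp
      Gt <- test_ds$G
      if (strategy == "adjusted_images")
        Gt <- apply_adjustment(Gt, augment_confounds(test_ds$C), model$adjustment)
      Xt <- standardize_features(Gt, stats = model$standardization)$train
      if (strategy == "images_confounds")
        Xt <- cbind(Xt, apply_confound_scaling(test_ds$C, model$confound_scaling))
      ks <- gram(gp$kernel, Xt, gp$X_train)
      Ainv_ks <- backsolve(gp$L, forwardsolve(t(gp$L), t(ks)))
      out$hat <- t(Ainv_ks)          # predictions = hat %*% y_train
      out$model <- model
    }
    out
  })

  eval_metrics <- function(y_train_list, y_test_list) {
    rows <- purrr::map_dfr(seq_along(prep), function(i) {
      p <- prep[[i]]
      if (fixed_hyperparameters) {
        yhat <- drop(p$hat %*% y_train_list[[i]])
      } else {
        train_ds <- p$train_ds; train_ds$y <- y_train_list[[i]]
        model <- train_strategy(train_ds, strategy,
                                test = if (strategy == "adjusted_images") p$test_ds,
                                rounding = rounding, ...)
        yhat <- predict(model, p$test_ds)
      }
      if (!is.null(rounding) && fixed_hyperparameters)
        yhat <- pmin(pmax(round(yhat), rounding[1]), rounding[2])
      prediction_metrics(y_test_list[[i]], yhat, p$group_test, p$part,
                         which = metrics)
    })
    colMeans(rows[, metrics, drop = FALSE])
  }

  observed <- eval_metrics(lapply(prep, function(p) p$train_ds$y),
                           lapply(prep, function(p) p$test_ds$y))

  null_rows <- with_seed(substream_seed(seed, "perm"), {
    lapply(seq_len(n_perm - 1), function(b) {
      ytr <- lapply(prep, function(p) permute_within_levels(p$train_ds$y, p$group_train))
      yte <- lapply(prep, function(p) permute_within_levels(p$test_ds$y, p$group_test))
      eval_metrics(ytr, yte)
    })
  })
  null <- dplyr::bind_rows(c(list(observed), lapply(null_rows, as.list)))
  p_values <- vapply(metrics, function(m) mean(null[[m]] <= observed[[m]]), numeric(1))
  structure(list(observed = observed, null = null, p_values = p_values,
                 n_perm = n_perm, strategy = strategy),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> strategy = %s, %d permutations (identity included)\n",
              x$strategy, x$n_perm))
  for (m in names(x$p_values))
    cat(sprintf("  %s: observed %.4f, p = %.4f\n", m, x$observed[[m]], x$p_values[[m]]))
  invisible(x)
}
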