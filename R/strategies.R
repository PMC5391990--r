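# The four confound-handling strategies behind one train/predict interface:
# images only, adjusted images, images & confounds, and images only with
# density-ratio instance weighting. All use GP regression with linear-family
# kernels, so predictions are (weighted) kernel ridge regression.

strategy_names <- c("images_only", "adjusted_images", "images_confounds",
                    "instance_weighted")

#' Train a confound-handling strategy
#'
#' Fits one of four strategies to a training [confound_dataset()]:
#'
#' * `images_only`: GP on the standardized features with a linear-plus-bias
#'   kernel; confounds ignored.
#' * `adjusted_images`: features residualised on the confounds
#'   ([fit_adjustment()]) before standardization and GP fitting. By default
#'   the adjustment model is fit transductively on the pooled training and
#'   test rows (supply `test` for that); with `test = NULL` it is fit on the
#'   training rows only.
#' * `images_confounds`: confounds appended to the features; kernel is the
#'   sum of linear-plus-bias on the feature block and a linear ARD kernel on
#'   the confound block, so each confound's contribution is controlled by its
#'   ARD scale. Continuous confounds are standardized with training
#'   statistics; two-level 0/1 encodings are left unscaled.
#' * `instance_weighted`: density-ratio instance weights
#'   ([compute_instance_weights()]) computed from the training targets and
#'   confounds, then a heteroscedastic-likelihood GP on the standardized
#'   features; the predictive function does not depend on the confounds.
#'
#' @param train A [confound_dataset()] of training subjects.
#' @param strategy One of `"images_only"`, `"adjusted_images"`,
#'   `"images_confounds"`, `"instance_weighted"`.
#' @param test Optional [confound_dataset()] (or list with elements `G` and
#'   `C`) whose rows join the adjustment fit for `adjusted_images`.
#' @param rounding Optional length-2 integer bounds `c(lower, upper)`; test
#'   predictions are rounded to the nearest whole number and clamped to this
#'   range (e.g. `c(0, 30)` for a bounded screening score).
#' @param weights Optional precomputed [instance_weights][compute_instance_weights]
#'   or numeric vector, overriding the estimated ones (only for
#'   `instance_weighted`).
#' @param normalize_weights Passed to [compute_instance_weights()].
#' @param ... Passed to [fit_gp()] (e.g. `n_restarts`, `maxit`).
#' @return An object of class `deconfound_model`.
#' @examples
#' pop <- simulate_population(n = 60, d_features = 10, seed = 1)
#' m <- train_strategy(pop, "images_only", n_restarts = 1)
#' head(predict(m, pop))
#' @export
train_strategy <- function(train, strategy = strategy_names, test = NULL,
                           rounding = NULL, weights = NULL,
                           normalize_weights = TRUE, ...) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(train, "confound_dataset"))
  if (!is.null(rounding) && (length(rounding) != 2 || rounding[1] > rounding[2]))
    abort("rounding must be c(lower, upper) with lower <= upper",
          class = "deconfound_configuration_error")
  if (strategy != "instance_weighted" && !is.null(weights))
    abort("weights are only meaningful for the instance_weighted strategy",
          class = "deconfound_configuration_error")
  if (strategy %in% c("adjusted_images", "images_confounds", "instance_weighted") &&
      ncol(train$C) == 0)
    abort(sprintf("strategy '%s' requires confounds", strategy),
          class = "deconfound_configuration_error")
  y <- train$y
  adjustment <- NULL; iw <- NULL; conf_std <- NULL

  if (strategy == "adjusted_images") {
    G_fit <- train$G; C_fit <- train$C
    if (!is.null(test)) {
      G_fit <- rbind(G_fit, test$G)
      C_fit <- rbind(C_fit, test$C)
    }
    C_hat <- augment_confounds(C_fit)
    adjustment <- fit_adjustment(G_fit, C_hat, subset = NULL)
    G_use <- apply_adjustment(train$G, augment_confounds(train$C), adjustment)
  } else {
    G_use <- train$G
  }

  std <- standardize_features(G_use)
  Xg <- std$train
  dG <- ncol(Xg)

  if (strategy == "images_confounds") {
    conf_std <- confound_scaling(train$C)
    Cs <- apply_confound_scaling(train$C, conf_std)
    X <- cbind(Xg, Cs)
    kern <- kernel_sum(kernel_linear_bias(cols = seq_len(dG)),
                       kernel_ard_linear(rep(1, ncol(Cs)), cols = dG + seq_len(ncol(Cs))))
    gp <- fit_gp(kern, X, y, ...)
  } else if (strategy == "instance_weighted") {
    if (is.null(weights)) iw <- compute_instance_weights(y, train$C,
                                                         normalize = normalize_weights)
    else if (inherits(weights, "instance_weights")) iw <- weights
    else iw <- structure(list(w = as.numeric(weights),
                              p_marginal = rep(NA_real_, length(y)),
                              p_conditional = rep(NA_real_, length(y)),
                              marginal_fit = NULL, conditional_fit = NULL),
                         class = "instance_weights")
    gp <- fit_gp(kernel_linear_bias(), Xg, y, weights = iw$w, ...)
  } else {
    gp <- fit_gp(kernel_linear_bias(), Xg, y, ...)
  }

  structure(list(strategy = strategy, gp = gp, adjustment = adjustment,
                 weights = iw, standardization = std$stats,
                 confound_scaling = conf_std, rounding = rounding,
                 feature_names = train$feature_names,
                 confound_names = train$confound_names),
            class = "deconfound_model")
}

# training-statistics scaling for confound columns: centre/scale continuous
# columns, leave two-level 0/1 encodings untouched
confound_scaling <- function(C) {
  lapply(seq_len(ncol(C)), function(j) {
    u <- unique(C[, j])
    if (length(u) <= 2) list(center = 0, scale = 1)
    else list(center = mean(C[, j]), scale = max(sd(C[, j]), .Machine$double.eps))
  })
}

apply_confound_scaling <- function(C, scaling) {
  out <- C
  for (j in seq_len(ncol(C)))
    out[, j] <- (C[, j] - scaling[[j]]$center) / scaling[[j]]$scale
  out
}

#' @export
print.deconfound_model <- function(x, ...) {
  cat(sprintf("<deconfound_model> strategy = %s\n", x$strategy))
  print(x$gp)
  invisible(x)
}

#' Predict from a trained confound-handling strategy
#'
#' Applies the strategy's stored preprocessing (adjustment, standardization,
#' confound scaling) to the test subjects and returns the GP posterior mean,
#' optionally rounded/clamped for bounded integer targets.
#'
#' @param object A [train_strategy()] result.
#' @param new_data A [confound_dataset()] (confounds required for
#'   `images_confounds` and for `adjusted_images`).
#' @param type `"numeric"` (default) for a plain vector, `"tibble"` for a
#'   tibble with `subject_id`, `y_true`, `y_pred`.
#' @param ... Unused.
#' @return Numeric vector of predictions, or a tibble.
#' @export
predict.deconfound_model <- function(object, new_data, type = c("numeric", "tibble"),
                                     ...) {
  type <- match.arg(type)
  stopifnot(inherits(new_data, "confound_dataset"))
  needs_c <- object$strategy %in% c("adjusted_images", "images_confounds")
  if (needs_c && ncol(new_data$C) == 0)
    abort(sprintf("strategy '%s' needs confounds at prediction time", object$strategy),
          class = "deconfound_input_error")
  G <- new_data$G
  if (object$strategy == "adjusted_images")
    G <- apply_adjustment(G, augment_confounds(new_data$C), object$adjustment)
  Xg <- standardize_features(G, stats = object$standardization)$train
  X <- if (object$strategy == "images_confounds")
    cbind(Xg, apply_confound_scaling(new_data$C, object$confound_scaling))
  else Xg
  pred <- predict(object$gp, X)$mean
  if (!is.null(object$rounding))
    pred <- pmin(pmax(round(pred), object$rounding[1]), object$rounding[2])
  if (type == "tibble")
    tibble(subject_id = new_data$subject_ids, y_true = new_data$y, y_pred = pred)
  else pred
}

#' Extract the primal (per-feature) weight map of a linear-kernel model
#'
#' For strategies whose kernel is linear in the features, converts the dual
#' GP solution into primal feature weights \eqn{v = X^T \alpha / l^2} (on the
#' standardized feature scale, in original feature order). A positive weight
#' at a feature indicates that predictions increase with that feature, all
#' else held constant. Predictions decompose as
#' `X_star %*% v + b^2 * sum(alpha)` plus, for `images_confounds`, the
#' analogous confound-block contribution.
#'
#' @param model A [train_strategy()] result.
#' @return A tibble with columns `feature` and `weight`, plus attributes
#'   `intercept` (the bias-kernel contribution \eqn{b^2 \sum_i \alpha_i}) and,
#'   when present, `confound_weights`.
#' @export
extract_weight_map <- function(model) {
  gp <- model$gp
  kern <- gp$kernel
  dG <- length(model$feature_names)
  if (model$strategy == "images_confounds") {
    lin <- kern$children[[1]]; ardc <- kern$children[[2]]
    Xg <- gp$X_train[, seq_len(dG), drop = FALSE]
    v <- unname(drop(crossprod(Xg, gp$alpha))) / lin$hyper[["l"]]^2
    intercept <- lin$hyper[["b"]]^2 * sum(gp$alpha)
    Cc <- gp$X_train[, -seq_len(dG), drop = FALSE]
    lard <- ardc$hyper[grep("^l", names(ardc$hyper))]
    cw <- drop(crossprod(Cc, gp$alpha)) / lard^2
    out <- tibble(feature = model$feature_names, weight = v)
    attr(out, "intercept") <- intercept
    attr(out, "confound_weights") <- setNames(cw, model$confound_names)
    return(out)
  }
  if (kern$kind != "linear_bias")
    abort("weight maps require a kernel linear in the features",
          class = "deconfound_unsupported_error")
  v <- unname(drop(crossprod(gp$X_train, gp$alpha))) / kern$hyper[["l"]]^2
  out <- tibble(feature = model$feature_names, weight = v)
  attr(out, "intercept") <- kern$hyper[["b"]]^2 * sum(gp$alpha)
  out
}

#' @rdname tidiers
#' @export
tidy.deconfound_model <- function(x, ...) tidy(x$gp)

#' Broom-style summaries for fitted objects
#'
#' `tidy()` returns a tibble of hyperparameter estimates; `glance()` a
#' one-row model summary (log evidence, noise scale, sample size).
#'
#' @param x A `gp_fit` or `deconfound_model`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
glance.deconfound_model <- function(x, ...) {
  dplyr::mutate(glance(x$gp), strategy = x$strategy, .before = 1)
}
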