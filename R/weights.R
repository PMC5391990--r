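# Density-ratio instance weights: each training subject is weighted by
# P(y_i) / P(y_i | c_i), both densities estimated with small GPs, so that
# weighted empirical risk approximates risk over a population in which the
# target and the confounds are independent.

#' Estimate the marginal density of the target
#'
#' Fits a GP with a bias-only kernel ([kernel_bias()]) and Gaussian
#' likelihood to the targets by evidence maximisation — effectively fitting a
#' normal distribution to the marginal of `y` — and evaluates the posterior
#' predictive density at each training point.
#'
#' @param y Numeric target vector (`n >= 3`).
#' @return A list with `density` (length-`n` vector of \eqn{\hat P(y_i)}) and
#'   `fit` (the underlying [gp_fit][fit_gp]).
#' @export
estimate_target_density <- function(y) {
  y <- as.numeric(y)
  if (length(y) < 3) abort("need at least 3 observations",
                           class = "deconfound_domain_error")
  X <- matrix(numeric(0), length(y), 0)
  fit <- fit_gp(kernel_bias(), X, y)
  list(density = gp_predictive_density(fit, X, y), fit = fit)
}

#' Estimate the conditional density of the target given the confounds
#'
#' Fits a GP with a bias plus linear-ARD-on-confounds kernel
#' (\eqn{k = b^2 + c_i \Lambda_{ARD} c_j^T}) and Gaussian likelihood —
#' effectively learning a linear relationship between confounds and target —
#' and evaluates the posterior predictive density at each `(c_i, y_i)`.
#'
#' @param y Numeric target vector (`n >= 3`).
#' @param C Confound matrix (`n x dC`, `dC >= 1`).
#' @return A list with `density` (\eqn{\hat P(y_i | c_i)}) and `fit`.
#' @export
estimate_conditional_density <- function(y, C) {
  y <- as.numeric(y); C <- as.matrix(C)
  if (length(y) < 3) abort("need at least 3 observations",
                           class = "deconfound_domain_error")
  if (ncol(C) < 1) abort("need at least one confound",
                         class = "deconfound_domain_error")
  kern <- kernel_sum(kernel_bias(), kernel_ard_linear(rep(1, ncol(C))))
  fit <- fit_gp(kern, C, y)
  list(density = gp_predictive_density(fit, C, y), fit = fit)
}

#' Compute density-ratio instance weights
#'
#' For each training subject, the weight \eqn{w_i = \hat P(y_i) /
#' \hat P(y_i | c_i)} down-weights subjects whose target value is typical of
#' their confound group in the biased sample and up-weights atypical ones, so
#' that the weighted sample behaves like one in which target and confound are
#' independent.
#'
#' @inheritParams estimate_conditional_density
#' @param normalize If `TRUE` (default), rescale the weights to mean 1 (keeps
#'   the noise scale comparable with an unweighted model); raw ratios with
#'   `FALSE`.
#' @param clip Optional upper percentile in `(0, 1]`; weights above that
#'   quantile are truncated. Off (`NULL`) by default.
#' @return An object of class `instance_weights`: a list with `w`,
#'   `p_marginal`, `p_conditional`, `marginal_fit`, `conditional_fit`.
#'   `as_tibble()` gives a per-subject table.
#' @examples
#' y <- rnorm(60); C <- matrix(rbinom(60, 1, 0.5), 60, 1)
#' iw <- compute_instance_weights(y, C)
#' summary(as_tibble(iw)$weight)
#' @export
compute_instance_weights <- function(y, C, normalize = TRUE, clip = NULL) {
  m <- estimate_target_density(y)
  cd <- estimate_conditional_density(y, C)
  w <- m$density / cd$density
  bad <- which(!is.finite(w) | w <= 0)
  if (length(bad))
    abort(sprintf("non-finite or non-positive weight at indices: %s",
                  paste(utils::head(bad, 10), collapse = ", ")),
          class = "deconfound_weighting_error")
  if (!is.null(clip)) {
    cap <- stats::quantile(w, clip)
    w <- pmin(w, cap)
  }
  if (normalize) w <- w / mean(w)
  structure(list(w = w, p_marginal = m$density, p_conditional = cd$density,
                 marginal_fit = m$fit, conditional_fit = cd$fit),
            class = "instance_weights")
}

#' @export
print.instance_weights <- function(x, ...) {
  cat(sprintf("<instance_weights> n = %d, range [%.3f, %.3f], max/min ratio %.2f\n",
              length(x$w), min(x$w), max(x$w), max(x$w) / min(x$w)))
  invisible(x)
}

#' @export
as_tibble.instance_weights <- function(x, ...) {
  tibble(subject = seq_along(x$w), p_marginal = x$p_marginal,
         p_conditional = x$p_conditional, weight = x$w)
}

#' Weighted standardized difference balance diagnostic
#'
#' Measures how strongly the target differs between the two levels of a
#' discrete confound, before and after instance weighting:
#' \deqn{\frac{m^{Wtd}_{Y_0} - m^{Wtd}_{Y_1}}
#'            {\sqrt{(s^{2,Wtd}_{Y_0} + s^{2,Wtd}_{Y_1}) / 2}}}
#' with weighted means \eqn{m^{Wtd}_{Y_k} = \sum w_i y_i / \sum w_i} and
#' frequency-weighted unbiased sample variances
#' \eqn{s^{2,Wtd}_{Y_k} = \frac{\sum w_i}{(\sum w_i)^2 - \sum w_i^2}
#' \sum w_i (y_i - m^{Wtd}_{Y_k})^2}. With equal weights this reduces exactly
#' to the usual standardized difference. A decrease in absolute value after
#' weighting indicates a more balanced pseudo-sample.
#'
#' @param y Numeric target vector.
#' @param group Two-level labels (the discrete confound); level order follows
#'   `sort(unique(group))`, the first level playing the role of group 0.
#' @param w Positive weights; default all ones.
#' @return A one-row tibble (class `balance_report`) with columns
#'   `std_diff_unweighted`, `std_diff_weighted`, and the weighted group means
#'   and variances `mean_0`, `mean_1`, `var_0`, `var_1`.
#' @export
weighted_standardized_difference <- function(y, group, w = NULL) {
  y <- as.numeric(y)
  lev <- sort(unique(group))
  if (length(lev) != 2)
    abort(sprintf("group must have exactly two levels (found %d)", length(lev)),
          class = "deconfound_domain_error")
  if (is.null(w)) w <- rep(1, length(y))
  if (any(w <= 0)) abort("weights must be positive", class = "deconfound_domain_error")
  stopifnot(length(group) == length(y), length(w) == length(y))
  wstats <- function(yk, wk) {
    sw <- sum(wk)
    m <- sum(wk * yk) / sw
    v <- sw / (sw^2 - sum(wk^2)) * sum(wk * (yk - m)^2)
    c(mean = m, var = v)
  }
  sd_of <- function(wk) {
    s0 <- wstats(y[group == lev[1]], wk[group == lev[1]])
    s1 <- wstats(y[group == lev[2]], wk[group == lev[2]])
    list(d = (s0["mean"] - s1["mean"]) / sqrt((s0["var"] + s1["var"]) / 2),
         s0 = s0, s1 = s1)
  }
  unw <- sd_of(rep(1, length(y)))
  wtd <- sd_of(w)
  out <- tibble(std_diff_unweighted = unname(unw$d),
                std_diff_weighted = unname(wtd$d),
                mean_0 = unname(wtd$s0["mean"]), mean_1 = unname(wtd$s1["mean"]),
                var_0 = unname(wtd$s0["var"]), var_1 = unname(wtd$s1["var"]))
  class(out) <- c("balance_report", class(out))
  out
}
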