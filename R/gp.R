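# Gaussian-process regression with homoscedastic and heteroscedastic
# (instance-weighted) Gaussian likelihoods. The posterior predictive mean is
# exactly (weighted) kernel ridge regression; hyperparameters are estimated
# by maximising the log marginal likelihood with analytic gradients in
# log-hyperparameter space.

# Cholesky with adaptive jitter: start at 1e-10 * mean diagonal, double at
# most `max_tries` times before giving up.
chol_jitter <- function(A, max_tries = 10) {
  L <- tryCatch(chol(A), error = function(e) NULL)
  if (!is.null(L)) return(list(L = L, jitter = 0))
  jit <- 1e-10 * mean(diag(A))
  if (jit <= 0) jit <- 1e-12
  for (i in seq_len(max_tries)) {
    L <- tryCatch(chol(A + diag(jit, nrow(A))), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = jit))
    jit <- jit * 2
  }
  abort("covariance matrix is not positive definite even after jitter",
        class = "deconfound_numerical_error")
}

# precompute the input-dependent pieces of linear-family kernels so the
# optimiser does not redo O(n^2 d) cross-products at every iteration
kernel_cache <- function(spec, X) {
  X <- as.matrix(X)
  switch(spec$kind,
    linear_bias = list(S = tcrossprod(sel_cols(spec, X))),
    ard_linear = {
      A <- sel_cols(spec, X)
      list(P = lapply(seq_len(ncol(A)), function(m) tcrossprod(A[, m])))
    },
    bias_only = list(),
    ard_se = list(A = sel_cols(spec, X)),
    sum = list(children = lapply(spec$children, function(ch) kernel_cache(ch, X))),
    abort(sprintf("unknown kernel kind '%s'", spec$kind))
  )
}

cache_gram <- function(spec, cache, n) {
  switch(spec$kind,
    linear_bias = cache$S / spec$hyper[["l"]]^2 + spec$hyper[["b"]]^2,
    ard_linear = {
      l <- spec$hyper[grep("^l", names(spec$hyper))]
      K <- matrix(0, n, n)
      for (m in seq_along(l)) K <- K + cache$P[[m]] / l[m]^2
      K
    },
    bias_only = matrix(spec$hyper[["b"]]^2, n, n),
    ard_se = gram(spec, cache$A),
    sum = Reduce(`+`, Map(cache_gram, spec$children, cache$children, n = n))
  )
}

cache_grads <- function(spec, cache, n) {
  switch(spec$kind,
    linear_bias = list(l = -2 * cache$S / spec$hyper[["l"]]^2,
                       b = matrix(2 * spec$hyper[["b"]]^2, n, n)),
    ard_linear = {
      l <- spec$hyper[grep("^l", names(spec$hyper))]
      setNames(lapply(seq_along(l), function(m) -2 * cache$P[[m]] / l[m]^2), names(l))
    },
    bias_only = list(b = matrix(2 * spec$hyper[["b"]]^2, n, n)),
    ard_se = gram_gradients(spec, cache$A),
    sum = {
      out <- list()
      for (i in seq_along(spec$children)) {
        g <- cache_grads(spec$children[[i]], cache$children[[i]], n)
        names(g) <- paste0("k", i, ".", names(g))
        out <- c(out, g)
      }
      out
    }
  )
}

#' Log marginal likelihood of a Gaussian-process regression model
#'
#' Evaluates \eqn{\log Z = -\tfrac12 y^T A^{-1} y - \tfrac12 \log|A| -
#' \tfrac{n}{2}\log 2\pi} with \eqn{A = K(\theta) + \sigma^2 W}, where `W` is
#' the identity for the homoscedastic Gaussian likelihood or
#' `diag(1 / w_i)` for the heteroscedastic (instance-weighted) likelihood in
#' which point `i` has noise variance \eqn{\sigma^2 / w_i}.
#'
#' @param kernel A [kernel_spec][kernels].
#' @param X Training input matrix (`n x d`).
#' @param y Numeric target vector, length `n`.
#' @param sigma Positive noise scale.
#' @param weights Optional positive instance weights `w_i` (length `n`).
#' @return The scalar log evidence.
#' @export
log_marginal_likelihood <- function(kernel, X, y, sigma, weights = NULL) {
  X <- as.matrix(X); n <- length(y)
  if (!is.null(weights)) {
    stopifnot(length(weights) == n)
    if (any(weights <= 0)) abort("weights must be positive",
                                 class = "deconfound_domain_error")
  }
  K <- gram(kernel, X)
  wdiag <- if (is.null(weights)) rep(1, n) else 1 / weights
  A <- K + diag(sigma^2 * wdiag, n)
  cj <- chol_jitter(A)
  alpha <- backsolve(cj$L, forwardsolve(t(cj$L), y))
  -0.5 * sum(y * alpha) - sum(log(diag(cj$L))) - n / 2 * log(2 * pi)
}

# objective + gradient in psi = c(log theta, log sigma); returns -logZ
gp_objective <- function(psi, spec, cache, y, wdiag, grad = TRUE) {
  n <- length(y)
  np <- length(kernel_params(spec))
  spec <- kernel_set_params(spec, exp(psi[seq_len(np)]))
  sigma <- exp(psi[np + 1])
  K <- cache_gram(spec, cache, n)
  A <- K + diag(sigma^2 * wdiag, n)
  cj <- chol_jitter(A)
  alpha <- backsolve(cj$L, forwardsolve(t(cj$L), y))
  logZ <- -0.5 * sum(y * alpha) - sum(log(diag(cj$L))) - n / 2 * log(2 * pi)
  out <- list(value = -logZ)
  if (grad) {
    Ainv <- chol2inv(cj$L)
    M <- tcrossprod(alpha) - Ainv      # dlogZ/dpsi = 0.5 * sum(M * dA/dpsi)
    dK <- cache_grads(spec, cache, n)
    g <- vapply(dK, function(D) 0.5 * sum(M * D), numeric(1))
    g_sigma <- 0.5 * sum(diag(M) * (2 * sigma^2 * wdiag))
    out$grad <- -c(g, g_sigma)
  }
  out
}

# analytic gradient of logZ wrt (log theta, log sigma); exposed for tests
gp_evidence_gradient <- function(kernel, X, y, sigma, weights = NULL) {
  n <- length(y)
  wdiag <- if (is.null(weights)) rep(1, n) else 1 / weights
  cache <- kernel_cache(kernel, as.matrix(X))
  psi <- c(log(kernel_params(kernel)), log(sigma))
  -gp_objective(psi, kernel, cache, y, wdiag)$grad
}

# data-scale initial values for (theta, sigma), per kernel structure
gp_init <- function(spec, X, y) {
  guard <- function(v) ifelse(is.finite(v) & v > 0, v, 1)
  init1 <- function(sp) {
    Xs <- sel_cols(sp, X)
    switch(sp$kind,
      linear_bias = c(l = guard(sqrt(mean(rowSums(Xs^2)))), b = guard(sd(y))),
      ard_linear = {
        l <- guard(sqrt(colMeans(Xs^2)))
        setNames(l, paste0("l", seq_along(l)))
      },
      bias_only = c(b = guard(sd(y))),
      ard_se = setNames(rep(1, ncol(Xs)), paste0("l", seq_len(ncol(Xs)))),
      sum = {
        out <- numeric(0)
        for (i in seq_along(sp$children)) {
          p <- init1(sp$children[[i]])
          names(p) <- paste0("k", i, ".", names(p))
          out <- c(out, p)
        }
        out
      })
  }
  c(init1(spec), sigma = guard(sd(y)) / 2)
}

#' Fit a Gaussian-process regression model
#'
#' Estimates kernel hyperparameters and the noise scale by maximising the log
#' marginal likelihood ([log_marginal_likelihood()]) with a quasi-Newton
#' (BFGS) optimiser in log-hyperparameter space, from several deterministic
#' restarts dispersed around data-scale initial values; the best restart is
#' kept. With `weights`, the heteroscedastic Gaussian likelihood is used
#' (point `i` has noise variance \eqn{\sigma^2 / w_i}), making the posterior
#' mean a weighted kernel ridge regression.
#'
#' @inheritParams log_marginal_likelihood
#' @param init Optional named initial values for `(theta, sigma)` on the
#'   natural scale, overriding the data-driven defaults.
#' @param optimize If `FALSE`, skip hyperparameter estimation and condition on
#'   the kernel's current hyperparameters and `sigma` (which must then be
#'   supplied).
#' @param n_restarts Number of optimiser restarts (deterministic log-space
#'   offsets `0, +1, -1, ...` applied to the initial values).
#' @param maxit Maximum BFGS iterations per restart.
#' @return An object of class `gp_fit` with elements `kernel`, `sigma`,
#'   `X_train`, `y_train`, `weights`, `alpha` (the solve coefficients
#'   \eqn{(K + \sigma^2 W)^{-1} y}), `L` (Cholesky factor), `log_evidence`
#'   and a `restarts` tibble.
#' @seealso [predict.gp_fit()], [tidy.gp_fit()], [glance.gp_fit()]
#' @examples
#' X <- matrix(rnorm(40), 20, 2)
#' y <- X[, 1] + rnorm(20, sd = 0.3)
#' fit <- fit_gp(kernel_linear_bias(), X, y)
#' glance(fit)
#' @export
fit_gp <- function(kernel, X, y, weights = NULL, sigma = NULL, init = NULL,
                   optimize = TRUE, n_restarts = 3, maxit = 200) {
  X <- as.matrix(X); y <- as.numeric(y); n <- length(y)
  if (nrow(X) != n) abort("X and y lengths differ", class = "deconfound_shape_error")
  if (optimize && n < 2) abort("need at least 2 observations to fit",
                               class = "deconfound_domain_error")
  if (!all(is.finite(X)) || !all(is.finite(y)))
    abort("non-finite inputs", class = "deconfound_validation_error")
  if (!is.null(weights)) {
    stopifnot(length(weights) == n)
    if (any(!is.finite(weights) | weights <= 0))
      abort("weights must be positive and finite", class = "deconfound_domain_error")
  }
  wdiag <- if (is.null(weights)) rep(1, n) else 1 / weights
  cache <- kernel_cache(kernel, X)
  restarts <- NULL

  if (optimize) {
    th0 <- gp_init(kernel, X, y)
    if (!is.null(init)) th0[names(init)] <- init
    np <- length(th0) - 1L
    offsets <- c(0, 1, -1, 0.5, -0.5)[seq_len(n_restarts)]
    best <- NULL
    rows <- list()
    for (r in seq_along(offsets)) {
      psi0 <- log(th0) + offsets[r]
      res <- tryCatch(
        optim(psi0,
              fn = function(p) gp_objective(p, kernel, cache, y, wdiag, grad = FALSE)$value,
              gr = function(p) gp_objective(p, kernel, cache, y, wdiag)$grad,
              method = "BFGS", control = list(maxit = maxit, reltol = 1e-10)),
        error = function(e) e)
      if (inherits(res, "error")) {
        rows[[r]] <- tibble(restart = r, init_log_evidence = NA_real_,
                            log_evidence = NA_real_, converged = FALSE,
                            message = conditionMessage(res))
        next
      }
      init_val <- -gp_objective(psi0, kernel, cache, y, wdiag, grad = FALSE)$value
      rows[[r]] <- tibble(restart = r, init_log_evidence = init_val,
                          log_evidence = -res$value,
                          converged = res$convergence == 0, message = "")
      if (is.null(best) || res$value < best$value) best <- res
    }
    restarts <- dplyr::bind_rows(rows)
    if (is.null(best))
      abort(paste("all optimiser restarts failed:",
                  paste(unique(restarts$message), collapse = "; ")),
            class = "deconfound_fit_error")
    kernel <- kernel_set_params(kernel, exp(best$par[seq_len(np)]))
    sigma <- exp(best$par[np + 1])
  } else {
    if (is.null(sigma)) abort("sigma must be supplied when optimize = FALSE")
  }

  K <- gram(kernel, X)
  A <- K + diag(sigma^2 * wdiag, n)
  cj <- chol_jitter(A)
  alpha <- backsolve(cj$L, forwardsolve(t(cj$L), y))
  logZ <- -0.5 * sum(y * alpha) - sum(log(diag(cj$L))) - n / 2 * log(2 * pi)
  structure(list(kernel = kernel, sigma = sigma, X_train = X, y_train = y,
                 weights = weights, alpha = alpha, L = cj$L, jitter = cj$jitter,
                 log_evidence = logZ, n = n, restarts = restarts),
            class = "gp_fit")
}

#' A Gaussian-process prior (zero training points)
#'
#' Builds an empty `gp_fit` whose predictions are the prior predictive:
#' mean 0 and variance `k(x*, x*) + sigma^2`.
#'
#' @inheritParams log_marginal_likelihood
#' @param d Input dimensionality.
#' @return A `gp_fit` with `n = 0`.
#' @export
gp_prior <- function(kernel, sigma, d) {
  structure(list(kernel = kernel, sigma = sigma,
                 X_train = matrix(numeric(0), 0, d), y_train = numeric(0),
                 weights = NULL, alpha = numeric(0), L = matrix(numeric(0), 0, 0),
                 jitter = 0, log_evidence = 0, n = 0L, restarts = NULL),
            class = "gp_fit")
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf("<gp_fit> n = %d, sigma = %.4g, log evidence = %.4f%s\n",
              x$n, x$sigma, x$log_evidence,
              if (!is.null(x$weights)) " (heteroscedastic likelihood)" else ""))
  print(x$kernel)
  invisible(x)
}

#' Posterior predictive distribution at new inputs
#'
#' Computes the closed-form posterior predictive mean
#' \eqn{\bar y_* = k_* (K + \sigma^2 W)^{-1} y} (identical to the (weighted)
#' kernel ridge regression prediction) and variance
#' \eqn{k(x_*, x_*) - k_* (K + \sigma^2 W)^{-1} k_*^T + \sigma^2}.
#'
#' @param object A [fit_gp()] result.
#' @param X_star Matrix of test inputs (`m x d`).
#' @param ... Unused.
#' @return A tibble with columns `mean` and `variance` (one row per test
#'   input).
#' @export
predict.gp_fit <- function(object, X_star, ...) {
  X_star <- as.matrix(X_star)
  if (ncol(X_star) != ncol(object$X_train))
    abort(sprintf("test inputs have %d columns; training had %d",
                  ncol(X_star), ncol(object$X_train)),
          class = "deconfound_shape_error")
  kss <- diag(gram(object$kernel, X_star))
  if (object$n == 0)
    return(tibble(mean = rep(0, nrow(X_star)), variance = kss + object$sigma^2))
  ks <- gram(object$kernel, X_star, object$X_train)   # m x n
  mean <- drop(ks %*% object$alpha)
  V <- forwardsolve(t(object$L), t(ks))               # n x m
  variance <- pmax(kss - colSums(V^2), 0) + object$sigma^2
  tibble(mean = mean, variance = variance)
}

# Gaussian posterior predictive density evaluated at observed targets
gp_predictive_density <- function(fit, X, y) {
  p <- predict(fit, X)
  dnorm(y, mean = p$mean, sd = sqrt(p$variance))
}

#' @rdname tidiers
#' @export
tidy.gp_fit <- function(x, ...) {
  th <- kernel_params(x$kernel)
  tibble(term = c(names(th), "sigma"), estimate = c(unname(th), x$sigma))
}

#' @rdname tidiers
#' @export
glance.gp_fit <- function(x, ...) {
  tibble(logLik = x$log_evidence, sigma = x$sigma, nobs = x$n,
         n_hyper = length(kernel_params(x$kernel)) + 1L,
         weighted = !is.null(x$weights))
}
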