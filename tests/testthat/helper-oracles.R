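# Independent oracles used across the suite. These deliberately avoid the
# package's Cholesky/caching code paths: plain solve()/determinant() dense
# linear algebra, per-feature lm() fits, and closed-form normal densities.

# dense GP oracle: posterior mean/variance and log evidence via solve()
oracle_gp <- function(X, y, X_star, l, b, sigma, w = NULL) {
  n <- length(y)
  K <- tcrossprod(X) / l^2 + b^2
  W <- if (is.null(w)) diag(n) else diag(1 / w, n)
  A <- K + sigma^2 * W
  ks <- tcrossprod(X_star, X) / l^2 + b^2
  kss <- diag(tcrossprod(X_star) / l^2 + b^2)
  list(mean = drop(ks %*% solve(A, y)),
       variance = kss - diag(ks %*% solve(A, t(ks))) + sigma^2,
       log_evidence = -0.5 * drop(crossprod(y, solve(A, y))) -
         0.5 * as.numeric(determinant(A, logarithm = TRUE)$modulus) -
         n / 2 * log(2 * pi))
}

# primal (feature-space) weighted ridge oracle for the linear-plus-bias
# kernel: phi(x) = [x / l, b], beta = (Phi' W Phi + sigma^2 I)^-1 Phi' W y
oracle_primal_ridge <- function(X, y, X_star, l, b, sigma, w = NULL) {
  if (is.null(w)) w <- rep(1, length(y))
  Phi <- cbind(X / l, b)
  Phis <- cbind(X_star / l, b)
  M <- crossprod(Phi, Phi * w) + diag(sigma^2, ncol(Phi))
  drop(Phis %*% solve(M, crossprod(Phi, w * y)))
}

# central finite differences of the log evidence in log-hyperparameter space
oracle_fd_gradient <- function(make_kernel, theta, X, y, w = NULL, h = 1e-5) {
  f <- function(th) {
    np <- length(th) - 1
    log_marginal_likelihood(make_kernel(th[seq_len(np)]), X, y, th[np + 1],
                            weights = w)
  }
  vapply(seq_along(theta), function(i) {
    up <- theta; up[i] <- up[i] * exp(h)
    dn <- theta; dn[i] <- dn[i] * exp(-h)
    (f(up) - f(dn)) / (2 * h)
  }, numeric(1))
}

# per-feature least-squares oracle via lm()
oracle_ols_residuals <- function(G, C) {
  sapply(seq_len(ncol(G)), function(j) stats::residuals(stats::lm(G[, j] ~ C)))
}

oracle_ols_beta <- function(G, C) {
  sapply(seq_len(ncol(G)), function(j) unname(stats::coef(stats::lm(G[, j] ~ C))))
}

# classical (unweighted) standardized difference
oracle_std_diff <- function(y, g) {
  lev <- sort(unique(g))
  (mean(y[g == lev[1]]) - mean(y[g == lev[2]])) /
    sqrt((var(y[g == lev[1]]) + var(y[g == lev[2]])) / 2)
}

# small random regression fixture
make_fixture <- function(n, d, seed, sd_noise = 0.5) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  beta <- rnorm(d)
  y <- drop(X %*% beta) / sqrt(d) + rnorm(n, sd = sd_noise)
  list(X = X, y = y)
}

# a two-level-confounded dataset whose target depends on the confound
# (conditional-null generator when signal = 0: y depends on c, G depends on
# c, and y is independent of G given c)
make_conditional_null <- function(n, d, beta_c = 0.8, conf_effect = 1, seed = 1) {
  set.seed(seed)
  c_raw <- rbinom(n, 1, 0.5)
  if (length(unique(c_raw)) < 2) c_raw[1] <- 1 - c_raw[1]
  ctil <- 2 * c_raw - 1
  y <- beta_c * ctil + rnorm(n)
  dload <- conf_effect * sample(c(-1, 1), d, replace = TRUE)
  G <- tcrossprod(ctil, dload) + matrix(rnorm(n * d), n, d)
  confound_dataset(G = G, y = y, C = matrix(c_raw, n, 1))
}
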