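test_that("adjustment equals per-feature OLS and residuals are orthogonal", {
  set.seed(4)
  n <- 4
  C <- matrix(c(0, 1, 1, 0), n, 1)
  G <- matrix(rnorm(n * 2), n, 2)
  Ch <- augment_confounds(C)
  model <- fit_adjustment(G, Ch)
  expect_equal(unname(model$beta), oracle_ols_beta(G, C), tolerance = 1e-10)
  GA <- apply_adjustment(G, Ch, model)
  expect_equal(unname(GA), unname(oracle_ols_residuals(G, C)), tolerance = 1e-10)
  expect_lt(max(abs(crossprod(Ch, GA))), 1e-8)

  # subset = all rows is the full-sample formula
  m2 <- fit_adjustment(G, Ch, subset = 1:n)
  expect_equal(m2$beta, model$beta)

  # G fully explained by the confounds adjusts to zero
  B <- matrix(rnorm(4), 2, 2)
  Gex <- Ch %*% B
  expect_lt(max(abs(adjust_features(Gex, C))), 1e-10)

  # projector idempotence
  GA2 <- adjust_features(GA, C)
  expect_equal(GA2, GA, tolerance = 1e-10)

  # rank-deficient augmented confounds
  Cbad <- cbind(C, 2 * C)
  expect_error(fit_adjustment(G, augment_confounds(Cbad)),
               class = "deconfound_singularity_error")

  # rows outside the fitting subset need not be orthogonal
  m3 <- fit_adjustment(G, Ch, subset = 1:3)
  GA3 <- apply_adjustment(G, Ch, m3)
  expect_lt(max(abs(crossprod(Ch[1:3, , drop = FALSE], GA3[1:3, , drop = FALSE]))), 1e-8)
})

test_that("the marginal target density behaves like a fitted normal", {
  set.seed(8)
  y <- rnorm(500)
  est <- estimate_target_density(y)
  rel <- abs(est$density - dnorm(y)) / dnorm(y)
  expect_gte(mean(rel < 0.15), 0.95)

  # input-independent kernel: identical y values get identical densities
  y2 <- c(1.3, 1.3, rnorm(20))
  e2 <- estimate_target_density(y2)
  expect_equal(e2$density[1], e2$density[2])

  # density integrates to ~1 over a wide grid
  grid <- seq(min(y) - 5 * sd(y), max(y) + 5 * sd(y), length.out = 2000)
  p <- predict(est$fit, matrix(numeric(0), length(grid), 0))
  dens <- dnorm(grid, p$mean, sqrt(p$variance))
  expect_equal(sum(dens) * diff(grid[1:2]), 1, tolerance = 1e-3)

  expect_error(estimate_target_density(c(1, 2)), class = "deconfound_domain_error")
})

test_that("the conditional density tracks the confound groups", {
  # independence limit: conditional ~ marginal
  set.seed(14)
  n <- 400
  y <- rnorm(n); C <- matrix(rbinom(n, 1, 0.5), n, 1)
  m <- estimate_target_density(y)$density
  cd <- estimate_conditional_density(y, C)$density
  ratio <- m / cd
  expect_gte(mean(ratio > 0.8 & ratio < 1.25), 0.90)

  # two-group construction: conditional density beats marginal near group means
  set.seed(15)
  cg <- rbinom(n, 1, 0.5)
  yg <- 2 * cg + rnorm(n, sd = 0.1)
  cdg <- estimate_conditional_density(yg, matrix(cg, n, 1))$density
  mg <- estimate_target_density(yg)$density
  near <- abs(yg - 2 * cg) < 0.1
  expect_true(all(cdg[near] > 2 * mg[near]))

  # determinism: identical (y, c) rows get identical densities
  expect_equal(cdg[which(cg == 1)[1]],
               estimate_conditional_density(yg, matrix(cg, n, 1))$density[which(cg == 1)[1]])
})

test_that("instance weights are the density ratio and upweight atypical subjects", {
  set.seed(16)
  n <- 300
  cg <- rbinom(n, 1, 0.5)
  delta <- 1.2
  y <- delta * (2 * cg - 1) + rnorm(n)
  iw <- compute_instance_weights(y, matrix(cg, n, 1), normalize = FALSE)
  expect_true(all(iw$w > 0))
  expect_equal(iw$w, iw$p_marginal / iw$p_conditional)

  # closed-form pdf-ratio oracle: N(y; 0, sd_tot) / N(y; +-delta, 1)
  sd_tot <- sqrt(1 + delta^2)
  oracle <- dnorm(y, 0, sd_tot) / dnorm(y, delta * (2 * cg - 1), 1)
  expect_gte(cor(iw$w, oracle, method = "spearman"), 0.9)
  # atypical-for-their-group subjects get the largest weights
  expect_gt(mean(iw$w[y * (2 * cg - 1) < -1]), mean(iw$w[abs(y - delta * (2 * cg - 1)) < 0.5]))

  # independence: weights ~ 1
  set.seed(17)
  y0 <- rnorm(n)
  iw0 <- compute_instance_weights(y0, matrix(cg, n, 1), normalize = FALSE)
  expect_gte(mean(iw0$w > 0.8 & iw0$w < 1.25), 0.9)

  # normalisation to mean 1 by default
  iwn <- compute_instance_weights(y, matrix(cg, n, 1))
  expect_equal(mean(iwn$w), 1, tolerance = 1e-12)
})

test_that("weighted standardized difference matches its formula and reductions", {
  # hand fixture via the printed formula
  y <- c(1, 2, 3, 4); g <- c(0, 0, 1, 1); w <- rep(1, 4)
  rep_ <- weighted_standardized_difference(y, g, w)
  m0 <- 1.5; m1 <- 3.5; v0 <- 0.5; v1 <- 0.5
  expect_equal(rep_$std_diff_weighted, (m0 - m1) / sqrt((v0 + v1) / 2))
  expect_equal(rep_$mean_0, m0); expect_equal(rep_$var_1, v1)

  # equal weights reduce exactly to the classical standardized difference
  set.seed(18)
  y2 <- rnorm(30); g2 <- rep(0:1, 15)
  r2 <- weighted_standardized_difference(y2, g2, rep(2.5, 30))
  expect_identical(r2$std_diff_weighted, r2$std_diff_unweighted)
  expect_equal(r2$std_diff_unweighted, oracle_std_diff(y2, g2), tolerance = 1e-12)

  # identical weighted group means -> zero
  r3 <- weighted_standardized_difference(c(1, 3, 1, 3), c(0, 0, 1, 1))
  expect_equal(r3$std_diff_weighted, 0)

  # scale equivariance: y -> s * y leaves it unchanged
  set.seed(19)
  w4 <- runif(30, 0.5, 2)
  r4a <- weighted_standardized_difference(y2, g2, w4)
  r4b <- weighted_standardized_difference(5 * y2, g2, w4)
  expect_equal(r4a$std_diff_weighted, r4b$std_diff_weighted, tolerance = 1e-12)

  expect_error(weighted_standardized_difference(y2, rep(1, 30)),
               class = "deconfound_domain_error")
})

test_that("instance weighting improves balance of biased samples", {
  # scaled-down version of the balance-bar comparison; the full 50-replicate
  # run is an acceptance criterion
  improved <- 0L; total <- 0L
  for (r in 1:10) {
    pop <- simulate_population(n = 300, d_features = 2, seed = 700 + r)
    draw <- draw_biased_sample(pop$y, pop$C[, 1], size = 100, lambda = 2,
                               seed = 800 + r)
    ys <- pop$y[draw$indices]; cs <- pop$C[draw$indices, 1]
    sd0 <- oracle_std_diff(ys, cs)
    if (abs(sd0) < 0.4) next
    total <- total + 1L
    iw <- compute_instance_weights(ys, matrix(cs, length(cs), 1))
    bal <- weighted_standardized_difference(ys, cs, iw$w)
    if (abs(bal$std_diff_weighted) < abs(bal$std_diff_unweighted))
      improved <- improved + 1L
  }
  expect_gte(total, 5L)
  expect_gte(improved / total, 0.8)
})
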