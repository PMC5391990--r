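test_that("half splits partition the pool deterministically per seed", {
  sp <- half_split(8, seed = 1)
  expect_length(sp$f1, 4); expect_length(sp$f2, 4)
  expect_length(intersect(sp$f1, sp$f2), 0)
  expect_setequal(c(sp$f1, sp$f2), 1:8)
  expect_identical(half_split(8, seed = 1), sp)
  # odd pools differ by one
  spo <- half_split(9, seed = 2)
  expect_equal(abs(length(spo$f1) - length(spo$f2)), 1)
  # different seeds give different splits essentially always
  splits <- vapply(1:20, function(s) paste(half_split(12, seed = s)$f1,
                                           collapse = ","), character(1))
  expect_gt(length(unique(splits)), 15)
})

test_that("the biased sampler plants and the unbiased sampler avoids association", {
  pop <- simulate_population(n = 200, d_features = 2, seed = 61)
  y <- pop$y; cf <- pop$C[, 1]

  # lambda = 0 with the non-significance acceptance rule: achieved p-values
  # follow the truncated-uniform oracle (uniform on [0.05, 1]); each draw uses
  # a fresh null pool so the p-values are independent
  ps <- vapply(1:200, function(r) {
    popr <- simulate_population(n = 100, d_features = 1, seed = 6500 + r)
    draw_biased_sample(popr$y, popr$C[, 1], size = 40, lambda = 0,
                       biased = FALSE, seed = 6000 + r)$p_value
  }, numeric(1))
  expect_true(all(ps >= 0.05))
  ks <- stats::ks.test((ps - 0.05) / 0.95, "punif")
  expect_gt(ks$p.value, 0.01)

  # lambda = 1.5: acceptance reached within 50 tries in >= 95% of seeds
  tries <- vapply(1:40, function(r)
    draw_biased_sample(y, cf, size = 80, lambda = 1.5, seed = 7000 + r)$tries,
    numeric(1))
  expect_gte(mean(tries <= 50), 0.95)

  d <- draw_biased_sample(y, cf, size = 80, lambda = 1.5, seed = 71)
  expect_lt(d$p_value, 0.05)
  expect_false(anyDuplicated(d$indices) > 0)
  expect_true(all(d$indices %in% seq_along(y)))

  expect_error(draw_biased_sample(y, rep(1, 200), size = 50),
               class = "deconfound_domain_error")
  expect_error(draw_biased_sample(y, cf, size = 200),
               class = "deconfound_domain_error")
})

test_that("mse and the target partition follow their definitions", {
  expect_equal(mse(c(1, 2), c(1, 2)), 0)
  expect_equal(mse(c(0, 0, 0), c(2, 2, 2)), 4)     # constant offset delta^2
  expect_equal(mse(c(1, 2, 3), c(2, 2, 2)), 2 / 3)
  expect_error(mse(1:3, 1:4), class = "deconfound_shape_error")

  p <- partition_by_target(1:10)
  expect_equal(attr(p, "threshold"), 5.5)
  expect_equal(sum(p == 1), 5)
  # ties at the threshold fall in the low subset (y <= threshold)
  p2 <- partition_by_target(c(26, 28, 28, 30), threshold = 28)
  expect_equal(as.integer(p2), c(1L, 1L, 1L, 2L))
  expect_error(partition_by_target(rep(3, 4)), class = "deconfound_domain_error")
  expect_error(partition_by_target(c(1, 2, 3), threshold = 10),
               class = "deconfound_domain_error")
})

test_that("balanced and signed difference errors match hand arithmetic", {
  # 8-subject fixture: subsets by target, two groups
  y    <- c(1, 2, 3, 4, 10, 11, 12, 13)
  yhat <- c(0, 2, 3, 6, 10, 13, 12, 12)
  g    <- c(0, 1, 0, 1, 0, 1, 0, 1)
  part <- partition_by_target(y, threshold = 5)
  # subset 1: errors g0 = (1, 0), g1 = (0, 4); subset 2: g0 = (0, 0), g1 = (4, 1)
  b <- balanced_mse(y, yhat, g, part)
  expect_equal(b$per_subset$value, c((0.5 + 2) / 2, (0 + 2.5) / 2))
  expect_equal(b$overall, 0.5 * 1.25 + 0.5 * 1.25)
  s <- signed_group_difference(y, yhat, g, part)
  expect_equal(s$per_subset$signed, c(0.5 - 2, 0 - 2.5))
  expect_equal(s$overall, 0.5 * 1.5 + 0.5 * 2.5)

  # equal group MSEs everywhere: balanced == plain MSE, signed == 0
  y2 <- c(1, 1, 9, 9); yhat2 <- c(2, 2, 8, 8); g2 <- c(0, 1, 0, 1)
  p2 <- partition_by_target(y2, threshold = 5)
  expect_equal(balanced_mse(y2, yhat2, g2, p2)$overall, mse(y2, yhat2))
  expect_equal(signed_group_difference(y2, yhat2, g2, p2)$per_subset$signed, c(0, 0))

  # single-subset balanced error is the plain half-sum regardless of sizes
  y3 <- c(0, 0, 0, 5); yhat3 <- c(2, 2, 2, 5); g3 <- c(0, 0, 0, 1)
  p3 <- structure(rep(1L, 4), threshold = 99)
  expect_equal(balanced_mse(y3, yhat3, g3, p3)$per_subset$value, (4 + 0) / 2)

  # swapping group labels flips signs, leaves the summary unchanged
  s_swap <- signed_group_difference(y, yhat, 1 - g, part)
  expect_equal(s_swap$per_subset$signed, -s$per_subset$signed)
  expect_equal(s_swap$overall, s$overall)

  # empty cell is an error
  expect_error(balanced_mse(y3, yhat3, g3, partition_by_target(y3, threshold = 2)),
               class = "deconfound_metric_error")
})

test_that("the protocol is reproducible and its bookkeeping is consistent", {
  pop <- simulate_population(n = 60, d_features = 8, seed = 63)
  args <- list(pool = pop, strategies = c("images_only", "images_only"),
               J = 1, sample_size = 20, seed = 17, n_restarts = 1)
  pr1 <- do.call(run_protocol, args)
  pr2 <- do.call(run_protocol, args)
  expect_identical(pr1$metrics, pr2$metrics)

  # duplicated strategy gives identical rows
  m <- pr1$metrics
  expect_equal(m$mse[m$fold == 1][1], m$mse[m$fold == 1][2])

  # averaged MSE equals recomputation from the per-subject prediction table
  recomputed <- pr1$predictions |>
    dplyr::group_by(.data$strategy, .data$fold, .data$j) |>
    dplyr::summarise(mse = mean((.data$y_true - .data$y_pred)^2), .groups = "drop")
  merged <- dplyr::inner_join(recomputed, pr1$metrics,
                              by = c("strategy", "fold", "j"))
  expect_equal(merged$mse.x, merged$mse.y, tolerance = 1e-12)
  expect_equal(pr1$summary$mse[1], mean(m$mse[!duplicated(paste(m$fold, m$j))]),
               tolerance = 1e-12)

  # pool-level independence check triggers on an associated pool
  bad <- make_conditional_null(60, 5, beta_c = 1.5, seed = 9)
  expect_error(run_protocol(bad, "images_only", J = 1, sample_size = 20,
                            check_pool = TRUE, seed = 1),
               class = "deconfound_domain_error")
})

test_that("restricted permutations preserve level multisets and count the identity", {
  set.seed(65)
  y <- rnorm(30); g <- rep(0:1, 15)
  yp <- deconfound:::permute_within_levels(y, g)
  expect_setequal(yp[g == 0], y[g == 0])
  expect_setequal(yp[g == 1], y[g == 1])

  pop <- make_conditional_null(40, 6, beta_c = 1, seed = 10)
  res <- restricted_permutation_test(pop, "images_only", J = 1, sample_size = 14,
                                     lambda = 0.5, n_perm = 20, seed = 3,
                                     fixed_hyperparameters = TRUE,
                                     optimize = FALSE, sigma = 1)
  expect_gte(min(res$p_values), 1 / 20)
  expect_lte(max(res$p_values), 1)
  expect_equal(nrow(res$null), 20)
})
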