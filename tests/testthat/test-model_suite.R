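make_pop <- function(n = 80, d = 12, seed = 1, ...)
  simulate_population(n = n, d_features = d, seed = seed, ...)

test_that("strategy reduction identities hold", {
  pop <- make_pop(seed = 41)
  tr <- pop[1:40]; te <- pop[41:80]

  # forced uniform weights reproduce images_only exactly
  m_io <- train_strategy(tr, "images_only", n_restarts = 1)
  m_w1 <- train_strategy(tr, "instance_weighted", weights = rep(1, 40),
                         n_restarts = 1)
  expect_identical(predict(m_io, te), predict(m_w1, te))

  # features orthogonal to the confounds: adjustment is (almost) the identity
  pool_C <- rbind(tr$C, te$C)
  pool_G <- rbind(tr$G, te$G)
  G_orth <- pool_G - augment_confounds(pool_C) %*%
    qr.coef(qr(augment_confounds(pool_C)), pool_G)
  tr2 <- confound_dataset(G_orth[1:40, ], tr$y, tr$C)
  te2 <- confound_dataset(G_orth[41:80, ], te$y, te$C)
  m_adj <- train_strategy(tr2, "adjusted_images", test = te2, n_restarts = 1)
  m_io2 <- train_strategy(tr2, "images_only", n_restarts = 1)
  expect_equal(predict(m_adj, te2), predict(m_io2, te2), tolerance = 1e-8)
})

test_that("uninformative confounds leave images_confounds near images_only", {
  pop <- simulate_population(n = 120, d_features = 10, confound_effect = 0,
                             seed = 43)
  tr <- pop[1:60]; te <- pop[61:120]
  m_ic <- train_strategy(tr, "images_confounds", n_restarts = 1)
  m_io <- train_strategy(tr, "images_only", n_restarts = 1)
  resid_sd <- sd(te$y - predict(m_io, te))
  expect_lt(mean(abs(predict(m_ic, te) - predict(m_io, te))), 0.5 * resid_sd)
})

test_that("bounded-score rounding clamps predictions to whole numbers", {
  pop <- make_pop(seed = 44)
  tr <- pop[1:40]; te <- pop[41:80]
  # map the latent target onto a 0-30 score scale for the fixture
  tr$y <- pmin(pmax(round(26 + 3 * tr$y), 0), 30)
  m <- train_strategy(tr, "images_only", rounding = c(0, 30), n_restarts = 1)
  pr <- predict(m, te)
  expect_true(all(pr == round(pr)))
  expect_true(all(pr >= 0 & pr <= 30))
  # the rounding rule itself
  m$rounding <- c(0, 30)
  expect_equal(pmin(pmax(round(c(30.7, 14.49)), 0), 30), c(30, 14))
})

test_that("an interpolating model reproduces its training targets", {
  # full-rank kernel (d > n) so the sigma -> 0 limit interpolates
  pop <- make_pop(n = 30, d = 40, seed = 45)
  m <- train_strategy(pop, "images_only", optimize = FALSE, sigma = 1e-4)
  expect_equal(predict(m, pop), pop$y, tolerance = 1e-3)
})

test_that("weight maps satisfy primal/dual equivalence and null features", {
  pop <- make_pop(n = 50, d = 8, seed = 46)
  # append a constant feature; it standardizes to zero and gets zero weight
  G2 <- cbind(pop$G, const = 7)
  pop2 <- confound_dataset(G2, pop$y, pop$C)
  m <- train_strategy(pop2, "images_only", n_restarts = 1)
  wm <- extract_weight_map(m)
  expect_equal(nrow(wm), 9)
  expect_equal(wm$weight[9], 0)

  te <- make_pop(n = 20, d = 8, seed = 47)
  te2 <- confound_dataset(cbind(te$G, const = 7), te$y, te$C)
  Xs <- standardize_features(te2$G, stats = m$standardization)$train
  manual <- drop(Xs %*% wm$weight) + attr(wm, "intercept")
  expect_equal(manual, predict(m, te2), tolerance = 1e-8)

  # images_confounds decomposes into feature + confound + intercept parts
  mic <- train_strategy(pop, "images_confounds", n_restarts = 1)
  wmc <- extract_weight_map(mic)
  Xs2 <- standardize_features(te$G, stats = mic$standardization)$train
  Cs2 <- deconfound:::apply_confound_scaling(te$C, mic$confound_scaling)
  manual2 <- drop(Xs2 %*% wmc$weight) + attr(wmc, "intercept") +
    drop(Cs2 %*% attr(wmc, "confound_weights"))
  expect_equal(manual2, predict(mic, te), tolerance = 1e-8)
})

test_that("planted sparse signals are recovered with correct signs", {
  hits <- 0L
  for (r in 1:10) {
    pop <- simulate_population(n = 100, d_features = 500, n_signal = 10,
                               signal_strength = 1, confound_effect = 0,
                               seed = 500 + r)
    a <- attr(pop, "signal")
    m <- train_strategy(pop, "images_only", n_restarts = 1)
    wm <- extract_weight_map(m)
    sup <- which(a != 0)
    if (all(sign(wm$weight[sup]) == sign(a[sup]))) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("training is deterministic and invariant to subject order", {
  pop <- make_pop(seed = 48)
  tr <- pop[1:40]; te <- pop[41:80]
  iw <- compute_instance_weights(tr$y, tr$C)
  perm <- c(17, seq_len(40)[-17])
  for (s in c("images_only", "adjusted_images", "images_confounds",
              "instance_weighted")) {
    # determinism of the full (optimised) fit
    m1 <- train_strategy(tr, s, test = if (s == "adjusted_images") te,
                         n_restarts = 1)
    m2 <- train_strategy(tr, s, test = if (s == "adjusted_images") te,
                         n_restarts = 1)
    expect_identical(predict(m1, te), predict(m2, te))
    # subject-order invariance of the predictor at fixed hyperparameters
    # (the optimiser's floating-point path is order sensitive, the model is not)
    w_arg <- if (s == "instance_weighted") iw$w
    f1 <- train_strategy(tr, s, test = if (s == "adjusted_images") te,
                         weights = w_arg, optimize = FALSE, sigma = 0.5)
    f3 <- train_strategy(tr[perm], s, test = if (s == "adjusted_images") te,
                         weights = if (!is.null(w_arg)) w_arg[perm],
                         optimize = FALSE, sigma = 0.5)
    expect_equal(predict(f1, te), predict(f3, te), tolerance = 1e-10)
  }
})

test_that("strategy configuration errors are raised", {
  pop <- make_pop(seed = 49)
  no_c <- confound_dataset(pop$G, pop$y)
  expect_error(train_strategy(no_c, "adjusted_images"),
               class = "deconfound_configuration_error")
  expect_error(train_strategy(pop, "images_only", weights = rep(1, 80)),
               class = "deconfound_configuration_error")
  expect_error(train_strategy(pop, "images_only", rounding = c(30, 0)),
               class = "deconfound_configuration_error")
  m <- train_strategy(pop, "images_confounds", n_restarts = 1)
  expect_error(predict(m, no_c), class = "deconfound_input_error")
  mio <- train_strategy(pop, "images_only", n_restarts = 1)
  expect_s3_class(glance(mio), "tbl_df")
  expect_equal(glance(mio)$strategy, "images_only")
})
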