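test_that("ground-truth coupling honours density and asymmetry", {
  # symmetric blend
  gt0 <- make_ground_truth(6, 20, density = 0.3, asymmetry = 0, seed = 1)
  expect_equal(asymmetry_index(gt0$C_star), 0, tolerance = 1e-12)
  expect_equal(diag(gt0$C_star), rep(0, 6))

  # fully directed draws have a clearly asymmetric coupling (distributional,
  # checked across seeds) and a plausible edge count
  idx <- vapply(1:20, function(s)
    asymmetry_index(make_ground_truth(6, 20, density = 0.2, asymmetry = 1,
                                      seed = s)$C_star), 1)
  expect_gte(median(idx), 0.5)
  counts <- vapply(1:50, function(s)
    sum(make_ground_truth(6, 20, density = 0.2, asymmetry = 1,
                          seed = 100 + s)$C_star != 0), 1L)
  expect_true(all(counts >= 1 & counts <= 15))
  expect_gt(mean(counts >= 2 & counts <= 11), 0.9)

  # magnitudes and dynamics parameters sit in the stated ranges
  gt <- make_ground_truth(5, 15, seed = 3)
  nz <- abs(gt$C_star[gt$C_star != 0])
  expect_true(all(nz >= 0.005 & nz <= 0.2 + 1e-12))
  expect_equal(gt$system$a, rep(-0.02, 5))
  expect_true(all(gt$system$omega >= 2 * pi * 0.01 &
                    gt$system$omega <= 2 * pi * 0.07))
  expect_equal(qr(gt$mixing)$rank, 5L)
})

test_that("generated datasets carry the latent covariance into source space", {
  gt <- make_ground_truth(4, 12, density = 0.3, asymmetry = 0.5, seed = 7,
                          obs_noise_sd = 0)
  ds <- generate_dataset(gt, 1, 5000, seed = 8)
  expect_length(generate_dataset(gt, 0, 500), 0L)
  X <- ds[[1]]$data
  expect_s3_class(ds[[1]], "bold_ts")
  # closed form: cov(X) = W cov(x) W' for the linear mixing W
  lat <- oracle_encode(X, gt)
  pred <- gt$mixing %*% cov(lat) %*% t(gt$mixing)
  err <- norm(cov(X) - pred, "F") / norm(pred, "F")
  expect_lt(err, 0.1)
  # with zero observation noise the oracle encoder inverts the mixing exactly
  expect_equal(lat %*% t(gt$mixing), X, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("different couplings imprint different forward correlations", {
  sims <- lapply(1:5, function(r) {
    g1 <- make_ground_truth(5, 14, density = 0.25, asymmetry = 0.9,
                            seed = 20 + r)
    g2 <- make_ground_truth(5, 14, density = 0.25, asymmetry = 0.9,
                            seed = 40 + r)
    g2$system$omega <- g1$system$omega  # same spectra, different coupling
    d1 <- generate_dataset(g1, 8, 400, seed = 60 + r)
    d2 <- generate_dataset(g2, 8, 400, seed = 80 + r)
    o1 <- average_observables(lapply(d1, oracle_encode, gt = g1), tau = 3)
    o2 <- average_observables(lapply(d2, oracle_encode, gt = g2), tau = 3)
    matrix_similarity(o1$fcf, o2$fcf)
  })
  expect_true(all(unlist(sims) < 0.9))
})

test_that("recovery metrics behave on known cases", {
  set.seed(5)
  C <- matrix(rnorm(36), 6, 6); diag(C) <- 0
  r_id <- recovery_report(C, C)
  expect_equal(r_id$pearson_offdiag, 1)
  expect_equal(r_id$sign_agreement, 1)
  expect_equal(r_id$frobenius_rel_error, 0)

  r_sc <- recovery_report(C, 2 * C)
  expect_equal(r_sc$pearson_offdiag, 1)
  expect_equal(r_sc$frobenius_rel_error, 1)

  # shuffled entries decorrelate
  off <- row(C) != col(C)
  med <- median(abs(vapply(1:20, function(k) {
    set.seed(k)
    Cs <- C
    Cs[off] <- sample(C[off])
    recovery_report(C, Cs)$pearson_offdiag
  }, 1)))
  expect_lt(med, 0.3)

  expect_error(recovery_report(C, matrix(0, 5, 5)), "same shape")
})

test_that("distinct couplings yield classifiable condition fingerprints", {
  # eight conditions differing only in their directed coupling; several
  # group-averaged observable sets per condition, one coupling fit per group
  scfg <- sim_config(dt = 0.1, t_sample = 0.72, n_samples = 100,
                     transient_s = 30)
  per_class <- 10L
  feats <- list(); labels <- integer(0)
  for (cond in 1:8) {
    gt <- make_ground_truth(4, 10, density = 0.4, asymmetry = 0.9,
                            seed = 300 + cond)
    ds <- generate_dataset(gt, 30, 240, seed = 400 + cond)
    lat <- lapply(ds, oracle_encode, gt = gt)
    gfc <- group_average(lapply(lat, compute_fc), 3, seed = cond)
    gfcf <- group_average(lapply(lat, compute_fcf, tau = 3), 3, seed = cond)
    ens <- fit_ensemble(gfc[seq_len(per_class)], gfcf[seq_len(per_class)],
                        gt$system, scfg,
                        inference_config(max_iter = 500, n_sim_avg = 3,
                                         tol = 0, seed = 500 + cond))
    expect_false(any(ens$failed))
    feats <- c(feats, lapply(ens$results, function(r) lgec_features(r$C)))
    labels <- c(labels, rep(cond, per_class))
  }
  X <- do.call(rbind, feats)

  rep_true <- train_task_classifier(X, labels,
                                    classifier_config(n_repeats = 20,
                                                      seed = 9))
  expect_gte(rep_true$accuracy_mean, 0.5)   # far above chance 1/8

  scr <- scramble_labels(labels, seed = 10)
  rep_scr <- train_task_classifier(X, scr,
                                   classifier_config(n_repeats = 20,
                                                     seed = 11))
  expect_lt(abs(rep_scr$accuracy_mean - 1 / 8), 0.15)
})
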