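test_that("the coupling update is exact, linear, and fixes the diagonal", {
  M <- 4
  set.seed(1)
  C <- matrix(rnorm(M * M, sd = 0.01), M, M); diag(C) <- 0
  fc <- matrix(rnorm(M * M), M, M)
  fcf <- matrix(rnorm(M * M), M, M)

  # zero discrepancy is a fixed point
  expect_identical(update_coupling(C, fc, fc, fcf, fcf, 1e-5), {
    C2 <- C; diag(C2) <- 0; C2
  })

  # a single discrepancy moves exactly by varsigma * (dFC + dFCf)
  fc_e <- fc; fcf_e <- fcf
  fc_e[2, 3] <- fc[2, 3] + 0.5
  fcf_e[2, 3] <- fcf[2, 3] + 0.3
  up <- update_coupling(C, fc_e, fc, fcf_e, fcf, 1e-5)
  expect_equal(up[2, 3] - C[2, 3], 8e-6, tolerance = 1e-9)
  expect_equal(up[-2, ], C[-2, ])

  # negative discrepancies mirror exactly
  fc_n <- fc; fcf_n <- fcf
  fc_n[2, 3] <- fc[2, 3] - 0.5
  fcf_n[2, 3] <- fcf[2, 3] - 0.3
  dn <- update_coupling(C, fc_n, fc, fcf_n, fcf, 1e-5)
  expect_equal(dn[2, 3] - C[2, 3], -8e-6, tolerance = 1e-9)

  # doubling varsigma doubles the step exactly
  C0 <- matrix(0, M, M)
  d1 <- update_coupling(C0, fc_e, fc, fcf_e, fcf, 1e-5)
  d2 <- update_coupling(C0, fc_e, fc, fcf_e, fcf, 2e-5)
  expect_identical(2 * d1, d2)

  expect_error(update_coupling(C, fc[1:3, 1:3], fc, fcf, fcf, 1e-5),
               "dimension")
})

test_that("infer_gec honours the iteration contract and is seeded", {
  set.seed(5)
  gt <- make_ground_truth(4, 10, density = 0.3, asymmetry = 0.5, seed = 5)
  ds <- generate_dataset(gt, 5, 200, seed = 6)
  obs <- average_observables(lapply(ds, oracle_encode, gt = gt), tau = 3)
  scfg <- sim_config(dt = 0.1, t_sample = 0.72, n_samples = 100,
                     transient_s = 20)
  icfg <- inference_config(max_iter = 1, n_sim_avg = 2, seed = 7)
  r1 <- infer_gec(obs$fc, obs$fcf, gt$system, scfg, icfg)
  expect_equal(r1$iterations, 1L)
  expect_equal(nrow(r1$trace), 1L)
  # after exactly one update from C = 0 every step is varsigma * discrepancy
  expect_lt(max(abs(r1$C)), 1)

  icfg5 <- inference_config(max_iter = 5, n_sim_avg = 2, seed = 7)
  r5a <- infer_gec(obs$fc, obs$fcf, gt$system, scfg, icfg5)
  r5b <- infer_gec(obs$fc, obs$fcf, gt$system, scfg, icfg5)
  expect_identical(r5a$C, r5b$C)
  expect_identical(r5a$trace, r5b$trace)

  # the reported C is the best-fit iterate along the trace
  fits <- (r5a$trace$fit_fc + r5a$trace$fit_fcf) / 2
  expect_equal(r5a$best_iteration, which.max(fits))
  expect_equal(r5a$best_fit, max(fits))
})

test_that("null data keep the inferred coupling at the update-noise floor", {
  # observables from uncoupled oscillators: C* = 0
  gt <- make_ground_truth(4, 10, density = 0.3, asymmetry = 0.5, seed = 8)
  gt$system$C <- matrix(0, 4, 4)
  gt$C_star <- matrix(0, 4, 4)
  ds <- generate_dataset(gt, 30, 400, seed = 9)
  obs <- average_observables(lapply(ds, oracle_encode, gt = gt), tau = 3)
  scfg <- sim_config(dt = 0.1, t_sample = 0.72, n_samples = 150,
                     transient_s = 30)
  n_it <- 200L
  icfg <- inference_config(max_iter = n_it, n_sim_avg = 5, tol = 0, seed = 10)
  fit <- infer_gec(obs$fc, obs$fcf, gt$system, scfg, icfg)

  # Monte-Carlo null: accumulate the same number of updates with C frozen
  # at zero, i.e. pure sampling fluctuation of the discrepancy terms
  set.seed(99)
  acc <- matrix(0, 4, 4)
  sps <- 7L; dt <- 0.72 / 7
  for (k in seq_len(n_it)) {
    om <- lgec:::hopf_obs_batch_cpp(gt$system$a, gt$system$omega,
                                    gt$system$sigma, matrix(0, 4, 4), dt,
                                    150L, sps, as.integer(round(30 / dt)), 5L,
                                    3L, sample.int(2^30, 1))
    acc <- update_coupling(acc, obs$fc, om$fc, t(obs$fcf), t(om$fcf), 1e-5)
  }
  null_scale <- max(abs(acc))
  expect_lt(max(abs(fit$C)), 5 * max(null_scale, 1e-12))
})

test_that("fit_ensemble maps groups to models deterministically", {
  gt <- make_ground_truth(3, 8, density = 0.5, asymmetry = 0.5, seed = 12)
  ds <- generate_dataset(gt, 8, 200, seed = 13)
  lat <- lapply(ds, oracle_encode, gt = gt)
  fcs <- lapply(lat, compute_fc)
  fcfs <- lapply(lat, compute_fcf, tau = 3)
  gfc <- group_average(fcs, 4, seed = 1)
  gfcf <- group_average(fcfs, 4, seed = 1)
  scfg <- sim_config(dt = 0.1, t_sample = 0.72, n_samples = 80,
                     transient_s = 20)
  icfg <- inference_config(max_iter = 3, n_sim_avg = 2, seed = 3)
  e1 <- fit_ensemble(gfc, gfcf, gt$system, scfg, icfg)
  e2 <- fit_ensemble(gfc, gfcf, gt$system, scfg, icfg)
  expect_length(e1$results, 2L)
  expect_false(any(e1$failed))
  expect_identical(e1$results[[1]]$C, e2$results[[1]]$C)
  expect_equal(e1$mean_C, (e1$results[[1]]$C + e1$results[[2]]$C) / 2)

  # identical groups with identical seeds give identical members
  e3 <- fit_ensemble(list(gfc[[1]], gfc[[1]]), list(gfcf[[1]], gfcf[[1]]),
                     gt$system, scfg, icfg)
  expect_false(identical(e3$results[[1]]$C, e3$results[[2]]$C))  # fresh seeds
  expect_equal(e3$mean_C, (e3$results[[1]]$C + e3$results[[2]]$C) / 2)
})
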