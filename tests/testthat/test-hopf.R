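test_that("hopf_system validates its fields", {
  expect_error(hopf_system(omega = c(0.2, 0.3), C = matrix(1, 2, 2)),
               "zero diagonal")
  expect_error(hopf_system(a = c(1, 2, 3), omega = c(0.2, 0.3)),
               "same length")
  sys <- hopf_system(omega = 2 * pi * c(0.03, 0.05))
  expect_equal(sys$a, c(-0.02, -0.02))
  expect_equal(sys$sigma, 0.01)
})

test_that("noise-free supercritical oscillators settle on sqrt(a)", {
  # Euler bias in the limit-cycle amplitude is O(dt), so use a fine step
  for (a in c(0.01, 0.04, 0.09)) {
    sys <- hopf_system(a = a, omega = 2 * pi * 0.05, sigma = 0,
                       C = matrix(0, 1, 1))
    cfg <- sim_config(dt = 0.002, t_sample = 1, n_samples = 2,
                      transient_s = 800, z0 = 0.01 + 0i)
    s <- simulate_hopf(sys, cfg)
    expect_equal(Mod(s$z_final), sqrt(a), tolerance = 0.01)
  }
})

test_that("subcritical oscillators decay to the fixed point", {
  sys <- hopf_system(a = -0.02, omega = 2 * pi * 0.05, sigma = 0,
                     C = matrix(0, 1, 1))
  cfg <- sim_config(dt = 0.01, t_sample = 1, n_samples = 2,
                    transient_s = 800, z0 = 0.1 + 0i)
  expect_lt(Mod(simulate_hopf(sys, cfg)$z_final), 1e-3)
})

test_that("the oscillation frequency matches omega", {
  sys <- hopf_system(a = 0.04, omega = 2 * pi * 0.05, sigma = 0,
                     C = matrix(0, 1, 1))
  cfg <- sim_config(dt = 0.01, t_sample = 0.72, n_samples = 2048,
                    transient_s = 300, z0 = 0.1 + 0.05i)
  x <- simulate_hopf(sys, cfg)$x[, 1]
  T <- length(x)
  freqs <- (0:(T - 1)) / (T * 0.72)
  peak <- freqs[which.max(Mod(fft(x - mean(x)))[1:(T %/% 2)]^2)]
  expect_lt(abs(peak - 0.05), 1 / (T * 0.72) + 1e-12)
})

test_that("noise sustains subcritical fluctuations without blow-up", {
  sys <- hopf_system(a = -0.02, omega = 2 * pi * c(0.03, 0.05), sigma = 0.01,
                     C = matrix(0, 2, 2))
  cfg <- sim_config(dt = 0.1, t_sample = 0.5, n_samples = 2000,
                    transient_s = 60, seed = 4)
  s <- simulate_hopf(sys, cfg)
  expect_true(all(is.finite(s$x)))
  expect_true(all(apply(s$x, 2, var) > 0))
})

test_that("the integrator is seeded and converges in dt", {
  sys <- hopf_system(a = -0.02, omega = 2 * pi * c(0.03, 0.06), sigma = 0.01,
                     C = matrix(c(0, 0.1, 0.05, 0), 2, 2))
  cfg <- sim_config(dt = 0.1, t_sample = 0.72, n_samples = 100,
                    transient_s = 10, seed = 11)
  expect_identical(simulate_hopf(sys, cfg)$x, simulate_hopf(sys, cfg)$x)

  # noise-free trajectories converge as dt shrinks
  sys0 <- hopf_system(a = 0.04, omega = 2 * pi * c(0.03, 0.06), sigma = 0,
                      C = matrix(c(0, 0.1, 0.05, 0), 2, 2))
  z0 <- c(0.1 + 0.02i, 0.05 - 0.1i)
  zf <- lapply(c(0.004, 0.002), function(dt) {
    simulate_hopf(sys0, sim_config(dt = dt, t_sample = 1, n_samples = 2,
                                   transient_s = 200, z0 = z0))$z_final
  })
  expect_lt(max(abs(Mod(zf[[1]]) - Mod(zf[[2]])) / Mod(zf[[2]])), 0.01)
})

test_that("coupling asymmetry breaks lagged-correlation symmetry", {
  # a common intrinsic frequency isolates coupling-driven irreversibility:
  # with heterogeneous frequencies the rotation itself already breaks the
  # time-reversal symmetry of the real-part cross-correlations
  omega <- 2 * pi * rep(0.04, 3)
  Csym <- matrix(0.12, 3, 3); diag(Csym) <- 0
  Casym <- matrix(c(0, 0.25, 0, 0, 0, 0.25, 0.25, 0, 0), 3, 3, byrow = TRUE)
  cfg <- sim_config(dt = 0.1, t_sample = 0.72, n_samples = 6000,
                    transient_s = 60, seed = 21)
  x_sym <- simulate_hopf(hopf_system(omega = omega, C = Csym), cfg)$x
  x_asym <- simulate_hopf(hopf_system(omega = omega, C = Casym), cfg)$x
  ai_sym <- asymmetry_index(compute_fcf(x_sym, 3))
  ai_asym <- asymmetry_index(compute_fcf(x_asym, 3))
  expect_gt(ai_asym, 2 * ai_sym)
})

test_that("intrinsic frequencies are recovered from latent spectra", {
  tr <- 0.72
  t <- (0:1999) * tr
  # pure sinusoid: estimate within one frequency bin
  x <- cbind(sin(2 * pi * 0.04 * t + 0.3), sin(2 * pi * 0.02 * t))
  f <- estimate_intrinsic_frequencies(x, tr)
  bin <- 1 / (2000 * tr)
  expect_lt(abs(f[1] - 0.04), bin + 1e-12)
  expect_lt(abs(f[2] - 0.02), bin + 1e-12)

  # two subjects with different peaks average arithmetically
  s1 <- cbind(sin(2 * pi * 0.03 * t), sin(2 * pi * 0.03 * t))
  s2 <- cbind(sin(2 * pi * 0.05 * t), sin(2 * pi * 0.05 * t))
  f2 <- estimate_intrinsic_frequencies(list(s1, s2), tr)
  expect_lt(max(abs(f2 - 0.04)), bin)

  # band-passed noise stays inside the analysis band
  set.seed(9)
  noise <- bandpass_filter(bold_timeseries(matrix(rnorm(4000), 2000, 2), tr))
  fn <- estimate_intrinsic_frequencies(noise$data, tr)
  expect_true(all(fn >= 0.008 & fn <= 0.08))

  # short trajectories warn about poor spectral resolution
  expect_warning(
    estimate_intrinsic_frequencies(x[1:100, ], tr),
    "poorly resolved")
})
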