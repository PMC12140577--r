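#' Coupled Stuart-Landau (Hopf normal form) system
#'
#' Each latent mode j obeys
#' `dz_j/dt = (a_j + i w_j - |z_j|^2) z_j + sum_k C[j,k] (z_k - z_j) + eta_j`
#' with complex state `z_j = x_j + i y_j` and additive uncorrelated Gaussian
#' noise of standard deviation `sigma`. `a_j < 0` gives a damped fixed point,
#' `a_j > 0` a self-sustained limit cycle of amplitude `sqrt(a_j)`; near the
#' bifurcation, noise produces complex amplitude-modulated oscillations.
#'
#' @param a bifurcation parameter(s); a scalar is recycled to all M modes
#'   (default -0.02, the subcritical working point used for model fitting).
#' @param omega intrinsic angular frequencies in rad/s (length M).
#' @param sigma noise standard deviation in signal units (default 0.01).
#' @param C M x M coupling matrix, `C[j, k]` = influence of mode k on mode j;
#'   the diagonal must be zero (self-influence lives in `a`).
#' @return An object of class `hopf_system`.
#' @export
hopf_system <- function(a = -0.02, omega, sigma = 0.01, C = NULL) {
  omega <- as.numeric(omega)
  M <- length(omega)
  stopifnot(M >= 1L, sigma >= 0)
  if (length(a) == 1L) a <- rep(a, M)
  if (length(a) != M)
    stop("'a' must be a scalar or have the same length as 'omega'",
         call. = FALSE)
  if (is.null(C)) C <- matrix(0, M, M)
  assert_square(C, "C")
  if (nrow(C) != M)
    stop("'C' must be M x M with M = length(omega)", call. = FALSE)
  if (any(diag(C) != 0))
    stop("'C' must have a zero diagonal (self-coupling belongs in 'a')",
         call. = FALSE)
  structure(list(a = as.numeric(a), omega = omega, sigma = sigma, C = C),
            class = "hopf_system")
}

#' Simulation configuration for the coupled-oscillator model
#'
#' @param dt Euler-Maruyama integration step in seconds (default 0.1);
#'   internally nudged to the nearest value dividing `t_sample` exactly so
#'   observation times are exact.
#' @param t_sample observation sampling period in seconds (the TR).
#' @param n_samples number of observed frames to return (>= 2).
#' @param transient_s initial duration discarded before sampling
#'   (default 60 s).
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @param z0 optional complex M-vector of initial states; by default small
#'   random complex values are drawn.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.1, t_sample, n_samples, transient_s = 60,
                       seed = NULL, z0 = NULL) {
  stopifnot(dt > 0, t_sample > 0, dt <= t_sample, n_samples >= 2L,
            transient_s >= 0)
  structure(list(dt = dt, t_sample = t_sample,
                 n_samples = as.integer(n_samples),
                 transient_s = transient_s, seed = seed, z0 = z0),
            class = "sim_config")
}

#' Simulate the coupled Stuart-Landau system
#'
#' Integrates the system by Euler-Maruyama with step `dt`, adding complex
#' Gaussian noise of SD `sigma * sqrt(dt)` independently to the real and
#' imaginary parts at every step, discards the transient, and samples the
#' observable `x = Re(z)` every `t_sample` seconds.
#'
#' @param system a [hopf_system()].
#' @param cfg a [sim_config()].
#' @return A list of class `hopf_sim` with `x` (n_samples x M real matrix)
#'   and `z_final` (complex M-vector).
#' @export
simulate_hopf <- function(system, cfg) {
  stopifnot(inherits(system, "hopf_system"), inherits(cfg, "sim_config"))
  M <- length(system$omega)
  set_seed_if(cfg$seed)
  z0 <- cfg$z0
  if (is.null(z0)) {
    z0 <- complex(real = rnorm(M, sd = 0.1), imaginary = rnorm(M, sd = 0.1))
  }
  if (length(z0) != M)
    stop("'z0' must have one entry per mode", call. = FALSE)
  # adjust dt so that an integer number of steps spans one sampling period
  steps_per_sample <- max(1L, as.integer(round(cfg$t_sample / cfg$dt)))
  dt <- cfg$t_sample / steps_per_sample
  n_discard <- as.integer(round(cfg$transient_s / dt))
  res <- hopf_sim_cpp(system$a, system$omega, system$sigma, system$C,
                      dt, cfg$n_samples, steps_per_sample, n_discard,
                      Re(z0), Im(z0))
  structure(list(x = res$x,
                 z_final = complex(real = res$z_re, imaginary = res$z_im)),
            class = "hopf_sim")
}

#' Estimate intrinsic mode frequencies from encoded data
#'
#' For each latent mode, locates the periodogram peak within the analysis
#' band for every trajectory, then averages the peak frequencies across
#' trajectories (subjects). Signals are assumed already band-limited.
#'
#' @param latents list of T x M latent-trajectory matrices (or one matrix).
#' @param tr_seconds sampling period of the trajectories in seconds.
#' @param band frequency band searched, in Hz (default `c(0.008, 0.08)`).
#' @return M-vector of peak frequencies in Hz (multiply by `2*pi` for the
#'   angular frequencies used by [hopf_system()]).
#' @export
estimate_intrinsic_frequencies <- function(latents, tr_seconds,
                                           band = c(0.008, 0.08)) {
  if (is.matrix(latents)) latents <- list(latents)
  stopifnot(length(latents) >= 1L, tr_seconds > 0)
  M <- ncol(latents[[1L]])
  if (any(vapply(latents, ncol, 1L) != M))
    stop("all trajectories must share the same number of modes",
         call. = FALSE)
  peaks <- vapply(latents, function(x) {
    T <- nrow(x)
    if (T * tr_seconds < 2 / band[1L])
      warning(sprintf(
        "trajectory of %d frames spans < 2 cycles of %g Hz; spectral peak is poorly resolved",
        T, band[1L]))
    freqs <- seq(0, by = 1 / (T * tr_seconds), length.out = T)
    keep <- which(freqs >= band[1L] & freqs <= band[2L])
    if (length(keep) == 0L)
      keep <- which(freqs > 0 & freqs <= 1 / (2 * tr_seconds))
    apply(x, 2L, function(col) {
      pw <- Mod(fft(col - mean(col)))^2
      freqs[keep[which.max(pw[keep])]]
    })
  }, numeric(M))
  if (M == 1L) mean(peaks) else rowMeans(matrix(peaks, nrow = M))
}
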