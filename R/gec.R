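#' Configuration for LGEC inference
#'
#' @param varsigma learning factor applied to both discrepancy terms
#'   (default 1e-5).
#' @param tau forward shift of the time-shifted connectivity, in frames
#'   (default 3).
#' @param n_sim_avg simulations averaged per iteration (default 10, matching
#'   the group size of the averaged empirical observables; 9 for
#'   rest-plus-task groups).
#' @param max_iter iteration cap (default 5000).
#' @param tol minimum improvement of the windowed mean similarity per
#'   `tol_window` iterations before stopping (default 1e-4); 0 disables early
#'   stopping and always runs to `max_iter`. Because the similarity trace is
#'   noisy while the coupling is still near zero, stopping additionally
#'   requires the coupling matrix to have changed by less than 1% (relative
#'   Frobenius norm) over the window.
#' @param tol_window convergence window in iterations (default 50).
#' @param seed master seed for all per-iteration simulations.
#' @return An object of class `inference_config`.
#' @export
inference_config <- function(varsigma = 1e-5, tau = 3L, n_sim_avg = 10L,
                             max_iter = 5000L, tol = 1e-4, tol_window = 50L,
                             seed = NULL) {
  stopifnot(varsigma > 0, tau >= 0L, n_sim_avg >= 1L, max_iter >= 1L,
            tol >= 0, tol_window >= 1L)
  structure(list(varsigma = varsigma, tau = as.integer(tau),
                 n_sim_avg = as.integer(n_sim_avg),
                 max_iter = as.integer(max_iter), tol = tol,
                 tol_window = as.integer(tol_window), seed = seed),
            class = "inference_config")
}

#' One pseudo-gradient update of the coupling matrix
#'
#' Pure function implementing the update
#' `C_ij <- C_ij + varsigma (FCemp_ij - FCmod_ij)
#'               + varsigma (FCfemp_ij - FCfmod_ij)`
#' for all off-diagonal entries; the diagonal stays zero.
#'
#' @param C current M x M coupling matrix.
#' @param fc_emp,fc_mod empirical and model zero-lag FC matrices.
#' @param fcf_emp,fcf_mod empirical and model forward-shifted FC matrices
#'   (same `tau`).
#' @param varsigma learning factor.
#' @return Updated M x M coupling matrix.
#' @export
update_coupling <- function(C, fc_emp, fc_mod, fcf_emp, fcf_mod, varsigma) {
  assert_square(C)
  for (m in list(fc_emp, fc_mod, fcf_emp, fcf_mod)) {
    assert_square(m)
    if (!all(dim(m) == dim(C)))
      stop("all matrices must share the dimension of 'C'", call. = FALSE)
  }
  out <- C + varsigma * (fc_emp - fc_mod) + varsigma * (fcf_emp - fcf_mod)
  diag(out) <- 0
  out
}

#' Infer the latent generative effective connectivity (LGEC)
#'
#' Starting from a zero coupling matrix, repeatedly simulates the coupled
#' Stuart-Landau system, averages the FC and FCf(tau) of `n_sim_avg`
#' simulations, and nudges every connection by `varsigma` times the
#' discrepancy between empirical and model observables until the fit
#' stabilises. The forward-shifted discrepancy is applied in the orientation
#' consistent with the row-receives coupling convention: the entry `C[i, j]`
#' (influence of j on i) is driven by the correlation between j earlier and
#' i later, i.e. by the transposed FCf discrepancy (see the methods
#' vignette).
#'
#' @param fc_emp empirical zero-lag FC in latent space (M x M).
#' @param fcf_emp empirical forward-shifted FC at the configured `tau`.
#' @param system a [hopf_system()] supplying `a`, `omega`, `sigma`; its own
#'   coupling matrix is ignored (inference always starts from zero).
#' @param sim_cfg a [sim_config()] describing each model simulation; its
#'   `n_samples` should match the empirical segment length.
#' @param inf_cfg an [inference_config()].
#' @return An object of class `gec_result`: `C` (the best-fit coupling along
#'   the trace), `trace` (data frame of per-iteration `fit_fc`, `fit_fcf`),
#'   `converged`, `iterations`, `best_iteration`.
#' @export
infer_gec <- function(fc_emp, fcf_emp, system, sim_cfg,
                      inf_cfg = inference_config()) {
  assert_square(fc_emp); assert_square(fcf_emp)
  stopifnot(inherits(system, "hopf_system"), inherits(sim_cfg, "sim_config"),
            inherits(inf_cfg, "inference_config"))
  M <- length(system$omega)
  if (nrow(fc_emp) != M || nrow(fcf_emp) != M)
    stop("observable dimensions must match the number of modes",
         call. = FALSE)

  set_seed_if(inf_cfg$seed)
  steps_per_sample <- max(1L, as.integer(round(sim_cfg$t_sample / sim_cfg$dt)))
  dt <- sim_cfg$t_sample / steps_per_sample
  n_discard <- as.integer(round(sim_cfg$transient_s / dt))
  iter_seeds <- draw_seeds(inf_cfg$max_iter)
  C <- matrix(0, M, M)
  C_prev_window <- C
  fit_fc <- fit_fcf <- rep(NA_real_, inf_cfg$max_iter)
  best <- list(fit = -Inf, C = C, iter = 0L)
  converged <- FALSE
  it <- 0L
  # loop-invariant pieces, kept out of the hot path
  off <- row(C) != col(C)
  fc_emp_off <- fc_emp[off]
  fcf_emp_off <- fcf_emp[off]
  tfcf_emp <- t(fcf_emp)
  vs <- inf_cfg$varsigma
  w <- inf_cfg$tol_window

  while (it < inf_cfg$max_iter) {
    it <- it + 1L
    obs_mod <- hopf_obs_batch_cpp(system$a, system$omega, system$sigma, C,
                                  dt, sim_cfg$n_samples, steps_per_sample,
                                  n_discard, inf_cfg$n_sim_avg, inf_cfg$tau,
                                  iter_seeds[it])
    fc_mod <- obs_mod$fc
    fcf_mod <- obs_mod$fcf

    fit_fc[it] <- cor(fc_emp_off, fc_mod[off])
    fit_fcf[it] <- cor(fcf_emp_off, fcf_mod[off])
    fit <- (fit_fc[it] + fit_fcf[it]) / 2
    if (!is.na(fit) && fit > best$fit) best <- list(fit = fit, C = C, iter = it)

    # Eq. 2 step with the forward-shifted discrepancy transposed into the
    # row-receives orientation (see the methods vignette)
    C <- C + vs * (fc_emp - fc_mod) + vs * (tfcf_emp - t(fcf_mod))
    diag(C) <- 0

    if (inf_cfg$tol > 0 && it %% w == 0L) {
      if (it >= 2L * w) {
        fits <- (fit_fc + fit_fcf) / 2
        recent <- mean(fits[(it - w + 1L):it])
        prev <- mean(fits[(it - 2L * w + 1L):(it - w)])
        c_change <- norm(C - C_prev_window, "F") /
          max(norm(C, "F"), 1e-12)
        if (recent - prev < inf_cfg$tol && c_change < 0.01) {
          converged <- TRUE
          break
        }
      }
      C_prev_window <- C
    }
  }

  structure(list(C = best$C,
                 trace = data.frame(iteration = seq_len(it),
                                    fit_fc = fit_fc[seq_len(it)],
                                    fit_fcf = fit_fcf[seq_len(it)]),
                 converged = converged, iterations = it,
                 best_iteration = best$iter, best_fit = best$fit),
            class = "gec_result")
}

#' @export
print.gec_result <- function(x, ...) {
  cat(sprintf(
    "<gec_result> %d x %d LGEC; %d iterations (%s); best fit %.3f at iteration %d\n",
    nrow(x$C), ncol(x$C), x$iterations,
    if (x$converged) "converged" else "iteration cap", x$best_fit,
    x$best_iteration))
  invisible(x)
}

#' Fit an ensemble of LGEC models to grouped observables
#'
#' Runs [infer_gec()] once per subgroup-averaged observable pair with
#' independent seeds drawn from the master seed, the way one model is fitted
#' per group of averaged participants.
#'
#' @param grouped_fc,grouped_fcf aligned lists of averaged FC / FCf matrices
#'   (e.g. from [group_average()]).
#' @param system,sim_cfg,inf_cfg as in [infer_gec()].
#' @return A list of class `gec_ensemble`: `results` (one [infer_gec()]
#'   result or error per group), `mean_C` (entrywise mean LGEC across
#'   successful fits), `failed` (logical vector).
#' @export
fit_ensemble <- function(grouped_fc, grouped_fcf, system, sim_cfg,
                         inf_cfg = inference_config()) {
  stopifnot(is.list(grouped_fc), is.list(grouped_fcf),
            length(grouped_fc) == length(grouped_fcf),
            length(grouped_fc) >= 1L)
  set_seed_if(inf_cfg$seed)
  seeds <- draw_seeds(length(grouped_fc))
  results <- vector("list", length(grouped_fc))
  failed <- logical(length(grouped_fc))
  for (g in seq_along(grouped_fc)) {
    cfg_g <- inf_cfg
    cfg_g$seed <- seeds[g]
    results[[g]] <- tryCatch(
      infer_gec(grouped_fc[[g]], grouped_fcf[[g]], system, sim_cfg, cfg_g),
      error = function(e) e)
    failed[g] <- inherits(results[[g]], "error")
  }
  ok <- which(!failed)
  mean_C <- if (length(ok))
    Reduce(`+`, lapply(results[ok], `[[`, "C")) / length(ok) else NULL
  structure(list(results = results, mean_C = mean_C, failed = failed),
            class = "gec_ensemble")
}
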