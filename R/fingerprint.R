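#' Probe one latent mode with Gaussian noise
#'
#' Builds a surrogate latent trajectory with i.i.d. `N(0, noise_sd^2)` noise
#' in mode `k` and zeros in every other mode, and decodes it to source space.
#' The decoded response reveals which regions a latent mode drives.
#'
#' @param vae a [train_vae()] model.
#' @param k mode index in `1..M`.
#' @param frames number of surrogate frames (default 2000).
#' @param noise_sd standard deviation of the injected noise (default 1,
#'   i.e. standard Gaussian).
#' @param seed integer seed for the draw.
#' @return List with `decoded` (frames x N matrix) and `injected`
#'   (the noise series put into mode k).
#' @export
probe_mode <- function(vae, k, frames = 2000L, noise_sd = 1, seed = NULL) {
  stopifnot(inherits(vae, "trained_vae"), frames >= 2L, noise_sd >= 0)
  M <- vae$spec$latent_dim
  k <- as.integer(k)
  if (k < 1L || k > M)
    stop(sprintf("mode index %d out of range 1..%d", k, M), call. = FALSE)
  set_seed_if(seed)
  injected <- rnorm(frames, sd = noise_sd)
  Z <- matrix(0, frames, M)
  Z[, k] <- injected
  list(decoded = vae_decode(vae, Z), injected = injected)
}

#' Source-space pattern of every latent mode
#'
#' Repeats [probe_mode()] for each mode. The unsigned pattern
#' `variance_map[k, j]` is the temporal variance of decoded region j under
#' noise in mode k; the signed pattern `signed_map[k, j]` is the Pearson
#' correlation between decoded region j and the injected noise series, which
#' splits each pattern into positively and negatively associated regions.
#'
#' @inheritParams probe_mode
#' @return An object of class `mode_pattern` with `variance_map` (M x N,
#'   nonnegative), `signed_map` (M x N in `[-1, 1]`), and `probe_config`.
#' @export
mode_patterns <- function(vae, frames = 2000L, noise_sd = 1, seed = NULL) {
  stopifnot(inherits(vae, "trained_vae"))
  M <- vae$spec$latent_dim
  N <- vae$spec$input_dim
  set_seed_if(seed)
  seeds <- draw_seeds(M)
  variance_map <- signed_map <- matrix(0, M, N)
  for (k in seq_len(M)) {
    pr <- probe_mode(vae, k, frames = frames, noise_sd = noise_sd,
                     seed = seeds[k])
    variance_map[k, ] <- apply(pr$decoded, 2L, var)
    if (sd(pr$injected) > 0) {
      sds <- apply(pr$decoded, 2L, sd)
      ok <- sds > 0
      signed_map[k, ok] <- cor(pr$decoded[, ok, drop = FALSE], pr$injected)
    }
  }
  structure(list(variance_map = variance_map, signed_map = signed_map,
                 probe_config = list(frames = as.integer(frames),
                                     noise_sd = noise_sd, seed = seed,
                                     mode_seeds = seeds)),
            class = "mode_pattern")
}

#' Region-by-network membership matrix
#'
#' Percentages of participation of each region in each reference functional
#' network (e.g. the seven canonical resting-state networks).
#'
#' @param values N x R numeric matrix of percentages in `[0, 100]`; row sums
#'   may be at most 100 up to rounding slack.
#' @param network_names character vector of R network names.
#' @return An object of class `rsn_membership`.
#' @export
rsn_membership <- function(values, network_names = colnames(values)) {
  values <- assert_matrix(values)
  if (any(values < 0) || any(values > 100))
    stop("membership percentages must lie in [0, 100]", call. = FALSE)
  if (any(rowSums(values) > 100 + 1))
    stop("membership row sums exceed 100 beyond rounding slack",
         call. = FALSE)
  if (is.null(network_names))
    network_names <- sprintf("RSN%d", seq_len(ncol(values)))
  if (length(network_names) != ncol(values))
    stop("'network_names' must name every column", call. = FALSE)
  colnames(values) <- network_names
  structure(list(values = values,
                 network_names = as.character(network_names)),
            class = "rsn_membership")
}

#' Associate latent-mode patterns with reference networks
#'
#' Correlates each mode's signed source-space pattern with the regional
#' participation of each reference network, with two-sided p-values and
#' Benjamini-Hochberg FDR correction across all M x R tests.
#'
#' @param patterns a [mode_patterns()] result.
#' @param membership an [rsn_membership()] (or a bare N x R matrix).
#' @param alpha FDR level (default 0.05).
#' @return An object of class `rsn_association` with `r`, `p`, `p_adj` and
#'   `significant` (all M x R).
#' @export
associate_rsn <- function(patterns, membership, alpha = 0.05) {
  stopifnot(inherits(patterns, "mode_pattern"))
  if (!inherits(membership, "rsn_membership"))
    membership <- rsn_membership(as.matrix(membership))
  V <- membership$values
  if (ncol(patterns$signed_map) != nrow(V))
    stop("pattern width must equal the number of membership rows",
         call. = FALSE)
  csd <- apply(V, 2L, sd)
  if (any(csd == 0))
    stop(sprintf("membership column %d is constant; correlation undefined",
                 which(csd == 0)[1L]), call. = FALSE)
  M <- nrow(patterns$signed_map)
  R <- ncol(V)
  r <- p <- matrix(NA_real_, M, R, dimnames = list(NULL,
                                                   membership$network_names))
  for (k in seq_len(M)) {
    for (j in seq_len(R)) {
      ct <- cor.test(patterns$signed_map[k, ], V[, j])
      r[k, j] <- unname(ct$estimate)
      p[k, j] <- ct$p.value
    }
  }
  p_adj <- matrix(p.adjust(p, method = "BH"), M, R,
                  dimnames = dimnames(p))
  structure(list(r = r, p = p, p_adj = p_adj,
                 significant = p_adj <= alpha, alpha = alpha),
            class = "rsn_association")
}
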