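# Shared fixtures, all generated in code.

# Multi-subject recordings whose frames lie in a `rank`-dimensional linear
# subspace of N regions (plus isotropic noise): the analytically tractable
# test bed for the autoencoder, with PCA as the linear-achievable oracle.
make_rank_data <- function(n_subj, frames, N, rank, noise_sd, seed,
                           scale = 2) {
  set.seed(seed)
  W <- qr.Q(qr(matrix(rnorm(N * rank), N, rank)))
  lapply(seq_len(n_subj), function(s) {
    Z <- matrix(rnorm(frames * rank), frames, rank)
    X <- Z %*% t(W) * scale +
      matrix(rnorm(frames * N, sd = noise_sd), frames, N)
    bold_timeseries(X, 0.72, subject_id = sprintf("S%02d", s),
                    condition = "TOY")
  })
}

# A hand-built "trained" autoencoder whose decoder is exactly the linear map
# W (latent -> source) and whose encoder is its pseudo-inverse: no hidden
# layers, so every analytic oracle for linear maps applies.
make_linear_vae <- function(W) {
  N <- nrow(W); M <- ncol(W)
  spec <- vae_spec(N, M, hidden_dims = integer(0))
  pinv <- solve(crossprod(W), t(W))
  params <- list(
    enc = list(),
    mu = list(W = t(pinv), b = rep(0, M)),
    lv = list(W = matrix(0, N, M), b = rep(-10, M)),
    dec = list(),
    out = list(W = t(W), b = rep(0, N))
  )
  structure(list(spec = spec, params = params,
                 loss_history = data.frame(),
                 normalization = NULL,
                 recon_error_train = NA_real_, recon_error_test = NA_real_),
            class = "trained_vae")
}

# Gaussian class-separable feature design for the classifier tests:
# `n_per` samples per class, D dimensions, class centroids N(0, center_sd^2).
make_class_features <- function(K, n_per, D, center_sd, seed) {
  set.seed(seed)
  centers <- matrix(rnorm(K * D, sd = center_sd), K, D)
  X <- do.call(rbind, lapply(seq_len(K), function(k)
    sweep(matrix(rnorm(n_per * D), n_per, D), 2, centers[k, ], "+")))
  list(X = X, labels = rep(seq_len(K), each = n_per))
}

# Brute-force Pearson correlation straight from the definition.
pearson_oracle <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Step-up Benjamini-Hochberg discovery set, written independently of
# p.adjust: largest k with p_(k) <= alpha * k / m, flag all p <= p_(k).
bh_oracle <- function(p, alpha) {
  m <- length(p)
  s <- sort(p)
  ok <- which(s <= alpha * seq_len(m) / m)
  if (length(ok) == 0L) return(rep(FALSE, m))
  p <= s[max(ok)]
}
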