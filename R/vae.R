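#' Variational autoencoder architecture specification
#'
#' Encoder: dense ReLU layers funnelling from `input_dim` through
#' `hidden_dims` into a variational layer of `latent_dim` Gaussians
#' (mean and log-variance heads). The decoder mirrors the encoder.
#'
#' @param input_dim number of regions N.
#' @param latent_dim number of latent modes M (< N).
#' @param hidden_dims integer vector of hidden widths, strictly decreasing
#'   from the input and no smaller than `latent_dim`; default
#'   `c(round(N/2), round(N/4))` clipped from below at `latent_dim`.
#' @param kl_weight weight of the Kullback-Leibler term in the loss
#'   (default 1).
#' @return An object of class `vae_spec`.
#' @export
vae_spec <- function(input_dim, latent_dim, hidden_dims = NULL,
                     kl_weight = 1) {
  input_dim <- as.integer(input_dim)
  latent_dim <- as.integer(latent_dim)
  stopifnot(input_dim >= 2L, latent_dim >= 1L, latent_dim < input_dim,
            kl_weight >= 0)
  if (is.null(hidden_dims)) {
    hidden_dims <- pmax(c(round(input_dim / 2), round(input_dim / 4)),
                        latent_dim)
    hidden_dims <- unique(hidden_dims[hidden_dims < input_dim])
  }
  hidden_dims <- as.integer(hidden_dims)
  if (length(hidden_dims)) {
    widths <- c(input_dim, hidden_dims)
    if (any(diff(widths) >= 0))
      stop("'hidden_dims' must decrease strictly from the input width",
           call. = FALSE)
    if (min(hidden_dims) < latent_dim)
      stop("'hidden_dims' must not fall below 'latent_dim'", call. = FALSE)
  }
  structure(list(input_dim = input_dim, latent_dim = latent_dim,
                 hidden_dims = hidden_dims, kl_weight = kl_weight),
            class = "vae_spec")
}

#' Training configuration for the autoencoder
#'
#' @param batch_size minibatch size (default 128).
#' @param epochs training epochs (default 50); 0 returns an untrained model.
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param seed integer seed controlling initialisation, shuffling and
#'   reparameterisation noise; `NULL` uses the current RNG stream.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 128L, epochs = 50L,
                         learning_rate = 1e-3, seed = NULL) {
  stopifnot(batch_size >= 1L, epochs >= 0L, learning_rate > 0)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = seed),
            class = "train_config")
}

# ---- internal dense-network machinery -------------------------------------

dense_init <- function(n_in, n_out) {
  list(W = matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = rep(0, n_out))
}

vae_init <- function(spec) {
  h <- spec$hidden_dims
  enc_widths <- c(spec$input_dim, h)
  dec_widths <- c(spec$latent_dim, rev(h))
  list(
    enc = lapply(seq_along(h),
                 function(l) dense_init(enc_widths[l], enc_widths[l + 1])),
    mu = dense_init(enc_widths[length(enc_widths)], spec$latent_dim),
    lv = dense_init(enc_widths[length(enc_widths)], spec$latent_dim),
    dec = lapply(seq_along(h),
                 function(l) dense_init(dec_widths[l], dec_widths[l + 1])),
    out = dense_init(dec_widths[length(dec_widths)], spec$input_dim)
  )
}

affine <- function(x, layer) sweep(x %*% layer$W, 2L, layer$b, "+")

encode_forward <- function(params, X) {
  acts <- list(X)
  h <- X
  for (layer in params$enc) {
    h <- pmax(affine(h, layer), 0)
    acts[[length(acts) + 1L]] <- h
  }
  list(acts = acts,
       mu = affine(h, params$mu),
       lv = affine(h, params$lv))
}

decode_forward <- function(params, Z) {
  acts <- list(Z)
  h <- Z
  for (layer in params$dec) {
    h <- pmax(affine(h, layer), 0)
    acts[[length(acts) + 1L]] <- h
  }
  list(acts = acts, xhat = affine(h, params$out))
}

# Backpropagate through a stack of ReLU dense layers.
# douts: gradient at the stack output. Returns grads per layer and gradient
# at the stack input.
relu_stack_backprop <- function(layers, acts, dout) {
  grads <- vector("list", length(layers))
  for (l in rev(seq_along(layers))) {
    dout <- dout * (acts[[l + 1L]] > 0)          # through ReLU
    grads[[l]] <- list(W = crossprod(acts[[l]], dout), b = colSums(dout))
    dout <- tcrossprod(dout, layers[[l]]$W)
  }
  list(grads = grads, din = dout)
}

# One minibatch: loss (reconstruction + kl_weight * KL) and all gradients.
# Reconstruction = per-sample sum of squared errors, averaged over the batch;
# KL = analytic Gaussian KL against N(0, I), averaged over the batch.
vae_loss_grad <- function(params, X, kl_weight, eps) {
  B <- nrow(X)
  ef <- encode_forward(params, X)
  sd_z <- exp(0.5 * ef$lv)
  Z <- ef$mu + eps * sd_z
  df <- decode_forward(params, Z)
  err <- df$xhat - X
  recon <- sum(err * err) / B
  kl <- 0.5 * sum(exp(ef$lv) + ef$mu^2 - 1 - ef$lv) / B
  loss <- recon + kl_weight * kl

  dxhat <- 2 * err / B
  g_out <- list(W = crossprod(df$acts[[length(df$acts)]], dxhat),
                b = colSums(dxhat))
  ddec_in <- tcrossprod(dxhat, params$out$W)
  dec_bp <- relu_stack_backprop(params$dec, df$acts, ddec_in)
  dZ <- dec_bp$din
  dmu <- dZ + kl_weight * ef$mu / B
  dlv <- dZ * (0.5 * eps * sd_z) + kl_weight * 0.5 * (exp(ef$lv) - 1) / B
  henc <- ef$acts[[length(ef$acts)]]
  g_mu <- list(W = crossprod(henc, dmu), b = colSums(dmu))
  g_lv <- list(W = crossprod(henc, dlv), b = colSums(dlv))
  denc_top <- tcrossprod(dmu, params$mu$W) + tcrossprod(dlv, params$lv$W)
  enc_bp <- relu_stack_backprop(params$enc, ef$acts, denc_top)

  list(loss = loss, recon = recon, kl = kl,
       grads = list(enc = enc_bp$grads, mu = g_mu, lv = g_lv,
                    dec = dec_bp$grads, out = g_out))
}

# Adam over the nested parameter list.
adam_state_init <- function(params) {
  st <- rapply(params, f = function(x) x * 0, how = "replace")
  list(m = st, v = st, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    m2 <- beta1 * m + (1 - beta1) * g
    v2 <- beta2 * v + (1 - beta2) * g^2
    mhat <- m2 / (1 - beta1^t)
    vhat <- v2 / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m2, v = v2)
  }
  walk <- function(p, g, m, v) {
    if (is.numeric(p)) {
      r <- upd(p, g, m, v)
      return(r)
    }
    out_p <- p; out_m <- m; out_v <- v
    for (k in seq_along(p)) {
      r <- walk(p[[k]], g[[k]], m[[k]], v[[k]])
      out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
    }
    list(p = out_p, m = out_m, v = out_v)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# ---- user-facing operations ------------------------------------------------

#' Train a variational autoencoder on spatial patterns
#'
#' Minimises reconstruction error plus `kl_weight` times the analytic
#' Gaussian KL divergence against a standard normal, using reparameterised
#' sampling, minibatch gradient descent with Adam, and seeded shuffling.
#'
#' @param patterns a [build_pattern_set()] object; training uses the rows
#'   flagged by `train_mask`.
#' @param spec a [vae_spec()] whose `input_dim` matches the pattern width.
#' @param cfg a [train_config()].
#' @return An object of class `trained_vae` with the learned weights, the
#'   per-epoch `loss_history` (columns epoch, loss, recon, kl), the stored
#'   training normalization, and deterministic (posterior-mean)
#'   reconstruction errors `recon_error_train` / `recon_error_test`
#'   measured as per-element mean squared error.
#' @export
train_vae <- function(patterns, spec, cfg = train_config()) {
  stopifnot(inherits(patterns, "pattern_set"), inherits(spec, "vae_spec"),
            inherits(cfg, "train_config"))
  if (ncol(patterns$patterns) != spec$input_dim)
    stop("pattern width does not match spec$input_dim", call. = FALSE)
  X <- patterns$patterns[patterns$train_mask, , drop = FALSE]
  Xte <- patterns$patterns[!patterns$train_mask, , drop = FALSE]

  set_seed_if(cfg$seed)
  params <- vae_init(spec)
  state <- adam_state_init(params)
  hist <- vector("list", cfg$epochs)

  if (cfg$epochs > 0L) {
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(nrow(X))
      starts <- seq(1L, nrow(X), by = cfg$batch_size)
      ep <- c(loss = 0, recon = 0, kl = 0)
      for (s in starts) {
        idx <- perm[s:min(s + cfg$batch_size - 1L, nrow(X))]
        xb <- X[idx, , drop = FALSE]
        eps <- matrix(rnorm(length(idx) * spec$latent_dim),
                      length(idx), spec$latent_dim)
        lg <- vae_loss_grad(params, xb, spec$kl_weight, eps)
        if (!is.finite(lg$loss))
          stop(sprintf("training diverged (non-finite loss) at epoch %d",
                       epoch), call. = FALSE)
        st <- adam_step(params, lg$grads, state, cfg$learning_rate)
        params <- st$params
        state <- st$state
        ep <- ep + c(lg$loss, lg$recon, lg$kl) * length(idx)
      }
      hist[[epoch]] <- c(epoch = epoch, ep / nrow(X))
    }
  }

  vae <- structure(
    list(spec = spec, params = params,
         loss_history = if (cfg$epochs > 0L)
           as.data.frame(do.call(rbind, hist)) else
           data.frame(epoch = integer(), loss = double(),
                      recon = double(), kl = double()),
         normalization = patterns$normalization),
    class = "trained_vae")
  vae$recon_error_train <- reconstruction_error(vae, X)
  vae$recon_error_test <- if (nrow(Xte) > 0L)
    reconstruction_error(vae, Xte) else NA_real_
  vae
}

#' @export
print.trained_vae <- function(x, ...) {
  cat(sprintf(
    "<trained_vae> N = %d -> [%s] -> M = %d; %d epochs; test MSE %.4g\n",
    x$spec$input_dim, paste(x$spec$hidden_dims, collapse = ", "),
    x$spec$latent_dim, nrow(x$loss_history), x$recon_error_test))
  invisible(x)
}

#' Encode spatial patterns into the latent space
#'
#' Returns the posterior mean of each frame by default (deterministic), which
#' is what all downstream dynamical modelling uses; set `sample = TRUE` for a
#' reparameterised draw.
#'
#' @param vae a [train_vae()] model.
#' @param patterns K x N matrix in the normalized space of the training set
#'   (set `normalized = FALSE` to apply the stored normalization first).
#' @param sample draw z ~ q(z|x) instead of returning the mean.
#' @param seed seed for the sampling draw.
#' @param normalized whether `patterns` are already normalized (default TRUE).
#' @return K x M matrix of latent-mode values.
#' @export
vae_encode <- function(vae, patterns, sample = FALSE, seed = NULL,
                       normalized = TRUE) {
  stopifnot(inherits(vae, "trained_vae"))
  patterns <- as.matrix(patterns)
  if (ncol(patterns) != vae$spec$input_dim)
    stop("pattern width does not match the model input dimension",
         call. = FALSE)
  if (!normalized)
    patterns <- apply_normalization(patterns, vae$normalization)
  ef <- encode_forward(vae$params, patterns)
  if (!sample) return(ef$mu)
  set_seed_if(seed)
  eps <- matrix(rnorm(length(ef$mu)), nrow(ef$mu), ncol(ef$mu))
  ef$mu + eps * exp(0.5 * ef$lv)
}

#' Decode latent-mode values back to source-space patterns
#'
#' @param vae a [train_vae()] model.
#' @param latent K x M matrix.
#' @param unnormalize map back to the original source units using the stored
#'   training normalization (default FALSE: stay in normalized space).
#' @return K x N matrix of reconstructed patterns.
#' @export
vae_decode <- function(vae, latent, unnormalize = FALSE) {
  stopifnot(inherits(vae, "trained_vae"))
  latent <- as.matrix(latent)
  if (ncol(latent) != vae$spec$latent_dim)
    stop("latent width does not match the model latent dimension",
         call. = FALSE)
  xhat <- decode_forward(vae$params, latent)$xhat
  if (unnormalize) xhat <- invert_normalization(xhat, vae$normalization)
  xhat
}

# Deterministic round-trip reconstruction error (per-element MSE).
reconstruction_error <- function(vae, X) {
  xhat <- vae_decode(vae, vae_encode(vae, X))
  mean((X - xhat)^2)
}

#' Scan latent dimensionality for the reconstruction-error elbow
#'
#' Trains one autoencoder per candidate dimension (identical seed policy),
#' records the held-out reconstruction error and its first difference, and
#' selects the elbow: the smallest dimension beyond which the error drop
#' falls below `elbow_frac` of the initial drop.
#'
#' @param patterns a [build_pattern_set()] object.
#' @param dims integer vector of candidate latent dimensions (default 5:12),
#'   each below the input dimension.
#' @param cfg a [train_config()] reused for every dimension.
#' @param hidden_dims optional shared hidden widths (otherwise per-spec
#'   defaults, which may vary with the latent dimension).
#' @param kl_weight KL weight passed to each [vae_spec()].
#' @param elbow_frac fraction of the initial error drop below which the curve
#'   counts as flat (default 0.1).
#' @return An object of class `dim_scan` with `dims`, `errors`, `derivative`,
#'   `elbow`, and `failed` flags for dimensions whose training errored.
#' @export
scan_latent_dims <- function(patterns, dims = 5:12, cfg = train_config(),
                             hidden_dims = NULL, kl_weight = 1,
                             elbow_frac = 0.1) {
  stopifnot(inherits(patterns, "pattern_set"), length(dims) >= 1L)
  dims <- sort(as.integer(dims))
  N <- ncol(patterns$patterns)
  if (any(dims >= N))
    stop("every scanned dimension must be below the input dimension",
         call. = FALSE)
  errors <- rep(NA_real_, length(dims))
  failed <- rep(FALSE, length(dims))
  for (i in seq_along(dims)) {
    res <- tryCatch(
      train_vae(patterns,
                vae_spec(N, dims[i], hidden_dims = hidden_dims,
                         kl_weight = kl_weight),
                cfg),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed[i] <- TRUE
    } else {
      errors[i] <- if (is.na(res$recon_error_test))
        res$recon_error_train else res$recon_error_test
    }
  }
  derivative <- if (length(dims) > 1L) diff(errors) else numeric(0)
  elbow <- NA_integer_
  if (!any(failed)) {
    if (length(dims) == 1L) {
      elbow <- dims[1L]
    } else {
      initial <- abs(derivative[1L])
      if (initial == 0) {
        elbow <- dims[1L]
      } else {
        idx <- which(abs(derivative) < elbow_frac * initial)[1L]
        elbow <- if (is.na(idx)) dims[length(dims)] else dims[idx]
      }
    }
  }
  structure(list(dims = dims, errors = errors, derivative = derivative,
                 elbow = elbow, failed = failed),
            class = "dim_scan")
}

#' @export
print.dim_scan <- function(x, ...) {
  cat("<dim_scan>\n")
  print(data.frame(dim = x$dims, error = x$errors,
                   derivative = c(NA, x$derivative), failed = x$failed))
  cat(sprintf("elbow: %s\n", x$elbow))
  invisible(x)
}
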