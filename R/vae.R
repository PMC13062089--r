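# Masked variational autoencoder for missing-segment reconstruction.
#
# Generative model: isotropic Gaussian prior p(z) = N(0, I_K); Gaussian
# decoder likelihood with diagonal covariance p(X|z) = N(mu_theta(z),
# diag(sigma_theta^2)).  The encoder approximates the posterior over z given
# the observed entries X_obs = M * X; the observation mask is concatenated
# to the input channels so the encoder can tell true zeros from missing
# data.  Training maximises the ELBO: masked Gaussian log-likelihood over
# observed entries minus beta times the KL divergence to the prior.

#' Masked VAE configuration
#'
#' @param latent_dim dimension `K` of the latent space.
#' @param hidden two convolutional channel widths for the encoder (the
#'   decoder mirrors them).
#' @param beta KL weight (`beta = 1` is the standard VAE).
#' @param kernel_size,conv_stride 1-D convolution geometry; the time axis
#'   shrinks by `conv_stride^2` before the dense latent heads.
#' @param window_len model window length in samples; longer records are
#'   processed in tiles of this size.
#' @param sigma_theta decoder output standard deviation; fixed (scalar) by
#'   default so the reconstruction loss reduces to masked squared error plus
#'   a constant.  Set `learn_sigma = TRUE` to learn one value per lead.
#' @param learn_sigma learn per-lead `sigma_theta` instead of fixing it.
#' @param learning_rate,epochs,batch_size Adam settings.
#' @param windows_per_record random training windows per record per epoch.
#' @param seed integer seed.
#' @return A list of class `vae_config`.
#' @export
vae_config <- function(latent_dim = 32L, hidden = c(32L, 64L), beta = 1,
                       kernel_size = 9L, conv_stride = 4L,
                       window_len = 1024L, sigma_theta = 1,
                       learn_sigma = FALSE, learning_rate = 1e-3,
                       epochs = 20L, batch_size = 8L,
                       windows_per_record = 2L, seed = 1L) {
  if (latent_dim < 1) abort_bad_arg("`latent_dim` must be >= 1.")
  if (beta < 0) abort_bad_arg("`beta` must be >= 0.")
  if (length(hidden) != 2L)
    abort_bad_arg("`hidden` must give two encoder channel widths.")
  if (window_len %% conv_stride^2 != 0)
    abort_bad_arg("`window_len` must be divisible by conv_stride^2.")
  if (sigma_theta <= 0) abort_bad_arg("`sigma_theta` must be positive.")
  structure(as.list(environment()), class = "vae_config")
}

vae_init_params <- function(cfg, n_leads = 12L) {
  k <- cfg$kernel_size
  h <- cfg$hidden
  Tb <- cfg$window_len %/% cfg$conv_stride^2
  flat <- Tb * h[2]
  p <- list()
  p <- par_conv(p, "enc1", k, 2L * n_leads, h[1])   # signal + mask channels
  p <- par_conv(p, "enc2", k, h[1], h[2])
  p <- par_dense(p, "mu", flat, cfg$latent_dim)
  p <- par_dense(p, "logsig", flat, cfg$latent_dim)
  p <- par_dense(p, "dec0", cfg$latent_dim, flat)
  p <- par_conv(p, "dec1", k, h[2], h[1])
  p <- par_conv(p, "dec2", k, h[1], h[1])
  p <- par_conv(p, "out", 5L, h[1], n_leads)
  if (cfg$learn_sigma)
    p[["logsig_theta"]] <- matrix(log(cfg$sigma_theta), 1L, n_leads)
  p
}

# encoder graph: x_obs, mask are (n_win*W) x L node/matrix; returns mu,
# log-sigma nodes of shape n_win x K
vae_encoder_net <- function(tp, ids, x_obs, mask, cfg, n_win) {
  W <- cfg$window_len
  s <- cfg$conv_stride
  k <- cfg$kernel_size
  xin <- ad_cbind(tp, c(x_obs, mask))
  e1 <- ad_relu(tp, nn_conv1d(tp, xin, ids[["enc1.W"]], ids[["enc1.b"]],
                              conv_tap_indices(W, k, s, n_win)))
  e2 <- ad_relu(tp, nn_conv1d(tp, e1, ids[["enc2.W"]], ids[["enc2.b"]],
                              conv_tap_indices(W %/% s, k, s, n_win)))
  flat <- ad_flatten_wins(tp, e2, W %/% s^2, n_win)
  list(mu = dense_f(tp, ids, "mu", flat),
       logsig = dense_f(tp, ids, "logsig", flat))
}

# decoder graph: z (n_win x K) -> mean matrix (n_win*W) x L
vae_decoder_net <- function(tp, ids, z, cfg, n_win, n_leads = 12L) {
  W <- cfg$window_len
  s <- cfg$conv_stride
  k <- cfg$kernel_size
  Tb <- W %/% s^2
  h0 <- ad_relu(tp, dense_f(tp, ids, "dec0", z))
  g <- ad_unflatten_wins(tp, h0, Tb, cfg$hidden[2])
  d1 <- ad_relu(tp, nn_conv1d(tp, g, ids[["dec1.W"]], ids[["dec1.b"]],
                              convt_tap_indices(Tb, s, k, n_win)))
  d2 <- ad_relu(tp, nn_conv1d(tp, d1, ids[["dec2.W"]], ids[["dec2.b"]],
                              convt_tap_indices(Tb * s, s, k, n_win)))
  nn_conv1d(tp, d2, ids[["out.W"]], ids[["out.b"]],
            conv_tap_indices(W, 5L, 1L, n_win))
}

vae_sigma_theta <- function(model) {
  if (model$config$learn_sigma)
    exp(as.numeric(model$params$logsig_theta))
  else rep(model$config$sigma_theta, 12L)
}

#' Encode observed ECG data to the variational posterior
#'
#' Returns the Gaussian posterior `q(z | X_obs) = N(mu, diag(sigma^2))`.
#' The observation mask is concatenated to the input channels, so true
#' zeros and missing entries are distinguishable.
#'
#' @param x_obs `T x L` matrix with missing entries set to 0 (or an
#'   [ecg_record()]).
#' @param mask binary `T x L` observation mask (1 = observed).
#' @param model a trained or initialised `vae_model`.
#' @return A list of class `gaussian_params` with vectors `mu` and `sigma`
#'   (per model window, rows of a matrix if several tiles are needed).
#' @export
vae_encode <- function(x_obs, mask, model) {
  x_obs <- if (inherits(x_obs, "ecg_record")) x_obs$signal else x_obs
  if (!all(dim(x_obs) == dim(mask)))
    abort_bad_arg("`x_obs` and `mask` must have identical shapes.")
  tiles <- vae_tile(x_obs, mask, model$config$window_len)
  tp <- ad_tape()
  ids <- ad_bind_params(tp, model$params)
  enc <- vae_encoder_net(tp, ids, ad_push(tp, tiles$x), ad_push(tp, tiles$m),
                         model$config, tiles$n_win)
  structure(list(mu = ad_val(tp, enc$mu),
                 sigma = exp(ad_val(tp, enc$logsig))),
            class = "gaussian_params")
}

# tile a T x L matrix into n_win windows of window_len rows; padding rows are
# marked missing so the model treats them as gaps
vae_tile <- function(x, mask, W) {
  n <- nrow(x)
  n_win <- ceiling(n / W)
  pad <- n_win * W - n
  if (pad > 0) {
    x <- rbind(x, matrix(0, pad, ncol(x)))
    mask <- rbind(mask, matrix(0, pad, ncol(mask)))
  }
  list(x = x, m = mask, n_win = n_win, pad = pad, n = n)
}

#' Reparameterization trick
#'
#' `z = mu + sigma * eps` with `eps ~ N(0, I)` supplied by the caller.
#'
#' @param params a `gaussian_params` list (vectors or matrices `mu`,
#'   `sigma`).
#' @param eps standard-normal draw of the same length as `mu`.
#' @return The latent draw `z`.
#' @export
vae_reparameterize <- function(params, eps) {
  if (length(eps) != length(params$mu))
    abort_bad_arg("`eps` must match the latent dimension.")
  params$mu + params$sigma * eps
}

#' Decode a latent vector to the Gaussian observation model
#'
#' @param z latent vector (length `K`) or matrix (rows = windows).
#' @param model a `vae_model`.
#' @return A list of class `gaussian_params` with `mu` (`T x L` matrix) and
#'   `sigma` (per-lead decoder standard deviations).
#' @export
vae_decode <- function(z, model) {
  if (is.null(dim(z))) z <- matrix(z, 1L)
  if (ncol(z) != model$config$latent_dim)
    abort_bad_arg("`z` must have length latent_dim.")
  tp <- ad_tape()
  ids <- ad_bind_params(tp, model$params)
  mu <- vae_decoder_net(tp, ids, ad_push(tp, z), model$config, nrow(z))
  structure(list(mu = ad_val(tp, mu), sigma = vae_sigma_theta(model)),
            class = "gaussian_params")
}

#' Closed-form KL divergence to the isotropic Gaussian prior
#'
#' `KL(N(mu, diag(sigma^2)) || N(0, I)) =
#'  0.5 * sum(mu^2 + sigma^2 - 1 - log(sigma^2))`, non-negative, zero only
#' at `mu = 0`, `sigma = 1`.
#'
#' @param params `gaussian_params` (or any list with `mu`, `sigma`).
#' @return A single non-negative number.
#' @export
kl_divergence <- function(params) {
  mu <- as.numeric(params$mu)
  sigma <- as.numeric(params$sigma)
  if (any(sigma <= 0)) abort_bad_arg("`sigma` must be strictly positive.")
  0.5 * sum(mu^2 + sigma^2 - 1 - 2 * log(sigma))
}

#' Masked VAE loss (negative ELBO)
#'
#' `L = L_recon + beta * KL`, with the reconstruction term the Gaussian
#' negative log-likelihood summed over observed entries only:
#' `sum_obs [0.5 * log(2 * pi * sigma^2) + (x - mu)^2 / (2 * sigma^2)]`.
#' Values stored at missing entries do not enter the loss.
#'
#' @param x `T x L` data matrix.
#' @param mask binary observation mask of the same shape.
#' @param recon_params decoder `gaussian_params` (`mu` matrix, `sigma`
#'   per lead or scalar).
#' @param post_params encoder posterior `gaussian_params`.
#' @param beta KL weight (>= 0).
#' @return A single number.
#' @export
vae_loss <- function(x, mask, recon_params, post_params, beta = 1) {
  if (beta < 0) abort_bad_arg("`beta` must be >= 0.")
  if (!all(dim(x) == dim(recon_params$mu)) || !all(dim(x) == dim(mask)))
    abort_bad_arg("`x`, `mask` and `recon_params$mu` shapes must agree.")
  sig <- recon_params$sigma
  sig_mat <- if (length(sig) == 1L) matrix(sig, nrow(x), ncol(x))
             else matrix(sig, nrow(x), ncol(x), byrow = TRUE)
  nll <- 0.5 * log(2 * pi * sig_mat^2) + (x - recon_params$mu)^2 /
    (2 * sig_mat^2)
  sum(nll * mask) + beta * kl_divergence(post_params)
}

#' Train the masked VAE
#'
#' Minimises the negative ELBO over windows drawn from the training records
#' (missing entries carry no reconstruction loss; the mask channels tell the
#' encoder where the gaps are).  One latent sample per window per step
#' (reparameterization trick).
#'
#' @param records list of normalized [ecg_record()]s.
#' @param masks list of binary masks matching each record (defaults to all
#'   ones; mix in masked copies so the model learns to impute).
#' @param config a [vae_config()].
#' @param verbose print per-epoch losses.
#' @return An object of class `vae_model` with `params`, `config` and
#'   `loss_trace` (per-epoch mean negative ELBO per window).
#' @export
train_vae <- function(records, masks = NULL, config = vae_config(),
                      verbose = FALSE) {
  if (length(records) == 0) abort_bad_arg("need at least one record.")
  for (r in records)
    if (!r$normalized)
      abort_state("training records must be normalized.",
                  "ecgmend_invalid_state")
  masks <- masks %||% lapply(records, function(r)
    matrix(1, nrow(r$signal), ncol(r$signal)))
  cfg <- config
  W <- cfg$window_len
  n_leads <- ncol(records[[1]]$signal)
  params <- with_seed(cfg$seed, vae_init_params(cfg, n_leads))
  opt <- adam_state(params)
  trace <- numeric(cfg$epochs)

  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(rep(seq_along(records), cfg$windows_per_record))
      ep_loss <- 0; n_seen <- 0L
      for (b0 in seq(1L, length(ord), by = cfg$batch_size)) {
        take <- ord[b0:min(b0 + cfg$batch_size - 1L, length(ord))]
        nw <- length(take)
        Xo <- matrix(0, nw * W, n_leads); Mk <- matrix(0, nw * W, n_leads)
        Xf <- matrix(0, nw * W, n_leads)
        for (j in seq_along(take)) {
          i <- take[j]
          Tn <- nrow(records[[i]]$signal)
          st <- if (Tn > W) sample.int(Tn - W + 1L, 1L) else 1L
          rows <- st:(st + min(W, Tn) - 1L)
          dst <- ((j - 1L) * W + 1L):(j * W)
          m <- masks[[i]][rows, , drop = FALSE]
          x <- records[[i]]$signal[rows, , drop = FALSE]
          Xf[dst, ] <- x
          Mk[dst, ] <- m
          Xo[dst, ] <- x * m
        }
        eps <- matrix(stats::rnorm(nw * cfg$latent_dim), nw)

        tp <- ad_tape()
        ids <- ad_bind_params(tp, params)
        enc <- vae_encoder_net(tp, ids, ad_push(tp, Xo), ad_push(tp, Mk),
                               cfg, nw)
        sig_n <- ad_exp(tp, enc$logsig)
        z <- ad_add(tp, enc$mu, ad_mul(tp, sig_n, ad_const(tp, eps)))
        mu_x <- vae_decoder_net(tp, ids, z, cfg, nw, n_leads)
        # masked squared-error NLL (sigma_theta fixed) summed over observed,
        # averaged over windows
        resid <- ad_mul(tp, ad_sub(tp, mu_x, ad_const(tp, Xf)),
                        ad_const(tp, Mk))
        s2 <- cfg$sigma_theta^2
        nll <- ad_scale(tp, ad_sum(tp, ad_square(tp, resid)),
                        1 / (2 * s2 * nw))
        # KL: 0.5 sum(mu^2 + sig^2 - 1 - 2 log sig), averaged over windows
        kl <- ad_scale(
          tp,
          ad_sub(tp,
                 ad_sum(tp, ad_add(tp, ad_square(tp, enc$mu),
                                   ad_square(tp, sig_n))),
                 ad_add(tp,
                        ad_const(tp, matrix(nw * cfg$latent_dim)),
                        ad_scale(tp, ad_sum(tp, enc$logsig), 2))),
          0.5 / nw)
        loss <- ad_add(tp, nll, ad_scale(tp, kl, cfg$beta))
        grads <- ad_backward(tp, loss, as.list(ids))
        names(grads) <- names(ids)
        stp <- adam_step(params, grads, opt, lr = cfg$learning_rate)
        params <- stp$params; opt <- stp$state
        ep_loss <- ep_loss + as.numeric(ad_val(tp, loss)) * nw
        n_seen <- n_seen + nw
      }
      trace[ep] <- ep_loss / n_seen
      if (verbose)
        message(sprintf("vae epoch %d/%d -ELBO %.4f", ep, cfg$epochs,
                        trace[ep]))
    }
  })
  structure(list(params = params, config = cfg, loss_trace = trace,
                 trained = TRUE),
            class = "vae_model")
}

#' @export
print.vae_model <- function(x, ...) {
  cat(sprintf("<vae_model> K=%d, trained %d epochs (final -ELBO %.4f)\n",
              x$config$latent_dim, length(x$loss_trace),
              utils::tail(x$loss_trace, 1)))
  invisible(x)
}

#' Reconstruct missing segments with the VAE
#'
#' Encodes the observed data, takes the posterior mean (default) or one
#' reparameterized sample, decodes, and imputes: observed entries are copied
#' from the input unchanged, only masked entries receive the decoder mean.
#'
#' @param record a normalized [ecg_record()] with missing entries zeroed
#'   (as produced by [simulate_missing()]).
#' @param mask binary observation mask.
#' @param model a trained `vae_model`.
#' @param eps_policy `"mean"` (deterministic, default) or `"sample"`.
#' @param seed seed for the `"sample"` policy.
#' @return The reconstructed [ecg_record()].
#' @export
vae_reconstruct <- function(record, mask, model,
                            eps_policy = c("mean", "sample"), seed = 1L) {
  stopifnot(inherits(record, "ecg_record"), inherits(model, "vae_model"))
  eps_policy <- match.arg(eps_policy)
  if (is.null(model$trained))
    abort_state("model has not been trained.", "ecgmend_invalid_state")
  x <- record$signal
  tiles <- vae_tile(x * mask, mask, model$config$window_len)
  tp <- ad_tape()
  ids <- ad_bind_params(tp, model$params)
  enc <- vae_encoder_net(tp, ids, ad_push(tp, tiles$x), ad_push(tp, tiles$m),
                         model$config, tiles$n_win)
  mu_z <- ad_val(tp, enc$mu)
  z <- if (eps_policy == "mean") mu_z else {
    sg <- exp(ad_val(tp, enc$logsig))
    mu_z + sg * matrix(with_seed(seed, stats::rnorm(length(mu_z))),
                       nrow(mu_z))
  }
  mu_x <- ad_val(tp, vae_decoder_net(tp, ids, ad_push(tp, z), model$config,
                                     tiles$n_win))
  mu_x <- mu_x[seq_len(tiles$n), , drop = FALSE]
  mu_x <- pmin(pmax(mu_x, 0), 1)
  out <- x
  out[mask == 0] <- mu_x[mask == 0]
  ecg_record(out, record$fs, record$lead_names, record$patient_id,
             record$label, normalized = record$normalized,
             scale_info = record$scale_info)
}
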