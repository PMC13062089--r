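# Transformer-based convolutional denoising autoencoder (TCDAE).
#
# Encoder: three GLU-gated 1-D convolutions (stride 2 each, so the time axis
# shrinks 8x).  Bottleneck: transformer encoder layers with multi-head
# self-attention and additive sinusoidal positional encoding.  Decoder:
# zero-stuffing upsample + convolution (transposed convolution) stages with
# skip connections from the matching encoder stages.  Trained to map noisy
# onto clean segments with a combined loss: time-domain Huber
# + frequency-weighted Huber on DFT magnitudes + cosine-similarity term.

#' TCDAE configuration
#'
#' @param encoder_channels integer vector of exactly three encoder channel
#'   widths (one per gated convolutional stage).
#' @param kernel_size convolution kernel length (samples).
#' @param stride stride of each encoder stage (time axis shrinks by
#'   `stride^3`).
#' @param d_model transformer width; must equal the last encoder width and
#'   be divisible by `n_heads`.
#' @param n_heads,n_transformer_layers self-attention geometry.
#' @param huber_delta Huber transition point (in normalized amplitude units).
#' @param cosine_weight weight of the cosine-similarity loss term
#'   (`lambda >= 0`).
#' @param freq_band_emphasis `c(low_hz, high_hz, multiplier)`: spectral-loss
#'   bins inside the band are weighted by the multiplier.  Diagnostic ECG
#'   content lives in roughly 0.5-40 Hz, hence the default.
#' @param learning_rate,epochs,batch_size Adam optimisation settings.
#' @param window_len training window length in samples (must be divisible by
#'   `stride^3`).
#' @param windows_per_record random training windows drawn from each record
#'   per epoch.
#' @param fs sampling frequency the spectral band refers to.
#' @param seed integer seed for weight initialisation and window sampling.
#' @return A list of class `tcdae_config`.
#' @export
tcdae_config <- function(encoder_channels = c(16L, 32L, 64L),
                         kernel_size = 7L, stride = 2L,
                         d_model = 64L, n_heads = 4L,
                         n_transformer_layers = 2L,
                         huber_delta = 0.1, cosine_weight = 0.1,
                         freq_band_emphasis = c(0.5, 40, 2.0),
                         learning_rate = 1e-3, epochs = 30L,
                         batch_size = 16L, window_len = 256L,
                         windows_per_record = 2L, fs = 500, seed = 1L) {
  if (length(encoder_channels) != 3L)
    abort_bad_arg("`encoder_channels` must have exactly three entries (three gated convolutional stages).")
  if (d_model %% n_heads != 0)
    abort_bad_arg("`d_model` must be divisible by `n_heads`.")
  if (d_model != encoder_channels[3])
    abort_bad_arg("`d_model` must equal the last encoder channel width.")
  if (huber_delta <= 0) abort_bad_arg("`huber_delta` must be positive.")
  if (cosine_weight < 0) abort_bad_arg("`cosine_weight` must be >= 0.")
  if (window_len %% stride^3 != 0)
    abort_bad_arg("`window_len` must be divisible by stride^3.")
  structure(as.list(environment()), class = "tcdae_config")
}

tcdae_init_params <- function(cfg, n_leads = 12L) {
  ch <- cfg$encoder_channels
  k <- cfg$kernel_size
  p <- list()
  p <- par_conv(p, "enc1a", k, n_leads, ch[1])
  p <- par_conv(p, "enc1b", k, n_leads, ch[1])
  p <- par_conv(p, "enc2a", k, ch[1], ch[2])
  p <- par_conv(p, "enc2b", k, ch[1], ch[2])
  p <- par_conv(p, "enc3a", k, ch[2], ch[3])
  p <- par_conv(p, "enc3b", k, ch[2], ch[3])
  for (l in seq_len(cfg$n_transformer_layers))
    p <- par_transformer_layer(p, sprintf("trf%d", l), cfg$d_model,
                               cfg$n_heads, 2L * cfg$d_model)
  p <- par_conv(p, "dec3", k, ch[3], ch[2])
  p <- par_conv(p, "skip3", 5L, 2L * ch[2], ch[2])
  p <- par_conv(p, "dec2", k, ch[2], ch[1])
  p <- par_conv(p, "skip2", 5L, 2L * ch[1], ch[1])
  p <- par_conv(p, "dec1", k, ch[1], ch[1])
  p <- par_conv(p, "out", 11L, ch[1] + n_leads, n_leads)
  p
}

# forward network: x is (n_win * T_win) x n_leads, T_win divisible by s^3
tcdae_net <- function(tp, ids, x, cfg, T_win, n_win, gate_override = NULL) {
  s <- cfg$stride
  k <- cfg$kernel_size
  t1 <- conv_tap_indices(T_win, k, s, n_win)
  e1 <- nn_gated_conv1d(tp, x, ids[["enc1a.W"]], ids[["enc1a.b"]],
                        ids[["enc1b.W"]], ids[["enc1b.b"]], t1,
                        gate_override)
  t2 <- conv_tap_indices(T_win %/% s, k, s, n_win)
  e2 <- nn_gated_conv1d(tp, e1, ids[["enc2a.W"]], ids[["enc2a.b"]],
                        ids[["enc2b.W"]], ids[["enc2b.b"]], t2,
                        gate_override)
  t3 <- conv_tap_indices(T_win %/% s^2, k, s, n_win)
  e3 <- nn_gated_conv1d(tp, e2, ids[["enc3a.W"]], ids[["enc3a.b"]],
                        ids[["enc3b.W"]], ids[["enc3b.b"]], t3,
                        gate_override)

  Tb <- T_win %/% s^3
  pe <- ad_const(tp, kronecker(matrix(1, n_win, 1),
                               sinusoidal_pe(Tb, cfg$d_model)))
  h <- ad_add(tp, e3, pe)
  for (l in seq_len(cfg$n_transformer_layers))
    h <- transformer_layer_f(tp, ids, sprintf("trf%d", l), h,
                             cfg$n_heads, cfg$d_model, Tb, n_win)

  tu3 <- convt_tap_indices(Tb, s, k, n_win)
  d3 <- ad_relu(tp, nn_conv1d(tp, h, ids[["dec3.W"]], ids[["dec3.b"]], tu3))
  s3 <- ad_relu(tp, nn_conv1d(tp, ad_cbind(tp, c(d3, e2)),
                              ids[["skip3.W"]], ids[["skip3.b"]],
                              conv_tap_indices(Tb * s, 5L, 1L, n_win)))
  tu2 <- convt_tap_indices(Tb * s, s, k, n_win)
  d2 <- ad_relu(tp, nn_conv1d(tp, s3, ids[["dec2.W"]], ids[["dec2.b"]], tu2))
  s2 <- ad_relu(tp, nn_conv1d(tp, ad_cbind(tp, c(d2, e1)),
                              ids[["skip2.W"]], ids[["skip2.b"]],
                              conv_tap_indices(Tb * s^2, 5L, 1L, n_win)))
  tu1 <- convt_tap_indices(Tb * s^2, s, k, n_win)
  d1 <- ad_relu(tp, nn_conv1d(tp, s2, ids[["dec1.W"]], ids[["dec1.b"]], tu1))
  # final skip from the input itself so the identity map is cheap to learn
  nn_conv1d(tp, ad_cbind(tp, c(d1, x)), ids[["out.W"]], ids[["out.b"]],
            conv_tap_indices(T_win, 11L, 1L, n_win))
}

spectral_bin_weights <- function(n, fs, band) {
  freq <- pmin(0:(n - 1), n - (0:(n - 1))) * fs / n
  ifelse(freq >= band[1] & freq <= band[2], band[3], 1)
}

# loss graph given node ids; target/indicators are plain matrices
tcdae_loss_node <- function(tp, pred, target, cfg) {
  l_time <- ad_huber(tp, pred, target, cfg$huber_delta)
  w <- spectral_bin_weights(nrow(target), cfg$fs, cfg$freq_band_emphasis)
  l_freq <- ad_spectral_huber(tp, pred, target, cfg$huber_delta, w)
  # per-lead cosine similarity between prediction and target
  eps <- 1e-12
  num <- ad_colsums(tp, ad_mul(tp, pred, ad_const(tp, target)))
  den_p <- ad_sqrt(tp, ad_colsums(tp, ad_square(tp, pred)))
  den_t <- matrix(sqrt(colSums(target^2)) + eps, 1L)
  cosim <- ad_div(tp, num, ad_mul(tp, den_p, ad_const(tp, den_t)))
  l_cos <- ad_sub(tp, ad_const(tp, matrix(1)), ad_mean(tp, cosim))
  ad_add(tp, ad_add(tp, l_time, l_freq),
         ad_scale(tp, l_cos, cfg$cosine_weight))
}

#' Combined TCDAE training loss
#'
#' `loss = Huber_time + Huber_freq + lambda * (1 - mean per-lead cosine)`.
#' The frequency term applies the Huber function to the difference of DFT
#' magnitude spectra, with bins inside `freq_band_emphasis` up-weighted by
#' the band multiplier; both Huber terms are means over entries.
#'
#' @param pred,target numeric `T x L` matrices of equal shape.
#' @param config a [tcdae_config()].
#' @return A single non-negative number.
#' @export
tcdae_loss <- function(pred, target, config = tcdae_config()) {
  if (!all(dim(pred) == dim(target)))
    abort_bad_arg("`pred` and `target` must have identical shapes.")
  tp <- ad_tape()
  p <- ad_push(tp, pred)
  as.numeric(ad_val(tp, tcdae_loss_node(tp, p, target, config)))
}

collect_pairs <- function(pairs) {
  if (length(pairs) == 0) abort_bad_arg("need at least one training pair.")
  lapply(pairs, function(p) {
    noisy <- p$noisy %||% p[[1]]
    clean <- p$clean %||% p[[2]]
    stopifnot(inherits(noisy, "ecg_record"), inherits(clean, "ecg_record"))
    if (!noisy$normalized || !clean$normalized)
      abort_state("training records must be normalized to [0, 1] first.",
                  "ecgmend_invalid_state")
    list(noisy = noisy$signal, clean = clean$signal)
  })
}

#' Train the TCDAE on noisy/clean record pairs
#'
#' Each epoch samples one random window per pair (seeded), groups windows
#' into minibatches and takes Adam steps on the combined loss.  Training is
#' fully reproducible given the config seed.
#'
#' @param pairs list of `list(noisy =, clean =)` record pairs (both
#'   normalized, identical geometry).
#' @param config a [tcdae_config()].
#' @param verbose print per-epoch losses.
#' @return An object of class `tcdae_model` with elements `params`,
#'   `config` and `loss_trace` (mean training loss per epoch).
#' @export
train_tcdae <- function(pairs, config = tcdae_config(), verbose = FALSE) {
  data <- collect_pairs(pairs)
  cfg <- config
  W <- cfg$window_len
  n_leads <- ncol(data[[1]]$noisy)

  params <- with_seed(cfg$seed, tcdae_init_params(cfg, n_leads))
  opt <- adam_state(params)
  trace <- numeric(cfg$epochs)

  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(rep(seq_along(data), cfg$windows_per_record))
      ep_loss <- 0; n_batches <- 0L
      for (b0 in seq(1L, length(ord), by = cfg$batch_size)) {
        take <- ord[b0:min(b0 + cfg$batch_size - 1L, length(ord))]
        wins <- lapply(take, function(i) {
          Tn <- nrow(data[[i]]$noisy)
          st <- if (Tn > W) sample.int(Tn - W + 1L, 1L) else 1L
          rows <- st:(st + min(W, Tn) - 1L)
          list(noisy = data[[i]]$noisy[rows, , drop = FALSE],
               clean = data[[i]]$clean[rows, , drop = FALSE])
        })
        X <- do.call(rbind, lapply(wins, `[[`, "noisy"))
        Y <- do.call(rbind, lapply(wins, `[[`, "clean"))
        tp <- ad_tape()
        ids <- ad_bind_params(tp, params)
        out <- tcdae_net(tp, ids, ad_push(tp, X), cfg, W, length(take))
        loss <- tcdae_loss_node(tp, out, Y, cfg)
        grads <- ad_backward(tp, loss, as.list(ids))
        names(grads) <- names(ids)
        st <- adam_step(params, grads, opt, lr = cfg$learning_rate)
        params <- st$params; opt <- st$state
        ep_loss <- ep_loss + as.numeric(ad_val(tp, loss))
        n_batches <- n_batches + 1L
      }
      trace[ep] <- ep_loss / n_batches
      if (verbose)
        message(sprintf("tcdae epoch %d/%d loss %.5f", ep, cfg$epochs,
                        trace[ep]))
    }
  })
  structure(list(params = params, config = cfg, loss_trace = trace),
            class = "tcdae_model")
}

#' @export
print.tcdae_model <- function(x, ...) {
  cat(sprintf(
    "<tcdae_model> %d parameters, trained %d epochs (final loss %.5f)\n",
    sum(lengths(x$params)), length(x$loss_trace),
    utils::tail(x$loss_trace, 1)))
  invisible(x)
}

#' Denoise a record with a trained TCDAE
#'
#' Runs the full record through the network in one pass (the record is
#' zero-padded up to a multiple of the stride stack and cropped back).
#'
#' @param record a normalized [ecg_record()].
#' @param model a trained `tcdae_model`.
#' @return The denoised [ecg_record()] (same shape, clipped to `[0, 1]`).
#' @export
tcdae_forward <- function(record, model) {
  stopifnot(inherits(record, "ecg_record"), inherits(model, "tcdae_model"))
  if (!record$normalized)
    abort_state("TCDAE operates on normalized records; call normalize_record() first.",
                "ecgmend_invalid_state")
  cfg <- model$config
  x <- record$signal
  n <- nrow(x)
  block <- cfg$stride^3
  n_pad <- (block - n %% block) %% block
  if (n_pad > 0) x <- rbind(x, matrix(0, n_pad, ncol(x)))
  tp <- ad_tape()
  ids <- ad_bind_params(tp, model$params)
  out <- tcdae_net(tp, ids, ad_push(tp, x), cfg, nrow(x), 1L)
  y <- ad_val(tp, out)[seq_len(n), , drop = FALSE]
  y <- pmin(pmax(y, 0), 1)
  ecg_record(y, record$fs, record$lead_names, record$patient_id,
             record$label, normalized = TRUE,
             scale_info = record$scale_info)
}

#' Per-lead denoising validation report
#'
#' Compares a denoised record against its raw counterpart lead by lead:
#' signal energies (`sum(x^2)`), the explicit energy ratio in percent,
#' Pearson correlation and mean absolute error.
#'
#' @param raw,denoised records (or matrices) of identical shape.
#' @return A tibble with one row per lead and columns `lead`, `energy_raw`,
#'   `energy_denoised`, `energy_ratio_pct`, `pearson_r`, `mae`.
#' @export
denoise_report <- function(raw, denoised) {
  xr <- if (inherits(raw, "ecg_record")) raw$signal else raw
  xd <- if (inherits(denoised, "ecg_record")) denoised$signal else denoised
  if (!all(dim(xr) == dim(xd)))
    abort_bad_arg("`raw` and `denoised` must have identical shapes.")
  e_raw <- colSums(xr^2)
  if (any(e_raw == 0))
    abort_state("zero-energy raw lead: energy ratio undefined.",
                "ecgmend_undefined_ratio")
  leads <- colnames(xr) %||% sprintf("lead%d", seq_len(ncol(xr)))
  tibble::tibble(
    lead = leads,
    energy_raw = e_raw,
    energy_denoised = colSums(xd^2),
    energy_ratio_pct = 100 * colSums(xd^2) / e_raw,
    pearson_r = vapply(seq_len(ncol(xr)),
                       function(j) stats::cor(xr[, j], xd[, j]), 0),
    mae = colMeans(abs(xr - xd)))
}

#' Mean band power of a signal
#'
#' Average squared DFT magnitude over the bins whose frequency falls in
#' `band` (used e.g. to verify powerline suppression around 50 Hz).
#'
#' @param x numeric vector or single-lead matrix column.
#' @param fs sampling frequency (Hz).
#' @param band `c(lo, hi)` frequency band in Hz.
#' @return Mean power in the band.
#' @export
band_power <- function(x, fs, band) {
  x <- as.numeric(x)
  n <- length(x)
  freq <- (0:(n - 1)) * fs / n
  p <- Mod(stats::fft(x))^2 / n
  sel <- freq >= band[1] & freq <= band[2]
  if (!any(sel)) return(0)
  mean(p[sel])
}
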