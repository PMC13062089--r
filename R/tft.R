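# Temporal fusion transformer adapted for 12-lead ECG gap reconstruction.
#
# Per timestep, each lead contributes an embedded feature vector built from
# its (possibly missing) amplitude, a cardiac-phase encoding and its
# observation flag; missing positions carry a shared learnable mask token.
# A variable selection network weights the leads, a bidirectional LSTM pair
# encodes the sequence, interpretable (head-averaged) multi-head attention
# lets gap positions attend to observed context on both sides (attention
# into missing segments is masked to exactly zero), static lead covariates
# enrich the attended features, and per-(quantile, lead) linear heads emit
# probabilistic reconstructions; the median is the point estimate.

#' TFT configuration
#'
#' @param d_model model width.
#' @param d_attn per-head attention dimension.
#' @param n_heads number of attention heads (`m_H`).
#' @param quantiles forecast quantile set; must contain 0.5 (the median is
#'   the point reconstruction).
#' @param T_obs observed context length per reconstruction window (samples).
#' @param tau_max maximum gap length reconstructed in one window; longer
#'   gaps are tiled into successive windows, re-conditioning on already
#'   imputed context.
#' @param grn_hidden hidden width of the gated residual networks.
#' @param dropout kept for completeness; 0 (deterministic) by default.
#' @param learning_rate,epochs,batch_size,windows_per_record Adam settings.
#' @param min_gap smallest artificial training-gap length (samples).
#' @param seed integer seed.
#' @return A list of class `tft_config`.
#' @export
tft_config <- function(d_model = 32L, d_attn = 8L, n_heads = 4L,
                       quantiles = c(0.1, 0.5, 0.9),
                       T_obs = 500L, tau_max = 250L, grn_hidden = 32L,
                       dropout = 0, learning_rate = 1e-3, epochs = 10L,
                       batch_size = 8L, windows_per_record = 1L,
                       min_gap = 50L, seed = 1L) {
  if (n_heads < 1) abort_bad_arg("`n_heads` must be >= 1.")
  if (!(0.5 %in% quantiles))
    abort_bad_arg("`quantiles` must contain the median 0.5.")
  if (any(quantiles <= 0 | quantiles >= 1))
    abort_bad_arg("quantiles must lie strictly inside (0, 1).")
  if (tau_max < 1) abort_bad_arg("`tau_max` must be >= 1.")
  quantiles <- sort(quantiles)
  structure(as.list(environment()), class = "tft_config")
}

# static covariates: lead type one-hot (limb/augmented/precordial) + lead
# identity one-hot
tft_static_features <- function() {
  leads <- standard_leads()
  type <- c(rep(1, 3), rep(2, 3), rep(3, 6))
  S <- cbind(stats::model.matrix(~ 0 + factor(type)), diag(12))
  rownames(S) <- leads
  colnames(S) <- c("limb", "augmented", "precordial", leads)
  unname(S)
}

tft_init_params <- function(cfg, n_leads = 12L) {
  d <- cfg$d_model
  h <- cfg$grn_hidden
  nq <- length(cfg$quantiles)
  p <- list()
  for (l in seq_len(n_leads))
    p <- par_dense(p, sprintf("emb%d", l), 4L, d)
  p[["mask_token"]] <- matrix(stats::rnorm(d, sd = 0.1), 1L)
  p <- par_grn(p, "static", ncol(tft_static_features()), h, d)
  p <- par_grn(p, "ctx_s", d, h, d)
  p <- par_grn(p, "ctx_e", d, h, d)
  p <- par_grn(p, "vsn", n_leads * d, h, n_leads, d_context = d)
  p <- par_grn(p, "sel", d, h, d)
  for (dir in c("f", "b")) {
    p[[paste0("lstm_", dir, ".Wx")]] <- init_mat(d, 4L * d)
    p[[paste0("lstm_", dir, ".Wh")]] <- init_mat(d, 4L * d)
    p[[paste0("lstm_", dir, ".b")]] <- init_zeros(4L * d)
  }
  p <- par_dense(p, "lstm_proj", 2L * d, d)
  p <- par_dense(p, "lstm_glu", d, 2L * d)
  p <- par_layernorm(p, "lstm_ln", d)
  p <- par_mha(p, "attn", d, cfg$n_heads, cfg$d_attn, average_heads = TRUE)
  p <- par_dense(p, "attn_glu", d, 2L * d)
  p <- par_layernorm(p, "attn_ln", d)
  p <- par_grn(p, "enrich", d, h, d, d_context = d)
  p <- par_grn(p, "ctx_h", d, h, d)
  p <- par_dense(p, "heads", 2L * d, n_leads * nq)
  p
}

# contexts derived from the static lead covariates (model constants)
tft_context_nodes <- function(tp, ids, cfg) {
  S <- ad_const(tp, tft_static_features())
  zeta <- grn_f(tp, ids, "static", S, d_out = cfg$d_model)   # L x d
  pooled <- ad_scale(tp, ad_matmul(
    tp, ad_const(tp, matrix(1, 1L, nrow(tft_static_features()))), zeta),
    1 / nrow(tft_static_features()))
  list(c_s = grn_f(tp, ids, "ctx_s", pooled, d_out = cfg$d_model),
       c_e = grn_f(tp, ids, "ctx_e", pooled, d_out = cfg$d_model))
}

# Cardiac phase for every sample given R-peak locations (0-based).  Phase
# grows linearly from 0 to 2*pi between successive peaks; beyond the first/
# last peak the median RR extrapolates.  With fewer than 2 peaks, falls back
# to a 1 Hz sinusoidal clock.
cardiac_phase <- function(n, r_peaks, fs) {
  if (length(r_peaks) < 2)
    return(2 * pi * (seq_len(n) - 1L) / fs)
  rp <- sort(r_peaks) + 1L
  rr_med <- stats::median(diff(rp))
  anchors <- c(rev(seq(rp[1], 1 - rr_med, by = -rr_med)),
               rp[-1], seq(rp[length(rp)] + rr_med, n + rr_med, by = rr_med))
  anchors <- sort(unique(anchors))
  beat_no <- stats::approx(anchors, seq_along(anchors), xout = seq_len(n),
                           rule = 2)$y
  2 * pi * beat_no
}

# per-lead feature tensors for a (possibly masked) signal
# returns list(feats = list of L (T x 4) matrices, obs_time = 0/1 vector)
tft_features <- function(x, mask, fs, r_peaks = NULL) {
  n <- nrow(x)
  obs_time <- as.numeric(rowSums(mask) == ncol(mask))
  if (is.null(r_peaks)) {
    lead2 <- x[, 2] * mask[, 2]
    r_peaks <- tryCatch(pan_tompkins(lead2, fs), error = function(e)
      integer(0))
    # keep only peaks detected in observed context
    r_peaks <- r_peaks[obs_time[r_peaks + 1L] == 1]
  }
  ph <- cardiac_phase(n, r_peaks, fs)
  s <- sin(ph); cph <- cos(ph)
  feats <- lapply(seq_len(ncol(x)), function(l)
    cbind(x[, l] * mask[, l], s, cph, mask[, l]))
  list(feats = feats, obs_time = obs_time)
}

# Full network over a batch of windows.
# feats: list of L matrices (n_win*W x 4); obs_wins: list of per-window 0/1
# observed-time vectors; query_rows: list of global row indices (gap
# positions) per window.  Returns prediction node (sum_q_rows x L*nq) plus
# the per-window attention weights.
tft_net <- function(tp, ids, feats, cfg, W, n_win, obs_wins, query_rows) {
  d <- cfg$d_model
  L <- length(feats)
  rows_tot <- n_win * W
  ctx <- tft_context_nodes(tp, ids, cfg)
  ones_col <- ad_const(tp, matrix(1, rows_tot, 1L))
  c_s_rows <- ad_matmul(tp, ones_col, ctx$c_s)

  # lead embeddings with mask-token substitution
  E <- vector("list", L)
  for (l in seq_len(L)) {
    f <- feats[[l]]
    e <- dense_f(tp, ids, sprintf("emb%d", l), ad_const(tp, f))
    m <- f[, 4]
    tok_rows <- ad_matmul(tp, ad_const(tp, matrix(1 - m, ncol = 1L)),
                          ids[["mask_token"]])
    E[[l]] <- ad_add(tp, ad_mul(tp, e, ad_const(tp, matrix(m, rows_tot, d))),
                     tok_rows)
  }

  # variable selection across leads
  v <- ad_softmax_rows(tp, grn_f(tp, ids, "vsn", ad_cbind(tp, E),
                                 context = c_s_rows, d_out = L))
  sel <- grn_f(tp, ids, "sel", ad_rbind(tp, E), d_out = d)  # (L*rows) x d
  xt <- ad_vsn_combine(tp, sel, v)

  # bidirectional sequence encoder (window-major -> time-major and back)
  # time-major index: row (t-1)*n_win + w  <-  window-major (w-1)*W + t
  idx_tm <- unlist(lapply(seq_len(W), function(t)
    (seq_len(n_win) - 1L) * W + t))
  idx_back <- order(idx_tm)
  x_tm <- ad_rows(tp, xt, idx_tm)
  h_f <- ad_lstm(tp, x_tm, ids[["lstm_f.Wx"]], ids[["lstm_f.Wh"]],
                 ids[["lstm_f.b"]], W, n_win)
  idx_rev <- unlist(lapply(rev(seq_len(W)), function(t)
    (seq_len(n_win) - 1L) * W + t))
  x_tm_rev <- ad_rows(tp, xt, idx_rev)
  h_b_rev <- ad_lstm(tp, x_tm_rev, ids[["lstm_b.Wx"]], ids[["lstm_b.Wh"]],
                     ids[["lstm_b.b"]], W, n_win)
  h_b <- ad_rows(tp, h_b_rev, rev(seq_len(rows_tot)))
  # reorder both back to window-major
  h_f <- ad_rows(tp, h_f, idx_back)
  h_b <- ad_rows(tp, h_b, order(idx_rev[rev(seq_len(rows_tot))]))
  h_bi <- dense_f(tp, ids, "lstm_proj", ad_cbind(tp, c(h_f, h_b)))
  gl <- dense_f(tp, ids, "lstm_glu", h_bi)
  gated <- ad_mul(tp, ad_cols(tp, gl, seq_len(d)),
                  ad_sigmoid(tp, ad_cols(tp, gl, d + seq_len(d))))
  seq_enc <- layernorm_f(tp, ids, "lstm_ln", ad_add(tp, xt, gated))

  # interpretable attention: gap positions query the observed context
  att_out <- vector("list", n_win)
  att_wts <- vector("list", n_win)
  q_glob <- integer(0)
  for (w in seq_len(n_win)) {
    qr <- query_rows[[w]]
    if (length(qr) == 0) next
    win_rows <- ((w - 1L) * W + 1L):(w * W)
    kv <- ad_rows(tp, seq_enc, win_rows)
    qn <- ad_rows(tp, seq_enc, qr)
    if (all(obs_wins[[w]] == 0))
      abort_state("window has no observed context at all.",
                  "ecgmend_degenerate_attention")
    mh <- mha_f(tp, ids, "attn", qn, kv, cfg$n_heads, cfg$d_attn,
                col_mask = obs_wins[[w]], average_heads = TRUE,
                return_weights = TRUE)
    att_out[[w]] <- mh$out
    att_wts[[w]] <- mh$weights
    q_glob <- c(q_glob, qr)
  }
  keep <- !vapply(att_out, is.null, TRUE)
  h_att <- if (sum(keep) == 1L) att_out[keep][[1]] else
    ad_rbind(tp, att_out[keep])
  theta_q <- ad_rows(tp, seq_enc, q_glob)
  gl2 <- dense_f(tp, ids, "attn_glu", h_att)
  gated2 <- ad_mul(tp, ad_cols(tp, gl2, seq_len(d)),
                   ad_sigmoid(tp, ad_cols(tp, gl2, d + seq_len(d))))
  h_tilde <- layernorm_f(tp, ids, "attn_ln", ad_add(tp, theta_q, gated2))

  # static enrichment of the attended features
  onesq <- ad_const(tp, matrix(1, length(q_glob), 1L))
  theta <- grn_f(tp, ids, "enrich", h_tilde,
                 context = ad_matmul(tp, onesq, ctx$c_e), d_out = d)
  # horizon context from the attention mechanism
  c_h <- grn_f(tp, ids, "ctx_h", h_att, d_out = d)
  pred <- dense_f(tp, ids, "heads", ad_cbind(tp, c(theta, c_h)))
  list(pred = pred, q_rows = q_glob, att_weights = att_wts)
}

#' Pinball (quantile) loss
#'
#' `p_q(u) = max(q * u, (q - 1) * u)` with `u = y - yhat`; non-negative,
#' minimised in expectation by the `q`-th quantile.
#'
#' @param y,yhat observed and predicted values (vectorised).
#' @param q quantile in (0, 1).
#' @return Elementwise pinball loss.
#' @export
pinball_loss <- function(y, yhat, q) {
  if (any(q <= 0 | q >= 1)) abort_bad_arg("`q` must lie in (0, 1).")
  u <- y - yhat
  pmax(q * u, (q - 1) * u)
}

#' Total TFT quantile loss
#'
#' Sums the pinball loss over timesteps, leads and quantiles, counting only
#' entries whose ground-truth indicator is 1 (unobserved truth contributes
#' exactly zero).
#'
#' @param targets `n x L` matrix of true values.
#' @param predictions `n x L x n_q` array (or `n x (L*n_q)` matrix,
#'   quantile-major blocks).
#' @param indicator binary `n x L` matrix; 1 where ground truth exists.
#' @param quantiles the quantile set matching the prediction slices.
#' @return A single non-negative number.
#' @export
tft_loss <- function(targets, predictions, indicator, quantiles) {
  L <- ncol(targets)
  if (length(dim(predictions)) == 3L) {
    predictions <- matrix(predictions, nrow = dim(predictions)[1])
  }
  if (nrow(predictions) != nrow(targets) ||
      ncol(predictions) != L * length(quantiles))
    abort_bad_arg("prediction shape must be n x (L * n_quantiles).")
  if (!all(dim(indicator) == dim(targets)))
    abort_bad_arg("`indicator` must match `targets`.")
  tot <- 0
  for (qi in seq_along(quantiles)) {
    cols <- (qi - 1L) * L + seq_len(L)
    tot <- tot + sum(pinball_loss(targets, predictions[, cols, drop = FALSE],
                                  quantiles[qi]) * indicator)
  }
  tot
}

#' Interpretable multi-head attention (head-averaged)
#'
#' Per head `h`: `softmax(Q W_Q^h (K W_K^h)' / sqrt(d_attn)) V W_V^h`,
#' with masked key positions receiving attention weight exactly 0; the
#' output is the mean over heads.
#'
#' @param Q,K,V input matrices (`T_q x d`, `T_k x d`, `T_k x d`).
#' @param W_Q,W_K,W_V lists of per-head projection matrices.
#' @param attn_mask optional 0/1 vector over key positions (0 = masked).
#' @return list with `output` (`T_q x d_v`) and `weights` (list of per-head
#'   `T_q x T_k` attention matrices, rows summing to 1 over unmasked keys).
#' @export
interpretable_mha <- function(Q, K, V, W_Q, W_K, W_V, attn_mask = NULL) {
  n_heads <- length(W_Q)
  if (!is.null(attn_mask) && all(attn_mask == 0))
    abort_state("all key positions are masked: attention degenerate.",
                "ecgmend_degenerate_attention")
  d_attn <- ncol(W_Q[[1]])
  out <- NULL
  wts <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    logits <- (Q %*% W_Q[[h]]) %*% t(K %*% W_K[[h]]) / sqrt(d_attn)
    if (!is.null(attn_mask)) logits[, attn_mask == 0] <- -Inf
    m <- apply(logits, 1, max)
    e <- exp(logits - m)
    A <- e / rowSums(e)
    if (!is.null(attn_mask)) A[, attn_mask == 0] <- 0
    wts[[h]] <- A
    o <- A %*% (V %*% W_V[[h]])
    out <- if (is.null(out)) o else out + o
  }
  list(output = out / n_heads, weights = wts)
}

#' Gated residual network applied to plain matrices
#'
#' `y = LayerNorm(skip(x) + GLU(W2 ELU(W1 x + W_c c)))`; used directly by
#' the variable selection, enrichment and context stages.  Exposed for
#' testing with explicit parameters.
#'
#' @param x input matrix (rows = positions).
#' @param params parameter list from [tft_grn_params()].
#' @param context optional context matrix (same rows as `x` or one row).
#' @param d_out output width.
#' @return The transformed matrix.
#' @export
tft_grn <- function(x, params, context = NULL, d_out = ncol(x)) {
  tp <- ad_tape()
  ids <- ad_bind_params(tp, params)
  if (!is.null(context) && nrow(as.matrix(context)) == 1L)
    context <- matrix(as.numeric(context), nrow(x), length(context),
                      byrow = TRUE)
  ctx <- if (is.null(context)) NULL else ad_const(tp, context)
  ad_val(tp, grn_f(tp, ids, "g", ad_const(tp, x), context = ctx,
                   d_out = d_out))
}

#' Initialise parameters for a standalone GRN
#' @param d_in,d_hidden,d_out,d_context layer widths (`d_context = NULL`
#'   for a context-free GRN).
#' @param seed seed for reproducible initialisation.
#' @return Named parameter list (prefix `g`).
#' @export
tft_grn_params <- function(d_in, d_hidden, d_out, d_context = NULL,
                           seed = 1L) {
  with_seed(seed, par_grn(list(), "g", d_in, d_hidden, d_out, d_context))
}

#' Variable selection across the 12 leads at one timestep
#'
#' `v = softmax(GRN_v(E, c_s))`, `x_tilde = sum_l v_l * GRN_sel(E_l)`.
#'
#' @param E `L x d_model` matrix of embedded lead features for one
#'   timestep.
#' @param model a `tft_model` (trained or freshly initialised).
#' @return list with `x_tilde` (length `d_model`) and `weights` (length
#'   `L`, non-negative, summing to 1).
#' @export
tft_variable_select <- function(E, model) {
  cfg <- model$config
  L <- nrow(E)
  if (L == 0) abort_bad_arg("`E` must have at least one lead row.")
  tp <- ad_tape()
  ids <- ad_bind_params(tp, model$params)
  ctx <- tft_context_nodes(tp, ids, cfg)
  Epad <- rbind(E, matrix(0, 12L - L, ncol(E)))  # VSN input is 12 lead slots
  flat <- ad_const(tp, matrix(as.numeric(t(Epad)), 1L))
  v <- ad_softmax_rows(tp, grn_f(tp, ids, "vsn", flat, context = ctx$c_s,
                                 d_out = 12L))
  vv <- as.numeric(ad_val(tp, v))[seq_len(L)]
  vv <- vv / sum(vv)
  sel <- ad_val(tp, grn_f(tp, ids, "sel", ad_const(tp, E),
                          d_out = cfg$d_model))
  list(x_tilde = as.numeric(crossprod(sel, vv)), weights = vv)
}

new_tft_model <- function(cfg, n_leads = 12L) {
  structure(list(params = with_seed(cfg$seed, tft_init_params(cfg, n_leads)),
                 config = cfg, loss_trace = numeric(0), trained = FALSE),
            class = "tft_model")
}

#' @export
print.tft_model <- function(x, ...) {
  cat(sprintf(
    "<tft_model> d=%d heads=%d quantiles=(%s)%s\n", x$config$d_model,
    x$config$n_heads, paste(x$config$quantiles, collapse = ", "),
    if (x$trained) sprintf(", trained %d epochs (final loss %.4f)",
                           length(x$loss_trace),
                           utils::tail(x$loss_trace, 1)) else " (untrained)"))
  invisible(x)
}

#' Train the ECG temporal fusion transformer
#'
#' Each training window cuts an artificial gap (length uniform between
#' `min_gap` and `tau_max` samples) into an otherwise observed stretch and
#' minimises the quantile loss of the gap predictions against the known
#' truth (the ground-truth indicator is 1 exactly where the underlying
#' record is observed).
#'
#' @param records list of normalized [ecg_record()]s.
#' @param masks optional list of availability masks (default: fully
#'   observed).
#' @param config a [tft_config()].
#' @param verbose print per-epoch losses.
#' @return A trained `tft_model`.
#' @export
train_tft <- function(records, masks = NULL, config = tft_config(),
                      verbose = FALSE) {
  if (length(records) == 0) abort_bad_arg("need at least one record.")
  for (r in records)
    if (!r$normalized)
      abort_state("training records must be normalized.",
                  "ecgmend_invalid_state")
  cfg <- config
  masks <- masks %||% lapply(records, function(r)
    matrix(1, nrow(r$signal), ncol(r$signal)))
  Wt <- cfg$T_obs + cfg$tau_max
  L <- ncol(records[[1]]$signal)
  nq <- length(cfg$quantiles)
  model <- new_tft_model(cfg, L)
  params <- model$params
  opt <- adam_state(params)
  trace <- numeric(cfg$epochs)

  # record-level R peaks on available data, for the cardiac-phase encoding
  rp_rec <- lapply(seq_along(records), function(i) {
    sig <- records[[i]]$signal[, 2] * masks[[i]][, 2]
    rp <- tryCatch(pan_tompkins(sig, records[[i]]$fs),
                   error = function(e) integer(0))
    obs <- rowSums(masks[[i]]) == ncol(masks[[i]])
    rp[obs[rp + 1L]]
  })

  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(rep(seq_along(records), cfg$windows_per_record))
      ep_loss <- 0; n_pts <- 0L
      for (b0 in seq(1L, length(ord), by = cfg$batch_size)) {
        take <- ord[b0:min(b0 + cfg$batch_size - 1L, length(ord))]
        nw <- length(take)
        feats <- lapply(seq_len(L), function(l) matrix(0, nw * Wt, 4L))
        obs_wins <- vector("list", nw)
        query_rows <- vector("list", nw)
        targ <- NULL; ind <- NULL
        for (j in seq_along(take)) {
          i <- take[j]
          x <- records[[i]]$signal
          mk <- masks[[i]]
          Tn <- nrow(x)
          st <- if (Tn > Wt) sample.int(Tn - Wt + 1L, 1L) else 1L
          rows <- st:(st + Wt - 1L)
          glen <- sample(cfg$min_gap:cfg$tau_max, 1L)
          gpos <- sample.int(Wt - glen - 2L * cfg$min_gap, 1L) + cfg$min_gap
          gap <- gpos:(gpos + glen - 1L)
          wm <- mk[rows, , drop = FALSE]
          wm[gap, ] <- 0
          wx <- x[rows, , drop = FALSE]
          rp_w <- rp_rec[[i]] - (st - 1L)
          rp_w <- rp_w[rp_w >= 0L & rp_w < Wt]
          rp_w <- rp_w[!(rp_w + 1L) %in% gap]
          ft <- tft_features(wx * wm, wm, records[[i]]$fs, r_peaks = rp_w)
          dst <- ((j - 1L) * Wt + 1L):(j * Wt)
          for (l in seq_len(L)) feats[[l]][dst, ] <- ft$feats[[l]]
          obs_wins[[j]] <- ft$obs_time
          query_rows[[j]] <- (j - 1L) * Wt + gap
          targ <- rbind(targ, wx[gap, , drop = FALSE])
          ind <- rbind(ind, mk[rows, , drop = FALSE][gap, , drop = FALSE])
        }
        tp <- ad_tape()
        ids <- ad_bind_params(tp, params)
        net <- tft_net(tp, ids, feats, cfg, Wt, nw, obs_wins, query_rows)
        loss <- NULL
        for (qi in seq_len(nq)) {
          cols <- (qi - 1L) * L + seq_len(L)
          lq <- ad_pinball(tp, ad_cols(tp, net$pred, cols), targ,
                           cfg$quantiles[qi], indicator = ind)
          loss <- if (is.null(loss)) lq else ad_add(tp, loss, lq)
        }
        loss <- ad_scale(tp, loss, 1 / max(1, sum(ind)))
        grads <- ad_backward(tp, loss, as.list(ids))
        names(grads) <- names(ids)
        stp <- adam_step(params, grads, opt, lr = cfg$learning_rate)
        params <- stp$params; opt <- stp$state
        ep_loss <- ep_loss + as.numeric(ad_val(tp, loss)) * sum(ind)
        n_pts <- n_pts + sum(ind)
      }
      trace[ep] <- ep_loss / n_pts
      if (verbose)
        message(sprintf("tft epoch %d/%d pinball %.5f", ep, cfg$epochs,
                        trace[ep]))
    }
  })
  model$params <- params
  model$loss_trace <- trace
  model$trained <- TRUE
  model
}

# forward pass for a list of prepared windows; returns per-window prediction
# matrices (gap_len x L*nq)
tft_forward_windows <- function(model, wins) {
  cfg <- model$config
  Wt <- cfg$T_obs + cfg$tau_max
  L <- 12L
  nw <- length(wins)
  feats <- lapply(seq_len(L), function(l) matrix(0, nw * Wt, 4L))
  obs_wins <- vector("list", nw)
  query_rows <- vector("list", nw)
  for (j in seq_len(nw)) {
    ft <- wins[[j]]$features
    dst <- ((j - 1L) * Wt + 1L):(j * Wt)
    for (l in seq_len(L)) feats[[l]][dst, ] <- ft$feats[[l]]
    obs_wins[[j]] <- ft$obs_time
    query_rows[[j]] <- (j - 1L) * Wt + wins[[j]]$gap_local
  }
  tp <- ad_tape()
  ids <- ad_bind_params(tp, model$params)
  net <- tft_net(tp, ids, feats, cfg, Wt, nw, obs_wins, query_rows)
  pred <- ad_val(tp, net$pred)
  lens <- vapply(wins, function(w) length(w$gap_local), 0L)
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_len(nw), function(j)
    pred[starts[j]:ends[j], , drop = FALSE])
}

#' Reconstruct missing segments with the TFT
#'
#' Contiguous missing spans are tiled into chunks of at most `tau_max`
#' samples.  Each chunk is reconstructed inside a window of
#' `T_obs + tau_max` samples centred on it, conditioning on observed (and
#' previously imputed) context on both sides; the median quantile fills the
#' gap and the outer quantiles form the uncertainty band.  Chunks are
#' processed in waves so independent gaps share a batched forward pass;
#' within one long gap successive chunks re-condition on what was just
#' imputed.
#'
#' @param record a normalized [ecg_record()] with missing entries zeroed.
#' @param mask binary observation mask.
#' @param model a trained `tft_model`.
#' @param band two quantiles (subset of the model's quantile set) reported
#'   as the uncertainty band.
#' @return list with `record` (imputed), `lower`/`upper` (`T x L` matrices,
#'   `NA` at observed positions).
#' @export
tft_reconstruct <- function(record, mask, model, band = c(0.1, 0.9)) {
  stopifnot(inherits(record, "ecg_record"), inherits(model, "tft_model"))
  if (!model$trained)
    abort_state("model has not been trained.", "ecgmend_invalid_state")
  cfg <- model$config
  if (!all(band %in% cfg$quantiles))
    abort_bad_arg("`band` quantiles must belong to the model's quantile set.")
  Wt <- cfg$T_obs + cfg$tau_max
  L <- ncol(record$signal)
  nq <- length(cfg$quantiles)
  n <- nrow(record$signal)
  if (n < Wt)
    abort_bad_arg(sprintf("record shorter than one window (%d samples).", Wt))
  x <- record$signal * mask
  wmask <- mask
  lower <- matrix(NA_real_, n, L)
  upper <- matrix(NA_real_, n, L)
  miss_time <- which(rowSums(wmask) < L)
  if (length(miss_time) == 0)
    return(list(record = record, lower = lower, upper = upper))
  if (length(miss_time) == n)
    abort_state("no observed context at all: cannot reconstruct.",
                "ecgmend_no_context")

  # contiguous missing runs, tiled into tau_max chunks; a run with no
  # observed sample before it (record starts missing) is imputed from its
  # far end first, where observed context exists
  runs <- split(miss_time, cumsum(c(1, diff(miss_time) != 1)))
  chunk_list <- lapply(runs, function(r) {
    ch <- split(r, ceiling(seq_along(r) / cfg$tau_max))
    if (r[1] == 1L) ch <- rev(ch)
    ch
  })
  n_waves <- max(vapply(chunk_list, length, 0L))
  med_i <- which(cfg$quantiles == 0.5)
  lo_i <- which(cfg$quantiles == band[1])
  hi_i <- which(cfg$quantiles == band[2])

  for (wave in seq_len(n_waves)) {
    rp_all <- tryCatch(pan_tompkins(x[, 2] * wmask[, 2], record$fs),
                       error = function(e) integer(0))
    obs_now <- rowSums(wmask) == L
    rp_all <- rp_all[obs_now[rp_all + 1L]]
    wins <- list()
    meta <- list()
    for (g in seq_along(chunk_list)) {
      if (wave > length(chunk_list[[g]])) next
      chunk <- chunk_list[[g]][[wave]]
      ctx <- Wt - length(chunk)
      st <- max(1L, min(chunk[1] - ctx %/% 2L, n - Wt + 1L))
      rows <- st:(st + Wt - 1L)
      rp_w <- rp_all - (st - 1L)
      rp_w <- rp_w[rp_w >= 0L & rp_w < Wt]
      ft <- tft_features(x[rows, , drop = FALSE],
                         wmask[rows, , drop = FALSE], record$fs,
                         r_peaks = rp_w)
      wins[[length(wins) + 1L]] <-
        list(features = ft, gap_local = chunk - st + 1L)
      meta[[length(meta) + 1L]] <- chunk
    }
    if (length(wins) == 0) next
    inf_batch <- max(cfg$batch_size, 16L)
    for (b0 in seq(1L, length(wins), by = inf_batch)) {
      sel <- b0:min(b0 + inf_batch - 1L, length(wins))
      preds <- tft_forward_windows(model, wins[sel])
      for (k in seq_along(sel)) {
        chunk <- meta[[sel[k]]]
        pr <- array(preds[[k]], dim = c(length(chunk), L, nq))
        pr <- aperm(apply(pr, c(1, 2), sort), c(2, 3, 1))  # monotone bands
        imput <- pmin(pmax(pr[, , med_i], 0), 1)
        gap_mask <- wmask[chunk, , drop = FALSE] == 0
        xs <- x[chunk, , drop = FALSE]
        xs[gap_mask] <- imput[gap_mask]
        x[chunk, ] <- xs
        tmp <- lower[chunk, , drop = FALSE]
        tmp[gap_mask] <- pr[, , lo_i][gap_mask]
        lower[chunk, ] <- tmp
        tmp <- upper[chunk, , drop = FALSE]
        tmp[gap_mask] <- pr[, , hi_i][gap_mask]
        upper[chunk, ] <- tmp
        wmask[chunk, ] <- 1  # imputed context for later waves
      }
    }
  }
  out <- ecg_record(x, record$fs, record$lead_names, record$patient_id,
                    record$label, normalized = record$normalized,
                    scale_info = record$scale_info)
  list(record = out, lower = lower, upper = upper)
}

#' Quantile predictions for prepared inputs (heads only)
#'
#' Applies the per-(quantile, lead) linear heads to enriched features and
#' optionally enforces non-crossing quantiles by monotone rearrangement.
#'
#' @param theta `n x d_model` enriched features.
#' @param c_h `n x d_model` horizon context.
#' @param model a `tft_model`.
#' @param monotone sort the quantile axis (default `TRUE`).
#' @return `n x L x n_q` array.
#' @export
tft_quantile_heads <- function(theta, c_h, model, monotone = TRUE) {
  cfg <- model$config
  W <- model$params[["heads.W"]]
  b <- model$params[["heads.b"]]
  pred <- cbind(theta, c_h) %*% W + rep(as.numeric(b), each = nrow(theta))
  L <- ncol(pred) / length(cfg$quantiles)
  arr <- array(pred, dim = c(nrow(pred), L, length(cfg$quantiles)))
  if (monotone) arr <- aperm(apply(arr, c(1, 2), sort), c(2, 3, 1))
  arr
}
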