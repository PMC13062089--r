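# Neural building blocks shared by the denoiser, the masked VAE and the
# temporal fusion transformer: 1-D (transposed) convolutions expressed as
# row-gather + matmul, dense layers, gated residual networks, multi-head
# attention and sinusoidal positional encodings.
#
# Batching convention: B equal-length windows are stacked down the rows
# (window-major), so position-wise layers see one big matrix; convolution
# tap indices and attention are built per window so no operation leaks
# across window boundaries.

# Tap indices for a batched 1-D convolution ("same"-style padding).
# Returns list(kernel index vectors into rbind(zero_row, x)); index 1 is the
# zero-padding row.
conv_tap_indices <- function(T_in, kernel, stride, n_win) {
  T_out <- ceiling(T_in / stride)
  pad_total <- max(0L, (T_out - 1L) * stride + kernel - T_in)
  pad_left <- pad_total %/% 2L
  starts <- (seq_len(T_out) - 1L) * stride - pad_left
  offs <- rep((seq_len(n_win) - 1L) * T_in, each = T_out)
  lapply(seq_len(kernel) - 1L, function(j) {
    src <- rep(starts + j, n_win)            # 0-based within window
    out <- src + offs + 2L                   # +1 for 1-based, +1 for pad row
    out[src < 0 | src >= T_in] <- 1L         # zero-padding row
    out
  })
}

# x: (n_win*T_in) x C_in; W: (kernel*C_in) x C_out; b: 1 x C_out
nn_conv1d <- function(tp, x, W, b, taps) {
  ad_conv1d(tp, x, W, b, taps)
}

# Tap indices for a transposed (fractionally strided) convolution realised
# as zero-stuffing upsample composed with a stride-1 convolution; the
# upsample never materialises.  Output length per window: T_in * stride.
convt_tap_indices <- function(T_in, stride, kernel, n_win) {
  T_up <- T_in * stride
  up_src <- rep(0L, T_up)                     # 0 => zero row
  up_src[seq.int(1L, T_up, by = stride)] <- seq_len(T_in)
  base <- conv_tap_indices(T_up, kernel, 1L, n_win)
  lapply(base, function(ix) {
    # ix indexes rbind(0, upsampled); map through the upsample source
    win <- (ix - 2L) %/% T_up                 # window number (valid ix only)
    pos <- (ix - 2L) %% T_up + 1L
    src <- ifelse(ix == 1L, 0L, up_src[pos])
    ifelse(src == 0L, 1L, src + win * T_in + 1L)
  })
}

# GLU-style gated convolution: conv_A(x) * sigmoid(conv_B(x)).
# gate_override = 1 replaces the sigmoid gate by the constant 1 (tests).
nn_gated_conv1d <- function(tp, x, Wa, ba, Wb, bb, taps,
                            gate_override = NULL) {
  a <- nn_conv1d(tp, x, Wa, ba, taps)
  if (!is.null(gate_override)) {
    ad_scale(tp, a, gate_override)
  } else {
    ad_mul(tp, a, ad_sigmoid(tp, nn_conv1d(tp, x, Wb, bb, taps)))
  }
}

# zero-stuffing upsample per window: T_in rows -> T_in*stride rows
upsample_indices <- function(T_in, stride, n_win) {
  T_out <- T_in * stride
  src <- rep(0L, T_out)
  pos <- seq.int(1L, T_out, by = stride)
  src[pos] <- seq_len(T_in)
  idx <- unlist(lapply(seq_len(n_win) - 1L, function(w)
    ifelse(src == 0L, 0L, src + w * T_in)))
  idx + 1L  # 1 => zero row
}

nn_upsample <- function(tp, x, up_idx) {
  zrow <- ad_const(tp, matrix(0, 1L, ncol(v_(tp, x))))
  ad_rows(tp, ad_rbind(tp, c(zrow, x)), up_idx)
}

nn_dense <- function(tp, x, W, b) {
  ad_add_bias(tp, ad_matmul(tp, x, W), b)
}

# parameter initialisers ------------------------------------------------------

par_dense <- function(params, name, nin, nout, zero = FALSE) {
  params[[paste0(name, ".W")]] <- if (zero) matrix(0, nin, nout)
                                  else init_mat(nin, nout)
  params[[paste0(name, ".b")]] <- init_zeros(nout)
  params
}

par_conv <- function(params, name, kernel, cin, cout) {
  params[[paste0(name, ".W")]] <- init_mat(kernel * cin, cout)
  params[[paste0(name, ".b")]] <- init_zeros(cout)
  params
}

par_layernorm <- function(params, name, d) {
  params[[paste0(name, ".g")]] <- init_ones(d)
  params[[paste0(name, ".o")]] <- init_zeros(d)
  params
}

dense_f <- function(tp, ids, name, x) {
  nn_dense(tp, x, ids[[paste0(name, ".W")]], ids[[paste0(name, ".b")]])
}

layernorm_f <- function(tp, ids, name, x) {
  ad_layernorm_rows(tp, x, ids[[paste0(name, ".g")]],
                    ids[[paste0(name, ".o")]])
}

# Gated residual network (temporal-fusion-transformer building block):
#   y = LayerNorm(skip(x) + GLU(W2 %*% ELU(W1 x + Wc c + b1) + b2))
# `context` (optional) enters additively without bias; skip is a linear map
# when input and output widths differ.
par_grn <- function(params, name, d_in, d_hidden, d_out, d_context = NULL) {
  params <- par_dense(params, paste0(name, ".fc1"), d_in, d_hidden)
  if (!is.null(d_context))
    params[[paste0(name, ".ctx.W")]] <- init_mat(d_context, d_hidden)
  params <- par_dense(params, paste0(name, ".fc2"), d_hidden, d_out)
  params <- par_dense(params, paste0(name, ".glu"), d_out, 2L * d_out)
  if (d_in != d_out)
    params <- par_dense(params, paste0(name, ".skip"), d_in, d_out)
  params <- par_layernorm(params, paste0(name, ".ln"), d_out)
  params
}

grn_f <- function(tp, ids, name, x, context = NULL, d_out) {
  nm <- function(suf) ids[[paste0(name, suf)]]
  has_ctx <- paste0(name, ".ctx.W") %in% names(ids)
  has_skip <- paste0(name, ".skip.W") %in% names(ids)
  ad_grn_fused(tp, x, context,
               nm(".fc1.W"), nm(".fc1.b"),
               if (has_ctx) nm(".ctx.W") else NULL,
               nm(".fc2.W"), nm(".fc2.b"),
               nm(".glu.W"), nm(".glu.b"),
               if (has_skip) nm(".skip.W") else NULL,
               if (has_skip) nm(".skip.b") else NULL,
               nm(".ln.g"), nm(".ln.o"))
}

# Multi-head attention over one window.
# q_rows/k_rows: node ids for (Tq x d) and (Tk x d) matrices.
# col_mask: optional 0/1 vector over key positions; masked keys get logits
# -1e9, i.e. attention weight exactly 0 after the softmax floor is squashed.
# average_heads: mean over heads (interpretable variant) instead of concat.
par_mha <- function(params, name, d_model, n_heads, d_attn,
                    average_heads = FALSE) {
  for (h in seq_len(n_heads)) {
    params <- par_dense(params, sprintf("%s.q%d", name, h), d_model, d_attn)
    params <- par_dense(params, sprintf("%s.k%d", name, h), d_model, d_attn)
    params <- par_dense(params, sprintf("%s.v%d", name, h), d_model, d_attn)
  }
  d_cat <- if (average_heads) d_attn else n_heads * d_attn
  params <- par_dense(params, paste0(name, ".out"), d_cat, d_model)
  params
}

mha_f <- function(tp, ids, name, q_in, kv_in, n_heads, d_attn,
                  col_mask = NULL, average_heads = FALSE,
                  return_weights = FALSE) {
  heads <- vector("list", n_heads)
  wts <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    Q <- dense_f(tp, ids, sprintf("%s.q%d", name, h), q_in)
    K <- dense_f(tp, ids, sprintf("%s.k%d", name, h), kv_in)
    V <- dense_f(tp, ids, sprintf("%s.v%d", name, h), kv_in)
    heads[[h]] <- ad_attention(tp, Q, K, V, col_mask)
    wts[[h]] <- attr(heads[[h]], "weights")
  }
  merged <- if (average_heads) {
    acc <- heads[[1]]
    if (n_heads > 1)
      for (h in 2:n_heads) acc <- ad_add(tp, acc, heads[[h]])
    ad_scale(tp, acc, 1 / n_heads)
  } else {
    ad_cbind(tp, heads)
  }
  out <- dense_f(tp, ids, paste0(name, ".out"), merged)
  if (return_weights) list(out = out, weights = wts) else out
}

# classic transformer encoder block (post-norm), batched over windows:
# attention runs per window, the feed-forward is position-wise.
par_transformer_layer <- function(params, name, d_model, n_heads, d_ff) {
  params <- par_mha(params, paste0(name, ".mha"), d_model, n_heads,
                    d_model %/% n_heads)
  params <- par_layernorm(params, paste0(name, ".ln1"), d_model)
  params <- par_dense(params, paste0(name, ".ff1"), d_model, d_ff)
  params <- par_dense(params, paste0(name, ".ff2"), d_ff, d_model)
  params <- par_layernorm(params, paste0(name, ".ln2"), d_model)
  params
}

transformer_layer_f <- function(tp, ids, name, x, n_heads, d_model,
                                T_win, n_win) {
  att_wins <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    rows <- ((w - 1L) * T_win + 1L):(w * T_win)
    xw <- ad_rows(tp, x, rows)
    att_wins[[w]] <- mha_f(tp, ids, paste0(name, ".mha"), xw, xw,
                           n_heads, d_model %/% n_heads)
  }
  att <- if (n_win == 1L) att_wins[[1]] else ad_rbind(tp, att_wins)
  h <- layernorm_f(tp, ids, paste0(name, ".ln1"), ad_add(tp, x, att))
  ff <- dense_f(tp, ids, paste0(name, ".ff2"),
                ad_relu(tp, dense_f(tp, ids, paste0(name, ".ff1"), h)))
  layernorm_f(tp, ids, paste0(name, ".ln2"), ad_add(tp, h, ff))
}

# sinusoidal positional encoding matrix (T x d)
sinusoidal_pe <- function(T_len, d) {
  pos <- seq_len(T_len) - 1L
  pe <- matrix(0, T_len, d)
  for (i in seq_len(ceiling(d / 2))) {
    freq <- 1 / 10000^((2 * (i - 1)) / d)
    pe[, 2 * i - 1] <- sin(pos * freq)
    if (2 * i <= d) pe[, 2 * i] <- cos(pos * freq)
  }
  pe
}
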