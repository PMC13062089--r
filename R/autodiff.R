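# Reverse-mode automatic differentiation on a flat tape of matrix nodes.
#
# All neural components in the package (denoising autoencoder, masked VAE,
# temporal fusion transformer) are built on these primitives.  A node is an
# integer index into the tape; values are numeric matrices.  Backward
# functions are closures capturing the parent values they need, returning one
# gradient per parent.  Gradients are accumulated by a single reverse sweep.

ad_tape <- function(reserve = 0L) {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- new.env(hash = TRUE, parent = emptyenv())
  tp$n <- 0L
  tp
}

ad_push <- function(tp, val, parents = integer(0), back = NULL) {
  force(val); force(parents); force(back)
  n <- tp$n + 1L
  tp$n <- n
  assign(as.character(n),
         list(val = val, parents = parents, back = back),
         envir = tp$nodes)
  n
}

# internal: fetch a node value
v_ <- function(tp, id) {
  force(id)
  get(as.character(id), envir = tp$nodes, inherits = FALSE)$val
}

ad_val <- function(tp, id) v_(tp, id)

ad_const <- function(tp, x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  ad_push(tp, x)
}

#' @noRd
ad_backward <- function(tp, loss_id, wrt) {
  grads <- new.env(hash = TRUE, parent = emptyenv())
  nodes <- tp$nodes
  lv <- v_(tp, loss_id)
  assign(as.character(loss_id), array(1, dim = dim(as.matrix(lv))), envir = grads)
  for (i in seq.int(loss_id, 1L)) {
    ki <- as.character(i)
    g <- get0(ki, envir = grads, inherits = FALSE)
    if (is.null(g)) next
    nd <- get(ki, envir = nodes, inherits = FALSE)
    if (is.null(nd$back)) next
    pg <- nd$back(g)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      gj <- pg[[j]]
      if (is.null(gj)) next
      kp <- as.character(ps[[j]])
      cur <- get0(kp, envir = grads, inherits = FALSE)
      assign(kp, if (is.null(cur)) gj else cur + gj, envir = grads)
    }
  }
  lapply(wrt, function(i) {
    g <- get0(as.character(i), envir = grads, inherits = FALSE)
    if (is.null(g)) array(0, dim = dim(as.matrix(v_(tp, i)))) else g
  })
}

# ---- elementwise / linear primitives ---------------------------------------

ad_add <- function(tp, a, b) {
  force(a)
  force(b)
  ad_push(tp, v_(tp, a) + v_(tp, b), c(a, b),
          function(g) list(g, g))
}

# bias: length-n numeric (or 1 x n) added to every row of a (m x n)
ad_add_bias <- function(tp, a, bias) {
  force(a)
  force(bias)
  bv <- v_(tp, bias)
  av <- v_(tp, a)
  ad_push(tp, av + rep(as.numeric(bv), each = nrow(av)), c(a, bias),
          function(g) list(g, matrix(colSums(g), 1L)))
}

ad_sub <- function(tp, a, b) {
  force(a)
  force(b)
  ad_push(tp, v_(tp, a) - v_(tp, b), c(a, b),
          function(g) list(g, -g))
}

ad_mul <- function(tp, a, b) {
  force(a)
  force(b)
  av <- v_(tp, a); bv <- v_(tp, b)
  ad_push(tp, av * bv, c(a, b),
          function(g) list(g * bv, g * av))
}

ad_scale <- function(tp, a, k) {
  force(a)
  ad_push(tp, v_(tp, a) * k, a, function(g) list(g * k))
}

ad_matmul <- function(tp, a, b) {
  force(a)
  force(b)
  av <- v_(tp, a); bv <- v_(tp, b)
  ad_push(tp, av %*% bv, c(a, b),
          function(g) list(g %*% t(bv), crossprod(av, g)))
}

ad_sigmoid <- function(tp, a) {
  force(a)
  y <- 1 / (1 + exp(-v_(tp, a)))
  ad_push(tp, y, a, function(g) list(g * y * (1 - y)))
}

ad_tanh <- function(tp, a) {
  force(a)
  y <- tanh(v_(tp, a))
  ad_push(tp, y, a, function(g) list(g * (1 - y * y)))
}

ad_relu <- function(tp, a) {
  force(a)
  v <- v_(tp, a)
  keep <- v > 0
  ad_push(tp, v * keep, a, function(g) list(g * keep))
}

ad_elu <- function(tp, a) {
  force(a)
  v <- v_(tp, a)
  neg <- v <= 0
  y <- ifelse(neg, expm1(v), v)
  ad_push(tp, y, a, function(g) list(g * ifelse(neg, y + 1, 1)))
}

ad_exp <- function(tp, a) {
  force(a)
  y <- exp(v_(tp, a))
  ad_push(tp, y, a, function(g) list(g * y))
}

ad_log <- function(tp, a) {
  force(a)
  v <- v_(tp, a)
  ad_push(tp, log(v), a, function(g) list(g / v))
}

ad_sqrt <- function(tp, a) {
  force(a)
  y <- sqrt(v_(tp, a))
  ad_push(tp, y, a, function(g) list(g / (2 * y)))
}

ad_square <- function(tp, a) {
  force(a)
  v <- v_(tp, a)
  ad_push(tp, v * v, a, function(g) list(2 * g * v))
}

ad_div <- function(tp, a, b) {
  force(a)
  force(b)
  av <- v_(tp, a); bv <- v_(tp, b)
  ad_push(tp, av / bv, c(a, b),
          function(g) list(g / bv, -g * av / (bv * bv)))
}

ad_softplus <- function(tp, a) {
  force(a)
  v <- v_(tp, a)
  # numerically stable log(1 + exp(v))
  y <- pmax(v, 0) + log1p(exp(-abs(v)))
  s <- 1 / (1 + exp(-v))
  ad_push(tp, y, a, function(g) list(g * s))
}

# ---- reductions ------------------------------------------------------------

ad_sum <- function(tp, a) {
  force(a)
  d <- dim(v_(tp, a))
  ad_push(tp, matrix(sum(v_(tp, a)), 1L, 1L), a,
          function(g) list(array(as.numeric(g), dim = d)))
}

ad_mean <- function(tp, a) {
  force(a)
  v <- v_(tp, a)
  d <- dim(v); nel <- length(v)
  ad_push(tp, matrix(mean(v), 1L, 1L), a,
          function(g) list(array(as.numeric(g) / nel, dim = d)))
}

ad_colsums <- function(tp, a) {
  force(a)
  v <- v_(tp, a)
  nr <- nrow(v)
  ad_push(tp, matrix(colSums(v), 1L), a,
          function(g) list(matrix(rep(as.numeric(g), each = nr), nr)))
}

ad_rowsums <- function(tp, a) {
  force(a)
  v <- v_(tp, a)
  nc <- ncol(v)
  ad_push(tp, matrix(rowSums(v), ncol = 1L), a,
          function(g) list(matrix(as.numeric(g), nrow(v), nc)))
}

# ---- shape ops -------------------------------------------------------------

ad_t <- function(tp, a) {
  force(a)
  ad_push(tp, t(v_(tp, a)), a, function(g) list(t(g)))
}

ad_cbind <- function(tp, ids) {
  force(ids)
  vals <- lapply(ids, function(i) v_(tp, i))
  ncols <- vapply(vals, ncol, 1L)
  ends <- cumsum(ncols)
  starts <- c(1L, head(ends, -1L) + 1L)
  ad_push(tp, do.call(cbind, vals), as.integer(ids),
          function(g) lapply(seq_along(ids), function(j)
            g[, starts[j]:ends[j], drop = FALSE]))
}

ad_rbind <- function(tp, ids) {
  force(ids)
  vals <- lapply(ids, function(i) v_(tp, i))
  nrows <- vapply(vals, nrow, 1L)
  ends <- cumsum(nrows)
  starts <- c(1L, head(ends, -1L) + 1L)
  ad_push(tp, do.call(rbind, vals), as.integer(ids),
          function(g) lapply(seq_along(ids), function(j)
            g[starts[j]:ends[j], , drop = FALSE]))
}

# row gather; scatter-adds on the way back (idx may repeat)
ad_rows <- function(tp, a, idx) {
  force(a)
  v <- v_(tp, a)
  nr <- nrow(v); nc <- ncol(v)
  idx <- as.integer(idx)
  ad_push(tp, v[idx, , drop = FALSE], a, function(g) {
    acc <- rowsum(g, group = idx, reorder = TRUE)
    out <- matrix(0, nr, nc)
    out[as.integer(rownames(acc)), ] <- acc
    list(out)
  })
}

ad_cols <- function(tp, a, idx) {
  force(a)
  v <- v_(tp, a)
  idx <- as.integer(idx)
  nc <- ncol(v)
  ad_push(tp, v[, idx, drop = FALSE], a, function(g) {
    out <- matrix(0, nrow(v), nc)
    # column indices are assumed distinct (slicing), enforced by callers
    out[, idx] <- g
    list(out)
  })
}

# zeros interleaved between rows: used by transposed (fractionally strided) conv
ad_upsample_rows <- function(tp, a, stride, out_len) {
  force(a)
  v <- v_(tp, a)
  pos <- seq.int(1L, by = stride, length.out = nrow(v))
  stopifnot(max(pos) <= out_len)
  val <- matrix(0, out_len, ncol(v))
  val[pos, ] <- v
  ad_push(tp, val, a, function(g) list(g[pos, , drop = FALSE]))
}

# ---- normalisation / attention ---------------------------------------------

ad_softmax_rows <- function(tp, a) {
  force(a)
  v <- v_(tp, a)
  m <- apply(v, 1L, max)
  e <- exp(v - m)
  y <- e / rowSums(e)
  ad_push(tp, y, a, function(g) {
    list(y * (g - rowSums(g * y)))
  })
}

ad_layernorm_rows <- function(tp, x, gamma, beta, eps = 1e-5) {
  force(x)
  force(gamma)
  force(beta)
  v <- v_(tp, x)
  gm <- as.numeric(v_(tp, gamma))
  bt <- as.numeric(v_(tp, beta))
  mu <- rowMeans(v)
  xc <- v - mu
  s <- sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc / s
  y <- xhat * rep(gm, each = nrow(v)) + rep(bt, each = nrow(v))
  ad_push(tp, y, c(x, gamma, beta), function(g) {
    ghat <- g * rep(gm, each = nrow(v))
    dx <- (ghat - rowMeans(ghat) - xhat * rowMeans(ghat * xhat)) / s
    list(dx,
         matrix(colSums(g * xhat), 1L),
         matrix(colSums(g), 1L))
  })
}

# ---- fused losses ----------------------------------------------------------

# mean Huber loss, optional elementwise weights (constant matrix)
ad_huber <- function(tp, pred, target, delta, weights = NULL) {
  force(pred)
  pv <- v_(tp, pred)
  tv <- if (is.numeric(target)) target else v_(tp, target)
  r <- pv - tv
  a <- abs(r)
  h <- ifelse(a <= delta, 0.5 * r * r, delta * (a - 0.5 * delta))
  w <- if (is.null(weights)) 1 else weights
  nel <- length(r)
  ad_push(tp, matrix(sum(w * h) / nel, 1L, 1L), pred, function(g) {
    list(as.numeric(g) * w * pmin(pmax(r, -delta), delta) / nel)
  })
}

# sum of pinball (quantile) losses over entries with indicator 1
ad_pinball <- function(tp, pred, target, q, indicator = NULL) {
  force(pred)
  pv <- v_(tp, pred)
  tv <- if (is.numeric(target)) target else v_(tp, target)
  ind <- if (is.null(indicator)) 1 else indicator
  u <- tv - pv
  p <- pmax(q * u, (q - 1) * u)
  ad_push(tp, matrix(sum(ind * p), 1L, 1L), pred, function(g) {
    du <- ifelse(u > 0, q, ifelse(u < 0, q - 1, 0))
    list(-as.numeric(g) * ind * du)
  })
}

# mean weighted Huber loss on DFT magnitudes, per column (lead).
# d/dx sum_k f(|X_k|) = Re(fft(c)) with c_k = f'(|X_k|) * Conj(X_k)/|X_k|.
ad_spectral_huber <- function(tp, pred, target, delta, bin_weights) {
  force(pred)
  pv <- v_(tp, pred)
  tv <- if (is.numeric(target)) target else v_(tp, target)
  n <- nrow(pv)
  # magnitudes scaled by 1/n so the spectral residual is commensurate with
  # the time-domain amplitudes (and with the same Huber delta)
  P <- stats::mvfft(pv)
  Tm <- Mod(stats::mvfft(tv)) / n
  Pm <- Mod(P) / n
  r <- Pm - Tm
  a <- abs(r)
  h <- ifelse(a <= delta, 0.5 * r * r, delta * (a - 0.5 * delta))
  w <- bin_weights  # length nrow(pv), recycled over columns
  nel <- length(r)
  val <- sum(w * h) / nel
  ad_push(tp, matrix(val, 1L, 1L), pred, function(g) {
    fp <- w * pmin(pmax(r, -delta), delta) / (nel * n)
    safe <- Pm > 1e-12
    C <- matrix(0 + 0i, n, ncol(pv))
    C[safe] <- fp[safe] * Conj(P[safe]) / (Pm[safe] * n)
    list(as.numeric(g) * Re(stats::mvfft(C)))
  })
}

# ---- parameter store and optimiser -----------------------------------------

# parameters live in a named list of matrices; each forward pass pushes them
# onto a fresh tape and records the mapping name -> node id.
ad_bind_params <- function(tp, params) {
  ids <- vapply(params, function(p) ad_push(tp, p), 0L)
  names(ids) <- names(params)
  ids
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(as.matrix(p)))),
       v = lapply(params, function(p) array(0, dim = dim(as.matrix(p)))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (k in seq_along(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    mhat <- state$m[[k]] / b1t
    vhat <- state$v[[k]] / b2t
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Glorot-uniform initialiser used across models
init_mat <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

init_zeros <- function(n) matrix(0, 1L, n)
init_ones <- function(n) matrix(1, 1L, n)

# ---- fused sequence LSTM ----------------------------------------------------

# Full-sequence LSTM as a single tape node with hand-written BPTT.
# x_seq: (T*B) x d_in, time-major blocks of B rows (rows (t-1)*B + 1..t*B are
# step t).  Returns the hidden-state sequence (T*B) x d_h.  Gradients flow to
# x_seq, Wx (d_in x 4d_h), Wh (d_h x 4d_h) and b (1 x 4d_h).  Gate order in
# the weight matrices: input, forget, output, candidate.
ad_lstm <- function(tp, x_seq, Wx, Wh, b, n_steps, batch) {
  force(x_seq); force(Wx); force(Wh); force(b)
  X <- v_(tp, x_seq)
  Wxv <- v_(tp, Wx); Whv <- v_(tp, Wh); bv <- as.numeric(v_(tp, b))
  d_in <- ncol(X); d_h <- ncol(Wxv) / 4L
  stopifnot(nrow(X) == n_steps * batch, nrow(Wxv) == d_in, ncol(Wxv) %% 4L == 0)
  i1 <- 1:d_h; i2 <- d_h + i1; i3 <- 2L * d_h + i1; i4 <- 3L * d_h + i1

  H <- matrix(0, n_steps * batch, d_h)
  cache <- vector("list", n_steps)
  h <- matrix(0, batch, d_h); cc <- matrix(0, batch, d_h)
  bmat <- rep(bv, each = batch)
  for (t in seq_len(n_steps)) {
    rows <- ((t - 1L) * batch + 1L):(t * batch)
    xt <- X[rows, , drop = FALSE]
    z <- xt %*% Wxv + h %*% Whv + bmat
    ig <- 1 / (1 + exp(-z[, i1, drop = FALSE]))
    fg <- 1 / (1 + exp(-z[, i2, drop = FALSE]))
    og <- 1 / (1 + exp(-z[, i3, drop = FALSE]))
    gg <- tanh(z[, i4, drop = FALSE])
    c_prev <- cc
    cc <- fg * c_prev + ig * gg
    tc <- tanh(cc)
    h <- og * tc
    H[rows, ] <- h
    cache[[t]] <- list(ig = ig, fg = fg, og = og, gg = gg,
                       c_prev = c_prev, tc = tc)
  }

  ad_push(tp, H, c(x_seq, Wx, Wh, b), function(gH) {
    dX <- matrix(0, nrow(X), d_in)
    dWx <- matrix(0, d_in, 4L * d_h)
    dWh <- matrix(0, d_h, 4L * d_h)
    db <- numeric(4L * d_h)
    dh_next <- matrix(0, batch, d_h)
    dc_next <- matrix(0, batch, d_h)
    for (t in seq.int(n_steps, 1L)) {
      rows <- ((t - 1L) * batch + 1L):(t * batch)
      ch <- cache[[t]]
      dh <- gH[rows, , drop = FALSE] + dh_next
      dc <- dc_next + dh * ch$og * (1 - ch$tc^2)
      d_og <- dh * ch$tc
      d_ig <- dc * ch$gg
      d_fg <- dc * ch$c_prev
      d_gg <- dc * ch$ig
      dc_next <- dc * ch$fg
      dz <- cbind(d_ig * ch$ig * (1 - ch$ig),
                  d_fg * ch$fg * (1 - ch$fg),
                  d_og * ch$og * (1 - ch$og),
                  d_gg * (1 - ch$gg^2))
      xt <- X[rows, , drop = FALSE]
      h_prev <- if (t > 1L) H[rows - batch, , drop = FALSE] else
        matrix(0, batch, d_h)
      dX[rows, ] <- dz %*% t(Wxv)
      dh_next <- dz %*% t(Whv)
      dWx <- dWx + crossprod(xt, dz)
      dWh <- dWh + crossprod(h_prev, dz)
      db <- db + colSums(dz)
    }
    list(dX, dWx, dWh, matrix(db, 1L))
  })
}

# ---- fused batched 1-D convolution -----------------------------------------

# One tape node for an im2col convolution.  `taps` is a list of `kernel`
# index vectors into rbind(zero_row, x) (index 1 = zero padding row), as
# built by conv_tap_indices()/convt_tap_indices().  Within one tap the
# indices are distinct, so the backward scatter is direct indexed addition.
ad_conv1d <- function(tp, x, W, b, taps) {
  force(x); force(W); force(b)
  X <- v_(tp, x)
  Wv <- v_(tp, W); bv <- as.numeric(v_(tp, b))
  cin <- ncol(X)
  Xp <- rbind(matrix(0, 1L, cin), X)
  Xcol <- do.call(cbind, lapply(taps, function(ix) Xp[ix, , drop = FALSE]))
  val <- Xcol %*% Wv
  val <- val + rep(bv, each = nrow(val))
  ad_push(tp, val, c(x, W, b), function(g) {
    dW <- crossprod(Xcol, g)
    db <- matrix(colSums(g), 1L)
    dXcol <- g %*% t(Wv)
    dX <- matrix(0, nrow(X), cin)
    for (j in seq_along(taps)) {
      ix <- taps[[j]]
      keep <- ix > 1L
      block <- dXcol[, ((j - 1L) * cin + 1L):(j * cin), drop = FALSE]
      rows <- ix[keep] - 1L
      dX[rows, ] <- dX[rows, ] + block[keep, , drop = FALSE]
    }
    list(dX, dW, db)
  })
}

# reshape window-major rows into one row per window (column-major flatten of
# each T_win x C block); inverse on the way back
ad_flatten_wins <- function(tp, a, T_win, n_win) {
  force(a)
  v <- v_(tp, a)
  C <- ncol(v)
  val <- matrix(0, n_win, T_win * C)
  for (w in seq_len(n_win))
    val[w, ] <- as.numeric(v[((w - 1L) * T_win + 1L):(w * T_win), ])
  ad_push(tp, val, a, function(g) {
    out <- matrix(0, nrow(v), C)
    for (w in seq_len(n_win))
      out[((w - 1L) * T_win + 1L):(w * T_win), ] <- matrix(g[w, ], T_win, C)
    list(out)
  })
}

# inverse of ad_flatten_wins: one row per window -> window-major rows
ad_unflatten_wins <- function(tp, a, T_win, C) {
  force(a)
  v <- v_(tp, a)
  n_win <- nrow(v)
  val <- matrix(0, n_win * T_win, C)
  for (w in seq_len(n_win))
    val[((w - 1L) * T_win + 1L):(w * T_win), ] <- matrix(v[w, ], T_win, C)
  ad_push(tp, val, a, function(g) {
    out <- matrix(0, n_win, T_win * C)
    for (w in seq_len(n_win))
      out[w, ] <- as.numeric(g[((w - 1L) * T_win + 1L):(w * T_win), ])
    list(out)
  })
}

# elementwise multiply every column of a by a column-vector node (m x 1)
ad_mul_bcast_col <- function(tp, a, colvec) {
  force(a); force(colvec)
  av <- v_(tp, a)
  cv <- as.numeric(v_(tp, colvec))
  ad_push(tp, av * cv, c(a, colvec), function(g) {
    list(g * cv, matrix(rowSums(g * av), ncol = 1L))
  })
}

# Variable-selection combine: sel is (L*rows) x d (lead-major blocks),
# v is rows x L of softmax weights; output rows x d = sum_l v[, l] * block_l.
ad_vsn_combine <- function(tp, sel, v) {
  force(sel); force(v)
  sv <- v_(tp, sel)
  vv <- v_(tp, v)
  rows <- nrow(vv); L <- ncol(vv); d <- ncol(sv)
  out <- matrix(0, rows, d)
  for (l in seq_len(L)) {
    blk <- sv[((l - 1L) * rows + 1L):(l * rows), , drop = FALSE]
    out <- out + blk * vv[, l]
  }
  ad_push(tp, out, c(sel, v), function(g) {
    dsel <- matrix(0, nrow(sv), d)
    dv <- matrix(0, rows, L)
    for (l in seq_len(L)) {
      idx <- ((l - 1L) * rows + 1L):(l * rows)
      blk <- sv[idx, , drop = FALSE]
      dsel[idx, ] <- g * vv[, l]
      dv[, l] <- rowSums(g * blk)
    }
    list(dsel, dv)
  })
}

# Fused gated residual network:
#   y = LayerNorm(skip(x) + GLU(W2 ELU(W1 x + b1 [+ Wc c]) + b2))
# One tape node; hand-written backward.  ctx, Ws/bs may be NULL (no context
# / identity skip).
ad_grn_fused <- function(tp, x, ctx, W1, b1, Wc, W2, b2, Wg, bg, Ws, bs,
                         gam, bet, eps = 1e-5) {
  force(x); force(ctx); force(W1); force(b1); force(Wc); force(W2)
  force(b2); force(Wg); force(bg); force(Ws); force(bs); force(gam)
  force(bet)
  X <- v_(tp, x)
  Cv <- if (is.null(ctx)) NULL else v_(tp, ctx)
  W1v <- v_(tp, W1); b1v <- as.numeric(v_(tp, b1))
  Wcv <- if (is.null(Wc)) NULL else v_(tp, Wc)
  W2v <- v_(tp, W2); b2v <- as.numeric(v_(tp, b2))
  Wgv <- v_(tp, Wg); bgv <- as.numeric(v_(tp, bg))
  Wsv <- if (is.null(Ws)) NULL else v_(tp, Ws)
  bsv <- if (is.null(bs)) NULL else as.numeric(v_(tp, bs))
  gamv <- as.numeric(v_(tp, gam)); betv <- as.numeric(v_(tp, bet))
  nr <- nrow(X)
  d <- length(gamv)

  h1 <- X %*% W1v
  if (!is.null(Wcv)) h1 <- h1 + Cv %*% Wcv
  h1 <- h1 + rep(b1v, each = nr)
  neg <- h1 <= 0
  a <- h1
  a[neg] <- expm1(h1[neg])
  h2 <- a %*% W2v + rep(b2v, each = nr)
  u <- h2 %*% Wgv + rep(bgv, each = nr)
  val <- u[, seq_len(d), drop = FALSE]
  gate <- 1 / (1 + exp(-u[, d + seq_len(d), drop = FALSE]))
  gl <- val * gate
  sk <- if (is.null(Wsv)) X else X %*% Wsv + rep(bsv, each = nr)
  y0 <- sk + gl
  mu <- rowMeans(y0)
  xc <- y0 - mu
  sdv <- sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc / sdv
  y <- xhat * rep(gamv, each = nr) + rep(betv, each = nr)

  parents <- c(x, if (!is.null(ctx)) ctx, W1, b1, if (!is.null(Wc)) Wc,
               W2, b2, Wg, bg, if (!is.null(Ws)) Ws,
               if (!is.null(bs)) bs, gam, bet)
  ad_push(tp, y, parents, function(gy) {
    ghat <- gy * rep(gamv, each = nr)
    dy0 <- (ghat - rowMeans(ghat) - xhat * rowMeans(ghat * xhat)) / sdv
    dgam <- matrix(colSums(gy * xhat), 1L)
    dbet <- matrix(colSums(gy), 1L)
    dval <- dy0 * gate
    dgate_u <- dy0 * val * gate * (1 - gate)
    du <- cbind(dval, dgate_u)
    dWg <- crossprod(h2, du)
    dbg <- matrix(colSums(du), 1L)
    dh2 <- du %*% t(Wgv)
    dW2 <- crossprod(a, dh2)
    db2 <- matrix(colSums(dh2), 1L)
    da <- dh2 %*% t(W2v)
    dh1 <- da
    dh1[neg] <- da[neg] * (a[neg] + 1)
    dW1 <- crossprod(X, dh1)
    db1 <- matrix(colSums(dh1), 1L)
    dx <- dh1 %*% t(W1v)
    out <- list(dx)
    if (!is.null(Wcv)) {
      out$dctx <- dh1 %*% t(Wcv)
      dWc <- crossprod(Cv, dh1)
    }
    if (is.null(Wsv)) {
      dx <- dx + dy0
      out[[1]] <- dx
      c(out[1], if (!is.null(Wcv)) list(out$dctx),
        list(dW1, db1), if (!is.null(Wcv)) list(dWc),
        list(dW2, db2, dWg, dbg, dgam, dbet))
    } else {
      dWs <- crossprod(X, dy0)
      dbs <- matrix(colSums(dy0), 1L)
      dx <- dx + dy0 %*% t(Wsv)
      out[[1]] <- dx
      c(out[1], if (!is.null(Wcv)) list(out$dctx),
        list(dW1, db1), if (!is.null(Wcv)) list(dWc),
        list(dW2, db2, dWg, dbg, dWs, dbs, dgam, dbet))
    }
  })
}

# Fused scaled-dot-product attention for one head:
#   A = softmax(Q K' / sqrt(d)), masked key columns forced to exactly 0;
#   out = A V.  Backward is the standard softmax/attention gradient.
ad_attention <- function(tp, Q, K, V, col_mask = NULL) {
  force(Q); force(K); force(V)
  Qv <- v_(tp, Q); Kv <- v_(tp, K); Vv <- v_(tp, V)
  sc <- 1 / sqrt(ncol(Qv))
  logits <- tcrossprod(Qv, Kv) * sc
  if (!is.null(col_mask)) logits[, col_mask == 0] <- -Inf
  mx <- apply(logits, 1L, max)
  e <- exp(logits - mx)
  A <- e / rowSums(e)
  if (!is.null(col_mask)) A[, col_mask == 0] <- 0
  out <- A %*% Vv
  nd <- ad_push(tp, out, c(Q, K, V), function(g) {
    dV <- crossprod(A, g)
    dA <- tcrossprod(g, Vv)
    dlog <- A * (dA - rowSums(dA * A))
    list(dlog %*% Kv * sc, crossprod(dlog, Qv) * sc, dV)
  })
  attr(nd, "weights") <- A
  nd
}
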