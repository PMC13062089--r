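tiny_tft <- function() fixture("tiny_tft", function()
  ecgmend:::new_tft_model(tft_config()))

test_that("pinball loss matches its max-form definition", {
  expect_equal(pinball_loss(1, 1, 0.5), 0)
  expect_equal(pinball_loss(1 + 0.3, 1, 0.5), 0.15)
  expect_equal(pinball_loss(1 - 0.3, 1, 0.5), 0.15)
  expect_equal(pinball_loss(2, 1, 0.9), 0.9)  # u = 1, branch q*u
  expect_equal(pinball_loss(0, 1, 0.9), 0.1)  # u = -1, branch (q-1)*u
  expect_error(pinball_loss(1, 1, 0), class = "ecgmend_invalid_argument")
  # exhaustive small grid against max(q*u, (q-1)*u)
  for (q in c(0.1, 0.25, 0.5, 0.75, 0.9))
    for (u in seq(-2, 2, by = 0.25))
      expect_equal(pinball_loss(u, 0, q), max(q * u, (q - 1) * u))
})

test_that("the empirical quantile minimises the mean pinball loss", {
  set.seed(14)
  for (q in c(0.1, 0.5, 0.9)) {
    y <- rnorm(25)
    grid <- seq(min(y) - 0.5, max(y) + 0.5, length.out = 400)
    risk <- sapply(grid, function(c) mean(pinball_loss(y, c, q)))
    best <- grid[which.min(risk)]
    expect_lt(abs(best - stats::quantile(y, q, type = 1)), 0.05)
  }
})

test_that("the total quantile loss sums only over indicated entries", {
  # 2 timesteps x 1 lead, Q = {0.5}, residuals (0.2, -0.4): 0.1 + 0.2
  targ <- matrix(c(1.2, 0.6), 2, 1)
  pred <- matrix(c(1.0, 1.0), 2, 1)
  expect_equal(tft_loss(targ, pred, matrix(1, 2, 1), 0.5), 0.3)
  # all-zero indicator kills the loss regardless of predictions
  expect_equal(tft_loss(targ, pred + 100, matrix(0, 2, 1), 0.5), 0)
  # perfect predictions at every quantile
  p3 <- cbind(targ, targ, targ)
  expect_equal(tft_loss(targ, p3, matrix(1, 2, 1), c(0.1, 0.5, 0.9)), 0)
  expect_error(tft_loss(targ, pred[1, , drop = FALSE], matrix(1, 2, 1), 0.5),
               class = "ecgmend_invalid_argument")
})

test_that("indicator zeroing is invariant to perturbing unobserved entries", {
  set.seed(15)
  for (i in 1:1000) {
    n <- 6; L <- 3
    targ <- matrix(rnorm(n * L), n, L)
    pred <- matrix(rnorm(n * L * 3), n, L * 3)
    ind <- matrix(rbinom(n * L, 1, 0.6), n, L)
    l1 <- tft_loss(targ, pred, ind, c(0.1, 0.5, 0.9))
    targ2 <- targ
    targ2[ind == 0] <- targ2[ind == 0] + rnorm(sum(ind == 0), 0, 10)
    expect_equal(tft_loss(targ2, pred, ind, c(0.1, 0.5, 0.9)), l1)
  }
})

test_that("gated residual network reduces to LayerNorm(skip) at zero weights", {
  pg <- tft_grn_params(4, 8, 4, seed = 3)
  pz <- lapply(pg, function(m) m * 0)
  pz[["g.ln.g"]] <- pg[["g.ln.g"]]  # keep unit layernorm gain
  x <- matrix(rnorm(20), 5, 4)
  out <- tft_grn(x, pz, d_out = 4)
  mu <- rowMeans(x)
  s <- sqrt(rowMeans((x - mu)^2) + 1e-5)
  expect_equal(out, (x - mu) / s, tolerance = 1e-9)
  # repeatability and finiteness under large inputs
  pg2 <- tft_grn_params(4, 8, 6, seed = 5)
  expect_identical(tft_grn(x, pg2, d_out = 6), tft_grn(x, pg2, d_out = 6))
  expect_true(all(is.finite(tft_grn(x * 100, pg2, d_out = 6))))
})

test_that("interpretable attention matches a brute-force oracle and masks exactly", {
  # single head, d_attn 1, hand-set projections
  Q <- matrix(c(1, 2), 2, 1); K <- matrix(c(0.5, -1), 2, 1)
  V <- matrix(c(3, 4), 2, 1)
  r <- interpretable_mha(Q, K, V, list(matrix(2)), list(matrix(1)),
                         list(matrix(0.5)))
  lg <- (Q * 2) %*% t(K) / 1
  A <- exp(lg); A <- A / rowSums(A)
  expect_equal(r$weights[[1]], A, tolerance = 1e-12)
  expect_equal(r$output, A %*% (V * 0.5), tolerance = 1e-12)

  # sequence length 1, no mask: weight exactly 1
  r1 <- interpretable_mha(matrix(1, 1, 1), matrix(2, 1, 1), matrix(5, 1, 1),
                          list(matrix(1)), list(matrix(1)), list(matrix(1)))
  expect_equal(as.numeric(r1$weights[[1]]), 1)
  expect_equal(as.numeric(r1$output), 5)

  # masked key columns get weight exactly 0; rows still sum to 1
  set.seed(16)
  for (i in 1:1000) {
    Tk <- sample(3:8, 1)
    msk <- rbinom(Tk, 1, 0.6)
    if (all(msk == 0)) msk[sample(Tk, 1)] <- 1
    Qr <- matrix(rnorm(2 * 3), 2, 3)
    Kr <- matrix(rnorm(Tk * 3), Tk, 3)
    Vr <- matrix(rnorm(Tk * 3), Tk, 3)
    rr <- interpretable_mha(Qr, Kr, Vr, list(diag(3)), list(diag(3)),
                            list(diag(3)), attn_mask = msk)
    expect_true(all(rr$weights[[1]][, msk == 0] == 0))
    expect_equal(rowSums(rr$weights[[1]]), c(1, 1), tolerance = 1e-9)
  }
  expect_error(interpretable_mha(Q, K, V, list(matrix(1)), list(matrix(1)),
                                 list(matrix(1)), attn_mask = c(0, 0)),
               class = "ecgmend_degenerate_attention")
})

test_that("head averaging with tied projections equals a single head", {
  set.seed(17)
  Q <- matrix(rnorm(12), 3, 4); K <- matrix(rnorm(20), 5, 4)
  V <- matrix(rnorm(20), 5, 4)
  Wq <- matrix(rnorm(8), 4, 2); Wk <- matrix(rnorm(8), 4, 2)
  Wv <- matrix(rnorm(8), 4, 2)
  tied <- interpretable_mha(Q, K, V, list(Wq, Wq, Wq), list(Wk, Wk, Wk),
                            list(Wv, Wv, Wv))
  single <- interpretable_mha(Q, K, V, list(Wq), list(Wk), list(Wv))
  expect_equal(tied$output, single$output, tolerance = 1e-12)
})

test_that("variable selection weights are a proper softmax over leads", {
  m <- tiny_tft()
  E <- matrix(rnorm(12 * 32), 12, 32)
  vs <- tft_variable_select(E, m)
  expect_equal(sum(vs$weights), 1, tolerance = 1e-6)
  expect_true(all(vs$weights >= 0))
  expect_length(vs$x_tilde, 32)
  # single lead: softmax of a singleton is 1
  vs1 <- tft_variable_select(matrix(rnorm(32), 1, 32), m)
  expect_equal(vs1$weights, 1, tolerance = 1e-12)
  # forced-constant selection scores give uniform 1/12
  m2 <- m
  for (nm in grep("^vsn\\.", names(m2$params), value = TRUE))
    m2$params[[nm]] <- m2$params[[nm]] * 0
  m2$params[["vsn.ln.o"]] <- m2$params[["vsn.ln.o"]] + 1  # constant output
  vsu <- tft_variable_select(E, m2)
  expect_equal(vsu$weights, rep(1 / 12, 12), tolerance = 1e-9)
  expect_error(tft_variable_select(E[0, , drop = FALSE], m),
               class = "ecgmend_invalid_argument")
})

test_that("quantile heads produce monotone, well-shaped outputs", {
  m <- tiny_tft()
  theta <- matrix(rnorm(5 * 32), 5, 32)
  ch <- matrix(rnorm(5 * 32), 5, 32)
  arr <- tft_quantile_heads(theta, ch, m)
  expect_equal(dim(arr), c(5L, 12L, 3L))
  # monotone rearrangement: q10 <= q50 <= q90 elementwise
  expect_true(all(arr[, , 1] <= arr[, , 2] + 1e-12))
  expect_true(all(arr[, , 2] <= arr[, , 3] + 1e-12))
  # zero-weight heads return the bias everywhere
  m0 <- m
  m0$params[["heads.W"]] <- m0$params[["heads.W"]] * 0
  m0$params[["heads.b"]] <- m0$params[["heads.b"]] * 0 + 0.25
  arr0 <- tft_quantile_heads(theta, ch, m0, monotone = FALSE)
  expect_true(all(arr0 == 0.25))
  expect_error(tft_config(quantiles = c(0.1, 0.9)),
               class = "ecgmend_invalid_argument")
})

test_that("reconstruction honours the copy contract and tiles long gaps", {
  recs <- fixture("tft_smoke_recs", function() training_records(8))
  m <- fixture("tft_smoke_model", function()
    train_tft(recs, config = tft_config(epochs = 1L, batch_size = 4L,
                                        seed = 2L)))
  te <- training_records(1, seed_base = 4900)[[1]]
  full <- matrix(1, 5000, 12)
  out <- tft_reconstruct(te, full, m)
  expect_identical(out$record$signal, te$signal)
  expect_true(all(is.na(out$lower)))

  # a gap longer than tau_max is tiled, not refused
  mask <- full; mask[1001:1600, ] <- 0
  rec <- te; rec$signal <- te$signal * mask
  r1 <- tft_reconstruct(rec, mask, m)
  # every tiled chunk of the long gap was processed (bands filled in)
  for (chunk in list(1001:1250, 1251:1500, 1501:1600))
    expect_true(all(!is.na(r1$lower[chunk, ])))
  obs <- mask == 1
  expect_identical(r1$record$signal[obs], rec$signal[obs])
  r2 <- tft_reconstruct(rec, mask, m)
  expect_identical(r1$record$signal, r2$record$signal)
  # bands present exactly at imputed positions
  expect_true(all(!is.na(r1$lower[mask == 0])))
  expect_true(all(r1$lower[mask == 0] <= r1$upper[mask == 0]))

  expect_error(tft_reconstruct(rec, 0 * full, m), class = "ecgmend_no_context")
})

test_that("training is seeded-reproducible and the loss falls on one record", {
  rec <- training_records(1, seed_base = 4800)
  cfg <- tft_config(epochs = 3L, windows_per_record = 2L, seed = 6L)
  m1 <- train_tft(rec, config = cfg)
  m2 <- train_tft(rec, config = cfg)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_lt(utils::tail(m1$loss_trace, 1), m1$loss_trace[1])
  expect_error(train_tft(list()), class = "ecgmend_invalid_argument")
})
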