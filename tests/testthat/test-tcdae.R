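tiny_tcdae <- function() fixture("tiny_tcdae", function() {
  cfg <- tcdae_config(epochs = 1L, window_len = 64L)
  structure(list(params = ecgmend:::with_seed(5,
                   ecgmend:::tcdae_init_params(cfg)),
                 config = cfg, loss_trace = numeric(0)),
            class = "tcdae_model")
})

test_that("forward pass preserves shape and is deterministic", {
  g <- clean_sinus()
  noisy <- normalize_record(add_noise(g$record, noise_spec(seed = 2)))
  m <- tiny_tcdae()
  o1 <- tcdae_forward(noisy, m)
  o2 <- tcdae_forward(noisy, m)
  expect_identical(o1$signal, o2$signal)
  expect_equal(dim(o1$signal), dim(noisy$signal))
  expect_error(tcdae_forward(g$record, m), class = "ecgmend_invalid_state")
})

test_that("combined loss is zero at identity and non-negative on random inputs", {
  set.seed(6)
  cfg <- tcdae_config()
  for (i in 1:1000) {
    p <- matrix(runif(24), 12, 2)
    expect_lt(abs(tcdae_loss(p, p, cfg)), 1e-8)
  }
  for (i in 1:200) {
    a <- matrix(runif(24), 12, 2); b <- matrix(runif(24), 12, 2)
    expect_gte(tcdae_loss(a, b, cfg), 0)
  }
})

test_that("loss components behave as specified", {
  cfg <- tcdae_config()
  # small residual r: time-domain Huber contributes r^2/2 per element
  t0 <- matrix(0.5, 32, 1)
  r <- 0.05
  l_small <- tcdae_loss(t0 + r, t0, tcdae_config(cosine_weight = 0))
  # constant shift has spectral content only in the DC bin; time term is
  # exactly r^2/2 and dominates the decomposition
  expect_gte(l_small, r^2 / 2 - 1e-12)
  # cosine term is scale-invariant: doubling a nonzero target keeps
  # similarity 1 while the Huber terms grow
  tgt <- matrix(runif(64, 0.1, 1), 32, 2)
  l5 <- tcdae_loss(2 * tgt, tgt, tcdae_config(cosine_weight = 5))
  l0 <- tcdae_loss(2 * tgt, tgt, tcdae_config(cosine_weight = 0))
  expect_lt(abs(l5 - l0), 1e-8)
  expect_gt(l0, 0)
  expect_error(tcdae_loss(matrix(0, 2, 2), matrix(0, 3, 2)),
               class = "ecgmend_invalid_argument")
})

test_that("gated convolution with the gate forced to 1 is a plain convolution", {
  m <- tiny_tcdae()
  tp <- ecgmend:::ad_tape()
  ids <- ecgmend:::ad_bind_params(tp, m$params)
  x <- ecgmend:::ad_push(tp, matrix(runif(64 * 12), 64, 12))
  taps <- ecgmend:::conv_tap_indices(64L, 7L, 2L, 1L)
  g1 <- ecgmend:::nn_gated_conv1d(tp, x, ids[["enc1a.W"]], ids[["enc1a.b"]],
                                  ids[["enc1b.W"]], ids[["enc1b.b"]], taps,
                                  gate_override = 1)
  g2 <- ecgmend:::nn_conv1d(tp, x, ids[["enc1a.W"]], ids[["enc1a.b"]], taps)
  expect_equal(ecgmend:::ad_val(tp, g1), ecgmend:::ad_val(tp, g2))
})

test_that("training is seeded-reproducible and fits a trivial pair", {
  g <- generate_clean_ecg(2, 500, 60, "sinus_rhythm", seed = 2)
  rec <- normalize_record(g$record)
  cfg <- tcdae_config(epochs = 4L, window_len = 256L, seed = 3L)
  m1 <- train_tcdae(list(list(noisy = rec, clean = rec)), cfg)
  m2 <- train_tcdae(list(list(noisy = rec, clean = rec)), cfg)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_true(utils::tail(m1$loss_trace, 1) < m1$loss_trace[1] ||
                m1$loss_trace[1] < 1e-6)
  expect_error(train_tcdae(list()), class = "ecgmend_invalid_argument")
  expect_error(train_tcdae(list(list(noisy = g$record, clean = g$record))),
               class = "ecgmend_invalid_state")
})

test_that("a trained denoiser beats the noisy baseline and suppresses powerline", {
  set.seed(42)
  make_pair <- function(i) {
    hr <- runif(1, 50, 140)
    cl <- sample(rhythm_classes(), 1)
    g <- generate_clean_ecg(10, 500, hr, cl, seed = 1000 + i)$record
    ns <- add_noise(g, noise_spec(seed = 2000 + i))
    list(noisy = normalize_record(ns), clean = normalize_record(g))
  }
  train <- lapply(1:60, make_pair)
  test <- lapply(61:72, make_pair)
  m <- train_tcdae(train, tcdae_config(epochs = 26L,
                                       windows_per_record = 3L, seed = 7L))
  # 5-epoch moving average of the loss trace is non-increasing (soft check)
  ma <- stats::filter(m$loss_trace, rep(1 / 5, 5), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_true(all(diff(ma) <= 0.02))

  mae_n <- mae_d <- pr_n <- pr_d <- numeric(length(test))
  for (i in seq_along(test)) {
    den <- tcdae_forward(test[[i]]$noisy, m)
    cl <- test[[i]]$clean$signal; no <- test[[i]]$noisy$signal
    mae_n[i] <- mean(abs(no - cl))
    mae_d[i] <- mean(abs(den$signal - cl))
    pr_n[i] <- mean(sapply(1:12, function(j) stats::cor(no[, j], cl[, j])))
    pr_d[i] <- mean(sapply(1:12, function(j)
      stats::cor(den$signal[, j], cl[, j])))
  }
  expect_lt(mean(mae_d), mean(mae_n))
  expect_gt(mean(pr_d), mean(pr_n))

  # spectral check: powerline-only fixture, 49-51 Hz band power down >= 10x
  ratios <- sapply(1:8, function(i) {
    g <- generate_clean_ecg(10, 500, runif(1, 55, 120), "sinus_rhythm",
                            seed = 5000 + i)$record
    pn <- normalize_record(add_noise(g, noise_spec(0, 0.33, 0.05, 50, 0,
                                                   c(20, 100), 0,
                                                   seed = 6000 + i)))
    den <- tcdae_forward(pn, m)
    band_power(pn$signal[, 2], 500, c(49, 51)) /
      max(band_power(den$signal[, 2], 500, c(49, 51)), 1e-15)
  })
  expect_gte(stats::median(ratios), 10)

  .fixtures$trained_tcdae <- m  # reused by the pipeline-coherence test
})

test_that("denoise_report matches hand-computed metrics", {
  x <- matrix(c(1, 2, 3, 4), 4, 1)
  # identity
  r0 <- denoise_report(x, x)
  expect_equal(r0$energy_ratio_pct, 100)
  expect_equal(r0$pearson_r, 1)
  expect_equal(r0$mae, 0)
  # constant shift: correlation invariant, MAE equals the shift
  rs <- denoise_report(x, x + 0.1)
  expect_equal(rs$pearson_r, 1)
  expect_equal(rs$mae, 0.1)
  # hand-rolled covariance oracle
  y <- matrix(c(1, 2, 3, 5), 4, 1)
  rh <- denoise_report(x, y)
  expect_equal(rh$mae, 0.25)
  cov_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(rh$pearson_r, cov_oracle)
  expect_equal(rh$energy_ratio_pct, 100 * sum(y^2) / sum(x^2))
  expect_error(denoise_report(matrix(0, 3, 1), matrix(1, 3, 1)),
               class = "ecgmend_undefined_ratio")
})

test_that("features from denoised noisy copies track the clean-signal features", {
  m <- .fixtures$trained_tcdae  # built by the training test above
  drr <- dqo <- dte <- numeric(6)
  for (i in 1:6) {
    g <- generate_clean_ecg(10, 500, 55 + 12 * i, "sinus_rhythm",
                            seed = 330 + i)
    clean_n <- normalize_record(g$record)
    noisy_n <- normalize_record(add_noise(g$record,
                                          noise_spec(seed = 340 + i)))
    den <- tcdae_forward(noisy_n, m)
    fc <- extract_features(list(clean_n))
    fd <- extract_features(list(den))
    drr[i] <- abs(fc$rr_interval - fd$rr_interval)
    dqo[i] <- abs(fc$qrs_onset - fd$qrs_onset)
    dte[i] <- abs(fc$t_end - fd$t_end)
  }
  # pipeline coherence: median feature shifts within 2x the clean-signal
  # delineation tolerances
  expect_lt(stats::median(drr), 0.02)
  expect_lt(stats::median(dqo), 0.04)
  expect_lt(stats::median(dte), 0.06)
})
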