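tiny_vae <- function() fixture("tiny_vae", function() {
  cfg <- vae_config(latent_dim = 8L, hidden = c(8L, 12L), window_len = 256L,
                    epochs = 1L)
  structure(list(params = ecgmend:::with_seed(2,
                   ecgmend:::vae_init_params(cfg)),
                 config = cfg, loss_trace = numeric(0), trained = TRUE),
            class = "vae_model")
})

test_that("reparameterization is elementwise mu + sigma * eps", {
  p <- structure(list(mu = c(1, 2), sigma = c(0.5, 2)),
                 class = "gaussian_params")
  expect_equal(vae_reparameterize(p, c(0, 0)), c(1, 2))
  p2 <- structure(list(mu = c(0, 0), sigma = c(1, 1)),
                  class = "gaussian_params")
  expect_equal(vae_reparameterize(p2, c(0.3, -0.7)), c(0.3, -0.7))
  expect_equal(vae_reparameterize(p, c(1, -1)), c(1.5, 0))
  expect_error(vae_reparameterize(p, c(1, 2, 3)),
               class = "ecgmend_invalid_argument")
})

test_that("closed-form KL matches hand values and a Monte-Carlo estimate", {
  expect_equal(kl_divergence(list(mu = 0, sigma = 1)), 0)
  expect_equal(kl_divergence(list(mu = 1, sigma = 1)), 0.5)
  expect_error(kl_divergence(list(mu = 0, sigma = -1)),
               class = "ecgmend_invalid_argument")

  # MC oracle: E_q[log q - log p] with 1e6 samples, agreement within 3 SE
  mu <- c(0.3, -0.2); sig <- c(0.8, 1.5)
  set.seed(9)
  z <- cbind(rnorm(1e6, mu[1], sig[1]), rnorm(1e6, mu[2], sig[2]))
  lq <- dnorm(z[, 1], mu[1], sig[1], log = TRUE) +
    dnorm(z[, 2], mu[2], sig[2], log = TRUE)
  lp <- dnorm(z[, 1], log = TRUE) + dnorm(z[, 2], log = TRUE)
  mc <- mean(lq - lp)
  se <- stats::sd(lq - lp) / sqrt(1e6)
  expect_lt(abs(kl_divergence(list(mu = mu, sigma = sig)) - mc), 3 * se)
})

test_that("KL is non-negative with equality only at the prior", {
  set.seed(10)
  for (i in 1:1000) {
    mu <- rnorm(4); sig <- exp(rnorm(4, 0, 0.5))
    kl <- kl_divergence(list(mu = mu, sigma = sig))
    expect_gte(kl, 0)
    if (max(abs(mu)) > 0.1 || max(abs(sig - 1)) > 0.1) expect_gt(kl, 0)
  }
  expect_equal(kl_divergence(list(mu = rep(0, 5), sigma = rep(1, 5))), 0)
})

test_that("the masked negative ELBO matches hand-computed values", {
  # exact mean, unit variance, full mask, beta 0: (T*L/2) * log(2*pi)
  x <- matrix(runif(20), 10, 2)
  full <- matrix(1, 10, 2)
  post <- list(mu = rep(0.5, 3), sigma = rep(2, 3))
  l <- vae_loss(x, full, list(mu = x, sigma = 1), post, beta = 0)
  expect_equal(l, (20 / 2) * log(2 * pi))
  # empty mask: KL only
  l2 <- vae_loss(x, 0 * full, list(mu = 0 * x, sigma = 1), post, beta = 1)
  expect_equal(l2, kl_divergence(post))
  # 2x1 toy by hand: sum(0.5 log(2 pi sigma^2) + (x - mu)^2 / (2 sigma^2))
  xt <- matrix(c(0.5, 0.7), 2, 1)
  l3 <- vae_loss(xt, matrix(1, 2, 1),
                 list(mu = matrix(0.5, 2, 1), sigma = 1),
                 list(mu = 0, sigma = 1), beta = 1)
  expect_equal(l3, log(2 * pi) + 0.02)
  expect_error(vae_loss(xt, matrix(1, 2, 1),
                        list(mu = matrix(0.5, 2, 1), sigma = 1),
                        post, beta = -1),
               class = "ecgmend_invalid_argument")
})

test_that("masked NLL ignores values stored at missing positions", {
  set.seed(11)
  for (i in 1:25) {
    x <- matrix(runif(60), 20, 3)
    mask <- matrix(rbinom(60, 1, 0.6), 20, 3)
    mu <- matrix(runif(60), 20, 3)
    post <- list(mu = rnorm(4), sigma = exp(rnorm(4, 0, 0.3)))
    l1 <- vae_loss(x, mask, list(mu = mu, sigma = 1), post, 1)
    x2 <- x
    x2[mask == 0] <- runif(sum(mask == 0), -5, 5)  # perturb missing entries
    l2 <- vae_loss(x2, mask, list(mu = mu, sigma = 1), post, 1)
    expect_equal(l1, l2)
  }
})

test_that("the loss is non-decreasing in beta", {
  set.seed(12)
  x <- matrix(runif(40), 20, 2)
  mask <- matrix(rbinom(40, 1, 0.7), 20, 2)
  recon <- list(mu = matrix(runif(40), 20, 2), sigma = 1)
  post <- list(mu = rnorm(6), sigma = exp(rnorm(6, 0, 0.4)))
  ls <- sapply(c(0, 0.5, 1, 2, 5), function(b)
    vae_loss(x, mask, recon, post, b))
  expect_true(all(diff(ls) >= 0))
})

test_that("encoder outputs are deterministic, positive-sigma and NaN-free", {
  m <- tiny_vae()
  x <- matrix(runif(256 * 12), 256, 12)
  mask <- matrix(rbinom(256 * 12, 1, 0.7), 256, 12)
  e1 <- vae_encode(x * mask, mask, m)
  e2 <- vae_encode(x * mask, mask, m)
  expect_identical(e1$mu, e2$mu)
  set.seed(13)
  for (i in 1:50) {
    xi <- matrix(runif(256 * 12), 256, 12)
    ei <- vae_encode(xi, matrix(1, 256, 12), m)
    expect_true(all(ei$sigma > 0))
  }
  # all-missing input stays finite
  e0 <- vae_encode(0 * x, 0 * mask, m)
  expect_true(all(is.finite(e0$mu)) && all(is.finite(e0$sigma)))
  expect_error(vae_encode(x, mask[1:10, ], m),
               class = "ecgmend_invalid_argument")
})

test_that("decoder has the right shape and survives extreme latents", {
  m <- tiny_vae()
  d1 <- vae_decode(rep(0, 8), m)
  expect_equal(dim(d1$mu), c(256L, 12L))
  expect_true(all(d1$sigma > 0))
  d2 <- vae_decode(rep(10, 8), m)
  d3 <- vae_decode(rep(-10, 8), m)
  expect_true(all(is.finite(d2$mu)) && all(is.finite(d3$mu)))
  expect_identical(vae_decode(rep(1, 8), m)$mu, vae_decode(rep(1, 8), m)$mu)
  expect_error(vae_decode(rep(0, 5), m), class = "ecgmend_invalid_argument")
})

test_that("reconstruction copies observed entries and is deterministic", {
  g <- clean_sinus()
  rec <- normalize_record(g$record)
  m <- tiny_vae()
  full <- matrix(1, 5000, 12)
  out <- vae_reconstruct(rec, full, m)
  expect_identical(out$signal, rec$signal)
  sm <- simulate_missing(rec, 0.3, "segments", seed = 5)
  r1 <- vae_reconstruct(sm$record, sm$mask, m)
  r2 <- vae_reconstruct(sm$record, sm$mask, m)
  expect_identical(r1$signal, r2$signal)
  obs <- sm$mask == 1
  expect_identical(r1$signal[obs], sm$record$signal[obs])
})

test_that("training is seeded-reproducible and overfits one record", {
  rec <- normalize_record(generate_clean_ecg(4, 500, 70, "sinus_rhythm",
                                             seed = 3)$record)
  cfg <- vae_config(latent_dim = 8L, hidden = c(8L, 12L), window_len = 512L,
                    epochs = 6L, seed = 4L)
  m1 <- train_vae(list(rec), config = cfg)
  m2 <- train_vae(list(rec), config = cfg)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_lt(utils::tail(m1$loss_trace, 1), m1$loss_trace[1])
  expect_error(train_vae(list()), class = "ecgmend_invalid_argument")
})
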