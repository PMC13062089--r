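test_that("cross-entropy matches hand-computed sums", {
  perfect <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(cross_entropy(perfect, perfect), 0)
  expect_equal(cross_entropy(matrix(c(1, 0, 0, 0), 1), matrix(0.25, 1, 4)),
               log(4))
  yt <- matrix(c(1, 0, 0, 1), 2, 2)
  yp <- matrix(c(0.8, 0.5, 0.2, 0.5), 2, 2)
  expect_equal(cross_entropy(yt, yp), -(log(0.8) + log(0.5)))
  expect_error(cross_entropy(yt, yp[1, , drop = FALSE]),
               class = "ecgmend_invalid_argument")
  # clipping keeps zero probabilities finite
  expect_true(is.finite(cross_entropy(yt, matrix(c(0, 1, 1, 0), 2, 2))))
})

test_that("all seven classifier kinds separate a linearly separable toy", {
  set.seed(20)
  n <- 60
  X <- rbind(matrix(rnorm(n * 2, -2), n, 2), matrix(rnorm(n * 2, 2), n, 2))
  colnames(X) <- c("f1", "f2")
  y <- rep(c("a", "b"), each = n)
  for (k in ecgmend:::classifier_kinds()) {
    cl <- train_classifier(classifier_spec(k, seed = 3), X, y)
    expect_gte(mean(as.character(predict(cl, X)) == y), 0.99)
    pr <- predict(cl, X, type = "prob")
    expect_equal(dim(pr), c(2L * n, 2L))
    expect_true(all(abs(rowSums(pr) - 1) < 1e-6))
    # seeded retrain gives identical predictions
    cl2 <- train_classifier(classifier_spec(k, seed = 3), X, y)
    expect_identical(predict(cl, X), predict(cl2, X))
  }
  expect_error(classifier_spec("neural_net"),
               class = "ecgmend_invalid_argument")
  expect_error(train_classifier(classifier_spec("decision_tree"), X,
                                rep("a", 2 * n)),
               class = "ecgmend_invalid_argument")
})

test_that("classification metrics match the confusion-matrix oracle", {
  y <- rep("x", 5)
  m0 <- classification_metrics(y, y)
  expect_equal(m0$accuracy, 1)
  expect_equal(m0$f1, 1)

  # 2-class counts TP=3 FP=1 FN=1 TN=5 for class "pos"
  truth <- c(rep("pos", 4), rep("neg", 6))
  pred <- c("pos", "pos", "pos", "neg", "pos", rep("neg", 5))
  m <- classification_metrics(truth, pred)
  expect_equal(unname(m$per_class_accuracy["pos"]), 0.75)  # recall
  cm <- table(truth, pred)
  prec_pos <- cm["pos", "pos"] / sum(cm[, "pos"])
  expect_equal(prec_pos, 0.75)
  expect_equal(m$accuracy, 0.8)

  # all-one-class prediction on a balanced set
  half <- c(rep("a", 10), rep("b", 10))
  expect_equal(classification_metrics(half, rep("a", 20))$accuracy, 0.5)
  expect_error(classification_metrics(character(0), character(0)),
               class = "ecgmend_invalid_argument")
})

test_that("weighted F1 lies between the per-class extremes", {
  set.seed(21)
  for (i in 1:50) {
    truth <- sample(letters[1:3], 60, replace = TRUE)
    pred <- ifelse(stats::runif(60) < 0.7, truth,
                   sample(letters[1:3], 60, replace = TRUE))
    m <- classification_metrics(truth, pred)
    cm <- table(factor(truth, levels = letters[1:3]),
                factor(pred, levels = letters[1:3]))
    f1s <- sapply(letters[1:3], function(cl) {
      p <- if (sum(cm[, cl]) > 0) cm[cl, cl] / sum(cm[, cl]) else 0
      r <- if (sum(cm[cl, ]) > 0) cm[cl, cl] / sum(cm[cl, ]) else 0
      if (p + r > 0) 2 * p * r / (p + r) else 0
    })
    present <- rowSums(cm) > 0
    expect_gte(m$f1, min(f1s[present]) - 1e-12)
    expect_lte(m$f1, max(f1s[present]) + 1e-12)
  }
})

test_that("reconstruction metrics match hand arithmetic and scale rules", {
  xt <- matrix(c(0, 1), 2, 1)
  xh <- matrix(c(1, 1), 2, 1)
  m <- reconstruction_metrics(xt, xh)
  expect_equal(m$mae, 0.5)
  expect_equal(m$mse, 0.5)
  expect_equal(m$rmse, sqrt(0.5))
  expect_equal(m$nrmse, sqrt(0.5))
  expect_equal(unlist(reconstruction_metrics(xt, xt)),
               c(mae = 0, mse = 0, rmse = 0, nrmse = 0))
  # NRMSE is invariant to rescaling both inputs
  for (k in c(0.5, 3, 100))
    expect_equal(reconstruction_metrics(k * xt, k * xh)$nrmse, m$nrmse)
  # selection mask restricts the evaluated entries
  sel <- matrix(c(1, 0), 2, 1)
  expect_error(reconstruction_metrics(matrix(1, 2, 1), matrix(1, 2, 1)),
               class = "ecgmend_undefined_metric")
  big <- matrix(runif(20), 10, 2)
  expect_equal(reconstruction_metrics(big, big + 0.1)$mae, 0.1)
})

test_that("bootstrap accuracy is seeded and matches the binomial scale", {
  y <- c(rep("a", 461), rep("b", 24))
  yp <- c(rep("a", 461), rep("a", 24))  # accuracy ~0.9505 on n = 485
  b1 <- bootstrap_accuracy(y, yp, 1000, seed = 1)
  b2 <- bootstrap_accuracy(y, yp, 1000, seed = 1)
  expect_identical(b1$mean, b2$mean)
  expect_identical(b1$sd, b2$sd)
  p <- mean(y == yp)
  expect_lt(abs(b1$sd - sqrt(p * (1 - p) / 485)) / sqrt(p * (1 - p) / 485),
            0.2)
  # perfect predictions: mean 1, sd 0
  bp <- bootstrap_accuracy(y, y, 100, seed = 2)
  expect_equal(bp$mean, 1)
  expect_equal(bp$sd, 0)
  # n_iter = 1 returns an achievable replicate accuracy
  b3 <- bootstrap_accuracy(y, yp, 1, seed = 3)
  expect_true(min(abs(b3$replicates - (0:485) / 485)) < 1e-12)
  expect_error(bootstrap_accuracy(character(0), character(0)),
               class = "ecgmend_invalid_argument")
})

test_that("McNemar's test follows the exact/asymptotic switch", {
  # b = c: exact p capped at 1
  m1 <- mcnemar_test(c(TRUE, FALSE, TRUE, TRUE), c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(m1$p_value, 1)
  # b = 10, c = 2: exact two-sided binomial
  a <- c(rep(TRUE, 10), rep(FALSE, 2), rep(TRUE, 5))
  b <- c(rep(FALSE, 10), rep(TRUE, 2), rep(TRUE, 5))
  m2 <- mcnemar_test(a, b)
  expect_equal(m2$b, 10); expect_equal(m2$c, 2)
  expect_equal(m2$p_value, 2 * stats::pbinom(2, 12, 0.5))
  expect_lt(abs(m2$p_value - 0.0386), 5e-4)
  expect_equal(m2$method, "exact-binomial")
  # no discordance is an error
  expect_error(mcnemar_test(c(TRUE, FALSE), c(TRUE, FALSE)),
               class = "ecgmend_no_discordance")
  expect_error(mcnemar_test(TRUE, c(TRUE, FALSE)),
               class = "ecgmend_invalid_argument")
})

test_that("exact and corrected chi-squared McNemar agree near the switch", {
  for (tot in 25:40) {
    for (b in ceiling(tot / 2):(tot - 3)) {
      cc <- tot - b
      exact <- min(1, 2 * stats::pbinom(min(b, cc), tot, 0.5))
      chi <- stats::pchisq(max(0, abs(b - cc) - 1)^2 / tot, 1,
                           lower.tail = FALSE)
      expect_lt(abs(exact - chi), 0.02)
    }
  }
})
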