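# Evaluation statistics: cross-entropy, classification metrics,
# reconstruction error metrics, bootstrap accuracy variability, and the
# paired McNemar test.

#' Multiclass cross-entropy
#'
#' `L = -sum_i sum_c y_ic * log(p_ic)` over samples (not averaged), with
#' probabilities clipped to `[1e-12, 1]`.
#'
#' @param y_true one-hot matrix, or a factor/character vector of labels.
#' @param y_prob matrix of predicted class probabilities (rows sum to 1;
#'   columns must be named with the class levels when `y_true` is a
#'   factor).
#' @return A single non-negative number.
#' @export
cross_entropy <- function(y_true, y_prob) {
  if (!is.matrix(y_true)) {
    y <- factor(y_true, levels = colnames(y_prob) %||% levels(factor(y_true)))
    Y <- matrix(0, length(y), nlevels(y))
    Y[cbind(seq_along(y), as.integer(y))] <- 1
    y_true <- Y
  }
  if (!all(dim(y_true) == dim(y_prob)))
    abort_bad_arg("`y_true` and `y_prob` must have identical shapes.")
  p <- pmin(pmax(y_prob, 1e-12), 1)
  -sum(y_true * log(p))
}

#' Classification metrics
#'
#' Accuracy plus support-weighted precision, recall and F1, and the
#' per-class accuracy (the diagonal of the row-normalised confusion
#' matrix, i.e. per-class recall).
#'
#' @param y_true,y_pred equal-length label vectors.
#' @return A list with scalars `accuracy`, `precision`, `recall`, `f1` and
#'   a named vector `per_class_accuracy`.
#' @export
classification_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0 || length(y_true) != length(y_pred))
    abort_bad_arg("`y_true` and `y_pred` must be non-empty and equal length.")
  lv <- union(levels(factor(y_true)), levels(factor(y_pred)))
  yt <- factor(y_true, levels = lv)
  yp <- factor(y_pred, levels = lv)
  cm <- table(truth = yt, pred = yp)
  support <- rowSums(cm)
  tp <- diag(cm)
  prec_c <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec_c <- ifelse(support > 0, tp / support, 0)
  f1_c <- ifelse(prec_c + rec_c > 0,
                 2 * prec_c * rec_c / (prec_c + rec_c), 0)
  w <- support / sum(support)
  present <- support > 0
  list(accuracy = sum(tp) / length(yt),
       precision = sum((prec_c * w)[present]),
       recall = sum((rec_c * w)[present]),
       f1 = sum((f1_c * w)[present]),
       per_class_accuracy = stats::setNames(rec_c, lv)[present])
}

#' Reconstruction error metrics
#'
#' MAE, MSE, RMSE and NRMSE (RMSE divided by the range of the true values)
#' over the selected entries.
#'
#' @param x_true,x_hat equal-shape numeric matrices.
#' @param select optional binary matrix; entries with 1 are evaluated
#'   (default: all entries).  Pass `1 - mask` to score imputation of the
#'   missing entries only.
#' @return A list with `mae`, `mse`, `rmse`, `nrmse`.
#' @export
reconstruction_metrics <- function(x_true, x_hat, select = NULL) {
  if (!all(dim(x_true) == dim(x_hat)))
    abort_bad_arg("`x_true` and `x_hat` must have identical shapes.")
  sel <- if (is.null(select)) rep(TRUE, length(x_true)) else select == 1
  xt <- x_true[sel]; xh <- x_hat[sel]
  if (length(xt) == 0) abort_bad_arg("no entries selected.")
  rng <- max(xt) - min(xt)
  if (rng == 0)
    abort_state("true values have zero range: NRMSE undefined.",
                "ecgmend_undefined_metric")
  mse <- mean((xt - xh)^2)
  list(mae = mean(abs(xt - xh)), mse = mse, rmse = sqrt(mse),
       nrmse = sqrt(mse) / rng)
}

#' Bootstrap variability of classification accuracy
#'
#' Resamples the prediction/truth pairs with replacement `n_iter` times and
#' returns the mean and sample standard deviation of the replicate
#' accuracies.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param n_iter number of bootstrap replicates (1000 in the standard
#'   protocol).
#' @param seed integer seed.
#' @return A list with `mean`, `sd` and the replicate vector `replicates`.
#' @export
bootstrap_accuracy <- function(y_true, y_pred, n_iter = 1000L, seed = 1L) {
  n <- length(y_true)
  if (n == 0 || n != length(y_pred))
    abort_bad_arg("`y_true` and `y_pred` must be non-empty and equal length.")
  if (n_iter < 1) abort_bad_arg("`n_iter` must be >= 1.")
  correct <- as.character(y_true) == as.character(y_pred)
  acc <- with_seed(seed, vapply(seq_len(n_iter), function(i)
    mean(correct[sample.int(n, n, replace = TRUE)]), 0))
  list(mean = mean(acc), sd = stats::sd(acc), replicates = acc)
}

#' Paired McNemar test on classifier correctness
#'
#' Counts the discordant pairs `b` (A correct, B wrong) and `c` (A wrong, B
#' correct).  For `b + c < 25` the exact two-sided binomial p-value
#' `min(1, 2 * P(X <= min(b, c)))` with `X ~ Binomial(b + c, 1/2)` is used;
#' otherwise the chi-squared statistic with continuity correction
#' `max(0, |b - c| - 1)^2 / (b + c)` on 1 df (the correction is clamped so
#' perfectly balanced discordance gives p = 1, matching the exact branch).
#'
#' @param correct_a,correct_b logical vectors of per-case correctness for
#'   the two classifiers, paired on identical test instances.
#' @return A list with `p_value`, `b`, `c` and `method`.
#' @export
mcnemar_test <- function(correct_a, correct_b) {
  if (length(correct_a) != length(correct_b))
    abort_bad_arg("`correct_a` and `correct_b` must have equal length.")
  b <- sum(correct_a & !correct_b)
  cc <- sum(!correct_a & correct_b)
  if (b + cc == 0)
    abort_state("no discordant pairs: McNemar test undefined.",
                "ecgmend_no_discordance")
  if (b + cc < 25) {
    p <- min(1, 2 * stats::pbinom(min(b, cc), b + cc, 0.5))
    method <- "exact-binomial"
  } else {
    # continuity correction clamped at zero so b == c gives p = 1
    stat <- max(0, abs(b - cc) - 1)^2 / (b + cc)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "chi-squared-cc"
  }
  list(p_value = p, b = b, c = cc, method = method)
}
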