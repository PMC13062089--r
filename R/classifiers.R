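# The seven rhythm classifiers behind the evaluation harness.  Six wrap
# established implementations (ranger, nnet, e1071, class, rpart, xgboost);
# plain gradient boosting is a small multiclass softmax boosting loop over
# rpart regression trees since no dedicated GBM package is available here.

#' The seven supported classifier kinds
#' @return Character vector of classifier identifiers.
#' @export
classifier_kinds <- function() {
  c("random_forest", "logistic_regression", "support_vector_machine",
    "k_nearest_neighbors", "decision_tree", "gradient_boosting",
    "extreme_gradient_boosting")
}

#' Classifier specification
#'
#' @param kind one of `random_forest`, `logistic_regression`,
#'   `support_vector_machine`, `k_nearest_neighbors`, `decision_tree`,
#'   `gradient_boosting`, `extreme_gradient_boosting`.
#' @param hyperparameters named list overriding the library defaults.
#' @param seed integer seed for stochastic learners.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = classifier_kinds(),
                            hyperparameters = list(), seed = 1L) {
  if (length(kind) == 1L && !kind %in% classifier_kinds())
    abort_bad_arg(sprintf("unknown classifier kind '%s'.", kind))
  kind <- match.arg(kind)
  structure(list(kind = kind, hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

# numeric design matrix from a feature tibble (drops id/label columns);
# missing values imputed with the training-set column medians
feature_matrix <- function(features) {
  drop <- intersect(c("patient_id", "label"), colnames(features))
  X <- as.matrix(features[, setdiff(colnames(features), drop), drop = FALSE])
  storage.mode(X) <- "double"
  X
}

#' Train a rhythm classifier on a feature table
#'
#' @param spec a [classifier_spec()].
#' @param features feature tibble (as from [build_feature_table()]) or a
#'   numeric matrix.
#' @param labels class labels (factor or character), at least two classes.
#' @return An object of class `ecg_classifier` with a [predict()] method
#'   (`type = "class"` or `"prob"`).
#' @export
train_classifier <- function(spec, features, labels) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- if (is.matrix(features)) features else feature_matrix(features)
  y <- factor(labels)
  if (nlevels(y) < 2)
    abort_bad_arg("training data must contain at least two classes.")
  if (nrow(X) != length(y))
    abort_bad_arg("`features` and `labels` must have the same length.")
  med <- apply(X, 2, function(c) stats::median(c, na.rm = TRUE))
  med[!is.finite(med)] <- 0
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- med[j]
  hp <- spec$hyperparameters

  fit <- with_seed(spec$seed, switch(
    spec$kind,
    random_forest = ranger::ranger(
      x = X, y = y, probability = TRUE,
      num.trees = hp$num.trees %||% 500,
      seed = spec$seed, num.threads = 1),
    logistic_regression = nnet::multinom(
      y ~ ., data = data.frame(y = y, X), trace = FALSE,
      maxit = hp$maxit %||% 200),
    support_vector_machine = {
      ctr <- colMeans(X); scl <- apply(X, 2, stats::sd)
      scl[scl == 0] <- 1
      list(svm = e1071::svm(x = scale(X, ctr, scl), y = y,
                            probability = TRUE, scale = FALSE,
                            kernel = hp$kernel %||% "radial",
                            cost = hp$cost %||% 1),
           center = ctr, scale = scl)
    },
    k_nearest_neighbors = {
      ctr <- colMeans(X); scl <- apply(X, 2, stats::sd)
      scl[scl == 0] <- 1
      list(X = scale(X, ctr, scl), y = y, k = hp$k %||% 5,
           center = ctr, scale = scl)
    },
    decision_tree = rpart::rpart(
      y ~ ., data = data.frame(y = y, X), method = "class",
      control = rpart::rpart.control(cp = hp$cp %||% 0.01)),
    gradient_boosting = gbm_softmax_fit(
      X, y, n_trees = hp$n_trees %||% 60,
      shrinkage = hp$shrinkage %||% 0.1,
      max_depth = hp$max_depth %||% 3),
    extreme_gradient_boosting = {
      xgboost::xgb.train(
        params = list(objective = "multi:softprob",
                      num_class = nlevels(y),
                      max_depth = hp$max_depth %||% 4,
                      eta = hp$eta %||% 0.3,
                      nthread = 1, seed = spec$seed),
        data = xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L),
        nrounds = hp$nrounds %||% 60, verbose = 0)
    }))

  structure(list(kind = spec$kind, fit = fit, levels = levels(y),
                 medians = med, feature_names = colnames(X),
                 seed = spec$seed),
            class = "ecg_classifier")
}

#' @export
print.ecg_classifier <- function(x, ...) {
  cat(sprintf("<ecg_classifier> %s over %d classes (%s)\n", x$kind,
              length(x$levels), paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Predict rhythm classes or class probabilities
#'
#' @param object an `ecg_classifier`.
#' @param newdata feature tibble or numeric matrix.
#' @param type `"class"` (factor) or `"prob"` (matrix, one column per
#'   class).
#' @param ... unused.
#' @export
predict.ecg_classifier <- function(object, newdata,
                                   type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  X <- X[, object$feature_names, drop = FALSE]
  for (j in seq_len(ncol(X)))
    X[is.na(X[, j]), j] <- object$medians[j]
  lv <- object$levels

  prob <- switch(
    object$kind,
    random_forest = stats::predict(object$fit, data = X,
                                   num.threads = 1)$predictions,
    logistic_regression = {
      p <- stats::predict(object$fit, newdata = data.frame(X),
                          type = "probs")
      if (is.null(dim(p))) {  # two-class multinom returns P(second level)
        p <- cbind(1 - p, p)
        dimnames(p) <- list(NULL, lv)
      }
      p
    },
    support_vector_machine = {
      Xs <- scale(X, object$fit$center, object$fit$scale)
      pr <- stats::predict(object$fit$svm, newdata = Xs,
                           probability = TRUE)
      attr(pr, "probabilities")[, lv, drop = FALSE]
    },
    k_nearest_neighbors = {
      Xs <- scale(X, object$fit$center, object$fit$scale)
      # knn breaks distance ties through the RNG; scope it for determinism
      pr <- with_seed(object$seed,
                      class::knn(object$fit$X, Xs, object$fit$y,
                                 k = object$fit$k, prob = TRUE,
                                 use.all = FALSE))
      p <- matrix(0, nrow(Xs), length(lv), dimnames = list(NULL, lv))
      win <- attr(pr, "prob")
      for (i in seq_along(pr)) {
        p[i, as.character(pr[i])] <- win[i]
        rest <- (1 - win[i]) / max(1, length(lv) - 1)
        p[i, setdiff(lv, as.character(pr[i]))] <- rest
      }
      p
    },
    decision_tree = stats::predict(object$fit, newdata = data.frame(X),
                                   type = "prob"),
    gradient_boosting = gbm_softmax_predict(object$fit, X),
    extreme_gradient_boosting = {
      p <- stats::predict(object$fit, xgboost::xgb.DMatrix(X))
      if (!is.matrix(p))
        p <- matrix(p, ncol = length(lv), byrow = TRUE)
      colnames(p) <- lv
      p
    })
  colnames(prob) <- if (is.null(colnames(prob))) lv else colnames(prob)
  prob <- prob[, lv, drop = FALSE]
  if (type == "prob") return(prob)
  factor(lv[max.col(prob, ties.method = "first")], levels = lv)
}

# ---- multiclass softmax gradient boosting over rpart regression trees -----

gbm_softmax_fit <- function(X, y, n_trees = 60, shrinkage = 0.1,
                            max_depth = 3) {
  C <- nlevels(y)
  n <- nrow(X)
  Y <- matrix(0, n, C)
  Y[cbind(seq_len(n), as.integer(y))] <- 1
  F <- matrix(0, n, C)
  trees <- vector("list", n_trees)
  df <- data.frame(X)
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0,
                               minsplit = 10, xval = 0)
  for (m in seq_len(n_trees)) {
    P <- exp(F - apply(F, 1, max))
    P <- P / rowSums(P)
    step <- vector("list", C)
    for (c in seq_len(C)) {
      df$r <- Y[, c] - P[, c]
      tr <- rpart::rpart(r ~ . - r, data = df, method = "anova",
                         control = ctrl)
      F[, c] <- F[, c] + shrinkage * stats::predict(tr, newdata = df)
      step[[c]] <- tr
    }
    trees[[m]] <- step
  }
  list(trees = trees, shrinkage = shrinkage, levels = levels(y))
}

gbm_softmax_predict <- function(fit, X) {
  C <- length(fit$levels)
  F <- matrix(0, nrow(X), C)
  df <- data.frame(X)
  for (step in fit$trees)
    for (c in seq_len(C))
      F[, c] <- F[, c] + fit$shrinkage * stats::predict(step[[c]],
                                                        newdata = df)
  P <- exp(F - apply(F, 1, max))
  P <- P / rowSums(P)
  colnames(P) <- fit$levels
  P
}
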