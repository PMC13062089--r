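# Head-to-head evaluation of the two reconstruction arms (masked VAE vs
# TFT) across missing-data ratios, with downstream classification metrics,
# bootstrap variability and paired McNemar tests.

reconstruct_with <- function(model, record, mask) {
  if (inherits(model, "vae_model")) {
    vae_reconstruct(record, mask, model)
  } else if (inherits(model, "tft_model")) {
    tft_reconstruct(record, mask, model)$record
  } else {
    abort_bad_arg("reconstructor must be a vae_model or tft_model.")
  }
}

#' Compare two reconstruction arms across missing-data ratios
#'
#' For every ratio and each reconstruction arm: the test records are
#' masked, reconstructed, delineated and classified with every classifier
#' (all classifiers are trained once, on the clean training-set features).
#' The report collects classification metrics with bootstrap variability,
#' masked-entry reconstruction errors, and per-classifier McNemar tests
#' between the two arms.
#'
#' @param reconstructor_a,reconstructor_b trained reconstruction models
#'   (`vae_model` / `tft_model`); their class names label the arms.
#' @param cohort an `ecg_cohort` from [generate_cohort()] (records are
#'   normalized internally).
#' @param split a [patient_split()] assignment for the cohort's patients.
#' @param classifier_specs list of [classifier_spec()]s.
#' @param missing_ratios missing-data fractions to sweep.
#' @param segment_len missing-segment length in samples.
#' @param n_boot bootstrap iterations per cell.
#' @param n_test_cap optional cap on the number of test records evaluated
#'   (a seeded subsample keeps demo sweeps affordable); `NULL` uses the
#'   whole test partition.
#' @param seed integer seed (drives masking, subsampling and bootstrap).
#' @return An object of class `eval_report`; see [tidy.eval_report()].
#' @export
run_comparison <- function(reconstructor_a, reconstructor_b, cohort, split,
                           classifier_specs,
                           missing_ratios = c(0.10, 0.30, 0.50),
                           segment_len = 250L, n_boot = 1000L,
                           n_test_cap = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "ecg_cohort"))
  arms <- list(a = reconstructor_a, b = reconstructor_b)
  arm_names <- vapply(arms, function(m)
    sub("_model$", "", class(m)[1]), "")
  names(arms) <- arm_names

  part <- split$partition[match(cohort$patient_ids, split$patient_id)]
  idx_train <- which(part == "train")
  idx_test <- which(part == "test")
  if (!is.null(n_test_cap) && length(idx_test) > n_test_cap)
    idx_test <- with_seed(derive_seed(seed, "testcap"),
                          sort(sample(idx_test, n_test_cap)))
  if (length(idx_train) == 0 || length(idx_test) == 0)
    abort_bad_arg("split leaves the cohort without train or test records.")

  norm <- lapply(cohort$records, normalize_record)
  labels <- cohort$labels

  feat_train <- extract_features(norm[idx_train],
                                 labels = labels[idx_train])
  classifiers <- lapply(classifier_specs, function(sp)
    train_classifier(sp, feat_train, labels[idx_train]))
  names(classifiers) <- vapply(classifier_specs, `[[`, "", "kind")

  cls_rows <- list(); per_class_rows <- list(); rec_rows <- list()
  mc_rows <- list()
  y_test <- labels[idx_test]

  for (ratio in missing_ratios) {
    preds_by_arm <- list()
    for (arm in names(arms)) {
      recon <- vector("list", length(idx_test))
      rec_m <- matrix(0, length(idx_test), 4,
                      dimnames = list(NULL, c("mae", "mse", "rmse", "nrmse")))
      for (k in seq_along(idx_test)) {
        i <- idx_test[k]
        sm <- simulate_missing(norm[[i]], ratio, "segments",
                               segment_len = segment_len,
                               seed = derive_seed(seed, paste0("mask", i,
                                                               ratio)))
        rr <- reconstruct_with(arms[[arm]], sm$record, sm$mask)
        recon[[k]] <- rr
        m <- reconstruction_metrics(norm[[i]]$signal, rr$signal,
                                    select = 1 - sm$mask)
        rec_m[k, ] <- unlist(m)
      }
      rec_rows[[paste(arm, ratio)]] <- tibble::tibble(
        arm = arm, ratio = ratio,
        mae = mean(rec_m[, "mae"]), mse = mean(rec_m[, "mse"]),
        rmse = mean(rec_m[, "rmse"]), nrmse = mean(rec_m[, "nrmse"]))

      feat_test <- extract_features(recon, labels = y_test)
      preds <- lapply(classifiers, function(cl)
        as.character(stats::predict(cl, feat_test)))
      preds_by_arm[[arm]] <- preds

      for (cn in names(classifiers)) {
        met <- classification_metrics(y_test, preds[[cn]])
        bt <- bootstrap_accuracy(y_test, preds[[cn]], n_iter = n_boot,
                                 seed = derive_seed(seed, paste0(
                                   "boot", arm, ratio, cn)))
        cls_rows[[paste(arm, ratio, cn)]] <- tibble::tibble(
          arm = arm, ratio = ratio, classifier = cn,
          accuracy = met$accuracy, precision = met$precision,
          recall = met$recall, f1 = met$f1,
          boot_mean = bt$mean, boot_sd = bt$sd)
        per_class_rows[[paste(arm, ratio, cn)]] <- tibble::tibble(
          arm = arm, ratio = ratio, classifier = cn,
          class = names(met$per_class_accuracy),
          accuracy = unname(met$per_class_accuracy))
      }
    }
    # paired McNemar between the two arms, per classifier
    for (cn in names(classifiers)) {
      ca <- preds_by_arm[[1]][[cn]] == y_test
      cb <- preds_by_arm[[2]][[cn]] == y_test
      mc <- tryCatch(mcnemar_test(ca, cb), error = function(e) NULL)
      mc_rows[[paste(ratio, cn)]] <- tibble::tibble(
        ratio = ratio, classifier = cn,
        b = if (is.null(mc)) 0L else mc$b,
        c = if (is.null(mc)) 0L else mc$c,
        p_value = if (is.null(mc)) 1 else mc$p_value,
        method = if (is.null(mc)) "no-discordance" else mc$method)
    }
  }

  mcn <- dplyr::bind_rows(mc_rows)
  mcn$p_holm <- stats::p.adjust(mcn$p_value, method = "holm")
  structure(list(
    classification = dplyr::bind_rows(cls_rows),
    per_class = dplyr::bind_rows(per_class_rows),
    reconstruction = dplyr::bind_rows(rec_rows),
    mcnemar = mcn,
    arms = arm_names, seed = as.integer(seed),
    n_test = length(idx_test)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> arms %s on %d test records\n",
              paste(x$arms, collapse = " vs "), x$n_test))
  print(as.data.frame(x$classification[, c("arm", "ratio", "classifier",
                                           "accuracy", "boot_sd")]))
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x an `eval_report`.
#' @param ... unused.
#' @return The per-(arm, ratio, classifier) metric tibble.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$classification

#' One-row summary of an evaluation report
#' @param x an `eval_report`.
#' @param ... unused.
#' @return A single-row tibble with the best accuracy per arm.
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  cl <- x$classification
  best <- dplyr::summarise(dplyr::group_by(cl, .data$arm),
                           best_accuracy = max(.data$accuracy),
                           .groups = "drop")
  tibble::tibble(
    n_test = x$n_test,
    n_classifiers = length(unique(cl$classifier)),
    n_ratios = length(unique(cl$ratio)),
    best_arm = best$arm[which.max(best$best_accuracy)],
    best_accuracy = max(best$best_accuracy),
    min_mcnemar_p = min(x$mcnemar$p_value))
}

#' Plot accuracy against missing ratio per classifier and arm
#' @param object an `eval_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- object$classification
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio, y = .data$accuracy,
                                   colour = .data$classifier)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$boot_mean - .data$boot_sd,
      ymax = .data$boot_mean + .data$boot_sd)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$arm)) +
    ggplot2::labs(x = "missing-data ratio", y = "accuracy")
}

#' Heat-map of per-class accuracy
#' @param report an `eval_report`.
#' @param ratio which missing ratio to show.
#' @return A ggplot object (classes x classifiers, filled by accuracy).
#' @export
plot_class_accuracy <- function(report, ratio = NULL) {
  df <- report$per_class
  if (!is.null(ratio)) df <- df[df$ratio == ratio, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$classifier, y = .data$class,
                                   fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(ggplot2::vars(.data$ratio),
                        ggplot2::vars(.data$arm)) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Export an evaluation report to CSV/JSON files
#'
#' Writes `classification.csv`, `per_class_accuracy.csv`,
#' `reconstruction.csv`, `mcnemar.csv` and `report.json` into `dir`.
#'
#' @param report an `eval_report`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$classification,
                   file.path(dir, "classification.csv"), row.names = FALSE)
  utils::write.csv(report$per_class,
                   file.path(dir, "per_class_accuracy.csv"),
                   row.names = FALSE)
  utils::write.csv(report$reconstruction,
                   file.path(dir, "reconstruction.csv"), row.names = FALSE)
  utils::write.csv(report$mcnemar, file.path(dir, "mcnemar.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(classification = report$classification,
         per_class = report$per_class,
         reconstruction = report$reconstruction,
         mcnemar = report$mcnemar,
         arms = report$arms, seed = report$seed, n_test = report$n_test),
    file.path(dir, "report.json"), dataframe = "rows", auto_unbox = TRUE,
    digits = NA)
  invisible(dir)
}
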