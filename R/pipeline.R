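# End-to-end pipeline orchestration: synthesize -> split -> denoise ->
# mask -> reconstruct -> extract features -> classify -> evaluate, driven
# by one configuration document with per-stage seeds derived from a single
# master seed (so toggling one stage never shifts another stage's
# randomness).

#' Default pipeline configuration
#'
#' @param out_dir artifact directory.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param n_patients,duration_s,fs cohort geometry.
#' @param ratios missing-data ratios for the evaluation sweep.
#' @param classifiers classifier kinds to evaluate.
#' @param tcdae_epochs,vae_epochs,tft_epochs training lengths.
#' @param n_boot bootstrap iterations.
#' @param stages named logical list switching stages on/off.
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(out_dir = tempfile("ecgmend_run_"),
                               seed = 7L, n_patients = 240L,
                               duration_s = 10, fs = 500,
                               ratios = c(0.10, 0.30, 0.50),
                               classifiers = classifier_kinds(),
                               tcdae_epochs = 12L, vae_epochs = 10L,
                               tft_epochs = 6L, n_boot = 1000L,
                               stages = list(synth = TRUE, split = TRUE,
                                             denoise = FALSE, mask = TRUE,
                                             reconstruct = TRUE,
                                             features = TRUE,
                                             evaluate = TRUE)) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 cohort = list(n_patients = n_patients,
                               duration_s = duration_s, fs = fs),
                 missing = list(ratios = ratios, mode = "segments",
                                segment_len = 250L),
                 models = list(tcdae = list(epochs = tcdae_epochs),
                               vae = list(epochs = vae_epochs),
                               tft = list(epochs = tft_epochs)),
                 classifiers = classifiers, n_boot = n_boot,
                 stages = stages),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file; fields missing from the file fall back to
#'   [default_run_config()] values.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_bad_arg(sprintf("no such file: %s", path))
  usr <- yaml::read_yaml(path)
  base <- default_run_config()
  out <- utils::modifyList(base, usr)
  class(out) <- "run_config"
  out
}

#' Validate a pipeline configuration
#'
#' @param config a `run_config` (or plain list).
#' @return Character vector of violations (empty when valid); each entry
#'   names the offending field and the rule it breaks.
#' @export
validate_config <- function(config) {
  v <- character(0)
  need <- function(cond, msg) if (!cond) v <<- c(v, msg)
  need(!is.null(config$seed), "seed: a master seed is required")
  need(!is.null(config$out_dir), "out_dir: an artifact directory is required")
  st <- config$stages
  need(!is.null(st), "stages: stage toggles are required")
  if (!is.null(st)) {
    on <- function(s) isTRUE(st[[s]])
    need(!(on("split") && !on("synth")),
         "stages$split: requires stages$synth")
    need(!(on("mask") && !on("synth")),
         "stages$mask: requires stages$synth")
    need(!(on("reconstruct") && !on("mask")),
         "stages$reconstruct: requires stages$mask")
    need(!(on("features") && !on("synth")),
         "stages$features: requires stages$synth")
    need(!(on("evaluate") && !(on("features") && on("reconstruct"))),
         "stages$evaluate: requires stages$features and stages$reconstruct")
  }
  rt <- config$missing$ratios
  need(is.null(rt) || all(rt >= 0 & rt < 1),
       "missing$ratios: ratios must lie in [0, 1)")
  cls <- config$classifiers
  need(is.null(cls) || all(cls %in% classifier_kinds()),
       "classifiers: unknown classifier kind")
  v
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order, writes every intermediate artifact
#' under `config$out_dir` (cohort as WFDB file pairs, split assignment,
#' denoising report, evaluation report CSV/JSON) together with a manifest
#' of stage seeds and a config hash, and returns the evaluation report.
#' The same configuration and seed always reproduce identical artifacts.
#'
#' @param config a `run_config`, see [default_run_config()] /
#'   [read_run_config()].
#' @param verbose print stage progress.
#' @return A list with `report` (an `eval_report` or `NULL`), `cohort`,
#'   `split`, `models` and `out_dir`.
#' @export
run_pipeline <- function(config = default_run_config(), verbose = TRUE) {
  viol <- validate_config(config)
  if (length(viol))
    abort_bad_arg(paste("invalid config:", paste(viol, collapse = "; ")))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  say <- function(...) if (verbose) message(sprintf(...))
  stage_on <- function(s) isTRUE(config$stages[[s]])
  t_stage <- function(name, expr) {
    t0 <- proc.time()[3]
    res <- force(expr)
    log[[name]] <<- tibble::tibble(stage = name,
                                   seed = derive_seed(config$seed, name),
                                   seconds = round(proc.time()[3] - t0, 2))
    say("stage %-12s done in %.1fs", name, proc.time()[3] - t0)
    res
  }

  cohort <- NULL; split <- NULL; report <- NULL
  models <- list()

  if (stage_on("synth")) {
    cohort <- t_stage("synth", {
      sp <- cohort_spec(config$cohort$n_patients,
                        duration_s = config$cohort$duration_s,
                        fs = config$cohort$fs,
                        seed = derive_seed(config$seed, "synth"))
      co <- generate_cohort(sp)
      cdir <- file.path(config$out_dir, "cohort")
      for (r in co$records) write_record(r, cdir)
      utils::write.csv(as_tibble(co),
                       file.path(config$out_dir, "cohort_manifest.csv"),
                       row.names = FALSE)
      co
    })
  }

  if (stage_on("split") && !is.null(cohort)) {
    split <- t_stage("split", {
      s <- patient_split(cohort$patient_ids,
                         seed = derive_seed(config$seed, "split"))
      utils::write.csv(s, file.path(config$out_dir, "split.csv"),
                       row.names = FALSE)
      s
    })
  }

  norm <- NULL
  if (!is.null(cohort)) norm <- lapply(cohort$records, normalize_record)

  if (stage_on("denoise") && !is.null(cohort)) {
    models$tcdae <- t_stage("denoise", {
      dseed <- derive_seed(config$seed, "denoise")
      train_idx <- which(split$partition[match(cohort$patient_ids,
                                               split$patient_id)] == "train")
      pairs <- lapply(train_idx, function(i) {
        ns <- add_noise(cohort$records[[i]],
                        noise_spec(seed = derive_seed(dseed, paste0("n", i))))
        list(noisy = normalize_record(ns), clean = norm[[i]])
      })
      mdl <- train_tcdae(pairs, tcdae_config(
        epochs = config$models$tcdae$epochs %||% 12L, seed = dseed))
      # denoising validation on a noisy copy of each record
      rep1 <- denoise_report(norm[[train_idx[1]]],
                             tcdae_forward(pairs[[1]]$noisy, mdl))
      utils::write.csv(rep1, file.path(config$out_dir,
                                       "denoise_report.csv"),
                       row.names = FALSE)
      mdl
    })
  }

  if (stage_on("reconstruct") && !is.null(cohort) && !is.null(split)) {
    part <- split$partition[match(cohort$patient_ids, split$patient_id)]
    train_idx <- which(part == "train")
    models$vae <- t_stage("train_vae", {
      masks <- lapply(seq_along(train_idx), function(j) {
        i <- train_idx[j]
        ratio <- c(0, config$missing$ratios)[1 + (j %% 4)]
        simulate_missing(norm[[i]], ratio, config$missing$mode,
                         config$missing$segment_len,
                         seed = derive_seed(config$seed,
                                            paste0("vmask", i)))$mask
      })
      train_vae(norm[train_idx], masks,
                vae_config(epochs = config$models$vae$epochs %||% 10L,
                           windows_per_record = 3L,
                           seed = derive_seed(config$seed, "vae")))
    })
    models$tft <- t_stage("train_tft", {
      train_tft(norm[train_idx],
                config = tft_config(
                  epochs = config$models$tft$epochs %||% 6L,
                  seed = derive_seed(config$seed, "tft")))
    })
  }

  if (stage_on("evaluate") && !is.null(models$vae) && !is.null(models$tft)) {
    report <- t_stage("evaluate", {
      specs <- lapply(config$classifiers, function(k)
        classifier_spec(k, seed = derive_seed(config$seed, k)))
      rep <- run_comparison(models$vae, models$tft, cohort, split, specs,
                            missing_ratios = config$missing$ratios,
                            segment_len = config$missing$segment_len,
                            n_boot = config$n_boot,
                            seed = derive_seed(config$seed, "evaluate"))
      write_eval_report(rep, file.path(config$out_dir, "report"))
      rep
    })
  }

  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    master_seed = config$seed,
    stages = dplyr::bind_rows(log))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (length(log))
    utils::write.csv(dplyr::bind_rows(log),
                     file.path(config$out_dir, "run_log.csv"),
                     row.names = FALSE)

  invisible(list(report = report, cohort = cohort, split = split,
                 models = models, out_dir = config$out_dir))
}
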