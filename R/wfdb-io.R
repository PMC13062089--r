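# WFDB-style record IO (format 16 only), min-max normalization, and the
# leakage-free patient-level train/validation/test split.
#
# The on-disk layout is the classic header + signal pair: `<name>.hea` is a
# text header (`name n_sig fs n_samples`, one descriptor line per signal,
# `#` comment lines) and `<name>.dat` holds interleaved little-endian 16-bit
# integer samples.  Other storage format codes are rejected on read: one
# well-tested dialect beats many fragile ones.

signed16 <- function(x) {
  x <- ((x %% 65536) + 65536) %% 65536
  ifelse(x > 32767, x - 65536, x)
}

wfdb_checksum <- function(stored) signed16(sum(as.numeric(stored)) %% 65536)

#' Write an ECG record as a WFDB format-16 file pair
#'
#' Digitizes each lead as `round(x * gain + baseline)` (baseline 0 here),
#' stores the samples as interleaved little-endian 16-bit integers in
#' `<name>.dat`, and writes the text header `<name>.hea` with per-signal
#' gain, baseline, units, initial value, 16-bit signed checksum and block
#' size.  The rhythm label, if any, is stored as a `# label:` comment line.
#'
#' @param record an [ecg_record()] (amplitudes must be finite).
#' @param dir output directory (created if needed).
#' @param name record name (file stem); defaults to the patient id.
#' @param gain ADC units per millivolt (> 0).
#' @return The header, invisibly, as returned by [read_record()]'s `header`
#'   element.
#' @export
write_record <- function(record, dir, name = record$patient_id, gain = 200) {
  stopifnot(inherits(record, "ecg_record"))
  if (!is.numeric(gain) || length(gain) != 1L || gain <= 0)
    abort_bad_arg("`gain` must be a single positive number (adu/mV).")
  if (any(!is.finite(record$signal)))
    abort_bad_arg("record contains non-finite values; cannot digitize.")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(record$signal)
  L <- ncol(record$signal)
  baseline <- 0L

  stored <- round(record$signal * gain) + baseline
  if (any(stored < -32768 | stored > 32767))
    abort_bad_arg("digitized samples overflow 16-bit range; lower `gain`.")
  mode(stored) <- "integer"

  dat_name <- paste0(name, ".dat")
  checksums <- if (n > 0) apply(stored, 2, wfdb_checksum) else integer(L)
  init <- if (n > 0) stored[1, ] else integer(L)

  hea <- c(
    sprintf("%s %d %g %d", name, L, record$fs, n),
    sprintf("%s 16 %g(%d)/mV 16 0 %d %d 0 %s",
            dat_name, gain, baseline, init, checksums, record$lead_names),
    if (!is.null(record$label)) sprintf("# label: %s", record$label))
  writeLines(hea, file.path(dir, paste0(name, ".hea")))

  con <- file(file.path(dir, dat_name), "wb")
  on.exit(close(con))
  if (n > 0)
    writeBin(as.integer(t(stored)), con, size = 2L, endian = "little")

  invisible(record_header(name, L, record$fs, n, dat_name, gain, baseline,
                          init, checksums, record$lead_names))
}

record_header <- function(record_name, n_sig, fs, n_samples, file_name,
                          gain, baseline, initial_value, checksum,
                          description) {
  structure(list(
    record_name = record_name, n_sig = n_sig, fs = fs, n_samples = n_samples,
    signals = tibble::tibble(
      file_name = file_name, format = 16L, gain = gain, baseline = baseline,
      units = "mV", adc_res = 16L, initial_value = as.integer(initial_value),
      checksum = as.integer(checksum), block_size = 0L,
      description = description)),
    class = "wfdb_header")
}

#' @export
print.wfdb_header <- function(x, ...) {
  cat(sprintf("<wfdb_header> %s: %d signals @ %g Hz, %d samples\n",
              x$record_name, x$n_sig, x$fs, x$n_samples))
  invisible(x)
}

#' Read a WFDB format-16 record
#'
#' Parses the header, reads the interleaved 16-bit samples, verifies the
#' per-signal checksums and the sample count, and recovers physical units as
#' `(stored - baseline) / gain` millivolts.
#'
#' @param path record path without extension (or the `.hea` path).
#' @return A list with `record` ([ecg_record()]) and `header`.
#' @export
read_record <- function(path) {
  path <- sub("\\.hea$", "", path)
  hea_path <- paste0(path, ".hea")
  if (!file.exists(hea_path))
    abort_bad_arg(sprintf("header file not found: %s", hea_path))
  lines <- readLines(hea_path)
  comments <- grep("^#", lines, value = TRUE)
  lines <- grep("^#", lines, value = TRUE, invert = TRUE)
  lines <- lines[nzchar(trimws(lines))]

  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 4)
    abort_state("malformed header line; expected 'name n_sig fs n_samples'.",
                "ecgmend_format_error")
  record_name <- top[1]
  n_sig <- as.integer(top[2])
  fs <- as.numeric(top[3])
  n_samples <- as.integer(top[4])
  if (length(lines) < 1 + n_sig)
    abort_state("header lists fewer signal lines than n_sig.",
                "ecgmend_format_error")

  sig_lines <- lines[2:(1 + n_sig)]
  parse_sig <- function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    gb <- regmatches(f[3], regexec("^([-0-9.eE+]+)\\(([-0-9]+)\\)/(\\S+)$",
                                   f[3]))[[1]]
    if (length(gb) != 4)
      abort_state(sprintf("cannot parse gain field '%s'.", f[3]),
                  "ecgmend_format_error")
    list(file_name = f[1], format = as.integer(f[2]),
         gain = as.numeric(gb[2]), baseline = as.integer(gb[3]),
         units = gb[4], initial_value = as.integer(f[6]),
         checksum = as.integer(f[7]),
         description = paste(f[-(1:8)], collapse = " "))
  }
  sigs <- lapply(sig_lines, parse_sig)
  fmts <- vapply(sigs, `[[`, 0L, "format")
  if (any(fmts != 16L))
    abort_state(sprintf(
      "unsupported WFDB storage format %s; only format 16 is handled.",
      paste(unique(fmts[fmts != 16L]), collapse = ", ")),
      "ecgmend_format_error")

  dat_path <- file.path(dirname(hea_path), sigs[[1]]$file_name)
  raw_n <- file.info(dat_path)$size / 2
  stored <- if (n_samples > 0) {
    con <- file(dat_path, "rb")
    on.exit(close(con))
    v <- readBin(con, "integer", n = raw_n, size = 2L, signed = TRUE,
                 endian = "little")
    if (length(v) != n_samples * n_sig)
      abort_state(sprintf(
        "signal file holds %d samples but header promises %d x %d.",
        length(v), n_samples, n_sig), "ecgmend_format_error")
    matrix(v, nrow = n_samples, ncol = n_sig, byrow = TRUE)
  } else matrix(integer(0), 0, n_sig)

  for (j in seq_len(n_sig)) {
    cs <- if (n_samples > 0) wfdb_checksum(stored[, j]) else 0L
    if (n_samples > 0 && cs != sigs[[j]]$checksum)
      abort_state(sprintf(
        "checksum mismatch on signal %d (stored %d, computed %d): corrupt record.",
        j, sigs[[j]]$checksum, cs), "ecgmend_corrupt_record")
  }

  gains <- vapply(sigs, `[[`, 0, "gain")
  baselines <- vapply(sigs, `[[`, 0L, "baseline")
  phys <- sweep(sweep(stored, 2, baselines, "-"), 2, gains, "/")

  label <- NULL
  lab_line <- grep("^#\\s*label:", comments, value = TRUE)
  if (length(lab_line))
    label <- trimws(sub("^#\\s*label:", "", lab_line[1]))

  hdr <- record_header(record_name, n_sig, fs, n_samples,
                       sigs[[1]]$file_name, gains, baselines,
                       vapply(sigs, `[[`, 0L, "initial_value"),
                       vapply(sigs, `[[`, 0L, "checksum"),
                       vapply(sigs, `[[`, "", "description"))
  list(record = ecg_record(phys, fs,
                           lead_names = hdr$signals$description,
                           patient_id = record_name, label = label),
       header = hdr)
}

#' Min-max normalize a record to [0, 1]
#'
#' Scales each lead independently as `(x - min) / (max - min)`; the per-lead
#' minima and maxima are stored on the record so [denormalize_record()] can
#' invert the map.  A constant lead has zero range and raises a
#' degenerate-lead error.
#'
#' @param record an [ecg_record()].
#' @return The normalized [ecg_record()] (`normalized = TRUE`).
#' @export
normalize_record <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  if (record$normalized) return(record)
  mins <- apply(record$signal, 2, min)
  maxs <- apply(record$signal, 2, max)
  if (any(maxs - mins <= 0))
    abort_state(sprintf(
      "lead(s) %s are constant; min-max normalization undefined.",
      paste(record$lead_names[maxs - mins <= 0], collapse = ", ")),
      "ecgmend_degenerate_lead")
  sig <- sweep(sweep(record$signal, 2, mins, "-"), 2, maxs - mins, "/")
  ecg_record(sig, record$fs, record$lead_names, record$patient_id,
             record$label, normalized = TRUE,
             scale_info = list(min = mins, max = maxs))
}

#' Invert min-max normalization
#' @param record a record previously scaled by [normalize_record()].
#' @return The record back in its original units.
#' @export
denormalize_record <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  if (!record$normalized || is.null(record$scale_info))
    abort_bad_arg("record is not normalized (or lost its scale info).")
  si <- record$scale_info
  sig <- sweep(sweep(record$signal, 2, si$max - si$min, "*"), 2, si$min, "+")
  ecg_record(sig, record$fs, record$lead_names, record$patient_id,
             record$label)
}

#' Leakage-free patient-level split
#'
#' Shuffles the patient ids with the given seed and assigns
#' `round(test * n)` patients to the test set, then `round(validation * n)`
#' to validation (rounding half away from zero), with the remainder
#' training.  All records of one patient therefore share one partition.
#'
#' @param patient_ids character vector of unique patient identifiers.
#' @param fractions numeric `(train, validation, test)` fractions, positive,
#'   summing to 1 (default `c(0.7, 0.1, 0.2)`).
#' @param seed integer seed.
#' @return A tibble of class `split_assignment` with columns `patient_id`
#'   and `partition` (factor: train/validation/test).
#' @export
#' @examples
#' sp <- patient_split(sprintf("P%04d", 1:2426), seed = 1)
#' table(sp$partition)[["test"]]  # 485
patient_split <- function(patient_ids, fractions = c(0.7, 0.1, 0.2),
                          seed = 1L) {
  if (anyDuplicated(patient_ids))
    abort_bad_arg("`patient_ids` must be unique.")
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    abort_bad_arg("`fractions` must be three positive numbers summing to 1.")
  n <- length(patient_ids)
  n_test <- round_half_up(fractions[3] * n)
  n_val <- round_half_up(fractions[2] * n)
  if (n_test + n_val > n)
    abort_bad_arg("fractions leave no patients for training.")
  shuffled <- with_seed(seed, sample(patient_ids))
  partition <- rep("train", n)
  partition[seq_len(n_test)] <- "test"
  if (n_val > 0) partition[n_test + seq_len(n_val)] <- "validation"
  out <- tibble::tibble(
    patient_id = shuffled,
    partition = factor(partition, levels = c("train", "validation", "test")))
  out <- out[order(match(out$patient_id, patient_ids)), ]
  attr(out, "fractions") <- fractions
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("split_assignment", class(out))
  out
}
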