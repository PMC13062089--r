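#' 12-lead ECG record
#'
#' Container for a multichannel ECG trace: a numeric `T x L` signal matrix
#' (time down the rows, one column per lead), the sampling frequency, lead
#' names, an opaque patient identifier and an optional rhythm label.
#' Amplitudes are in millivolts unless the record has been min-max scaled by
#' [normalize_record()], in which case `normalized` is `TRUE` and all entries
#' lie in `[0, 1]`.
#'
#' @param signal numeric matrix, `T` samples by `L` leads.
#' @param fs sampling frequency in Hz.
#' @param lead_names character vector of `L` unique lead identifiers.
#' @param patient_id opaque identifier (coerced to character).
#' @param label optional rhythm class (see [rhythm_classes()]).
#' @param normalized logical; `TRUE` once per-lead min-max scaling applied.
#' @param scale_info internal list of per-lead min/max kept for inversion.
#'
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(signal, fs, lead_names = standard_leads(),
                       patient_id = "anonymous", label = NULL,
                       normalized = FALSE, scale_info = NULL) {
  if (!is.matrix(signal) || !is.numeric(signal))
    abort_bad_arg("`signal` must be a numeric matrix (samples x leads).")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    abort_bad_arg("`fs` must be a single positive number (Hz).")
  if (length(lead_names) != ncol(signal))
    abort_bad_arg("`lead_names` must have one entry per signal column.")
  if (anyDuplicated(lead_names))
    abort_bad_arg("`lead_names` must be unique.")
  if (!is.null(label)) label <- match.arg(label, rhythm_classes())
  if (isTRUE(normalized) &&
      (min(signal) < -1e-9 || max(signal) > 1 + 1e-9))
    abort_bad_arg("a normalized record must have entries in [0, 1].")
  colnames(signal) <- lead_names
  structure(
    list(signal = signal, fs = fs, lead_names = as.character(lead_names),
         patient_id = as.character(patient_id), label = label,
         normalized = isTRUE(normalized), scale_info = scale_info),
    class = "ecg_record")
}

#' Standard 12-lead montage names
#' @return Character vector of the 12 conventional lead identifiers.
#' @export
standard_leads <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF",
    "V1", "V2", "V3", "V4", "V5", "V6")
}

#' Rhythm classes modelled by the synthetic generator
#' @return Character vector of the four rhythm class labels.
#' @export
rhythm_classes <- function() {
  c("sinus_rhythm", "sinus_bradycardia", "sinus_tachycardia",
    "atrial_fibrillation")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf(
    "<ecg_record> %d samples x %d leads @ %g Hz (%.1f s)%s\n",
    nrow(x$signal), ncol(x$signal), x$fs, nrow(x$signal) / x$fs,
    if (x$normalized) ", normalized" else ""))
  cat(sprintf("  patient: %s  label: %s\n", x$patient_id,
              x$label %||% "<none>"))
  invisible(x)
}

#' @export
dim.ecg_record <- function(x) dim(x$signal)

#' Tidy a record into a long tibble
#'
#' One row per (sample, lead) with the time in seconds, suitable for ggplot2.
#'
#' @param x an [ecg_record()].
#' @param leads optional subset of lead names.
#' @param ... unused.
#' @return A tibble with columns `time`, `lead`, `amplitude`.
#' @method tidy ecg_record
#' @export
tidy.ecg_record <- function(x, leads = NULL, ...) {
  leads <- leads %||% x$lead_names
  sig <- x$signal[, leads, drop = FALSE]
  tibble::tibble(
    time = rep((seq_len(nrow(sig)) - 1L) / x$fs, times = length(leads)),
    lead = factor(rep(leads, each = nrow(sig)), levels = x$lead_names),
    amplitude = as.numeric(sig))
}

#' Plot an ECG record
#'
#' @param object an [ecg_record()].
#' @param leads leads to draw (default all 12).
#' @param ... unused.
#' @return A ggplot object, one facet per lead.
#' @method autoplot ecg_record
#' @export
autoplot.ecg_record <- function(object, leads = NULL, ...) {
  df <- tidy.ecg_record(object, leads = leads)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$lead), ncol = 2,
                        scales = "free_y") +
    ggplot2::labs(x = "time (s)",
                  y = if (object$normalized) "amplitude (scaled)"
                      else "amplitude (mV)")
}

#' Fiducial annotations for an ECG record
#'
#' Per-beat landmark sample indices (0-based): the R peak plus P-wave
#' onset/end, QRS onset/end and T-wave end.  For rhythms without P waves
#' (atrial fibrillation) the P fields are `NA`.  Within every beat the
#' ordering `p_onset < p_end <= qrs_onset < qrs_end < t_end` holds for all
#' non-missing entries.
#'
#' @param r_peaks integer vector of R-peak sample indices (0-based).
#' @param p_onset,p_end,qrs_onset,qrs_end,t_end per-beat indices (0-based),
#'   `NA` allowed for absent waves.
#' @param n_samples record length used for bounds checking.
#' @return An object of class `ecg_fiducials`; its `as_tibble()` method gives
#'   one row per beat.
#' @export
ecg_fiducials <- function(r_peaks, p_onset = NULL, p_end = NULL,
                          qrs_onset = NULL, qrs_end = NULL, t_end = NULL,
                          n_samples = NULL) {
  nb <- length(r_peaks)
  fill <- function(v) if (is.null(v)) rep(NA_real_, nb) else as.numeric(v)
  out <- list(r_peaks = as.numeric(r_peaks), p_onset = fill(p_onset),
              p_end = fill(p_end), qrs_onset = fill(qrs_onset),
              qrs_end = fill(qrs_end), t_end = fill(t_end))
  lens <- lengths(out)
  if (any(lens != nb))
    abort_bad_arg("all fiducial fields must have one entry per beat.")
  if (!is.null(n_samples)) {
    vals <- unlist(out)
    vals <- vals[!is.na(vals)]
    if (length(vals) && (min(vals) < 0 || max(vals) >= n_samples))
      abort_bad_arg("fiducial indices must lie in [0, n_samples).")
  }
  ord_ok <- function(a, b) all(is.na(a) | is.na(b) | a <= b)
  if (!(ord_ok(out$p_onset, out$p_end) && ord_ok(out$p_end, out$qrs_onset) &&
        ord_ok(out$qrs_onset, out$qrs_end) && ord_ok(out$qrs_end, out$t_end)))
    abort_bad_arg("fiducials must be ordered p_onset < p_end <= qrs_onset < qrs_end < t_end within each beat.")
  structure(out, class = "ecg_fiducials")
}

#' @export
print.ecg_fiducials <- function(x, ...) {
  cat(sprintf("<ecg_fiducials> %d beats (%d with P wave)\n",
              length(x$r_peaks), sum(!is.na(x$p_onset))))
  invisible(x)
}

#' @method as_tibble ecg_fiducials
#' @export
as_tibble.ecg_fiducials <- function(x, ...) {
  tibble::tibble(beat = seq_along(x$r_peaks), r_peak = x$r_peaks,
                 p_onset = x$p_onset, p_end = x$p_end,
                 qrs_onset = x$qrs_onset, qrs_end = x$qrs_end,
                 t_end = x$t_end)
}
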