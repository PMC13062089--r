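# Fiducial delineation and morphological feature extraction.
#
# QRS detection is the classic Pan-Tompkins chain (band-pass, derivative,
# squaring, moving-window integration, adaptive dual thresholds with a
# refractory period and search-back).  P/T boundaries use windowed searches
# with percentage-of-peak crossings; QRS onset/end use a slope threshold.
# All window parameters are exposed so the delineator can be tuned.

#' Pan-Tompkins QRS detection
#'
#' Stage chain: zero-phase 5-15 Hz band-pass, 5-point derivative, squaring,
#' 150 ms moving-window integration, then adaptive dual thresholds with a
#' 200 ms refractory period and search-back at 1.66 times the running RR
#' estimate.  Detected beats are refined to the absolute band-passed maximum
#' within +/-75 ms.
#'
#' @param x single-lead numeric signal.
#' @param fs sampling frequency (Hz).
#' @return Strictly increasing integer vector of R-peak sample indices
#'   (0-based); empty for flat signals.
#' @export
pan_tompkins <- function(x, fs) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2 * fs)
    abort_bad_arg("signal must be at least 2 s long for QRS detection.")
  if (max(x) - min(x) < 1e-9) return(integer(0))

  bf <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  bp <- signal::filtfilt(bf, x)
  # centred 5-point derivative (zero phase)
  der <- stats::filter(bp, c(-1, -2, 0, 2, 1) / 8, sides = 2)
  der[is.na(der)] <- 0
  sq <- as.numeric(der)^2
  N <- max(3L, round(0.150 * fs))
  mwi <- stats::filter(sq, rep(1 / N, N), sides = 2)
  mwi[is.na(mwi)] <- 0
  mwi <- as.numeric(mwi)

  refrac <- round(0.2 * fs)
  # candidate peaks: local maxima of the integrated signal
  cand <- which(diff(sign(diff(mwi))) < 0) + 1L
  if (length(cand) == 0) return(integer(0))

  spki <- 0.5 * max(mwi[seq_len(min(n, 2 * fs))])
  npki <- 0.5 * mean(mwi[seq_len(min(n, 2 * fs))])
  thr1 <- npki + 0.25 * (spki - npki)

  peaks <- integer(0)
  rr_est <- NA_real_
  last_peak <- -Inf
  i <- 1L
  while (i <= length(cand)) {
    p <- cand[i]
    v <- mwi[p]
    if (p - last_peak > refrac && v > thr1) {
      if (length(peaks) > 0) {
        rr <- p - last_peak
        rr_est <- if (is.na(rr_est)) rr else 0.875 * rr_est + 0.125 * rr
      }
      peaks <- c(peaks, p)
      last_peak <- p
      spki <- 0.125 * v + 0.875 * spki
    } else if (v > thr1 && p - last_peak <= refrac) {
      # refractory: keep the larger of the two competing peaks
      if (length(peaks) && v > mwi[peaks[length(peaks)]]) {
        peaks[length(peaks)] <- p
        last_peak <- p
        spki <- 0.125 * v + 0.875 * spki
      }
    } else {
      npki <- 0.125 * v + 0.875 * npki
    }
    thr1 <- npki + 0.25 * (spki - npki)
    # search-back: no beat within 1.66 * RR estimate
    if (!is.na(rr_est) && length(peaks) &&
        p - last_peak > 1.66 * rr_est) {
      back <- cand[cand > last_peak + refrac & cand < p]
      if (length(back)) {
        vb <- mwi[back]
        j <- which.max(vb)
        if (vb[j] > 0.5 * thr1) {
          peaks <- c(peaks, back[j])
          last_peak <- back[j]
          spki <- 0.25 * vb[j] + 0.75 * spki
        }
      }
    }
    i <- i + 1L
  }
  if (length(peaks) == 0) return(integer(0))

  # refine to the band-passed absolute maximum near each integrated peak
  half <- round(0.075 * fs)
  refined <- vapply(peaks, function(p) {
    w <- max(1L, p - half):min(n, p + half)
    w[which.max(abs(bp[w]))]
  }, 0L)
  refined <- sort(unique(refined))
  # enforce the refractory period after refinement
  keep <- c(TRUE, diff(refined) > refrac)
  as.integer(refined[keep] - 1L)  # 0-based
}

#' Delineate P, QRS and T boundaries around known R peaks
#'
#' Per beat (all windows are configurable, defaults in milliseconds):
#' QRS onset/end by a slope-threshold search outward from the R peak within
#' +/-120 ms (boundary where the absolute derivative stays below 2% of the
#' beat's peak slope); P wave as the maximum in `[R - 300, R - 100]` ms with
#' onset/end at 10%-of-peak crossings (the P wave is reported absent when
#' its prominence is under `p_min_frac` of the R amplitude); T end at the
#' post-T-peak 10% crossing inside `[R + 120, R + min(500, 0.7 RR)]` ms.
#' Beats whose windows leave the record are dropped.
#'
#' @param record an [ecg_record()] (lead II is delineated by default).
#' @param r_peaks R-peak indices (0-based), e.g. from [pan_tompkins()].
#' @param lead lead name used for delineation.
#' @param qrs_win,p_win,t_win,slope_frac,cross_frac,p_min_frac tuning
#'   parameters (windows in seconds).
#' @return An [ecg_fiducials()] object (P fields `NA` where absent).
#' @export
delineate <- function(record, r_peaks, lead = "II",
                      qrs_win = 0.120, p_win = c(0.300, 0.100),
                      t_win = c(0.120, 0.500), slope_frac = 0.02,
                      cross_frac = 0.10, p_min_frac = 0.06) {
  stopifnot(inherits(record, "ecg_record"))
  if (length(r_peaks) < 1)
    abort_bad_arg("need at least one R peak to delineate.")
  fs <- record$fs
  x <- record$signal[, lead]
  n <- length(x)
  r1 <- as.integer(r_peaks) + 1L  # 1-based
  d <- c(0, diff(x)) * fs
  # lightly smoothed derivative for the slope-threshold search, so residual
  # high-frequency ripple (e.g. after denoising) cannot mask the QRS bounds
  ds <- as.numeric(stats::filter(d, rep(1 / 7, 7), sides = 2))
  ds[is.na(ds)] <- 0
  rr_mean <- if (length(r1) > 1) mean(diff(r1)) / fs else 1

  slope_bound <- function(r, dir) {
    lim <- round(qrs_win * fs)
    idx <- if (dir < 0) r:max(1L, r - lim) else r:min(n, r + lim)
    mx <- max(abs(ds[idx]))
    # adaptive floor: stay above the record's background slope (residual
    # ripple on denoised signals) while tracking the QRS peak slope
    thr <- max(slope_frac * mx, 2 * stats::median(abs(ds)))
    run <- 0L
    for (j in idx) {
      if (abs(ds[j]) < thr) run <- run + 1L else run <- 0L
      if (run >= 5L) return(j)
    }
    idx[length(idx)]
  }

  res <- list(r = integer(0), po = numeric(0), pe = numeric(0),
              qo = numeric(0), qe = numeric(0), te = numeric(0))
  for (b in seq_along(r1)) {
    r <- r1[b]
    rr <- if (b < length(r1)) (r1[b + 1] - r) / fs else rr_mean
    t_hi <- r + round(min(t_win[2], 0.7 * rr) * fs)
    p_lo <- r - round(p_win[1] * fs)
    if (p_lo < 1L || t_hi > n) next  # window leaves the record

    qo <- slope_bound(r, -1L)
    qe <- slope_bound(r, +1L)

    # P wave search; the window shrinks with the local RR so the previous
    # beat's T wave cannot masquerade as a P wave at short cycle lengths
    rr_prev <- if (b > 1) (r - r1[b - 1]) / fs else rr
    p_lo_b <- r - round(min(p_win[1], 0.45 * rr_prev) * fs)
    p_hi <- r - round(p_win[2] * fs)
    pw <- p_lo_b:p_hi
    base_p <- (x[p_lo_b] + x[p_hi]) / 2
    pk <- pw[which.max(x[pw])]
    prom <- x[pk] - base_p
    r_amp <- abs(x[r] - base_p)
    if (prom >= p_min_frac * r_amp && pk > p_lo_b && pk < p_hi) {
      lev <- base_p + cross_frac * prom
      po <- pk; while (po > p_lo_b && x[po - 1] > lev) po <- po - 1L
      pe <- pk; while (pe < p_hi && x[pe + 1] > lev) pe <- pe + 1L
    } else {
      po <- NA_integer_; pe <- NA_integer_
    }

    # T wave end
    t_lo <- r + round(t_win[1] * fs)
    tw <- t_lo:t_hi
    base_t <- x[t_hi]
    tk <- tw[which.max(abs(x[tw] - base_t))]
    prom_t <- x[tk] - base_t
    lev_t <- base_t + cross_frac * prom_t
    te <- tk
    if (prom_t > 0) {
      while (te < t_hi && x[te + 1] > lev_t) te <- te + 1L
    } else {
      while (te < t_hi && x[te + 1] < lev_t) te <- te + 1L
    }

    # ordering safety: clip into the invariant required of fiducials
    if (!is.na(pe)) pe <- min(pe, qo)
    if (!is.na(po)) po <- min(po, pe - 1L)
    qe <- max(qe, r + 1L)
    te <- max(te, qe + 1L)

    res$r <- c(res$r, r - 1L)
    res$po <- c(res$po, po - 1L)
    res$pe <- c(res$pe, pe - 1L)
    res$qo <- c(res$qo, qo - 1L)
    res$qe <- c(res$qe, qe - 1L)
    res$te <- c(res$te, te - 1L)
  }
  ecg_fiducials(res$r, res$po, res$pe, res$qo, res$qe, res$te,
                n_samples = n)
}

#' Frontal-plane electrical axis from leads I and aVF
#'
#' `axis = atan2(net_aVF, net_I) * 180 / pi`: 0 degrees points leftward
#' (positive lead I), +90 degrees inferior (positive aVF).
#'
#' @param net_amp_lead_i,net_amp_avf net wave amplitudes (signed areas) in
#'   leads I and aVF.
#' @return Axis in degrees in `(-180, 180]`.
#' @export
electrical_axis <- function(net_amp_lead_i, net_amp_avf) {
  if (net_amp_lead_i == 0 && net_amp_avf == 0)
    abort_state("both net amplitudes are zero: axis indeterminate.",
                "ecgmend_indeterminate_axis")
  atan2(net_amp_avf, net_amp_lead_i) * 180 / pi
}

# signed area of lead `lead` between 0-based bounds a..b (per beat), mean
# over beats with non-missing bounds
net_amplitude <- function(record, a, b, lead) {
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NA_real_)
  x <- record$signal[, lead]
  mean(vapply(which(ok), function(i) {
    idx <- (a[i] + 1L):(b[i] + 1L)
    sum(x[idx]) / record$fs
  }, 0))
}

#' Build the per-record morphological feature table
#'
#' One row per record with the feature schema used for rhythm
#' classification: mean RR interval; mean per-beat fiducial offsets relative
#' to the R peak (seconds); P/QRS/T electrical axes from the signed wave
#' areas in leads I and aVF; device metadata pass-throughs (`bandwidth`,
#' `filtering`); and a `p_present` indicator (fraction of beats with a
#' detected P wave >= 0.5).  Absent-P features carry the sentinel -1.
#'
#' @param records list of [ecg_record()]s.
#' @param annotations list of [ecg_fiducials()], one per record.
#' @param labels optional character labels (default: record labels).
#' @param bandwidth,filtering metadata columns (recycled).
#' @return A tibble with columns `patient_id`, `label`, `bandwidth`,
#'   `filtering`, `rr_interval`, `p_onset`, `p_end`, `qrs_onset`,
#'   `qrs_end`, `t_end`, `p_axis`, `qrs_axis`, `t_axis`, `p_present`.
#' @export
build_feature_table <- function(records, annotations, labels = NULL,
                                bandwidth = 40, filtering = 0L) {
  if (length(records) != length(annotations))
    abort_bad_arg("need exactly one annotation set per record.")
  labels <- labels %||% vapply(records, function(r)
    r$label %||% NA_character_, "")
  bandwidth <- rep_len(bandwidth, length(records))
  filtering <- rep_len(filtering, length(records))

  rows <- lapply(seq_along(records), function(i) {
    rec <- records[[i]]
    f <- annotations[[i]]
    if (length(f$r_peaks) < 2)
      return(tibble::tibble(
        patient_id = rec$patient_id, label = labels[i],
        bandwidth = bandwidth[i], filtering = filtering[i],
        rr_interval = NA_real_, p_onset = -1, p_end = -1,
        qrs_onset = NA_real_, qrs_end = NA_real_, t_end = NA_real_,
        p_axis = -1, qrs_axis = NA_real_, t_axis = NA_real_,
        p_present = 0))
    fs <- rec$fs
    rel <- function(v) mean((v - f$r_peaks) / fs, na.rm = TRUE)
    p_frac <- mean(!is.na(f$p_onset))
    has_p <- p_frac >= 0.5
    qrs_ax <- electrical_axis(
      net_amplitude(rec, f$qrs_onset, f$qrs_end, "I"),
      net_amplitude(rec, f$qrs_onset, f$qrs_end, "aVF"))
    t_ax <- electrical_axis(
      net_amplitude(rec, f$qrs_end, f$t_end, "I"),
      net_amplitude(rec, f$qrs_end, f$t_end, "aVF"))
    p_ax <- if (has_p)
      electrical_axis(net_amplitude(rec, f$p_onset, f$p_end, "I"),
                      net_amplitude(rec, f$p_onset, f$p_end, "aVF"))
      else -1
    tibble::tibble(
      patient_id = rec$patient_id, label = labels[i],
      bandwidth = bandwidth[i], filtering = filtering[i],
      rr_interval = mean(diff(f$r_peaks)) / fs,
      p_onset = if (has_p) rel(f$p_onset) else -1,
      p_end = if (has_p) rel(f$p_end) else -1,
      qrs_onset = rel(f$qrs_onset),
      qrs_end = rel(f$qrs_end),
      t_end = rel(f$t_end),
      p_axis = p_ax, qrs_axis = qrs_ax, t_axis = t_ax,
      p_present = p_frac)
  })
  dplyr::bind_rows(rows)
}

#' Extract features for a whole cohort
#'
#' Convenience wrapper: runs [pan_tompkins()] on lead II of every record,
#' delineates, and assembles the feature table.  Records where detection
#' fails fall back to NA features (rows are kept so the table aligns with
#' the cohort).
#'
#' @param records list of [ecg_record()]s.
#' @param labels optional labels (default: record labels).
#' @param filtering metadata code for the preprocessing applied.
#' @return A feature tibble as from [build_feature_table()].
#' @export
extract_features <- function(records, labels = NULL, filtering = 0L) {
  anns <- lapply(records, function(r) {
    rp <- pan_tompkins(r$signal[, "II"], r$fs)
    if (length(rp) < 1) return(ecg_fiducials(integer(0)))
    tryCatch(delineate(r, rp), error = function(e) ecg_fiducials(rp))
  })
  build_feature_table(records, anns, labels = labels,
                      filtering = filtering)
}
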