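# Synthetic 12-lead ECG cohorts with analytically known fiducials.
#
# A single-lead template beat is a sum of Gaussian bumps (P, Q, R, S, T),
# tiled at the beat period; the 12 leads are fixed linear projections of the
# template with lead-specific gains (Einthoven-consistent limb leads).  The
# bump centres/widths are the ground truth the delineation stage is scored
# against, so they are returned alongside the signal.

# Wave timing (seconds relative to the R peak) and amplitudes (mV).  P and T
# positions/widths shrink with sqrt(RR) so fast rhythms stay physiological
# (Bazett-style rate correction); QRS timing is rate-invariant.
wave_params <- function(rr) {
  s <- sqrt(rr)
  list(
    P = list(center = -min(max(0.16 * s, 0.11), 0.28), width = 0.018 * s,
             amp = 0.15),
    Q = list(center = -0.040, width = 0.008, amp = -0.12),
    R = list(center = 0.000, width = 0.012, amp = 1.20),
    S = list(center = 0.040, width = 0.010, amp = -0.25),
    T = list(center = min(max(0.22 * s, 0.14), 0.34), width = 0.030 * s,
             amp = 0.35))
}

# fixed lead projection gains; limb leads satisfy Einthoven/Goldberger
# relations (III = II - I, aVR = -(I+II)/2, ...), giving a normal QRS axis
# of about 43 degrees
lead_gains <- function() {
  c(I = 0.70, II = 1.00, III = 0.30, aVR = -0.85, aVL = 0.20, aVF = 0.65,
    V1 = -0.35, V2 = 0.25, V3 = 0.65, V4 = 1.05, V5 = 0.95, V6 = 0.85)
}

#' Generate a clean synthetic 12-lead ECG with known fiducials
#'
#' Builds a noiseless record of the requested rhythm.  For the three sinus
#' classes the beat period is exactly `60 / heart_rate` seconds; for atrial
#' fibrillation the P bump is suppressed and successive RR intervals are
#' drawn i.i.d. from a log-normal distribution with `sdlog = 0.15` (so the
#' coefficient of variation of RR is about 15%), giving the irregularly
#' irregular rhythm.
#'
#' @param duration_s record length in seconds (> 0).
#' @param fs sampling frequency in Hz (> 0).
#' @param heart_rate mean heart rate in beats per minute, in `[20, 300]`.
#' @param rhythm one of [rhythm_classes()].
#' @param seed integer seed (drives the AF interval draws).
#' @param patient_id identifier stored on the record.
#' @return A list with elements `record` ([ecg_record()]) and `fiducials`
#'   ([ecg_fiducials()], 0-based sample indices; P fields `NA` for atrial
#'   fibrillation).
#' @export
#' @examples
#' g <- generate_clean_ecg(10, 500, 60, "sinus_rhythm", seed = 1)
#' nrow(g$record$signal)  # 5000
#' diff(g$fiducials$r_peaks)  # all 500
generate_clean_ecg <- function(duration_s = 10, fs = 500, heart_rate = 75,
                               rhythm = rhythm_classes(), seed = 1L,
                               patient_id = "synthetic") {
  rhythm <- match.arg(rhythm)
  if (!is.numeric(duration_s) || duration_s <= 0)
    abort_bad_arg("`duration_s` must be positive.")
  if (!is.numeric(fs) || fs <= 0)
    abort_bad_arg("`fs` must be positive.")
  if (!is.numeric(heart_rate) || heart_rate < 20 || heart_rate > 300)
    abort_bad_arg("`heart_rate` must lie in [20, 300] bpm.")

  n <- round(duration_s * fs)
  mean_rr <- 60 / heart_rate

  # beat-onset times: periodic for sinus rhythms, log-normal i.i.d. for AF
  r_times <- if (rhythm == "atrial_fibrillation") {
    with_seed(seed, {
      # enough draws to cover the record; sdlog 0.15 => CV(RR) ~ 0.15
      k <- ceiling(duration_s / mean_rr * 2) + 5
      rr <- stats::rlnorm(k, meanlog = log(mean_rr) - 0.15^2 / 2,
                          sdlog = 0.15)
      cumsum(c(mean_rr / 2, rr))
    })
  } else {
    seq(mean_rr / 2, duration_s, by = mean_rr)
  }
  r_times <- r_times[r_times < duration_s]

  tt <- (seq_len(n) - 1L) / fs
  template <- numeric(n)
  nb <- length(r_times)
  fid <- list(r = numeric(nb), po = numeric(nb), pe = numeric(nb),
              qo = numeric(nb), qe = numeric(nb), te = numeric(nb))
  rr_next <- c(diff(r_times), mean_rr)

  for (k in seq_len(nb)) {
    wp <- wave_params(rr_next[k])
    if (rhythm == "atrial_fibrillation") wp$P$amp <- 0
    for (w in wp) {
      if (w$amp == 0) next
      c_t <- r_times[k] + w$center
      lo <- max(1L, floor((c_t - 4 * w$width) * fs) + 1L)
      hi <- min(n, ceiling((c_t + 4 * w$width) * fs) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      template[idx] <- template[idx] +
        w$amp * exp(-((tt[idx] - c_t)^2) / (2 * w$width^2))
    }
    # analytically known bump boundaries: centre +/- 3 widths (0-based idx)
    fid$r[k] <- round(r_times[k] * fs)
    fid$po[k] <- round((r_times[k] + wp$P$center - 3 * wp$P$width) * fs)
    fid$pe[k] <- round((r_times[k] + wp$P$center + 3 * wp$P$width) * fs)
    fid$qo[k] <- round((r_times[k] + wp$Q$center - 3 * wp$Q$width) * fs)
    fid$qe[k] <- round((r_times[k] + wp$S$center + 3 * wp$S$width) * fs)
    fid$te[k] <- round((r_times[k] + wp$T$center + 3 * wp$T$width) * fs)
  }

  # keep only beats whose full complex fits inside the record
  keep <- fid$po >= 0 & fid$te < n
  if (rhythm == "atrial_fibrillation") keep <- fid$qo >= 0 & fid$te < n
  fid <- lapply(fid, `[`, keep)
  # ordering safety clip (P end may touch QRS onset at extreme rates)
  fid$pe <- pmin(fid$pe, fid$qo)

  sig <- outer(template, lead_gains())
  colnames(sig) <- standard_leads()

  af <- rhythm == "atrial_fibrillation"
  list(
    record = ecg_record(sig, fs, patient_id = patient_id, label = rhythm),
    fiducials = ecg_fiducials(
      r_peaks = fid$r,
      p_onset = if (af) NULL else fid$po,
      p_end = if (af) NULL else fid$pe,
      qrs_onset = fid$qo, qrs_end = fid$qe, t_end = fid$te,
      n_samples = n))
}

#' Mixed-noise specification
#'
#' Parameters of the four noise sources added by [add_noise()]: sinusoidal
#' baseline wander, sinusoidal powerline interference, band-limited Gaussian
#' muscle (EMG) artifact, and white Gaussian noise.  Amplitudes are in the
#' record's units (mV for raw records).
#'
#' @param baseline_wander_amp,baseline_wander_freq amplitude (mV) and
#'   frequency (Hz) of the baseline wander sinusoid.
#' @param powerline_amp,powerline_freq amplitude and mains frequency
#'   (50 or 60 Hz typically).
#' @param emg_amp,emg_band amplitude and passband (Hz) of the muscle-artifact
#'   noise.
#' @param white_sigma standard deviation of the white noise.
#' @param seed integer seed making the noise draw reproducible.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(baseline_wander_amp = 0.10, baseline_wander_freq = 0.33,
                       powerline_amp = 0.05, powerline_freq = 50,
                       emg_amp = 0.05, emg_band = c(20, 100),
                       white_sigma = 0.02, seed = 1L) {
  amps <- c(baseline_wander_amp, powerline_amp, emg_amp, white_sigma)
  if (any(amps < 0)) abort_bad_arg("noise amplitudes must be >= 0.")
  structure(list(baseline_wander_amp = baseline_wander_amp,
                 baseline_wander_freq = baseline_wander_freq,
                 powerline_amp = powerline_amp,
                 powerline_freq = powerline_freq,
                 emg_amp = emg_amp, emg_band = emg_band,
                 white_sigma = white_sigma, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Add mixed noise to an ECG record
#'
#' Adds the four noise components of a [noise_spec()].  Baseline wander and
#' powerline interference are sinusoids with per-record random phase, shared
#' across leads (they are common-mode in practice); EMG and white noise are
#' drawn independently per lead.  The draw is fully determined by
#' `spec$seed`, so the same record and spec always give the same output.
#'
#' @param record an [ecg_record()].
#' @param spec a [noise_spec()].
#' @return A new [ecg_record()] with noise added.
#' @export
add_noise <- function(record, spec) {
  stopifnot(inherits(record, "ecg_record"), inherits(spec, "noise_spec"))
  fs <- record$fs
  if (spec$baseline_wander_freq >= fs / 2 || spec$powerline_freq >= fs / 2 ||
      max(spec$emg_band) >= fs / 2)
    abort_bad_arg("noise frequencies must be below the Nyquist rate fs/2.")
  n <- nrow(record$signal)
  L <- ncol(record$signal)
  tt <- (seq_len(n) - 1L) / fs

  noise <- with_seed(spec$seed, {
    out <- matrix(0, n, L)
    if (spec$baseline_wander_amp > 0) {
      ph <- stats::runif(1, 0, 2 * pi)
      out <- out + spec$baseline_wander_amp *
        sin(2 * pi * spec$baseline_wander_freq * tt + ph)
    }
    if (spec$powerline_amp > 0) {
      ph <- stats::runif(1, 0, 2 * pi)
      out <- out + spec$powerline_amp *
        sin(2 * pi * spec$powerline_freq * tt + ph)
    }
    if (spec$emg_amp > 0) {
      bf <- signal::butter(2, spec$emg_band / (fs / 2), type = "pass")
      emg <- apply(matrix(stats::rnorm(n * L), n, L), 2,
                   function(x) signal::filtfilt(bf, x))
      # rescale to the requested RMS amplitude
      emg <- emg / max(stats::sd(as.numeric(emg)), 1e-12) * spec$emg_amp
      out <- out + emg
    }
    if (spec$white_sigma > 0)
      out <- out + matrix(stats::rnorm(n * L, sd = spec$white_sigma), n, L)
    out
  })

  ecg_record(record$signal + noise, fs, record$lead_names,
             record$patient_id, record$label)
}

# Partial Fisher-Yates shuffle: the first k entries of a uniformly shuffled
# 1..n, driven by R's Mersenne-Twister stream.  Used for all index sampling
# without replacement in the missing-data simulator.
fisher_yates <- function(n, k) {
  idx <- seq_len(n)
  k <- min(k, n)
  for (i in seq_len(k)) {
    j <- i + floor(stats::runif(1) * (n - i + 1))
    if (j > n) j <- n  # guard the measure-zero runif(1) == 1 case
    tmp <- idx[i]; idx[i] <- idx[j]; idx[j] <- tmp
  }
  idx[seq_len(k)]
}

#' Simulate missing data in an ECG record
#'
#' Masks `round(ratio * T)` time samples, selected without replacement by a
#' partial Fisher-Yates shuffle over sample indices (Mersenne-Twister
#' stream).  In `samples` mode individual time points are dropped; in
#' `segments` mode (the default; equipment dropouts are contiguous)
#' non-overlapping blocks of `segment_len` samples are masked until the
#' requested ratio is met exactly (the final block is truncated if needed).
#' By default the same time indices are masked in every lead; set
#' `per_lead = TRUE` for independent per-lead masks.
#'
#' @param record an [ecg_record()].
#' @param ratio fraction of samples to remove, in `[0, 1)`.
#' @param mode `"segments"` or `"samples"`.
#' @param segment_len block length in samples for segment mode (default 250,
#'   i.e. 0.5 s at 500 Hz).
#' @param seed integer seed.
#' @param per_lead mask each lead independently instead of sharing the mask.
#' @return A list with `record` (masked entries set to 0) and `mask`
#'   (binary `T x L` matrix, 1 = observed).
#' @export
simulate_missing <- function(record, ratio, mode = c("segments", "samples"),
                             segment_len = 250L, seed = 1L,
                             per_lead = FALSE) {
  stopifnot(inherits(record, "ecg_record"))
  mode <- match.arg(mode)
  if (!is.numeric(ratio) || ratio < 0 || ratio >= 1)
    abort_bad_arg("`ratio` must lie in [0, 1).")
  if (mode == "segments" && (!is_count(segment_len) || segment_len < 1))
    abort_bad_arg("`segment_len` must be a positive integer.")
  n <- nrow(record$signal)
  L <- ncol(record$signal)
  n_missing <- round_half_up(ratio * n)

  pick_indices <- function() {
    if (n_missing == 0) return(integer(0))
    if (mode == "samples") {
      fisher_yates(n, n_missing)
    } else {
      n_slots <- floor(n / segment_len)
      n_blocks <- ceiling(n_missing / segment_len)
      if (n_blocks > n_slots)
        abort_bad_arg("requested ratio cannot be met with non-overlapping segments of this length.")
      slots <- fisher_yates(n_slots, n_blocks)
      rem <- n_missing - (n_blocks - 1L) * segment_len
      unlist(lapply(seq_along(slots), function(j) {
        s0 <- (slots[j] - 1L) * segment_len
        len <- if (j == length(slots)) rem else segment_len
        s0 + seq_len(len)
      }))
    }
  }

  mask <- matrix(1, n, L)
  with_seed(seed, {
    if (per_lead) {
      for (l in seq_len(L)) mask[pick_indices(), l] <- 0
    } else {
      mask[pick_indices(), ] <- 0
    }
  })
  out <- record
  out$signal <- record$signal * mask
  list(record = out, mask = mask)
}

#' Cohort specification for the synthetic generator
#'
#' @param n_patients number of records to generate (one per patient).
#' @param class_priors named probabilities over [rhythm_classes()]
#'   (non-negative, summing to 1).
#' @param hr_ranges named list of `c(lo, hi)` heart-rate ranges (bpm) per
#'   class.  Defaults: bradycardia 40-59, sinus 60-100, tachycardia 101-170,
#'   atrial fibrillation 60-150.  Bradycardia must stay below 60 bpm and
#'   tachycardia above 100, and the three sinus ranges must not overlap.
#' @param duration_s,fs record geometry (defaults 10 s at 500 Hz).
#' @param seed integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 240L,
                        class_priors = c(sinus_rhythm = 0.25,
                                         sinus_bradycardia = 0.25,
                                         sinus_tachycardia = 0.25,
                                         atrial_fibrillation = 0.25),
                        hr_ranges = list(sinus_rhythm = c(60, 100),
                                         sinus_bradycardia = c(40, 59),
                                         sinus_tachycardia = c(101, 170),
                                         atrial_fibrillation = c(60, 150)),
                        duration_s = 10, fs = 500, seed = 1L) {
  if (!is_count(n_patients) || n_patients <= 0)
    abort_bad_arg("`n_patients` must be a positive integer.")
  cls <- rhythm_classes()
  if (!setequal(names(class_priors), cls))
    abort_bad_arg("`class_priors` must be named by the four rhythm classes.")
  class_priors <- class_priors[cls]
  if (any(class_priors < 0) || abs(sum(class_priors) - 1) > 1e-8)
    abort_bad_arg("`class_priors` must be non-negative and sum to 1.")
  if (hr_ranges$sinus_bradycardia[2] >= 60)
    abort_bad_arg("bradycardia heart-rate range must stay below 60 bpm.")
  if (hr_ranges$sinus_tachycardia[1] <= 100)
    abort_bad_arg("tachycardia heart-rate range must stay above 100 bpm.")
  if (hr_ranges$sinus_bradycardia[2] >= hr_ranges$sinus_rhythm[1] ||
      hr_ranges$sinus_rhythm[2] >= hr_ranges$sinus_tachycardia[1])
    abort_bad_arg("sinus-class heart-rate ranges must not overlap.")
  structure(list(n_patients = as.integer(n_patients),
                 class_priors = class_priors, hr_ranges = hr_ranges,
                 duration_s = duration_s, fs = fs, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a labelled synthetic cohort
#'
#' Draws a rhythm label per patient from the class priors and a heart rate
#' uniformly from the class range, then generates each record with
#' [generate_clean_ecg()].  By construction the label is recoverable from
#' the signal: mean RR maps back into the generating class's range, and
#' atrial fibrillation is marked by RR irregularity plus absent P waves.
#'
#' @param spec a [cohort_spec()].
#' @return A list of class `ecg_cohort` with elements `records` (list of
#'   [ecg_record()]), `fiducials` (list of [ecg_fiducials()]), `labels`
#'   (character) and `patient_ids`.  `as_tibble()` gives the per-record
#'   metadata.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  draws <- with_seed(spec$seed, {
    labels <- sample(rhythm_classes(), n, replace = TRUE,
                     prob = spec$class_priors)
    hrs <- vapply(labels, function(cl) {
      r <- spec$hr_ranges[[cl]]
      stats::runif(1, r[1], r[2])
    }, 0)
    list(labels = labels, hrs = hrs,
         seeds = sample.int(2^31 - 1, n))
  })
  ids <- sprintf("P%05d", seq_len(n))
  gen <- lapply(seq_len(n), function(i)
    generate_clean_ecg(spec$duration_s, spec$fs, draws$hrs[i],
                       draws$labels[i], seed = draws$seeds[i],
                       patient_id = ids[i]))
  structure(list(records = lapply(gen, `[[`, "record"),
                 fiducials = lapply(gen, `[[`, "fiducials"),
                 labels = draws$labels, heart_rates = draws$hrs,
                 patient_ids = ids),
            class = "ecg_cohort")
}

#' @export
print.ecg_cohort <- function(x, ...) {
  cat(sprintf("<ecg_cohort> %d records\n", length(x$records)))
  print(table(x$labels))
  invisible(x)
}

#' @method as_tibble ecg_cohort
#' @export
as_tibble.ecg_cohort <- function(x, ...) {
  tibble::tibble(patient_id = x$patient_ids, label = x$labels,
                 heart_rate = x$heart_rates,
                 n_beats = vapply(x$fiducials,
                                  function(f) length(f$r_peaks), 0))
}
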