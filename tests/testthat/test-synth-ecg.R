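test_that("clean generator produces the requested geometry and periodic beats", {
  g <- clean_sinus()
  expect_equal(dim(g$record$signal), c(5000L, 12L))
  expect_equal(g$record$fs, 500)
  expect_length(g$fiducials$r_peaks, 10)
  expect_true(all(diff(g$fiducials$r_peaks) == 500))
  # fiducial ordering invariant
  f <- g$fiducials
  expect_true(all(f$p_onset < f$p_end))
  expect_true(all(f$p_end <= f$qrs_onset))
  expect_true(all(f$qrs_onset < f$qrs_end))
  expect_true(all(f$qrs_end < f$t_end))
})

test_that("annotated R peaks sit on the lead II maxima", {
  for (hr in c(45, 60, 110, 160)) {
    g <- generate_clean_ecg(10, 500, hr, "sinus_rhythm", seed = 3)
    ii <- g$record$signal[, "II"]
    for (p in g$fiducials$r_peaks) {
      w <- max(1, p - 9):min(5000, p + 11)
      expect_equal(w[which.max(ii[w])] - 1, p)
    }
  }
})

test_that("atrial fibrillation has irregular RR and no P annotations", {
  af <- generate_clean_ecg(10, 500, 90, "atrial_fibrillation", seed = 7)
  rr <- diff(af$fiducials$r_peaks)
  expect_gt(stats::sd(rr) / mean(rr), 0.05)
  expect_true(all(is.na(af$fiducials$p_onset)))
  expect_true(all(is.na(af$fiducials$p_end)))
  # same seed reproduces the same record
  af2 <- generate_clean_ecg(10, 500, 90, "atrial_fibrillation", seed = 7)
  expect_identical(af$record$signal, af2$record$signal)
})

test_that("generator rejects invalid arguments", {
  expect_error(generate_clean_ecg(0, 500, 60), class = "ecgmend_invalid_argument")
  expect_error(generate_clean_ecg(10, -1, 60), class = "ecgmend_invalid_argument")
  expect_error(generate_clean_ecg(10, 500, 10), class = "ecgmend_invalid_argument")
  expect_error(generate_clean_ecg(10, 500, 400), class = "ecgmend_invalid_argument")
})

test_that("noise injection is additive, seeded and has the right scale", {
  g <- clean_sinus()
  # zero noise leaves the record untouched
  z <- add_noise(g$record, noise_spec(0, 0.33, 0, 50, 0, c(20, 100), 0, seed = 1))
  expect_identical(z$signal, g$record$signal)
  # seeded determinism: bit-identical outputs
  ns <- noise_spec(seed = 3)
  expect_identical(add_noise(g$record, ns)$signal,
                   add_noise(g$record, ns)$signal)
  # white-noise sd close to sigma at n = 5000 (law of large numbers)
  zero <- ecg_record(matrix(0, 5000, 12), 500)
  nz <- add_noise(zero, noise_spec(0, 0.33, 0, 50, 0, c(20, 100), 0.5, seed = 4))
  expect_lt(abs(stats::sd(as.numeric(nz$signal)) - 0.5) / 0.5, 0.05)
  # aliasing guard
  expect_error(add_noise(g$record, noise_spec(powerline_freq = 400)),
               class = "ecgmend_invalid_argument")
})

test_that("sample-mode missingness removes exactly round(ratio * T) distinct indices", {
  g <- clean_sinus()
  m0 <- simulate_missing(g$record, 0, seed = 1)
  expect_true(all(m0$mask == 1))
  expect_identical(m0$record$signal, g$record$signal)

  m <- simulate_missing(g$record, 0.5, "samples", seed = 5)
  miss <- which(m$mask[, 1] == 0)
  expect_length(miss, 2500)
  expect_equal(anyDuplicated(miss), 0)
  # shared across leads by default
  expect_true(all(apply(m$mask, 1, function(r) all(r == r[1]))))
  expect_true(all(m$record$signal[m$mask == 0] == 0))
  expect_error(simulate_missing(g$record, 1.2), class = "ecgmend_invalid_argument")
})

test_that("segment-mode blocks are non-overlapping (brute-force pairwise check)", {
  g <- clean_sinus()
  m <- simulate_missing(g$record, 0.3, "segments", segment_len = 100L, seed = 6)
  expect_equal(sum(m$mask[, 1] == 0), 1500)
  runs <- rle(m$mask[, 1])
  blocks <- which(runs$values == 0)
  starts <- cumsum(c(1, utils::head(runs$lengths, -1)))[blocks]
  ends <- starts + runs$lengths[blocks] - 1
  # brute-force interval intersection across all pairs
  for (i in seq_along(starts))
    for (j in seq_along(starts))
      if (i != j)
        expect_true(ends[i] < starts[j] || ends[j] < starts[i])
  expect_gte(length(starts), 1)
})

test_that("Fisher-Yates selection is marginally uniform (2 of 5)", {
  counts <- integer(5)
  set.seed(11)
  for (i in 1:10000) {
    s <- ecgmend:::fisher_yates(5, 2)
    counts[s] <- counts[s] + 1
  }
  expect_true(all(abs(counts / 10000 - 0.4) <= 0.02))
})

test_that("normalization commutes with masking on observed entries", {
  g <- clean_sinus()
  for (seed in 1:5) {
    m <- simulate_missing(g$record, 0.3, "segments", seed = seed)
    nm <- normalize_record(g$record)
    obs <- m$mask == 1
    # normalize-then-mask vs mask-then-normalize agree on observed entries
    # (mins/maxes are computed on the full record in both orders here)
    masked_norm <- nm$signal * m$mask
    expect_equal(masked_norm[obs], nm$signal[obs])
    expect_true(all(masked_norm[!obs] == 0))
  }
})

test_that("cohort generation follows the class priors", {
  co <- fixture("cohort100", function()
    generate_cohort(cohort_spec(100, duration_s = 2, seed = 9)))
  expect_length(co$labels, 100)
  expect_equal(sum(table(co$labels)), 100)
  expect_length(co$records, 100)

  one <- generate_cohort(cohort_spec(
    10, class_priors = c(sinus_rhythm = 1, sinus_bradycardia = 0,
                         sinus_tachycardia = 0, atrial_fibrillation = 0),
    duration_s = 2, seed = 2))
  expect_true(all(one$labels == "sinus_rhythm"))
  expect_error(cohort_spec(0), class = "ecgmend_invalid_argument")
})

test_that("large-cohort class counts stay within 3 sigma of the multinomial", {
  co <- generate_cohort(cohort_spec(2000, duration_s = 1, seed = 13))
  counts <- table(factor(co$labels, levels = rhythm_classes()))
  sigma <- sqrt(2000 * 0.25 * 0.75)
  expect_true(all(abs(counts - 500) <= 3 * sigma))
  # labels are recoverable from RR statistics by construction
  hr <- co$heart_rates
  expect_true(all(hr[co$labels == "sinus_bradycardia"] < 60))
  expect_true(all(hr[co$labels == "sinus_tachycardia"] > 100))
})
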