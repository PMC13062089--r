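test_that("write/read round-trips within one quantization step", {
  g <- clean_sinus()
  d <- withr::local_tempdir()
  hdr <- write_record(g$record, d, name = "rec1", gain = 200)
  rt <- read_record(file.path(d, "rec1"))
  expect_lte(max(abs(rt$record$signal - g$record$signal)), 1 / 200)
  expect_equal(ncol(rt$record$signal), 12)
  expect_equal(rt$record$lead_names, standard_leads())
  expect_equal(rt$record$label, "sinus_rhythm")
  expect_equal(rt$header$n_samples, 5000L)
  expect_equal(rt$header$fs, 500)
})

test_that("constant-signal storage matches the integer arithmetic oracle", {
  d <- withr::local_tempdir()
  v <- 0.5; gn <- 200; n <- 100
  rec <- ecg_record(matrix(v, n, 1), 500, lead_names = "I")
  hdr <- write_record(rec, d, name = "const", gain = gn)
  stored <- round(v * gn)  # baseline 0
  expect_equal(hdr$signals$initial_value, stored)
  expect_equal(hdr$signals$checksum,
               ecgmend:::signed16((n * stored) %% 2^16))
  rt <- read_record(file.path(d, "const.hea"))
  expect_true(all(abs(rt$record$signal - v) <= 1 / gn))
})

test_that("corrupt and malformed records are rejected", {
  g <- clean_sinus()
  d <- withr::local_tempdir()
  write_record(g$record, d, name = "rec1", gain = 200)
  dat <- file.path(d, "rec1.dat")
  raw <- readBin(dat, "raw", file.info(dat)$size)
  raw[5] <- as.raw(0xFF)
  writeBin(raw, dat)
  expect_error(read_record(file.path(d, "rec1")),
               class = "ecgmend_corrupt_record")

  # unsupported storage format code
  hea <- readLines(file.path(d, "rec1.hea"))
  writeLines(sub(" 16 ", " 212 ", hea), file.path(d, "rec1.hea"))
  expect_error(read_record(file.path(d, "rec1")),
               class = "ecgmend_format_error")
})

test_that("degenerate write cases behave per contract", {
  d <- withr::local_tempdir()
  empty <- ecg_record(matrix(numeric(0), 0, 2), 500, lead_names = c("I", "II"))
  hdr <- write_record(empty, d, name = "empty")
  expect_equal(hdr$n_samples, 0L)
  expect_equal(file.info(file.path(d, "empty.dat"))$size, 0)
  rt <- read_record(file.path(d, "empty"))
  expect_equal(nrow(rt$record$signal), 0L)

  g <- clean_sinus()
  expect_error(write_record(g$record, d, gain = -5),
               class = "ecgmend_invalid_argument")
  bad <- g$record; bad$signal[1, 1] <- NA
  expect_error(write_record(bad, d), class = "ecgmend_invalid_argument")
})

test_that("min-max normalization matches hand-computed affine maps", {
  r1 <- ecg_record(matrix(c(0, 5, 10), 3, 1), 500, lead_names = "I")
  expect_equal(as.numeric(normalize_record(r1)$signal), c(0, 0.5, 1))
  r2 <- ecg_record(matrix(c(-2, 0, 2, 6), 4, 1), 500, lead_names = "I")
  expect_equal(as.numeric(normalize_record(r2)$signal), c(0, 0.25, 0.5, 1))
  r3 <- ecg_record(matrix(c(0, 1), 2, 1), 500, lead_names = "I")
  expect_equal(as.numeric(normalize_record(r3)$signal), c(0, 1))
  # constant lead: zero range
  r4 <- ecg_record(matrix(1, 5, 1), 500, lead_names = "I")
  expect_error(normalize_record(r4), class = "ecgmend_degenerate_lead")
  # inversion
  g <- clean_sinus()
  expect_equal(denormalize_record(normalize_record(g$record))$signal,
               g$record$signal, tolerance = 1e-12)
})

test_that("random records round-trip through WFDB files", {
  d <- withr::local_tempdir()
  set.seed(21)
  for (i in 1:100) {
    n <- sample(10:200, 1)
    L <- sample(c(1, 3, 12), 1)
    sig <- matrix(rnorm(n * L), n, L)
    rec <- ecg_record(sig, 250, lead_names = paste0("ch", seq_len(L)),
                      patient_id = sprintf("r%03d", i))
    write_record(rec, d, gain = 1000)
    rt <- read_record(file.path(d, sprintf("r%03d", i)))
    expect_lte(max(abs(rt$record$signal - sig)), 1 / 1000)
  }
})

test_that("patient split sizes follow round-half-away-from-zero on test then validation", {
  sp10 <- patient_split(sprintf("P%02d", 1:10), seed = 2)
  expect_equal(as.integer(table(sp10$partition)), c(7L, 1L, 2L))
  sp <- patient_split(sprintf("P%04d", 1:2426), seed = 1)
  expect_equal(sum(sp$partition == "test"), 485L)
  expect_error(patient_split(c("a", "a", "b")),
               class = "ecgmend_invalid_argument")
  expect_error(patient_split(letters, fractions = c(0.5, 0.2, 0.2)),
               class = "ecgmend_invalid_argument")
})

test_that("partitions are always disjoint and cover all patients", {
  ids <- sprintf("P%03d", 1:97)
  for (seed in 1:250) {
    sp <- patient_split(ids, seed = seed)
    expect_setequal(sp$patient_id, ids)
    expect_equal(anyDuplicated(sp$patient_id), 0)
    expect_false(any(is.na(sp$partition)))
  }
  # determinism
  expect_identical(patient_split(ids, seed = 42), patient_split(ids, seed = 42))
})
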