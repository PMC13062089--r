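# Shared fixtures, built once per test run and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# one clean 10 s sinus record at 60 bpm with known fiducials
clean_sinus <- function() fixture("clean_sinus", function()
  generate_clean_ecg(10, 500, 60, "sinus_rhythm", seed = 1))

# numeric gradient of a scalar-valued function of a matrix
num_grad <- function(fn, x, eps = 1e-6) {
  g <- array(0, dim = dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (fn(xp) - fn(xm)) / (2 * eps)
  }
  g
}

# mixed-rhythm normalized records for model training tests
training_records <- function(n, seed_base = 4000) {
  lapply(seq_len(n), function(i) {
    set.seed(seed_base + i)
    hr <- runif(1, 50, 140)
    cl <- sample(rhythm_classes(), 1)
    normalize_record(
      generate_clean_ecg(10, 500, hr, cl, seed = seed_base + i)$record)
  })
}
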