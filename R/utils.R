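# Shared internal helpers: argument checking, seeded RNG scoping, rounding.

abort_bad_arg <- function(msg) {
  rlang::abort(msg, class = "ecgmend_invalid_argument")
}

abort_state <- function(msg, class) {
  rlang::abort(msg, class = c(class, "ecgmend_error"))
}

# evaluate `expr` under a given seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed), kind = "Mersenne-Twister")
  }
  expr
}

# derive a per-stage child seed from one master seed; keeps results of one
# stage independent of whether another stage ran (splittable counter scheme)
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131L)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# round half away from zero (round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
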