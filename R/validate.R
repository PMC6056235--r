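# Input checks shared across the package. Errors name the offending field.

check_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(name, " must be a single finite number", call. = FALSE)
  }
  invisible(x)
}

check_positive <- function(x, name) {
  check_number(x, name)
  if (x <= 0) stop(name, " must be > 0", call. = FALSE)
  invisible(x)
}

check_fraction <- function(x, name) {
  check_number(x, name)
  if (x < 0 || x > 1) {
    stop(name, " must lie in [0, 1] (got ", x, ")", call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name) {
  check_number(x, name)
  if (x < 0 || x != round(x)) {
    stop(name, " must be a non-negative integer", call. = FALSE)
  }
  invisible(x)
}

# Run `expr` under `seed` without disturbing the caller's RNG state; with
# seed = NULL the current stream is used. All randomness in the package flows
# through this single gate so a top-level seed makes whole pipelines
# reproducible.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) {
    expr
  } else {
    check_count(seed, "seed")
    withr::with_seed(as.integer(seed), expr)
  }
}

# Derive independent child seeds from one parent seed, so that stages of a
# pipeline (landing, per-run kinetics, bootstrap) draw from separate streams.
split_seed <- function(seed, n) {
  if (is.null(seed)) return(vector("list", n))
  with_seed_if(seed, as.list(sample.int(.Machine$integer.max - 1L, n)))
}
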