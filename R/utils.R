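# Internal helpers shared across modules.

# Split a sequence string into a character vector of residues.
seq_chars <- function(seq) {
  strsplit(seq, "", fixed = TRUE)[[1]]
}

assert_string <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, what, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(what, " must be a single integer >= ", min, call. = FALSE)
  }
  invisible(as.integer(x))
}

# Lehmer multiplicative congruential step, exact in double arithmetic
# (16807 * (2^31 - 2) < 2^53).
lehmer_step <- function(x) {
  (16807 * x) %% 2147483647
}

#' Derive a reproducible child seed
#'
#' Hash-mixes a master seed with an ordinal (e.g. a record index) into an
#' independent child seed, so per-record randomness is reproducible and
#' does not depend on iteration order. Uses iterated Lehmer
#' (minimal-standard) steps modulo 2^31 − 1; all arithmetic is exact in
#' doubles and the result is always a valid 32-bit seed.
#'
#' @param master Master seed (single integer).
#' @param ordinal Non-negative integer identifying the stream.
#' @return A single integer in \[1, 2^31 − 2\].
#' @export
child_seed <- function(master, ordinal) {
  master <- assert_count(master, "master", min = 0)
  ordinal <- assert_count(ordinal, "ordinal", min = 0)
  x <- (as.double(master) %% 2147483646) + 1
  x <- lehmer_step(x)
  x <- (x + as.double(ordinal) * 48271) %% 2147483647
  if (x == 0) x <- 1
  x <- lehmer_step(x)
  x <- lehmer_step(x)
  as.integer(x)
}

# Evaluate `expr` under a fixed RNG seed without touching the caller's
# RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
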