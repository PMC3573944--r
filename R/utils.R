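# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

## run code with a private RNG stream; the caller's .Random.seed is untouched
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

## FNV-1a 32-bit hash of a character scalar, as 8 hex digits.  Used to stamp
## pipeline artifacts with a configuration fingerprint without pulling in a
## hashing dependency; not cryptographic.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    h <- bitwXor32(h, b)
    # (h * m) mod 2^32 in double arithmetic, split to stay under 2^53
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * m + ((hi * m) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

bitwXor32 <- function(a, b) {
  # a may exceed .Machine$integer.max; xor the two 16-bit halves
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}

stop_bad_arg <- function(...) stop(sprintf(...), call. = FALSE)

is_count_vec <- function(x) is.numeric(x) && all(is.finite(x)) &&
  all(x >= 0) && all(x == round(x))
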