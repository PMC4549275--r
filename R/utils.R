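
# Small 2x2 linear-algebra helpers used on the hot path of the rejection
# sampler. Inputs are plain numeric; no dimension checks here — callers
# validate once.

det2 <- function(a, b, c) a * c - b * b          # det of [[a,b],[b,c]]

# Inverse of symmetric 2x2 [[a,b],[b,c]]; returns c(a*, b*, c*).
inv2 <- function(a, b, c) {
  d <- det2(a, b, c)
  c(c / d, -b / d, a / d)
}

# Lower Cholesky factor of symmetric PD 2x2: returns c(l11, l21, l22).
chol2 <- function(a, b, c) {
  l11 <- sqrt(a)
  l21 <- b / l11
  c(l11, l21, sqrt(c - l21 * l21))
}

is_pd2 <- function(a, b, c, floor = 0) {
  a > floor & det2(a, b, c) > floor
}

`%||%` <- function(x, y) if (is.null(x)) y else x

as_len2 <- function(x, what = "vector") {
  x <- as.numeric(x)
  if (length(x) != 2L || anyNA(x)) {
    stop(sprintf("`%s` must be a finite numeric vector of length 2", what),
         call. = FALSE)
  }
  x
}

check_sym_psd <- function(S, what = "matrix", tol = 1e-10) {
  if (!is.matrix(S) || any(dim(S) != 2L)) {
    stop(sprintf("`%s` must be a 2x2 matrix", what), call. = FALSE)
  }
  if (abs(S[1, 2] - S[2, 1]) > tol * (1 + max(abs(S)))) {
    stop(sprintf("`%s` must be symmetric", what), call. = FALSE)
  }
  invisible(S)
}

# Per-participant seed streams: a documented counter scheme so that a single
# top-level seed yields independent, replayable substreams. Streams are
# seed * 2654435761 + index hashed into [0, 2^31 - 2] (Knuth multiplicative
# hashing, kept in integer range).
participant_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) + 1
  h <- (s * 48271 + index * 16807) %% 2147483647
  as.integer(h)
}
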