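# Internal numerical helpers shared across modules.

# Deterministic child seed derived from a master seed.  Keeps every value in
# [0, 2^31); distinct salts give effectively independent streams.
child_seed <- function(seed, salt) {
  s <- (as.double(seed) %% 2147483647) + 1
  s <- (s * 48271) %% 2147483647
  s <- (s + as.double(salt) * 9973) %% 2147483647
  as.integer(s)
}

fft2 <- function(x) stats::fft(x)

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Signed FFT frequency indices for an axis of length n: 0, 1, ..., -1.
fft_freq <- function(n) {
  k <- seq_len(n) - 1L
  ifelse(k > n / 2, k - n, k)
}

# Circular shift of a matrix by integer (dr, dc); positive shifts move
# content down/right, matching the (row, col) lag convention used throughout.
circ_shift <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  dr <- ((dr %% nr) + nr) %% nr
  dc <- ((dc %% nc) + nc) %% nc
  if (dr > 0) m <- m[c((nr - dr + 1):nr, 1:(nr - dr)), , drop = FALSE]
  if (dc > 0) m <- m[, c((nc - dc + 1):nc, 1:(nc - dc)), drop = FALSE]
  m
}

# Map a 0-based circular index to a signed lag in [-n/2, n/2).
wrap_lag <- function(idx, n) {
  idx <- ((idx %% n) + n) %% n
  ifelse(idx >= n / 2, idx - n, idx)
}

# argmax of a matrix as 1-based (row, col).
which_max_rc <- function(m) {
  i <- which.max(m)
  nr <- nrow(m)
  c((i - 1L) %% nr + 1L, (i - 1L) %/% nr + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " contains non-finite values")
}
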