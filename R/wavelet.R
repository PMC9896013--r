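# Periodized Daubechies-2 discrete wavelet transform.
#
# Implemented in-package (no wavelet package is available in the target
# environment). Standard pyramid algorithm with periodic boundary handling;
# perfect reconstruction is exercised in the test suite.

db2_filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))  # scaling (low-pass)
  g <- rev(h) * c(1, -1, 1, -1)                           # wavelet (high-pass)
  list(h = h, g = g)
}

# One analysis step: x (even length) -> list(approx, detail), each length/2.
dwt_step <- function(x, h, g) {
  n <- length(x)
  l <- length(h)
  idx <- outer(seq(1L, n, by = 2L), 0:(l - 1L), `+`)
  idx <- ((idx - 1L) %% n) + 1L
  xm <- matrix(x[idx], ncol = l)
  list(approx = as.numeric(xm %*% h), detail = as.numeric(xm %*% g))
}

# One synthesis step, inverse of dwt_step.
idwt_step <- function(approx, detail, h, g) {
  n2 <- length(approx)
  n <- 2L * n2
  l <- length(h)
  x <- numeric(n)
  pos <- seq(1L, n, by = 2L)
  for (k in seq_len(l)) {
    tgt <- ((pos + k - 2L) %% n) + 1L
    x[tgt] <- x[tgt] + approx * h[k] + detail * g[k]
  }
  x
}

# Full decomposition to `levels` levels; length(x) must be divisible by
# 2^levels. Returns list(approx, details = list(level1..levelL)).
dwt_db2 <- function(x, levels) {
  f <- db2_filters()
  if (length(x) %% (2^levels) != 0)
    stop_invalid("series length must be divisible by 2^levels for the DWT")
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- dwt_step(a, f$h, f$g)
    details[[j]] <- s$detail
    a <- s$approx
  }
  list(approx = a, details = details)
}

idwt_db2 <- function(decomp) {
  f <- db2_filters()
  a <- decomp$approx
  for (j in rev(seq_along(decomp$details)))
    a <- idwt_step(a, decomp$details[[j]], f$h, f$g)
  a
}
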