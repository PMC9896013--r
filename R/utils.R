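# Internal helpers shared across modules.

#' Derive a child RNG seed from a root seed and a counter
#'
#' Deterministic counter-based splitting so that every subject/run/repetition
#' gets its own reproducible stream while the user supplies a single root
#' seed. Values stay below 2^31 - 1 so they are valid R integer seeds.
#'
#' @param seed root seed (integer-like scalar).
#' @param counter non-negative integer counter (scalar or vector).
#' @return integer seed(s) in [0, 2^31 - 2].
#' @keywords internal
split_seed <- function(seed, counter) {
  # LCG-style mixing on doubles; exact for inputs < 2^31 since the
  # intermediate products stay within the 2^53 integer range of doubles.
  m <- 2147483647  # 2^31 - 1, prime
  s <- (as.numeric(seed) %% m)
  ctr <- as.numeric(counter) %% m
  mixed <- (s * 48271 + ctr * 16807 + 12345) %% m
  mixed <- (mixed * 69621 + 1013904223 %% m) %% m
  as.integer(mixed)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

#' Assemble a block-diagonal matrix
#' @param blocks list of square matrices.
#' @return block-diagonal matrix; row/col names concatenated when present.
#' @keywords internal
block_diag <- function(blocks) {
  stopifnot(length(blocks) >= 1L)
  dims <- vapply(blocks, nrow, integer(1))
  out <- matrix(0, sum(dims), sum(dims))
  nm <- character(0)
  at <- 0L
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    idx <- at + seq_len(nrow(b))
    out[idx, idx] <- b
    nm <- c(nm, if (is.null(rownames(b))) rep("", nrow(b)) else
      paste0("b", i, ".", rownames(b)))
    at <- at + nrow(b)
  }
  if (any(nzchar(nm))) dimnames(out) <- list(nm, nm)
  out
}

#' Generate a random symmetric positive-definite matrix
#'
#' Used by tests and examples; eigenvalues drawn uniformly in
#' `eig_range` with a Haar-random orthogonal basis.
#'
#' @param n dimension.
#' @param eig_range eigenvalue range, positive.
#' @return `n x n` SPD matrix.
#' @export
random_spd <- function(n, eig_range = c(0.5, 2)) {
  stopifnot(n >= 1, all(eig_range > 0))
  q <- qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
  lam <- stats::runif(n, eig_range[1], eig_range[2])
  q %*% (lam * t(q))
}
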