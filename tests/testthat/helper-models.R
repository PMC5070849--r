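# Shared fixture builders. Everything is generated in code under explicit
# seeds; no data files.

# Random system matrix rescaled to a given spectral radius, plus a random
# control matrix.
random_stable_model <- function(m1, m2, seed, radius = 0.9) {
  set.seed(seed)
  A <- matrix(rnorm(m1 * m1), m1)
  A <- A * (radius / max(Mod(eigen(A, only.values = TRUE)$values)))
  B <- matrix(rnorm(m1 * m2), m1, m2)
  list(A = A, B = B)
}

rand_inputs <- function(m2, T, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(m2 * T), m2, T)
}

# Real matrix with an exactly known spectrum: 1x1 blocks for real
# eigenvalues, 2x2 rotation-scaling blocks for complex pairs (positive-Im
# member listed once), conjugated by a random orthogonal matrix.
matrix_with_spectrum <- function(eigs, seed) {
  set.seed(seed)
  sizes <- ifelse(abs(Im(eigs)) > 0, 2L, 1L)
  m <- sum(sizes)
  Lam <- matrix(0, m, m)
  pos <- 1L
  for (i in seq_along(eigs)) {
    if (sizes[i] == 1L) {
      Lam[pos, pos] <- Re(eigs[i])
      pos <- pos + 1L
    } else {
      a <- Re(eigs[i]); b <- abs(Im(eigs[i]))
      Lam[pos, pos] <- a; Lam[pos, pos + 1L] <- b
      Lam[pos + 1L, pos] <- -b; Lam[pos + 1L, pos + 1L] <- a
      pos <- pos + 2L
    }
  }
  Q <- qr.Q(qr(matrix(rnorm(m * m), m)))
  Q %*% Lam %*% t(Q)
}

# Small dataset wrapper for tests that need an expression_dataset quickly.
toy_dataset <- function(internal, external, iid = NULL, eid = NULL) {
  if (is.null(iid)) iid <- sprintf("g%03d", seq_len(nrow(internal)))
  if (is.null(eid)) eid <- sprintf("tf%03d", seq_len(nrow(external)))
  suppressWarnings(expression_dataset(
    internal = list(ids = iid, matrix = internal),
    external = list(ids = eid, matrix = external)))
}
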