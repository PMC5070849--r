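# Moore-Penrose pseudo-inverse and numerical rank from one SVD.
# Singular values below rtol * sigma_max are treated as zero.
.pinv_svd <- function(M, rtol = 1e-10) {
  sv <- svd(M)
  if (!length(sv$d) || sv$d[1L] == 0) {
    return(list(pinv = matrix(0, ncol(M), nrow(M)), rank = 0L))
  }
  keep <- sv$d > rtol * sv$d[1L]
  r <- sum(keep)
  pinv <- sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  list(pinv = pinv, rank = as.integer(r))
}

# Memoized powers A^0 .. A^kmax by repeated multiplication; powers[[k+1]] = A^k.
.matrix_powers <- function(A, kmax) {
  m <- nrow(A)
  powers <- vector("list", kmax + 1L)
  powers[[1L]] <- diag(1, m)
  if (kmax >= 1L) {
    powers[[2L]] <- A
    for (k in seq_len(kmax - 1L) + 1L) powers[[k + 1L]] <- powers[[k]] %*% A
  }
  powers
}

#' Estimate the effective metagene state-space model
#'
#' Fits the one-step transition model \eqn{\tilde X_{t+1} = \tilde A \tilde
#' X_t + \tilde B \tilde U_t} at metagene level by least squares: with
#' \eqn{Z = [\tilde X_2 \cdots \tilde X_T]} and the stacked regressor matrix
#' \eqn{\Upsilon = [\tilde X_1 \cdots \tilde X_{T-1}; \tilde U_1 \cdots
#' \tilde U_{T-1}]}, the estimate is \eqn{[\tilde A\ \tilde B] = Z
#' \Upsilon^+}. \eqn{\tilde A} is the effective internal system matrix (the
#' metagene-level regulatory network of the group itself); \eqn{\tilde B}
#' the effective control matrix carrying the external regulators' influence.
#'
#' @param X_scores M1 x T internal metagene series.
#' @param U_scores M2 x T external metagene series on the same time grid.
#' @param rtol Relative singular-value tolerance of the pseudo-inverse;
#'   values below \code{rtol * sigma_max} are treated as zero.
#' @return An object of class \code{effective_model}: \code{A_tilde}
#'   (M1 x M1), \code{B_tilde} (M1 x M2), \code{residual_norm} (Frobenius
#'   norm of \eqn{Z - [\tilde A\ \tilde B]\Upsilon}), \code{rank_upsilon},
#'   \code{M1}, \code{M2}, \code{T}.
#' @details Estimability requires \code{M1 + M2 <= T - 1}: the regression has
#'   T - 1 columns, and a right inverse of \eqn{\Upsilon} needs at least as
#'   many columns as rows. When \eqn{\Upsilon} is numerically rank-deficient
#'   the exact right-inverse condition fails; the Moore-Penrose solution is
#'   still the minimum-norm least-squares fit and a warning is emitted.
#' @export
estimate_model <- function(X_scores, U_scores, rtol = 1e-10) {
  X <- as.matrix(X_scores)
  U <- as.matrix(U_scores)
  if (ncol(X) != ncol(U)) stop("internal and external series must share T")
  tt <- ncol(X)
  m1 <- nrow(X)
  m2 <- nrow(U)
  if (m1 + m2 > tt - 1L) {
    stop(sprintf(
      "model not estimable: M1 + M2 = %d exceeds T - 1 = %d one-step transitions",
      m1 + m2, tt - 1L))
  }
  Z <- X[, 2:tt, drop = FALSE]
  Ups <- rbind(X[, 1:(tt - 1L), drop = FALSE], U[, 1:(tt - 1L), drop = FALSE])
  pi <- .pinv_svd(Ups, rtol = rtol)
  if (pi$rank < m1 + m2) {
    warning(sprintf(
      "regressor matrix is rank deficient (rank %d < %d); minimum-norm solution returned",
      pi$rank, m1 + m2))
  }
  AB <- Z %*% pi$pinv
  A <- AB[, seq_len(m1), drop = FALSE]
  B <- AB[, m1 + seq_len(m2), drop = FALSE]
  res <- Z - AB %*% Ups
  structure(
    list(A_tilde = A, B_tilde = B,
         residual_norm = sqrt(sum(res^2)),
         rank_upsilon = pi$rank, M1 = m1, M2 = m2, T = tt),
    class = "effective_model")
}

#' @export
print.effective_model <- function(x, ...) {
  cat(sprintf("Effective state-space model: M1 = %d, M2 = %d, T = %d\n",
              x$M1, x$M2, x$T))
  cat(sprintf("  one-step fit residual (Frobenius): %.6g\n", x$residual_norm))
  cat(sprintf("  regressor rank: %d of %d\n", x$rank_upsilon, x$M1 + x$M2))
  ev <- eigen(x$A_tilde, only.values = TRUE)$values
  cat("  eigenvalues of A~: ",
      paste(format(ev, digits = 4L), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Decompose a trajectory into internal, external and interaction components
#'
#' Expanding the recursion \eqn{X_{t+1} = A X_t + B U_t} from the initial
#' state gives an exact three-way split of the state at every time:
#' \itemize{
#'   \item internal: \eqn{A^{t-1} X_1}, the part driven purely by the
#'     group's own network propagating the initial state;
#'   \item external: \eqn{B U_{t-1}} (t >= 2), the part injected directly by
#'     the external regulators one step back;
#'   \item interaction: \eqn{\sum_{k=1}^{t-2} A^k B U_{t-1-k}} (t >= 3),
#'     older external input already filtered through the internal network.
#' }
#' The split of the external-related terms is a convention: any grouping of
#' the lagged terms \eqn{A^k B U_{t-1-k}} is algebraically valid.
#' \code{external_lags} moves the first \code{L} lags (k = 0..L-1) into the
#' external component; the default \code{L = 1} is the pure-external
#' convention above.
#'
#' @param model An \code{effective_model} (or any list with \code{A_tilde},
#'   \code{B_tilde}).
#' @param X1 Initial internal metagene state (length M1).
#' @param U_scores M2 x T external metagene series.
#' @param external_lags Number of lags attributed to the external component.
#' @return Object of class \code{ssd_decomposition}: \code{internal},
#'   \code{external}, \code{interaction} (each M1 x T; columns outside a
#'   component's support are zero), \code{total_check} (max deviation of the
#'   component sum from the propagated trajectory), \code{external_lags}.
#' @export
decompose_dynamics <- function(model, X1, U_scores, external_lags = 1L) {
  A <- as.matrix(model$A_tilde)
  B <- as.matrix(model$B_tilde)
  U <- as.matrix(U_scores)
  m1 <- nrow(A)
  if (length(X1) != m1) stop("X1 length must equal M1")
  if (nrow(U) != ncol(B)) stop("U_scores rows must equal M2")
  L <- max(1L, as.integer(external_lags))
  tt <- ncol(U)
  X1 <- as.numeric(X1)
  powers <- .matrix_powers(A, tt - 1L)
  internal <- matrix(0, m1, tt)
  external <- matrix(0, m1, tt)
  interact <- matrix(0, m1, tt)
  internal[, 1L] <- X1
  for (t in 2:tt) {
    internal[, t] <- powers[[t]] %*% X1   # A^{t-1} X1
    for (k in 0:(t - 2L)) {
      term <- powers[[k + 1L]] %*% (B %*% U[, t - 1L - k])
      if (k < L) external[, t] <- external[, t] + term
      else interact[, t] <- interact[, t] + term
    }
  }
  prop <- matrix(0, m1, tt)
  prop[, 1L] <- X1
  for (t in seq_len(tt - 1L)) prop[, t + 1L] <- A %*% prop[, t] + B %*% U[, t]
  structure(
    list(internal = internal, external = external, interaction = interact,
         total_check = max(abs(internal + external + interact - prop)),
         external_lags = L),
    class = "ssd_decomposition")
}

#' @export
print.ssd_decomposition <- function(x, ...) {
  cat(sprintf("State decomposition over T = %d samples (external lags = %d)\n",
              ncol(x$internal), x$external_lags))
  cat(sprintf("  conservation check (max |sum - propagated|): %.3g\n",
              x$total_check))
  invisible(x)
}

#' Simulate a linear state-space trajectory
#'
#' Runs the recursion \eqn{X_{t+1} = A X_t + B U_t + \epsilon_t} with
#' optional i.i.d. Gaussian noise. With \code{noise_sd = 0} the recursion is
#' deterministic; with a seed, output is reproducible.
#'
#' @param A System matrix (square).
#' @param B Control matrix, or \code{NULL} for an autonomous system.
#' @param U_series Control input series (N2 x (T-1) or N2 x T; only the
#'   first T-1 columns are used), or \code{NULL}.
#' @param X1 Initial state.
#' @param n_steps Number of time samples T; defaults to \code{ncol(U_series)
#'   + 1} when inputs are given.
#' @param noise_sd Standard deviation of the additive state noise.
#' @param seed Optional integer seed.
#' @return N x T state matrix; column t is the state at time t.
#' @details States exceeding 1e12 in magnitude trigger an overflow warning
#'   (unstable system) but the recursion continues.
#' @export
simulate_states <- function(A, B = NULL, U_series = NULL, X1,
                            n_steps = NULL, noise_sd = 0, seed = NULL) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (length(X1) != n) stop("X1 length must match A")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(n_steps)) {
    if (is.null(U_series)) stop("n_steps required when no input series given")
    n_steps <- ncol(as.matrix(U_series)) + 1L
  }
  tt <- as.integer(n_steps)
  X <- matrix(0, n, tt)
  X[, 1L] <- as.numeric(X1)
  use_input <- !is.null(B) && !is.null(U_series)
  if (use_input) {
    B <- as.matrix(B)
    U <- as.matrix(U_series)
    if (ncol(U) < tt - 1L) stop("U_series must cover at least T - 1 samples")
  }
  warned <- FALSE
  for (t in seq_len(tt - 1L)) {
    x <- A %*% X[, t]
    if (use_input) x <- x + B %*% U[, t]
    if (noise_sd > 0) x <- x + stats::rnorm(n, sd = noise_sd)
    X[, t + 1L] <- x
    if (!warned && any(abs(x) > 1e12)) {
      warning("state magnitude exceeded 1e12: unstable system, continuing")
      warned <- TRUE
    }
  }
  X
}
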