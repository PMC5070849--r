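#' Generate a synthetic internal/external expression dataset with known truth
#'
#' Builds a metagene-level state-space system with a requested eigenvalue
#' spectrum, simulates it, and lifts both groups to gene level through
#' random orthonormal loadings, optionally adding gene-level Gaussian noise.
#' The generating objects are returned so estimators can be scored against
#' ground truth.
#'
#' @param N1,N2 Gene counts of the internal and external groups.
#' @param M1,M2 Metagene dimensions of the generating model.
#' @param T Number of time samples.
#' @param eigen_spec Requested spectrum of the internal system matrix: a
#'   vector/list of eigenvalues in which a real entry contributes one
#'   eigenvalue and a complex entry (nonzero imaginary part) stands for a
#'   conjugate pair and contributes two. The contributed total must equal
#'   \code{M1}.
#' @param noise_sd Gene-level additive Gaussian noise standard deviation.
#' @param seed Integer seed; the generator is fully reproducible under it.
#' @return A list of class \code{ssd_synthetic}: \code{dataset} (an
#'   [expression_dataset()]) and \code{truth} with \code{A_tilde},
#'   \code{B_tilde}, \code{W_X}, \code{W_U}, \code{X_scores},
#'   \code{U_scores}, \code{X1} and \code{eigenvalues} (the full spectrum,
#'   conjugates expanded).
#' @details The system matrix is built from the real block form of the
#'   requested spectrum (1 x 1 blocks for real eigenvalues, 2 x 2 rotation
#'   scaling blocks for conjugate pairs) conjugated by a random orthogonal
#'   similarity, so the spectrum is exact and the construction well
#'   conditioned. External inputs are smooth random low-order Fourier series
#'   with a linear trend, which generically keeps the one-step regressor
#'   matrix full rank. With \code{noise_sd = 0} the lifted internal matrix
#'   has rank exactly \code{M1}.
#' @export
make_synthetic_dataset <- function(N1, N2, M1, M2, T, eigen_spec,
                                   noise_sd = 0, seed = 1L) {
  if (M1 + M2 > T - 2L) stop("need M1 + M2 <= T - 2")
  ev <- as.complex(unlist(eigen_spec))
  counts <- ifelse(abs(Im(ev)) > 0, 2L, 1L)
  if (sum(counts) != M1) {
    stop(sprintf(
      "eigen_spec contributes %d eigenvalues (conjugate pairs count twice) but M1 = %d",
      sum(counts), M1))
  }
  set.seed(as.integer(seed))
  # real block-diagonal form with the requested spectrum
  Lam <- matrix(0, M1, M1)
  pos <- 1L
  full_spec <- complex(0)
  for (i in seq_along(ev)) {
    if (counts[i] == 1L) {
      Lam[pos, pos] <- Re(ev[i])
      full_spec <- c(full_spec, complex(real = Re(ev[i])))
      pos <- pos + 1L
    } else {
      a <- Re(ev[i]); b <- abs(Im(ev[i]))
      Lam[pos, pos] <- a;          Lam[pos, pos + 1L] <- b
      Lam[pos + 1L, pos] <- -b;    Lam[pos + 1L, pos + 1L] <- a
      full_spec <- c(full_spec, complex(real = a, imaginary = b),
                     complex(real = a, imaginary = -b))
      pos <- pos + 2L
    }
  }
  P <- qr.Q(qr(matrix(stats::rnorm(M1 * M1), M1)))
  A <- P %*% Lam %*% t(P)
  B <- matrix(stats::rnorm(M1 * M2, sd = 0.5), M1, M2)

  # smooth inputs: 3-harmonic Fourier series + linear trend per metagene
  tgrid <- seq_len(T)
  U <- t(vapply(seq_len(M2), function(q) {
    amp <- stats::rnorm(3L, sd = 1)
    ph <- stats::runif(3L, 0, 2 * pi)
    trend <- stats::rnorm(1L, sd = 0.3)
    rowSums(vapply(1:3, function(h) {
      amp[h] * sin(2 * pi * h * tgrid / T + ph[h])
    }, numeric(T))) + trend * tgrid / T
  }, numeric(T)))
  U <- matrix(U, M2, T)

  X1 <- stats::rnorm(M1)
  X <- simulate_states(A, B, U, X1, n_steps = T, noise_sd = 0)

  W_X <- qr.Q(qr(matrix(stats::rnorm(N1 * M1), N1, M1)))
  W_U <- qr.Q(qr(matrix(stats::rnorm(N2 * M2), N2, M2)))
  im <- W_X %*% X
  em <- W_U %*% U
  if (noise_sd > 0) {
    im <- im + matrix(stats::rnorm(length(im), sd = noise_sd), nrow(im))
    em <- em + matrix(stats::rnorm(length(em), sd = noise_sd), nrow(em))
  }
  iid <- sprintf("g%04d", seq_len(N1))
  eid <- sprintf("tf%04d", seq_len(N2))
  ds <- suppressWarnings(expression_dataset(
    internal = list(ids = iid, matrix = im),
    external = list(ids = eid, matrix = em),
    time_labels = as.character(tgrid),
    name = sprintf("synthetic-seed%d", as.integer(seed))))
  structure(
    list(dataset = ds,
         truth = list(A_tilde = A, B_tilde = B, W_X = W_X, W_U = W_U,
                      X_scores = X, U_scores = U, X1 = X1,
                      eigenvalues = full_spec)),
    class = "ssd_synthetic")
}

#' @export
print.ssd_synthetic <- function(x, ...) {
  cat("Synthetic state-space dataset with known ground truth\n")
  print(x$dataset)
  cat("  generating eigenvalues: ",
      paste(format(x$truth$eigenvalues, digits = 4L), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
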