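#' Project an expression matrix onto SVD metagenes
#'
#' Computes the top-\code{M} left singular vectors of the genes x time matrix
#' and the corresponding metagene time series. A metagene is a single
#' low-dimensional component standing in for many co-varying genes: its gene
#' loadings are a left singular vector, its time profile the projection of
#' the data onto that vector.
#'
#' @param matrix Numeric N x T matrix (genes in rows, time in columns).
#' @param M Number of metagenes, \code{1 <= M < T} and \code{M <= min(N, T)}.
#' @param group_tag \code{"internal"} or \code{"external"}; bookkeeping only.
#' @return An object of class \code{metagene_basis}: \code{W} (N x M,
#'   orthonormal columns), \code{scores} (M x T metagene series, equal to
#'   \code{t(W) \%*\% matrix}), \code{singular_values} (top M),
#'   \code{explained_fraction} (share of total squared singular value mass
#'   captured), \code{M}, \code{T}, \code{group_tag}.
#' @details The SVD sign ambiguity is resolved deterministically: each column
#'   of \code{W} is flipped so that its largest-magnitude entry is positive.
#'   Because columns of \code{W} are orthonormal, its left inverse is simply
#'   \code{t(W)}, satisfying \code{t(W) \%*\% W = I}. The matrix is not
#'   centered before decomposition: the explained fraction is of total
#'   covariation about zero.
#' @export
fit_metagenes <- function(matrix, M, group_tag = c("internal", "external")) {
  group_tag <- match.arg(group_tag)
  matrix <- as.matrix(matrix)
  n <- nrow(matrix)
  tt <- ncol(matrix)
  M <- as.integer(M)
  if (M < 1L) stop("M must be at least 1")
  if (M >= tt) stop(sprintf("M = %d must be smaller than T = %d", M, tt))
  if (M > min(n, tt)) {
    stop(sprintf("M = %d exceeds min(N, T) = %d", M, min(n, tt)))
  }
  sv <- svd(matrix)
  W <- sv$u[, seq_len(M), drop = FALSE]
  for (j in seq_len(M)) {
    s <- sign(W[which.max(abs(W[, j])), j])
    if (s < 0) W[, j] <- -W[, j]
  }
  rownames(W) <- rownames(matrix)
  scores <- t(W) %*% matrix
  rownames(scores) <- paste0("mg", seq_len(M))
  total <- sum(sv$d^2)
  explained <- if (total > 0) sum(sv$d[seq_len(M)]^2) / total else 1
  structure(
    list(W = W, scores = scores, singular_values = sv$d[seq_len(M)],
         explained_fraction = explained, M = M, T = tt,
         group_tag = group_tag),
    class = "metagene_basis")
}

#' Choose the number of metagenes from a covariation target
#'
#' Returns the smallest \code{M} whose top-\code{M} squared singular values
#' capture at least \code{variance_target} of the total, clamped so the
#' state-space regression stays estimable: with a partner group of dimension
#' \code{partner_M}, the joint dimension is held to \code{M + partner_M <=
#' T - 2}, leaving one spare sample beyond the T - 1 one-step transitions.
#' \code{M = 1} is the floor; the clamp never errors.
#'
#' @param matrix Numeric N x T matrix.
#' @param variance_target Fraction in (0, 1], e.g. 0.98.
#' @param partner_M Dimension already committed to the partner group, or
#'   \code{NULL}.
#' @return List with \code{M} and \code{explained_fraction} achieved at that
#'   \code{M}.
#' @export
choose_dimension <- function(matrix, variance_target = 0.98, partner_M = NULL) {
  matrix <- as.matrix(matrix)
  if (variance_target <= 0 || variance_target > 1) {
    stop("variance_target must lie in (0, 1]")
  }
  tt <- ncol(matrix)
  d2 <- svd(matrix, nu = 0, nv = 0)$d^2
  total <- sum(d2)
  cum <- if (total > 0) cumsum(d2) / total else rep(1, length(d2))
  M <- which(cum >= variance_target - 1e-12)[1L]
  if (is.na(M)) M <- length(d2)
  cap <- tt - 1L
  if (!is.null(partner_M)) cap <- min(cap, tt - 2L - as.integer(partner_M))
  M <- max(1L, min(M, cap, min(dim(matrix))))
  list(M = as.integer(M), explained_fraction = cum[M])
}

#' Back-project metagene series to gene level
#'
#' Genes and metagenes are linearly related, so any series expressed in
#' metagene coordinates lifts to gene coordinates through the loading
#' matrix: returns \code{W \%*\% metagene_series}.
#'
#' @param basis A \code{metagene_basis}.
#' @param metagene_series Numeric M x K matrix (or length-M vector).
#' @return Numeric N x K matrix.
#' @export
project_back <- function(basis, metagene_series) {
  stopifnot(inherits(basis, "metagene_basis"))
  s <- if (is.null(dim(metagene_series))) {
    matrix(metagene_series, ncol = 1L)
  } else as.matrix(metagene_series)
  if (nrow(s) != basis$M) {
    stop(sprintf("series has %d rows but basis has M = %d", nrow(s), basis$M))
  }
  out <- basis$W %*% s
  rownames(out) <- rownames(basis$W)
  out
}

#' @export
print.metagene_basis <- function(x, ...) {
  cat(sprintf("Metagene basis (%s): %d genes -> %d metagenes over T = %d\n",
              x$group_tag, nrow(x$W), x$M, x$T))
  cat(sprintf("  explained covariation: %.4f\n", x$explained_fraction))
  invisible(x)
}
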