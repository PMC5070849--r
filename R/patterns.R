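# Deterministic eigenvalue ordering: modulus desc, then real part desc, then
# imaginary part desc (puts the +Im member of a conjugate pair first). This
# makes leave-one-out pairing and cross-dataset matching reproducible.
.order_eigen <- function(lambda) {
  order(-Mod(lambda), -Re(lambda), -Im(lambda))
}

#' Classify an eigenvalue by its canonical trajectory shape
#'
#' The dynamic pattern attached to an eigenvalue \eqn{\lambda} is the power
#' trajectory \eqn{\lambda^1, \lambda^2, \ldots}; its qualitative shape is
#' fully determined by \eqn{\lambda}'s position relative to the unit circle
#' and the real axis.
#'
#' @param lambda A (possibly complex) eigenvalue.
#' @param unit_tol Half-width of the band around the unit circle (and around
#'   0) treated as "on" it.
#' @param real_tol Imaginary parts below this are treated as exactly real.
#' @return A class label string, one of \code{"growing"}, \code{"constant"},
#'   \code{"decaying"}, \code{"impulse"}, \code{"alternating-decaying"},
#'   \code{"alternating-growing/sustained"}, \code{"damped-oscillation"},
#'   \code{"sustained-oscillation"}, \code{"growing-oscillation"}. For
#'   complex labels the oscillation period \eqn{2\pi/|\arg\lambda|} (in
#'   samples) is attached as attribute \code{"period"}.
#' @export
classify_eigenvalue <- function(lambda, unit_tol = 1e-6, real_tol = 1e-9) {
  lambda <- as.complex(lambda)
  if (abs(Im(lambda)) < real_tol) {
    x <- Re(lambda)
    label <-
      if (x > 1 + unit_tol) "growing"
      else if (abs(x - 1) <= unit_tol) "constant"
      else if (abs(x) <= unit_tol) "impulse"
      else if (x > 0) "decaying"
      else if (x > -1) "alternating-decaying"
      else "alternating-growing/sustained"
    return(label)
  }
  m <- Mod(lambda)
  label <-
    if (abs(m - 1) <= unit_tol) "sustained-oscillation"
    else if (m < 1) "damped-oscillation"
    else "growing-oscillation"
  attr(label, "period") <- 2 * pi / abs(Arg(lambda))
  label
}

.unit_norm <- function(v) {
  n <- sqrt(sum(v^2))
  if (n > 0) v / n else v
}

#' Extract internal principal dynamic patterns (iPDPs)
#'
#' Diagonalizes the effective internal system matrix and expands the
#' internally driven trajectory \eqn{\tilde A^{t-1} \tilde X_1} into one
#' pattern per eigenvalue: with \eqn{\tilde A H = H E} and \eqn{S = H^{-1}
#' \tilde X_1}, the p-th pattern has metagene coefficient vector
#' \eqn{\tilde K_p = s_p H_p} and contributes \eqn{\tilde K_p
#' \lambda_p^{t-1}} at time t, so the pattern contributions sum exactly to
#' the propagated internal component. Complex eigenvalues come in conjugate
#' pairs (the system matrix is real); each pair is merged into one real
#' oscillatory pattern with trajectory \eqn{\lambda^t + \bar\lambda^t =
#' 2|\lambda|^t \cos(t \arg\lambda)}, the member with positive imaginary
#' part kept as the representative.
#'
#' @param A_tilde Effective internal system matrix (M1 x M1, real).
#' @param X1 Initial internal metagene state (length M1).
#' @param T Number of time samples for the trajectories.
#' @param unit_tol,real_tol Classification tolerances, see
#'   [classify_eigenvalue()].
#' @param cond_limit Maximum accepted condition number of the eigenvector
#'   matrix; beyond it the matrix is treated as non-diagonalizable.
#' @return Object of class \code{ssd_pdp_list}: a list of patterns, each
#'   with \code{kind} ("iPDP"), \code{index}, \code{eigenvalue} (complex;
#'   representative of the pair when merged), \code{is_merged_conjugate},
#'   \code{class_label} (with \code{period} attribute for oscillations),
#'   \code{trajectory} (\eqn{\lambda^1..\lambda^T}, conjugates summed),
#'   \code{trajectory_unit} (norm 1), \code{metagene_coefficients}
#'   (complex \eqn{\tilde K_p}) and \code{contribution} (real M1 x T).
#'   Patterns are ordered by descending eigenvalue modulus, ties by
#'   descending real part.
#' @export
extract_ipdps <- function(A_tilde, X1, T, unit_tol = 1e-6, real_tol = 1e-9,
                          cond_limit = 1e8) {
  A <- as.matrix(A_tilde)
  m1 <- nrow(A)
  if (length(X1) != m1) stop("X1 length must equal M1")
  eg <- eigen(A)
  H <- eg$vectors + 0i
  lam <- as.complex(eg$values)
  sh <- svd(H)$d
  if (sh[length(sh)] == 0 || sh[1L] / sh[length(sh)] > cond_limit) {
    stop("system matrix is numerically non-diagonalizable ",
         "(eigenvector condition number > ", format(cond_limit),
         "); perturb M1 and refit")
  }
  S <- solve(H, as.complex(X1))
  ord <- .order_eigen(lam)
  used <- logical(m1)
  tgrid <- seq_len(T)
  pats <- list()
  for (p in ord) {
    if (used[p]) next
    used[p] <- TRUE
    if (abs(Im(lam[p])) < real_tol) {
      l <- Re(lam[p])
      K <- S[p] * H[, p]
      traj <- l^tgrid
      contrib <- Re(K %o% as.complex(l)^(tgrid - 1))
      pat <- list(kind = "iPDP", eigenvalue = complex(real = l),
                  is_merged_conjugate = FALSE,
                  class_label = classify_eigenvalue(l, unit_tol, real_tol),
                  trajectory = traj, trajectory_unit = .unit_norm(traj),
                  metagene_coefficients = K, contribution = contrib)
    } else {
      cand <- which(!used & Mod(lam - Conj(lam[p])) <
                      1e-6 * max(1, Mod(lam[p])))
      if (!length(cand)) {
        stop("unpaired complex eigenvalue ", format(lam[p]),
             ": system matrix is not real")
      }
      q <- cand[which.min(Mod(lam[cand] - Conj(lam[p])))]
      used[q] <- TRUE
      rep_i <- if (Im(lam[p]) > 0) p else q
      l <- lam[rep_i]
      K <- S[rep_i] * H[, rep_i]
      traj <- 2 * Mod(l)^tgrid * cos(tgrid * Arg(l))
      contrib <- 2 * Re(K %o% l^(tgrid - 1))
      pat <- list(kind = "iPDP", eigenvalue = l,
                  is_merged_conjugate = TRUE,
                  class_label = classify_eigenvalue(l, unit_tol, real_tol),
                  trajectory = traj, trajectory_unit = .unit_norm(traj),
                  metagene_coefficients = K, contribution = contrib)
    }
    class(pat) <- "ssd_pdp"
    pats[[length(pats) + 1L]] <- pat
  }
  for (i in seq_along(pats)) pats[[i]]$index <- i
  structure(pats, class = "ssd_pdp_list", kind = "iPDP", T = T, M1 = m1)
}

#' Extract external principal dynamic patterns (ePDPs)
#'
#' The q-th ePDP is the q-th external metagene's time profile
#' \eqn{\tilde U_1(q) .. \tilde U_{T-1}(q)}; it enters the internal system
#' one step delayed, weighted by column q of the effective control matrix,
#' so the externally driven component satisfies \eqn{\tilde X^{EXT}_t =
#' \sum_q \tilde B_{\cdot q} \tilde U_{t-1}(q)} exactly.
#'
#' @param B_tilde Effective control matrix (M1 x M2).
#' @param U_scores External metagene series (M2 x T).
#' @return Object of class \code{ssd_pdp_list} of \code{ssd_pdp} patterns in
#'   external singular-value order (q = 1..M2), each with
#'   \code{trajectory} (length T - 1), \code{trajectory_unit},
#'   \code{metagene_coefficients} (column \eqn{\tilde B_{\cdot q}}) and
#'   \code{contribution} (M1 x T, column 1 zero). ePDPs have no eigenvalue
#'   or class label.
#' @export
extract_epdps <- function(B_tilde, U_scores) {
  B <- as.matrix(B_tilde)
  U <- as.matrix(U_scores)
  if (nrow(U) != ncol(B)) stop("U_scores rows must equal ncol(B_tilde)")
  tt <- ncol(U)
  pats <- lapply(seq_len(nrow(U)), function(q) {
    traj <- U[q, seq_len(tt - 1L)]
    contrib <- cbind(0, B[, q] %o% traj)
    structure(
      list(kind = "ePDP", index = q, eigenvalue = NA_complex_,
           is_merged_conjugate = FALSE, class_label = NA_character_,
           trajectory = traj, trajectory_unit = .unit_norm(traj),
           metagene_coefficients = B[, q], contribution = contrib),
      class = "ssd_pdp")
  })
  structure(pats, class = "ssd_pdp_list", kind = "ePDP", T = tt,
            M1 = nrow(B))
}

#' @export
print.ssd_pdp <- function(x, ...) {
  if (x$kind == "iPDP") {
    cat(sprintf("iPDP %d: lambda = %s%s, class = %s\n", x$index,
                format(x$eigenvalue, digits = 4L),
                if (x$is_merged_conjugate) " (conjugate pair merged)" else "",
                x$class_label))
    per <- attr(x$class_label, "period")
    if (!is.null(per)) cat(sprintf("  oscillation period: %.3f samples\n", per))
  } else {
    cat(sprintf("ePDP %d (external metagene profile, %d samples)\n",
                x$index, length(x$trajectory)))
  }
  invisible(x)
}

#' @export
print.ssd_pdp_list <- function(x, ...) {
  cat(sprintf("%d %s pattern(s):\n", length(x), attr(x, "kind")))
  for (p in x) print(p)
  invisible(x)
}

# signed/magnitude coefficient conventions shared by iPDP and ePDP tables:
# real patterns carry their real coefficient; merged conjugate pairs carry
# magnitude 2|C| and phase arg(C), with 2 Re(C) as the signed value (their
# real contribution at time t is 2|C| |lambda|^t cos(t arg(lambda) + arg(C))).
.coef_object <- function(kind, ids, labels, C, merged) {
  signed <- matrix(0, nrow(C), ncol(C))
  magnitude <- matrix(0, nrow(C), ncol(C))
  phase <- matrix(0, nrow(C), ncol(C))
  for (j in seq_len(ncol(C))) {
    if (merged[j]) {
      signed[, j] <- 2 * Re(C[, j])
      magnitude[, j] <- 2 * Mod(C[, j])
      phase[, j] <- Arg(C[, j])
    } else {
      signed[, j] <- Re(C[, j])
      magnitude[, j] <- abs(Re(C[, j]))
    }
  }
  dimnames(signed) <- dimnames(magnitude) <- dimnames(phase) <-
    dimnames(C) <- list(ids, labels)
  structure(list(kind = kind, ids = ids, labels = labels, C = C,
                 signed = signed, magnitude = magnitude, phase = phase,
                 merged = merged),
            class = "ssd_gene_coef")
}

#' Extract the coefficient matrix from a gene-coefficient table
#'
#' @param object An \code{ssd_gene_coef} table.
#' @param mode \code{"absolute"} (coefficient magnitudes; for merged
#'   conjugate patterns \eqn{2|C|}) or \code{"signed"}.
#' @return Numeric genes x patterns matrix.
#' @export
coef_values <- function(object, mode = c("absolute", "signed")) {
  stopifnot(inherits(object, "ssd_gene_coef"))
  mode <- match.arg(mode)
  if (mode == "absolute") object$magnitude else object$signed
}

#' @export
print.ssd_gene_coef <- function(x, ...) {
  cat(sprintf("%s gene coefficients: %d genes x %d patterns (%s)\n",
              x$kind, length(x$ids), length(x$labels),
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Gene-level coefficients of the internal patterns
#'
#' Lifts the metagene coefficient vector of each iPDP through the internal
#' loading matrix: \eqn{C_p = W_X \tilde K_p}, so gene i's internally driven
#' expression is \eqn{\sum_p C_p(i) \lambda_p^{t-1}} (real patterns; merged
#' pairs contribute \eqn{2 Re(C_p(i) \lambda_p^{t-1})}).
#'
#' @param basis_internal The internal [fit_metagenes()] basis of the same
#'   fit.
#' @param ipdps Patterns from [extract_ipdps()].
#' @return An \code{ssd_gene_coef} table; see [coef_values()]. The complex
#'   \eqn{C_p} of merged pairs is kept in field \code{C}, with magnitude
#'   \eqn{2|C_p(i)|} and phase reported.
#' @export
gene_coefficients_ipdp <- function(basis_internal, ipdps) {
  stopifnot(inherits(basis_internal, "metagene_basis"),
            attr(ipdps, "kind") == "iPDP")
  if (attr(ipdps, "M1") != basis_internal$M) {
    stop("patterns and basis disagree on M1")
  }
  C <- vapply(ipdps, function(p) basis_internal$W %*% p$metagene_coefficients,
              complex(nrow(basis_internal$W)))
  C <- matrix(C, nrow(basis_internal$W), length(ipdps))
  .coef_object("iPDP", rownames(basis_internal$W),
               paste0("iPDP", seq_along(ipdps)), C,
               vapply(ipdps, `[[`, logical(1L), "is_merged_conjugate"))
}

#' Gene-level coefficients of the external patterns
#'
#' \eqn{D = W_X \tilde B}: element (i, q) weighs the q-th external metagene
#' profile in gene i's externally driven expression, \eqn{X^{EXT}_t(i) =
#' \sum_q D_{iq} \tilde U_{t-1}(q)}.
#'
#' @param basis_internal The internal metagene basis.
#' @param B_tilde Effective control matrix (M1 x M2).
#' @return An \code{ssd_gene_coef} table.
#' @export
gene_coefficients_epdp <- function(basis_internal, B_tilde) {
  stopifnot(inherits(basis_internal, "metagene_basis"))
  B <- as.matrix(B_tilde)
  if (nrow(B) != basis_internal$M) stop("B_tilde rows must equal basis M")
  D <- basis_internal$W %*% B
  .coef_object("ePDP", rownames(basis_internal$W),
               paste0("ePDP", seq_len(ncol(B))), D + 0i,
               rep(FALSE, ncol(B)))
}

#' Leave-one-out eigenvalue sensitivity
#'
#' Removes one gene at a time from the chosen group, reruns the metagene
#' projection and model estimation, and records the ordered spectrum of the
#' effective system matrix, yielding per-rank variation ranges (the error
#' bars of a spectrum robustness plot). Runs are paired by the deterministic
#' eigenvalue ordering rule.
#'
#' @param dataset An [expression_dataset()].
#' @param M1,M2 Metagene dimensions used in every rerun.
#' @param group \code{"internal"} or \code{"external"}: the group to perturb.
#' @param rtol Pseudo-inverse tolerance passed to [estimate_model()].
#' @return List with \code{eigenvalues} (genes x M1 complex matrix, row g =
#'   ordered spectrum with gene g removed) and \code{ranges} (data frame,
#'   one row per eigenvalue rank, min/max/mean of modulus, real and
#'   imaginary parts), plus \code{group} and \code{genes}.
#' @export
loo_sensitivity <- function(dataset, M1, M2,
                            group = c("internal", "external"),
                            rtol = 1e-10) {
  stopifnot(inherits(dataset, "expression_dataset"))
  group <- match.arg(group)
  target <- if (group == "internal") dataset$internal_matrix else dataset$external_matrix
  other <- if (group == "internal") dataset$external_matrix else dataset$internal_matrix
  n <- nrow(target)
  if (n < 3L) stop("leave-one-out needs at least 3 genes in the ", group, " group")
  eigmat <- matrix(NA_complex_, n, M1)
  for (g in seq_len(n)) {
    red <- target[-g, , drop = FALSE]
    if (group == "internal") {
      bi <- fit_metagenes(red, M1)
      be <- fit_metagenes(other, M2, group_tag = "external")
    } else {
      bi <- fit_metagenes(other, M1)
      be <- fit_metagenes(red, M2, group_tag = "external")
    }
    mod <- estimate_model(bi$scores, be$scores, rtol = rtol)
    lam <- as.complex(eigen(mod$A_tilde, only.values = TRUE)$values)
    eigmat[g, ] <- lam[.order_eigen(lam)]
  }
  stat3 <- function(v) c(min = min(v), max = max(v), mean = mean(v))
  ranges <- do.call(rbind, lapply(seq_len(M1), function(r) {
    v <- eigmat[, r]
    data.frame(rank = r,
               mod_min = min(Mod(v)), mod_max = max(Mod(v)), mod_mean = mean(Mod(v)),
               re_min = min(Re(v)), re_max = max(Re(v)), re_mean = mean(Re(v)),
               im_min = min(Im(v)), im_max = max(Im(v)), im_mean = mean(Im(v)))
  }))
  list(eigenvalues = eigmat, ranges = ranges, group = group,
       genes = rownames(target))
}

#' Principal patterns of the interaction component
#'
#' SVD of the stacked interaction series (past external input filtered
#' through the internal network): returns the top-K right singular vectors
#' as time trajectories, each with its share of the interaction
#' covariation.
#'
#' @param decomp An [decompose_dynamics()] result.
#' @param K Number of trajectories, \code{K < T}.
#' @return List of class \code{ssd_interaction_patterns} with
#'   \code{vectors} (T x K, sign-fixed right singular vectors) and
#'   \code{fractions} (length K). An identically zero interaction component
#'   yields an empty result with a warning.
#' @export
interaction_patterns <- function(decomp, K) {
  X <- decomp$interaction
  tt <- ncol(X)
  if (K >= tt) stop("K must be smaller than T")
  if (max(abs(X)) == 0) {
    warning("interaction component is identically zero; no patterns")
    return(structure(list(vectors = matrix(0, tt, 0L), fractions = numeric(0)),
                     class = "ssd_interaction_patterns"))
  }
  sv <- svd(X)
  K <- min(K, sum(sv$d > 0))
  V <- sv$v[, seq_len(K), drop = FALSE]
  for (j in seq_len(K)) {
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  }
  structure(list(vectors = V, fractions = sv$d[seq_len(K)]^2 / sum(sv$d^2)),
            class = "ssd_interaction_patterns")
}
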