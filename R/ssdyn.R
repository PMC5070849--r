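#' Fit a state-space decomposition of internal vs external expression dynamics
#'
#' The one-call interface: projects the internal and external expression
#' matrices onto SVD metagenes, estimates the effective metagene state-space
#' model \eqn{\tilde X_{t+1} = \tilde A \tilde X_t + \tilde B \tilde U_t},
#' decomposes the internal trajectory into internally driven, externally
#' driven and interaction components, extracts and classifies the internal
#' (iPDP) and external (ePDP) principal dynamic patterns, and back-projects
#' the per-gene pattern coefficients.
#'
#' @param dataset An [expression_dataset()] (or the \code{$dataset} of a
#'   [make_synthetic_dataset()] result).
#' @param M1,M2 Metagene dimensions. When \code{NULL}, chosen as the
#'   smallest dimensions capturing \code{variance_target} of each group's
#'   covariation, jointly clamped to \code{M1 + M2 <= T - 2} (see
#'   [choose_dimension()]). Explicit values take precedence.
#' @param variance_target Covariation fraction for automatic dimension
#'   choice; default 0.98.
#' @param external_lags Lag split between the external and interaction
#'   components; see [decompose_dynamics()].
#' @param unit_tol,real_tol Eigenvalue classification tolerances.
#' @param pinv_rtol Relative singular-value tolerance of the estimation
#'   pseudo-inverse.
#' @return An object of class \code{ssdyn} with components \code{dataset}
#'   (name, ids, T), \code{basis_internal}, \code{basis_external},
#'   \code{model} (the \code{effective_model}), \code{decomposition},
#'   \code{ipdps}, \code{epdps}, \code{gene_coef_ipdp},
#'   \code{gene_coef_epdp} and \code{control} (all tolerances used).
#'   Standard methods: \code{print}, \code{summary}, \code{coef},
#'   \code{fitted}, \code{residuals}, \code{predict}, \code{simulate},
#'   \code{plot}.
#' @examples
#' syn <- make_synthetic_dataset(N1 = 60, N2 = 20, M1 = 3, M2 = 2, T = 16,
#'                               eigen_spec = list(0.9, complex(real = 0.7,
#'                                                              imaginary = 0.4)),
#'                               seed = 7)
#' fit <- ssdyn(syn$dataset, M1 = 3, M2 = 2)
#' summary(fit)
#' @export
ssdyn <- function(dataset, M1 = NULL, M2 = NULL, variance_target = 0.98,
                  external_lags = 1L, unit_tol = 1e-6, real_tol = 1e-9,
                  pinv_rtol = 1e-10) {
  stopifnot(inherits(dataset, "expression_dataset"))
  im <- dataset$internal_matrix
  em <- dataset$external_matrix
  tt <- dataset$T
  if (is.null(M1)) {
    M1 <- choose_dimension(im, variance_target, partner_M = 1L)$M
  }
  if (is.null(M2)) {
    M2 <- choose_dimension(em, variance_target, partner_M = M1)$M
  }
  basis_internal <- fit_metagenes(im, M1, group_tag = "internal")
  basis_external <- fit_metagenes(em, M2, group_tag = "external")
  model <- estimate_model(basis_internal$scores, basis_external$scores,
                          rtol = pinv_rtol)
  decomposition <- decompose_dynamics(model, basis_internal$scores[, 1L],
                                      basis_external$scores,
                                      external_lags = external_lags)
  ipdps <- extract_ipdps(model$A_tilde, basis_internal$scores[, 1L], tt,
                         unit_tol = unit_tol, real_tol = real_tol)
  epdps <- extract_epdps(model$B_tilde, basis_external$scores)
  structure(
    list(dataset = list(name = dataset$name,
                        internal_ids = dataset$internal_ids,
                        external_ids = dataset$external_ids,
                        time_labels = dataset$time_labels, T = tt),
         basis_internal = basis_internal, basis_external = basis_external,
         model = model, decomposition = decomposition,
         ipdps = ipdps, epdps = epdps,
         gene_coef_ipdp = gene_coefficients_ipdp(basis_internal, ipdps),
         gene_coef_epdp = gene_coefficients_epdp(basis_internal,
                                                 model$B_tilde),
         control = list(M1 = M1, M2 = M2, variance_target = variance_target,
                        external_lags = external_lags, unit_tol = unit_tol,
                        real_tol = real_tol, pinv_rtol = pinv_rtol)),
    class = "ssdyn")
}

#' @export
print.ssdyn <- function(x, ...) {
  cat(sprintf("State-space decomposition of '%s'\n", x$dataset$name))
  cat(sprintf("  %d internal genes -> M1 = %d metagenes (%.1f%% covariation)\n",
              length(x$dataset$internal_ids), x$control$M1,
              100 * x$basis_internal$explained_fraction))
  cat(sprintf("  %d external genes -> M2 = %d metagenes (%.1f%% covariation)\n",
              length(x$dataset$external_ids), x$control$M2,
              100 * x$basis_external$explained_fraction))
  cat(sprintf("  T = %d samples; one-step fit residual %.4g\n",
              x$dataset$T, x$model$residual_norm))
  cat(sprintf("  %d internal pattern(s), %d external pattern(s)\n",
              length(x$ipdps), length(x$epdps)))
  invisible(x)
}

#' @export
summary.ssdyn <- function(object, ...) {
  ip <- object$ipdps
  tab <- data.frame(
    pattern = paste0("iPDP", seq_along(ip)),
    eigenvalue = vapply(ip, function(p) format(p$eigenvalue, digits = 4L),
                        character(1L)),
    modulus = vapply(ip, function(p) Mod(p$eigenvalue), numeric(1L)),
    merged_pair = vapply(ip, `[[`, logical(1L), "is_merged_conjugate"),
    class = vapply(ip, function(p) as.character(p$class_label), character(1L)),
    stringsAsFactors = FALSE)
  per <- vapply(ip, function(p) {
    pr <- attr(p$class_label, "period")
    if (is.null(pr)) NA_real_ else pr
  }, numeric(1L))
  tab$period <- per
  structure(list(name = object$dataset$name, table = tab,
                 model = object$model,
                 explained_internal = object$basis_internal$explained_fraction,
                 explained_external = object$basis_external$explained_fraction,
                 conservation = object$decomposition$total_check,
                 n_epdp = length(object$epdps)),
            class = "summary.ssdyn")
}

#' @export
print.summary.ssdyn <- function(x, ...) {
  cat(sprintf("State-space decomposition of '%s'\n", x$name))
  cat(sprintf("Explained covariation: internal %.4f, external %.4f\n",
              x$explained_internal, x$explained_external))
  cat(sprintf("One-step fit residual (Frobenius): %.6g; regressor rank %d/%d\n",
              x$model$residual_norm, x$model$rank_upsilon,
              x$model$M1 + x$model$M2))
  cat(sprintf("Component conservation check: %.3g\n\n", x$conservation))
  cat("Internal principal dynamic patterns:\n")
  print(x$table, row.names = FALSE, digits = 4L)
  cat(sprintf("\n%d external principal dynamic pattern(s)\n", x$n_epdp))
  invisible(x)
}

#' Coefficients of a fitted decomposition
#'
#' @param object An \code{ssdyn} fit.
#' @param level \code{"genes"} for per-gene pattern coefficients,
#'   \code{"metagenes"} for the effective model matrices.
#' @param kind For gene level, \code{"ipdp"} or \code{"epdp"}.
#' @param mode Coefficient convention, see [coef_values()].
#' @param ... Unused.
#' @return Gene level: a genes x patterns numeric matrix. Metagene level: a
#'   list with \code{A_tilde} and \code{B_tilde}.
#' @export
coef.ssdyn <- function(object, level = c("genes", "metagenes"),
                       kind = c("ipdp", "epdp"),
                       mode = c("absolute", "signed"), ...) {
  level <- match.arg(level)
  if (level == "metagenes") {
    return(list(A_tilde = object$model$A_tilde, B_tilde = object$model$B_tilde))
  }
  kind <- match.arg(kind)
  coef_values(if (kind == "ipdp") object$gene_coef_ipdp else object$gene_coef_epdp,
              match.arg(mode))
}

#' One-step-ahead fitted values
#'
#' \eqn{\hat{\tilde X}_t = \tilde A \tilde X_{t-1} + \tilde B \tilde
#' U_{t-1}} for t = 2..T, at metagene or gene level (gene level through the
#' internal loadings).
#'
#' @param object An \code{ssdyn} fit.
#' @param level \code{"metagenes"} or \code{"genes"}.
#' @param ... Unused.
#' @return M1 x (T-1) or N1 x (T-1) matrix, columns t = 2..T.
#' @export
fitted.ssdyn <- function(object, level = c("metagenes", "genes"), ...) {
  level <- match.arg(level)
  X <- object$basis_internal$scores
  U <- object$basis_external$scores
  tt <- ncol(X)
  Z_hat <- object$model$A_tilde %*% X[, 1:(tt - 1L), drop = FALSE] +
    object$model$B_tilde %*% U[, 1:(tt - 1L), drop = FALSE]
  colnames(Z_hat) <- object$dataset$time_labels[-1L]
  if (level == "genes") project_back(object$basis_internal, Z_hat) else Z_hat
}

#' @export
residuals.ssdyn <- function(object, ...) {
  X <- object$basis_internal$scores
  tt <- ncol(X)
  X[, 2:tt, drop = FALSE] - fitted(object, level = "metagenes")
}

#' Predict internal dynamics from the fitted model
#'
#' Propagates the fitted model \eqn{\tilde X_{t+1} = \tilde A \tilde X_t +
#' \tilde B \tilde U_t} from the observed initial state, through the
#' observed external inputs and, optionally, \code{n_ahead} further steps
#' with zero external input.
#'
#' @param object An \code{ssdyn} fit.
#' @param n_ahead Extra steps beyond T.
#' @param level \code{"metagenes"} or \code{"genes"}.
#' @param ... Unused.
#' @return Matrix with T + n_ahead columns.
#' @export
predict.ssdyn <- function(object, n_ahead = 0L,
                          level = c("metagenes", "genes"), ...) {
  level <- match.arg(level)
  A <- object$model$A_tilde
  B <- object$model$B_tilde
  U <- object$basis_external$scores
  tt <- ncol(U)
  U_ext <- cbind(U, matrix(0, nrow(U), n_ahead))
  out <- simulate_states(A, B, U_ext, object$basis_internal$scores[, 1L],
                         n_steps = tt + n_ahead, noise_sd = 0)
  if (level == "genes") project_back(object$basis_internal, out) else out
}

#' Simulate metagene trajectories from a fitted decomposition
#'
#' Re-runs the fitted recursion from the observed initial state and external
#' inputs with additive Gaussian state noise, giving parametric-bootstrap
#' style replicate trajectories.
#'
#' @param object An \code{ssdyn} fit.
#' @param nsim Number of replicates.
#' @param seed Optional integer seed.
#' @param noise_sd State noise standard deviation; defaults to the fitted
#'   one-step residual standard deviation.
#' @param ... Unused.
#' @return A list of \code{nsim} M1 x T matrices.
#' @export
simulate.ssdyn <- function(object, nsim = 1L, seed = NULL, noise_sd = NULL, ...) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(noise_sd)) {
    r <- residuals(object)
    noise_sd <- stats::sd(as.numeric(r))
  }
  lapply(seq_len(nsim), function(i) {
    simulate_states(object$model$A_tilde, object$model$B_tilde,
                    object$basis_external$scores,
                    object$basis_internal$scores[, 1L],
                    n_steps = object$dataset$T, noise_sd = noise_sd)
  })
}

#' Plot the principal dynamic patterns of a fit
#'
#' Two base-graphics panels: unit-normalized internal pattern trajectories
#' (labelled by eigenvalue class) and external pattern trajectories.
#'
#' @param x An \code{ssdyn} fit.
#' @param ... Passed to \code{matplot}.
#' @return \code{x}, invisibly.
#' @export
plot.ssdyn <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  itraj <- vapply(x$ipdps, `[[`, numeric(x$dataset$T), "trajectory_unit")
  graphics::matplot(itraj, type = "l", lty = 1, lwd = 2,
                    xlab = "time index", ylab = "unit trajectory",
                    main = "Internal patterns (iPDP)", ...)
  graphics::legend("topright", bty = "n", lty = 1, lwd = 2,
                   col = seq_along(x$ipdps), cex = 0.8,
                   legend = vapply(x$ipdps, function(p)
                     sprintf("%d: %s", p$index, as.character(p$class_label)),
                     character(1L)))
  etraj <- vapply(x$epdps, `[[`, numeric(x$dataset$T - 1L), "trajectory_unit")
  graphics::matplot(etraj, type = "l", lty = 1, lwd = 2,
                    xlab = "time index", ylab = "unit trajectory",
                    main = "External patterns (ePDP)", ...)
  invisible(x)
}
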