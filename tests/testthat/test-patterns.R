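test_that("diagonal systems give unit-basis patterns ordered by modulus", {
  p <- extract_ipdps(diag(c(0.5, 2)), X1 = c(1, 1), T = 5)
  expect_length(p, 2L)
  expect_equal(p[[1]]$eigenvalue, complex(real = 2))
  expect_equal(p[[2]]$eigenvalue, complex(real = 0.5))
  expect_equal(p[[1]]$trajectory, 2^(1:5))
  expect_equal(p[[2]]$trajectory, 0.5^(1:5))
  expect_equal(as.complex(p[[1]]$metagene_coefficients), c(0 + 0i, 1 + 0i))
  expect_equal(as.complex(p[[2]]$metagene_coefficients), c(1 + 0i, 0 + 0i))
  expect_equal(as.character(p[[1]]$class_label), "growing")
  expect_equal(as.character(p[[2]]$class_label), "decaying")
})

test_that("conjugate pairs merge into the closed-form damped cosine", {
  pair <- complex(modulus = 0.9, argument = pi / 4)
  A <- matrix_with_spectrum(c(0.7, 0.3, pair), seed = 31)
  p <- extract_ipdps(A, X1 = rnorm(4), T = 12)
  merged <- Filter(function(q) q$is_merged_conjugate, p)
  expect_length(merged, 1L)
  expect_equal(Mod(merged[[1]]$eigenvalue), 0.9, tolerance = 1e-9)
  expect_gt(Im(merged[[1]]$eigenvalue), 0)
  t <- 1:12
  expect_lt(max(abs(merged[[1]]$trajectory - 2 * 0.9^t * cos(t * pi / 4))),
            1e-9)
  expect_equal(as.character(merged[[1]]$class_label), "damped-oscillation")
  expect_equal(attr(merged[[1]]$class_label, "period"), 8, tolerance = 1e-9)
})

test_that("pattern contributions sum to the propagated internal component", {
  for (seed in c(32, 33, 34)) {
    set.seed(seed)
    m <- sample(2:5, 1)
    A <- matrix(rnorm(m * m, sd = 0.5), m)
    X1 <- rnorm(m)
    T <- 10
    p <- extract_ipdps(A, X1, T)
    total <- Reduce(`+`, lapply(p, `[[`, "contribution"))
    pow <- diag(m)
    for (t in 1:T) {
      expect_lt(max(abs(total[, t] - pow %*% X1)), 1e-8)
      pow <- A %*% pow
    }
    # conjugate closure: merged contributions are real up to round-off
    for (q in Filter(function(z) z$is_merged_conjugate, p)) {
      l <- q$eigenvalue; K <- q$metagene_coefficients
      z <- K %o% l^(0:(T - 1)) + Conj(K) %o% Conj(l)^(0:(T - 1))
      expect_lt(max(abs(Im(z))), 1e-10)
    }
  }
})

test_that("defective matrices are rejected", {
  J <- matrix(c(1, 0, 1, 1), 2)  # Jordan block
  expect_error(extract_ipdps(J, c(1, 1), 8), "non-diagonalizable")
})

test_that("eigenvalue classes cover the plane with correct oscillation periods", {
  expect_equal(as.character(classify_eigenvalue(0.5)), "decaying")
  expect_equal(as.character(classify_eigenvalue(1)), "constant")
  expect_equal(as.character(classify_eigenvalue(1.5)), "growing")
  expect_equal(as.character(classify_eigenvalue(0)), "impulse")
  expect_equal(as.character(classify_eigenvalue(-0.5)), "alternating-decaying")
  expect_equal(as.character(classify_eigenvalue(-1)), "alternating-growing/sustained")
  expect_equal(as.character(classify_eigenvalue(-2)), "alternating-growing/sustained")

  d <- classify_eigenvalue(complex(modulus = 0.9, argument = pi / 4))
  expect_equal(as.character(d), "damped-oscillation")
  expect_equal(attr(d, "period"), 8, tolerance = 1e-12)

  s <- classify_eigenvalue(complex(modulus = 1, argument = pi / 3))
  expect_equal(as.character(s), "sustained-oscillation")
  expect_equal(attr(s, "period"), 6, tolerance = 1e-12)

  g <- classify_eigenvalue(complex(modulus = 1.2, argument = pi / 5))
  expect_equal(as.character(g), "growing-oscillation")
})

test_that("unit trajectories have norm one", {
  A <- matrix_with_spectrum(c(0.9, complex(modulus = 0.8, argument = pi / 3)),
                            seed = 35)
  p <- extract_ipdps(A, rnorm(3), 15)
  for (q in p) expect_equal(sqrt(sum(q$trajectory_unit^2)), 1,
                            tolerance = 1e-12)
  e <- extract_epdps(matrix(rnorm(6), 3, 2), matrix(rnorm(24), 2, 12))
  for (q in e) expect_equal(sqrt(sum(q$trajectory_unit^2)), 1,
                            tolerance = 1e-12)
})

test_that("external patterns reconstruct the externally driven component", {
  set.seed(36)
  B <- matrix(rnorm(8), 4, 2)
  U <- matrix(rnorm(20), 2, 10)
  e <- extract_epdps(B, U)
  expect_length(e, 2L)
  recon <- Reduce(`+`, lapply(e, `[[`, "contribution"))
  expect_lt(max(abs(recon[, -1] - B %*% U[, 1:9])), 1e-10)
  expect_equal(recon[, 1], rep(0, 4))
  expect_equal(e[[1]]$trajectory, U[1, 1:9])

  z <- extract_epdps(matrix(0, 4, 2), U)
  for (q in z) expect_equal(q$metagene_coefficients, rep(0, 4))

  one <- extract_epdps(matrix(rnorm(4), 4, 1), U[1, , drop = FALSE])
  expect_length(one, 1L)
  expect_lt(max(abs(one[[1]]$contribution[, -1] -
                    one[[1]]$metagene_coefficients %o% U[1, 1:9])), 1e-12)
})

test_that("gene coefficients lift metagene coefficients through the loadings", {
  syn <- make_synthetic_dataset(N1 = 30, N2 = 12, M1 = 3, M2 = 2, T = 14,
                                eigen_spec = list(0.85, complex(modulus = 0.7,
                                                                argument = pi / 5)),
                                seed = 37)
  fit <- ssdyn(syn$dataset, M1 = 3, M2 = 2)
  gc <- fit$gene_coef_ipdp
  # reconstruction: summed gene-level contributions equal the lifted
  # internal component
  T <- syn$dataset$T
  recon <- matrix(0, 30, T)
  for (j in seq_along(fit$ipdps)) {
    p <- fit$ipdps[[j]]
    l <- p$eigenvalue
    fac <- if (p$is_merged_conjugate) 2 else 1
    recon <- recon + fac * Re(gc$C[, j] %o% l^(0:(T - 1)))
  }
  lifted <- project_back(fit$basis_internal, fit$decomposition$internal)
  expect_lt(max(abs(recon - lifted)), 1e-9)
})

test_that("identity loadings pass metagene coefficients through unchanged", {
  set.seed(38)
  # N1 = M1: loadings are a permutation/rotation-free identity when the
  # data are the metagene series themselves
  A <- matrix_with_spectrum(c(0.8, 0.4), seed = 39)
  X <- simulate_states(A, NULL, NULL, c(1, 2), n_steps = 10)
  b <- fit_metagenes(rbind(X, 0), 2)  # 3 genes so W is 3x2 with zero row
  p <- extract_ipdps(A, X[, 1], 10)
  gc <- gene_coefficients_ipdp(b, p)
  for (j in seq_along(p)) {
    expect_equal(gc$C[, j], drop(b$W %*% p[[j]]$metagene_coefficients),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("external gene coefficients obey the product identity", {
  set.seed(40)
  m <- matrix(rnorm(20 * 10), 20, 10)
  b <- fit_metagenes(m, 3)
  B <- matrix(rnorm(6), 3, 2)
  gc <- gene_coefficients_epdp(b, B)
  expect_equal(unname(gc$signed), b$W %*% B, tolerance = 1e-14)
  # orthonormal invariance of the Frobenius norm
  expect_equal(sqrt(sum(gc$signed^2)), sqrt(sum(B^2)), tolerance = 1e-10)
  z <- gene_coefficients_epdp(b, matrix(0, 3, 2))
  expect_true(all(z$signed == 0))
  # reconstruction at gene level
  U <- matrix(rnorm(20), 2, 10)
  ext <- cbind(0, B %*% U[, 1:9])
  expect_lt(max(abs(gc$signed %*% U[, 1:9] - project_back(b, ext[, -1]))),
            1e-9)
})

test_that("leave-one-out on identical genes has zero-width ranges", {
  set.seed(41)
  profile <- as.numeric(arima.sim(list(ar = 0.7), 12))
  im <- matrix(rep(profile, each = 10), 10, 12)
  em <- matrix(rnorm(24), 2, 12)
  ds <- toy_dataset(im, em)
  loo <- suppressWarnings(loo_sensitivity(ds, M1 = 1, M2 = 1))
  expect_lt(max(loo$ranges$mod_max - loo$ranges$mod_min), 1e-9)
  expect_lt(max(loo$ranges$re_max - loo$ranges$re_min), 1e-9)
})

test_that("leave-one-out matches a brute-force rerun loop", {
  syn <- make_synthetic_dataset(N1 = 20, N2 = 8, M1 = 3, M2 = 2, T = 14,
                                eigen_spec = list(0.9, 0.6, 0.3), seed = 42)
  ds <- syn$dataset
  loo <- loo_sensitivity(ds, M1 = 3, M2 = 2)
  # independent loop over the same operations
  for (g in c(1, 7, 20)) {
    bi <- fit_metagenes(ds$internal_matrix[-g, ], 3)
    be <- fit_metagenes(ds$external_matrix, 2)
    lam <- eigen(estimate_model(bi$scores, be$scores)$A_tilde)$values
    lam <- lam[order(-Mod(lam), -Re(lam), -Im(lam))]
    expect_equal(loo$eigenvalues[g, ], as.complex(lam))
  }
  expect_equal(nrow(loo$eigenvalues), 20L)
  expect_error(loo_sensitivity(toy_dataset(matrix(rnorm(8), 2, 4),
                                           matrix(rnorm(8), 2, 4)),
                               M1 = 1, M2 = 1), "at least 3")
})

test_that("removing a gene invisible to the metagenes leaves the spectrum unchanged", {
  syn <- make_synthetic_dataset(N1 = 15, N2 = 6, M1 = 2, M2 = 2, T = 12,
                                eigen_spec = list(0.8, 0.5), seed = 43)
  im <- rbind(syn$dataset$internal_matrix, spike = 0)  # orthogonal null gene
  ds <- toy_dataset(im, syn$dataset$external_matrix)
  loo <- loo_sensitivity(ds, M1 = 2, M2 = 2)
  full <- {
    bi <- fit_metagenes(im, 2)
    be <- fit_metagenes(syn$dataset$external_matrix, 2)
    lam <- eigen(estimate_model(bi$scores, be$scores)$A_tilde)$values
    lam[order(-Mod(lam), -Re(lam), -Im(lam))]
  }
  expect_lt(max(Mod(loo$eigenvalues[16, ] - full)), 1e-8)
})

test_that("interaction patterns recover the component's singular structure", {
  mod <- random_stable_model(3, 2, seed = 44)
  U <- rand_inputs(2, 14, seed = 45)
  d <- decompose_dynamics(list(A_tilde = mod$A, B_tilde = mod$B), rnorm(3), U)
  ip <- interaction_patterns(d, K = 3)
  sv <- svd(d$interaction)
  expect_equal(ip$fractions, (sv$d[1:3]^2 / sum(sv$d^2)), tolerance = 1e-12)
  expect_equal(dim(ip$vectors), c(14L, 3L))
  for (j in 1:3) {
    expect_lt(min(max(abs(ip$vectors[, j] - sv$v[, j])),
                  max(abs(ip$vectors[, j] + sv$v[, j]))), 1e-10)
  }

  dz <- decompose_dynamics(list(A_tilde = mod$A, B_tilde = mod$B), rnorm(3),
                           matrix(0, 2, 14))
  expect_warning(z <- interaction_patterns(dz, 2), "identically zero")
  expect_length(z$fractions, 0L)

  # rank-1 interaction: single pattern captures all covariation
  d1 <- decompose_dynamics(list(A_tilde = diag(0.5, 2),
                                B_tilde = matrix(c(1, 0), 2, 1)),
                           c(0, 0), matrix(rnorm(14), 1, 14))
  ip1 <- interaction_patterns(d1, 1)
  expect_equal(ip1$fractions, 1, tolerance = 1e-12)
})
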