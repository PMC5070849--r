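test_that("noiseless data from a known model is recovered exactly", {
  mod <- random_stable_model(2, 2, seed = 11, radius = 0.9)
  U <- rand_inputs(2, 10, seed = 12)
  X <- simulate_states(mod$A, mod$B, U, X1 = c(1, -1), n_steps = 10)
  est <- estimate_model(X, U)
  expect_lt(max(abs(est$A_tilde - mod$A)), 1e-8)
  expect_lt(max(abs(est$B_tilde - mod$B)), 1e-8)
  expect_equal(est$rank_upsilon, 4L)
})

test_that("zero input forces B to zero with a rank-deficiency warning", {
  mod <- random_stable_model(2, 2, seed = 13)
  U <- matrix(0, 2, 10)
  X <- simulate_states(mod$A, mod$B, U, X1 = c(2, 1), n_steps = 10)
  expect_warning(est <- estimate_model(X, U), "rank deficient")
  expect_lt(max(abs(est$A_tilde - mod$A)), 1e-8)
  expect_equal(est$B_tilde, matrix(0, 2, 2), ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("a square regressor system interpolates exactly", {
  set.seed(14)
  # T - 1 = M1 + M2 = 4: regressor is square and generically invertible
  X <- matrix(rnorm(2 * 5), 2, 5)
  U <- matrix(rnorm(2 * 5), 2, 5)
  est <- estimate_model(X, U)
  expect_lt(est$residual_norm, 1e-9)
})

test_that("estimability bound M1 + M2 <= T - 1 is enforced", {
  X <- matrix(rnorm(3 * 6), 3, 6)
  U <- matrix(rnorm(3 * 6), 3, 6)
  expect_error(estimate_model(X, U), "not estimable")
  expect_error(estimate_model(X, matrix(rnorm(12), 2, 6)), NA)
})

test_that("the estimate is one-step least-squares optimal", {
  mod <- random_stable_model(3, 2, seed = 15)
  U <- rand_inputs(2, 12, seed = 16)
  X <- simulate_states(mod$A, mod$B, U, X1 = rnorm(3), n_steps = 12,
                       noise_sd = 0.3, seed = 17)
  est <- estimate_model(X, U)
  Z <- X[, 2:12]
  Ups <- rbind(X[, 1:11], U[, 1:11])
  AB <- cbind(est$A_tilde, est$B_tilde)
  set.seed(18)
  for (i in 1:10) {
    pert <- AB + matrix(rnorm(length(AB), sd = 0.05), nrow(AB))
    expect_gte(sqrt(sum((Z - pert %*% Ups)^2)), est$residual_norm)
  }
})

test_that("decomposition components behave under degenerate models", {
  mod <- random_stable_model(3, 2, seed = 19)
  U <- rand_inputs(2, 10, seed = 20)
  X1 <- rnorm(3)

  # no external input: everything is internal propagation
  d0 <- decompose_dynamics(list(A_tilde = mod$A, B_tilde = mod$B), X1,
                           matrix(0, 2, 10))
  expect_equal(d0$external, matrix(0, 3, 10))
  expect_equal(d0$interaction, matrix(0, 3, 10))
  prop <- simulate_states(mod$A, NULL, NULL, X1, n_steps = 10)
  expect_lt(max(abs(d0$internal - prop)), 1e-12)

  # no internal propagation: the state is a pure one-lag copy of the input
  dA0 <- decompose_dynamics(list(A_tilde = matrix(0, 3, 3), B_tilde = mod$B),
                            X1, U)
  expect_equal(dA0$internal[, -1], matrix(0, 3, 9))
  expect_equal(dA0$interaction, matrix(0, 3, 10))
  expect_lt(max(abs(dA0$external[, -1] - mod$B %*% U[, 1:9])), 1e-12)
})

test_that("internal + external + interaction equals the propagated state", {
  mod <- random_stable_model(3, 3, seed = 21)
  U <- rand_inputs(3, 12, seed = 22)
  d <- decompose_dynamics(list(A_tilde = mod$A, B_tilde = mod$B),
                          rnorm(3), U)
  expect_lt(d$total_check, 1e-9)

  # the lag split is a convention: moving lags between external and
  # interaction never changes their sum
  d2 <- decompose_dynamics(list(A_tilde = mod$A, B_tilde = mod$B),
                           d$internal[, 1], U, external_lags = 3)
  expect_lt(max(abs((d$external + d$interaction) -
                    (d2$external + d2$interaction))), 1e-10)
  expect_false(isTRUE(all.equal(d$external, d2$external)))
})

test_that("simulation honors fixed points, seeds and hand-checked decay", {
  X <- simulate_states(diag(3), NULL, NULL, c(1, 2, 3), n_steps = 6)
  expect_equal(X, matrix(c(1, 2, 3), 3, 6))

  a <- simulate_states(diag(0.5, 2), NULL, NULL, c(1, 1), n_steps = 4,
                       noise_sd = 0.1, seed = 23)
  b <- simulate_states(diag(0.5, 2), NULL, NULL, c(1, 1), n_steps = 4,
                       noise_sd = 0.1, seed = 23)
  c_ <- simulate_states(diag(0.5, 2), NULL, NULL, c(1, 1), n_steps = 4,
                        noise_sd = 0.1, seed = 24)
  expect_identical(a, b)
  expect_false(identical(a, c_))

  h <- simulate_states(matrix(0.5), NULL, NULL, 1, n_steps = 5)
  expect_equal(as.numeric(h), c(1, 0.5, 0.25, 0.125, 0.0625))
})

test_that("unstable trajectories warn but keep going", {
  expect_warning(
    X <- simulate_states(diag(10, 1), NULL, NULL, 1, n_steps = 16),
    "unstable")
  expect_equal(as.numeric(X)[16], 1e15)
})

test_that("synthetic datasets reproduce the requested spectrum through the pipeline", {
  syn <- make_synthetic_dataset(N1 = 50, N2 = 20, M1 = 2, M2 = 2, T = 14,
                                eigen_spec = list(0.9, 0.4), seed = 25)
  bi <- fit_metagenes(syn$dataset$internal_matrix, 2)
  be <- fit_metagenes(syn$dataset$external_matrix, 2)
  est <- estimate_model(bi$scores, be$scores)
  lam <- sort(Re(eigen(est$A_tilde, only.values = TRUE)$values))
  expect_lt(max(abs(lam - c(0.4, 0.9))), 1e-6)

  pair <- complex(modulus = 0.8, argument = pi / 6)
  syn2 <- make_synthetic_dataset(N1 = 40, N2 = 15, M1 = 3, M2 = 2, T = 16,
                                 eigen_spec = list(0.5, pair), seed = 26)
  bi2 <- fit_metagenes(syn2$dataset$internal_matrix, 3)
  be2 <- fit_metagenes(syn2$dataset$external_matrix, 2)
  lam2 <- eigen(estimate_model(bi2$scores, be2$scores)$A_tilde)$values
  hit <- min(Mod(lam2 - pair))
  expect_lt(hit, 1e-6)
})

test_that("synthetic construction yields exact metagene rank and validates the spec", {
  syn <- make_synthetic_dataset(N1 = 3, N2 = 10, M1 = 3, M2 = 2, T = 12,
                                eigen_spec = list(0.9, 0.6, 0.3),
                                noise_sd = 0, seed = 27)
  d <- svd(syn$dataset$internal_matrix)$d
  expect_equal(sum(d > 1e-10 * d[1]), 3L)

  expect_error(
    make_synthetic_dataset(10, 10, 4, 2, 12,
                           eigen_spec = list(0.9, complex(real = 0.5,
                                                          imaginary = 0.2)),
                           seed = 1),
    "conjugate pairs count twice")
  expect_error(make_synthetic_dataset(10, 10, 5, 5, 10, list(1), seed = 1),
               "T - 2")
})

test_that("estimation error grows from zero with gene-level noise", {
  err_at <- function(noise) {
    syn <- make_synthetic_dataset(N1 = 80, N2 = 30, M1 = 2, M2 = 2, T = 20,
                                  eigen_spec = list(0.9, 0.5),
                                  noise_sd = noise, seed = 28)
    bi <- fit_metagenes(syn$dataset$internal_matrix, 2)
    be <- fit_metagenes(syn$dataset$external_matrix, 2)
    lam <- sort(Re(eigen(estimate_model(bi$scores, be$scores)$A_tilde,
                         only.values = TRUE)$values))
    max(abs(lam - c(0.5, 0.9)))
  }
  e0 <- err_at(0); e1 <- err_at(0.005); e2 <- err_at(0.2)
  expect_lt(e0, 1e-8)
  expect_gt(e1, e0)
  expect_gt(e2, e1)
})
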