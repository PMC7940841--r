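test_that("update_E shrinks the constraint slack elementwise", {
  set.seed(1)
  U <- matrix(rnorm(8), 4, 2); V <- qr.Q(qr(matrix(rnorm(6), 3, 2)))
  X <- U %*% t(V)
  # zero argument stays zero for any shrink threshold
  expect_equal(update_E(X, U, V, matrix(0, 4, 3), mu = 1, p = 0.5),
               matrix(0, 4, 3))
  # scalar case reduces to the shrink example
  expect_equal(update_E(matrix(4), matrix(0), matrix(0), matrix(0), 1, 0.5),
               matrix(3.5))
  # flipping the sign of the argument flips E
  Y <- matrix(rnorm(12), 4, 3)
  E1 <- update_E(X + Y, U, V, matrix(0, 4, 3), 1, 0.5)
  E2 <- update_E(X - Y, U, V, matrix(0, 4, 3), 1, 0.5)
  expect_equal(E1, -E2 + 2 * update_E(X, U, V, matrix(0, 4, 3), 1, 0.5))
})

test_that("update_U is the diagonal-reweighted ridge solution", {
  set.seed(2)
  H <- matrix(rnorm(12), 4, 3); V <- qr.Q(qr(matrix(rnorm(6), 3, 2)))
  q <- reweight_q(matrix(rnorm(8), 4, 2))
  # lambda = 0 -> plain projection HV
  expect_equal(update_U(H, V, q, lambda = 0, mu = 1)$U, H %*% V)
  # enormous penalty crushes every row
  expect_lt(max(abs(update_U(H, V, q, lambda = 1e12, mu = 1)$U)), 1e-8)
  # one-gene closed form: H = (2, 0), V = e1, q = 1, lambda = mu = 1 -> 2/3
  res <- update_U(matrix(c(2, 0), 1), matrix(c(1, 0), 2, 1), 1, 1, 1)
  expect_equal(res$U, matrix(2 / 3))
  expect_equal(res$a, 1 / 3)
})

test_that("update_V returns orthonormal smallest-eigenvalue eigenvectors", {
  set.seed(3)
  H <- matrix(rnorm(5 * 7), 5, 7)
  # alpha = 0, A = I: top-k right singular subspace of H
  V <- update_V(H, a = rep(1, 5), L = NULL, alpha = 0, mu = 1, k = 3)
  expect_equal(crossprod(V), diag(3), tolerance = 1e-12)
  sv <- svd(H, nu = 0, nv = 3)$v
  expect_equal(svd(crossprod(V, sv))$d, rep(1, 3), tolerance = 1e-10)

  # diagonal closed form with deterministic sign fixing:
  # H = diag(2, 1) makes M = -diag(4, 1); k = 1 picks e1 with positive sign
  V1 <- update_V(diag(c(2, 1)), a = rep(1, 2), L = NULL, alpha = 0, mu = 1,
                 k = 1)
  expect_equal(V1, matrix(c(1, 0), 2, 1), tolerance = 1e-12)

  expect_error(update_V(H, rep(1, 5), NULL, 0, 1, k = 10), "exceed")
})

test_that("noise-free rank-k data is recovered to SVD accuracy", {
  X <- rank_k_matrix(60, 20, 3, seed = 4)
  cfg <- pl21gpca_config(k = 3, lambda = 0, alpha = 0, tol = 1e-9)
  fit <- pl21gpca_fit(X, cfg)
  expect_true(fit$converged)
  expect_lte(utils::tail(fit$residual_trace, 1), 1e-9)
  sv <- svd(X, nu = 0, nv = 3)$v
  # max principal angle to the SVD subspace
  cosines <- pmin(svd(crossprod(fit$V, sv))$d, 1)
  expect_lt(max(acos(cosines)), 1e-6)
  expect_lt(norm(X - fit$U %*% t(fit$V), "F") / norm(X, "F"), 1e-8)
})

test_that("V stays orthonormal at every sweep and residual decreases to tol", {
  fx <- block_fixture()
  cfg <- pl21gpca_config(k = 3, lambda = 1, alpha = 10, max_iter = 300)
  fit <- pl21gpca_fit(fx$X, cfg)
  expect_true(fit$converged)
  expect_lt(max(fit$ortho_trace), 1e-8)
  expect_lte(utils::tail(fit$residual_trace, 1), cfg$tol)
  # returned V satisfies the constraint too
  expect_equal(crossprod(fit$V), diag(3), tolerance = 1e-10)
})

test_that("relabeling the samples permutes the embedding rows identically", {
  fx <- block_fixture(seed = 9)
  g <- sample_graph(fx$X, k_neighbors = 4)
  cfg <- pl21gpca_config(k = 3, lambda = 1, alpha = 10, max_iter = 200)
  fit <- pl21gpca_fit(fx$X, cfg, g)
  set.seed(10)
  perm <- sample(ncol(fx$X))
  gp <- list(L = g$L[perm, perm])
  fitp <- pl21gpca_fit(fx$X[, perm], cfg, gp$L)
  expect_equal(fitp$V, fit$V[perm, ], tolerance = 1e-6)
  expect_equal(fitp$U, fit$U, tolerance = 1e-6)
})

test_that("the E-update does not increase the augmented Lagrangian", {
  al <- pl21gpca:::augmented_lagrangian
  set.seed(11)
  for (i in 1:25) {
    p <- sample(3:8, 1); n <- sample(3:8, 1); k <- 2
    X <- matrix(rnorm(p * n, 0, 2), p, n)
    U <- matrix(rnorm(p * k), p, k)
    V <- qr.Q(qr(matrix(rnorm(n * k), n, k)))
    Y <- matrix(rnorm(p * n), p, n)
    mu <- 10^runif(1, -2, 2); pp <- runif(1, 0.1, 0.9)
    E0 <- matrix(rnorm(p * n), p, n)
    E1 <- update_E(X, U, V, Y, mu, pp)
    expect_lte(al(X, E1, U, V, Y, mu, pp, 0, 0),
               al(X, E0, U, V, Y, mu, pp, 0, 0) + 1e-10)
  }
})

test_that("larger lambda never increases the number of surviving gene rows", {
  fx <- block_fixture()
  g <- sample_graph(fx$X)
  counts <- vapply(c(1, 10, 100, 1000), function(lam) {
    fit <- pl21gpca_fit(fx$X, pl21gpca_config(k = 3, lambda = lam, alpha = 10,
                                              max_iter = 300), g)
    sum(sqrt(rowSums(fit$U^2)) > 1e-3)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], 0)   # the grid is not vacuous at the low end
})

test_that("larger alpha never increases the embedding roughness Tr(V'LV)", {
  fx <- block_fixture()
  g <- sample_graph(fx$X)
  rough <- vapply(c(0.1, 1, 10, 100), function(al) {
    fit <- pl21gpca_fit(fx$X, pl21gpca_config(k = 3, lambda = 1, alpha = al,
                                              max_iter = 300), g)
    sum(fit$V * (g$L %*% fit$V))
  }, numeric(1))
  expect_true(all(diff(rough) <= 1e-10))
})

test_that("config validation rejects out-of-range hyperparameters", {
  expect_error(pl21gpca_config(k = 2, p = 1.2), "strictly in")
  expect_error(pl21gpca_config(k = 2, rho = 0.9), "rho")
  expect_error(pl21gpca_config(k = 2, lambda = -1), "lambda")
  expect_error(pl21gpca_fit(matrix(NA_real_, 2, 2), pl21gpca_config(k = 1)),
               "non-finite")
  expect_error(pl21gpca_fit(matrix(rnorm(8), 2, 4),
                            pl21gpca_config(k = 4, alpha = 0)), "smaller")
})
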