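# Closed-form ridge posterior for centred X with fixed variances: the
# oracle for the pi = 0 sampler.
ridge_posterior <- function(y, X, sigma_b2, sigma_e2) {
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  A <- crossprod(Xc)
  diag(A) <- diag(A) + sigma_e2 / sigma_b2
  list(beta = drop(solve(A, crossprod(Xc, yc))),
       sd = sqrt(diag(solve(A)) * sigma_e2))
}

test_that("pi = 0 with fixed variances reproduces the ridge solution", {
  set.seed(1)
  n <- 20; p <- 5
  X <- matrix(rbinom(n * p, 2, 0.4), n)
  beta_true <- rnorm(p, 0, 0.5)
  y <- drop(X %*% beta_true) + rnorm(n)
  sb2 <- 0.25; se2 <- 1
  oracle <- ridge_posterior(y, X, sb2, se2)
  cfg <- wgr_config("gblup", chain_length = 22000, burn_in = 2000,
                    fix_var = TRUE, sigma_beta2 = sb2, sigma_e2 = se2)
  set.seed(2)
  fit <- fit_wgr(y, X, cfg)
  # 3 x Monte-Carlo SE of the posterior mean, with a conservative
  # effective-sample-size deflation for the Gibbs autocorrelation
  mcse <- 3 * oracle$sd / sqrt(20000 / 20)
  expect_true(all(abs(fit$beta - oracle$beta) < mcse))
  expect_true(all(fit$mf == 1))
})

test_that("monomorphic columns carry no signal and prior-driven inclusion", {
  set.seed(3)
  n <- 60
  X <- cbind(rbinom(n, 2, 0.4), rep(1, n), rbinom(n, 2, 0.3))
  y <- rnorm(n) + 0.5 * X[, 1]
  fit <- fit_wgr(y, X, wgr_config("bayesC", pi = 0.9,
                                  chain_length = 6000, burn_in = 1000))
  expect_lt(abs(fit$beta[2]), 0.2)
  expect_equal(fit$mf[2], 0.1, tolerance = 0.03)
})

test_that("a null trait under pi = 0.98 includes markers at the prior rate", {
  set.seed(4)
  n <- 150; p <- 300
  X <- matrix(rbinom(n * p, 2, 0.3), n)
  y <- rnorm(n)
  fit <- fit_wgr(y, X, wgr_config("bayesC", chain_length = 4000,
                                  burn_in = 1000))
  se <- sd(fit$mf) / sqrt(p)
  expect_lt(abs(mean(fit$mf) - 0.02), 3 * se + 0.003)
  expect_true(all(fit$mf >= 0 & fit$mf <= 1))
})

test_that("genomic heritability tracks the signal content", {
  set.seed(5)
  n <- 500; p <- 100
  X <- matrix(rbinom(n * p, 2, 0.3), n)
  null_fit <- fit_wgr(rnorm(n), X, wgr_config("bayesC", chain_length = 3000,
                                              burn_in = 500))
  expect_lt(genomic_h2(null_fit), 0.1)
  beta <- rnorm(p)
  y_perfect <- drop(X %*% beta) + rnorm(n, 0, 1e-3 * sd(X %*% beta))
  fit2 <- fit_wgr(y_perfect, X, wgr_config("gblup", chain_length = 3000,
                                           burn_in = 500))
  expect_gt(genomic_h2(fit2), 0.95)
  keep <- seq(501, 3000)
  expect_true(all(fit2$h2m_chain[keep] >= 0 & fit2$h2m_chain[keep] <= 1))
  expect_equal(genomic_h2(fit2), fit2$h2m)
})

test_that("rrblup_solve shrinks to the mean and matches hand algebra", {
  set.seed(6)
  X <- matrix(rbinom(40, 2, 0.5), 20)
  y <- rnorm(20, 3)
  sol <- rrblup_solve(y, X, 1e12)
  expect_equal(sol$beta, rep(0, 2), tolerance = 1e-6)
  expect_equal(sol$intercept, mean(y), tolerance = 1e-6)
  # orthonormal centred columns, lambda = 1: beta_j = x_j'y / 2
  Xo <- cbind(c(-1, 1, -1, 1) / 2, c(-1, -1, 1, 1) / 2)
  yo <- c(0.3, -1.2, 2.5, 0.7)
  sol2 <- rrblup_solve(yo, Xo, 1)
  yc <- yo - mean(yo)
  expect_equal(sol2$beta, drop(crossprod(Xo, yc)) / 2, tolerance = 1e-12)
  expect_error(rrblup_solve(yo, cbind(Xo, Xo), 0), "singular")
})

test_that("marker ridge predictions equal G-matrix animal-model BLUP", {
  set.seed(7)
  n_r <- 30; n_v <- 10; p <- 50
  X <- matrix(rbinom((n_r + n_v) * p, 2, runif(p, 0.1, 0.9)), n_r + n_v,
              byrow = TRUE)
  q <- colMeans(X[seq_len(n_r), , drop = FALSE]) / 2
  poly <- q > 0 & q < 1
  X <- X[, poly]; q <- q[poly]; p <- sum(poly)
  Z <- sweep(sweep(X, 2, 2 * q), 2, sqrt(2 * q * (1 - q)), "/")
  Z_R <- Z[seq_len(n_r), ]; Z_V <- Z[n_r + seq_len(n_v), ]
  y <- rnorm(n_r, 5)
  lambda <- 2.5
  sol <- rrblup_solve(y, Z_R, lambda)
  pred_ridge <- sol$intercept + drop(Z_V %*% sol$beta)
  G <- tcrossprod(Z) / p
  K <- G[seq_len(n_r), seq_len(n_r)]
  diag(K) <- diag(K) + lambda / p
  u_hat <- drop(G[n_r + seq_len(n_v), seq_len(n_r)] %*%
                  solve(K, y - mean(y)))
  expect_equal(pred_ridge, mean(y) + u_hat, tolerance = 1e-8)
})

test_that("pi = 0 sampler agrees with ridge at the posterior variance ratio", {
  set.seed(8)
  n <- 120; p <- 40
  X <- matrix(rbinom(n * p, 2, 0.4), n)
  Q <- X[, 1:8]
  tr <- simulate_trait(Q, 0.6)
  fit <- fit_wgr(tr$y, X, wgr_config("gblup", chain_length = 6000,
                                     burn_in = 1000))
  keep <- seq(1001, 6000)
  lambda_hat <- mean(fit$sigma_e2_chain[keep]) / mean(fit$sigma_b2_chain[keep])
  sol <- rrblup_solve(tr$y, X, lambda_hat)
  expect_gt(cor(fit$beta, sol$beta), 0.99)
})

test_that("chains are reproducible and inputs validated", {
  set.seed(9)
  X <- matrix(rbinom(200, 2, 0.3), 50)
  y <- rnorm(50)
  cfg <- wgr_config("bayesB", chain_length = 500, burn_in = 100)
  set.seed(10); a <- fit_wgr(y, X, cfg)
  set.seed(10); b <- fit_wgr(y, X, cfg)
  expect_identical(a$beta, b$beta)
  expect_identical(a$mf, b$mf)
  expect_error(fit_wgr(rep(1, 50), X, cfg), "constant")
  expect_error(fit_wgr(c(y[-1], NA), X, cfg), "non-finite")
  expect_error(wgr_config("gblup", pi = 0.5), "pi = 0")
})
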