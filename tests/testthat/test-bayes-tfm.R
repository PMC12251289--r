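test_that("Laplacian regularizer annihilates constants and matches stencil eigenvalues", {
  reg <- build_regularizer(8, 8, "laplacian")
  L <- reg$L
  expect_equal(max(abs(L %*% rep(1, 64))), 0)
  expect_equal(max(abs(rowSums(L))), 0)

  # linear-in-x field: interior rows of Lt vanish (mirror boundaries fold
  # the gradient at the edges)
  lin <- as.vector(matrix(rep(1:8, each = 8), 8))
  lt <- matrix(L %*% lin, 8)
  expect_equal(max(abs(lt[, 2:7])), 0)

  # Neumann cosine mode is an eigenvector: f_i = cos(pi m (i + 1/2) / N)
  N <- 8; m <- 3
  f1 <- cos(pi * m * ((0:(N - 1)) + 0.5) / N)
  fx <- as.vector(outer(f1, rep(1, N)))        # varies along rows only
  ev <- 2 * (cos(pi * m / N) - 1)
  expect_equal(as.numeric(L %*% fx), ev * fx, tolerance = 1e-10)
  # prior energy |Lt|^2 then follows the eigenvalue formula
  expect_equal(sum((L %*% fx)^2), ev^2 * sum(fx^2), tolerance = 1e-10)

  # P is block-diagonal over components and PSD
  expect_equal(reg$P[1:64, 65:128], matrix(0, 64, 64))
  ei <- eigen(reg$P, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ei), -1e-10)
})

test_that("likelihood log-density matches the closed form and an MVN oracle", {
  toy <- make_toy_inversion(n = 5)
  obs <- toy$obs0
  n2 <- obs$n
  # exact fit with Sigma = 0: -Nw log(2pi) + Nw log beta
  t_exact <- solve(obs$M, obs$uh)
  beta <- 37
  expect_equal(likelihood_logpdf(t_exact, beta, obs),
               -obs$nw * log(2 * pi) + obs$nw * log(beta), tolerance = 1e-6)
  # generic MVN oracle on a random instance with heteroskedastic Sigma
  set.seed(31)
  sig2 <- runif(n2, 0.001, 0.01)
  obs2 <- observation_model(obs$uh, sig2, toy$op)
  t0 <- rnorm(n2, sd = 50)
  lam <- 1 / beta + sig2
  r <- obs2$uh - obs2$M %*% t0
  oracle <- sum(stats::dnorm(r, 0, sqrt(lam), log = TRUE))
  expect_equal(likelihood_logpdf(t0, beta, obs2), oracle, tolerance = 1e-8)
  # sharper beta increases the density at zero residual
  expect_gt(likelihood_logpdf(t_exact, 100, obs),
            likelihood_logpdf(t_exact, 10, obs))
})

test_that("alpha conditional is the exact Gamma with |Lt|^2 rate", {
  toy <- make_toy_inversion(n = 5)
  t0 <- toy$t_true
  energy <- sum(t0 * (toy$reg$P %*% t0))
  set.seed(41)
  draws <- replicate(1e5, sample_alpha_conditional(t0, toy$reg, toy$obs))
  shape <- toy$obs$nw + 1
  rate <- energy / 2 + 1e-5
  expect_equal(mean(draws), shape / rate, tolerance = 0.02)
  expect_equal(var(draws), shape / rate^2, tolerance = 0.05)
  # doubling |Lt|^2 halves the conditional mean (phi ~ 0)
  d2 <- replicate(1e4, sample_alpha_conditional(sqrt(2) * t0, toy$reg, toy$obs))
  expect_equal(mean(d2) / mean(draws[1:1e4]), 0.5, tolerance = 0.05)
  # Lt = 0 case: Gamma(Nw + 1, phi)
  tc <- rep(1, toy$obs$n)
  set.seed(42)
  dc <- replicate(2e4, sample_alpha_conditional(tc, toy$reg, toy$obs))
  expect_equal(mean(dc), (toy$obs$nw + 1) / 1e-5, tolerance = 0.05)
})

test_that("numerical beta sampler matches the analytic Gamma when Sigma = 0", {
  toy <- make_toy_inversion(n = 5)
  obs <- toy$obs0
  t0 <- toy$t_true * 0.9
  r2 <- as.numeric(obs$uh - obs$M %*% t0)^2
  shape <- obs$nw + 1
  rate <- sum(r2) / 2 + 1e-5
  set.seed(51)
  draws <- replicate(4000, sample_beta_conditional(t0, obs, beta_init = shape / rate))
  expect_equal(mean(draws), shape / rate, tolerance = 0.02)
  expect_equal(sd(draws), sqrt(shape) / rate, tolerance = 0.05)
  # reproducible under a fixed seed
  set.seed(5); b1 <- sample_beta_conditional(t0, obs)
  set.seed(5); b2 <- sample_beta_conditional(t0, obs)
  expect_identical(b1, b2)
  # huge Sigma everywhere: likelihood flat, draws follow the hyperprior
  obs_flat <- observation_model(obs$uh, rep(1e6, obs$n), toy$op)
  set.seed(52)
  dflat <- replicate(2000, sample_beta_conditional(t0, obs_flat, beta_init = 1e5))
  expect_equal(mean(dflat), 1 / 1e-5, tolerance = 0.1)   # Gamma(1, 1e-5) mean
})

test_that("t conditional has the exact Gaussian moments on a toy system", {
  toy <- make_toy_inversion(n = 3, noise_um = 0.05)
  obs <- toy$obs
  alpha <- 1e-3; beta <- 500
  S <- spost_matrix(alpha, beta, obs, toy$reg)
  w <- 1 / (1 / beta + obs$sigma2)
  mean_exact <- as.numeric(S %*% crossprod(obs$M, w * obs$uh))
  set.seed(61)
  draws <- t(replicate(2e4, sample_t_conditional(alpha, beta, obs, toy$reg)$draw))
  expect_equal(colMeans(draws), mean_exact, tolerance = 4 * max(sqrt(diag(S) / 2e4)) /
                 max(abs(mean_exact)))
  expect_equal(apply(draws, 2, var), diag(S), tolerance = 0.05)
  expect_equal(sample_t_conditional(alpha, beta, obs, toy$reg)$mean, mean_exact,
               tolerance = 1e-10)
  # alpha -> infinity with a full-rank (identity) prior: draws shrink to the
  # zero field (the Laplacian prior leaves its constant null space to the data)
  reg_id <- build_regularizer(3, 3, "identity")
  big <- sample_t_conditional(1e12, beta, obs, reg_id)
  expect_lt(max(abs(big$draw)), 1e-2)
})

test_that("clamped hyperparameters reproduce the Tikhonov solution exactly", {
  toy <- make_toy_inversion(n = 9)
  alpha <- 0.37; beta <- 1234
  pm <- posterior_mean_clamped(alpha, beta, toy$obs0, toy$reg)
  tk <- solve_tikhonov(toy$obs0, tikhonov_config(lambda = alpha / beta,
                                                 regularizer_obj = toy$reg))
  expect_lt(sqrt(sum((pm - tk)^2) / sum(tk^2)), 1e-8)
  # and the clamped Gibbs chain concentrates on the same mean
  post <- run_gibbs(toy$obs0, toy$reg,
                    config = gibbs_config(n_draws = 200, burn_in = 40,
                                          alpha0 = alpha, beta0 = beta,
                                          fix_alpha = TRUE, fix_beta = TRUE),
                    seed = 3)
  expect_equal(post$t_hat, pm, tolerance = 0.1)
  expect_equal(unique(post$alpha_chain), alpha)
  expect_equal(unique(post$beta_chain), beta)
})

test_that("posterior variance respects the pure-shear regularization bounds", {
  # thin substrate so kh << 1 for every mode: M ~ (h/mu) I, and with L = U,
  # Sigma = 0 the posterior variance lies between the weak-regularization
  # bound beta^-1 mu^2/h^2 and the strong-regularization bound alpha^-1
  sub <- substrate_model(5000, 0.45, 0.05)
  kern <- build_spectral_kernel(sub, 5, 500)
  op <- assemble_dense_operator(kern)
  n2 <- nrow(op$M)
  obs <- observation_model(rnorm(n2, sd = 1e-4), rep(0, n2), op)
  reg <- build_regularizer(5, 5, "identity")
  for (lam_case in list(c(1e-12, 1e6), c(1e-2, 1e6), c(10, 1e6))) {
    alpha <- lam_case[1]; beta <- lam_case[2]
    S <- spost_matrix(alpha, beta, obs, reg)
    # composite form 1/(beta h^2/mu^2 + alpha), which interpolates between
    # the weak-regularization bound beta^-1 mu^2/h^2 and the strong bound 1/alpha
    expect_equal(diag(S),
                 rep(1 / (beta * (sub$h / sub$mu)^2 + alpha), n2),
                 tolerance = 0.01)
    expect_lte(max(diag(S)), 1.01 * min((1 / beta) * (sub$mu / sub$h)^2,
                                        1 / alpha))
  }
  # extreme regimes approach their respective bounds
  S_weak <- spost_matrix(1e-12, 1e6, obs, reg)
  expect_equal(diag(S_weak), rep(1e-6 * (sub$mu / sub$h)^2, n2),
               tolerance = 0.01)
  S_strong <- spost_matrix(1e4, 1e6, obs, reg)
  expect_equal(diag(S_strong), rep(1e-4, n2), tolerance = 0.01)
})

test_that("Gibbs chains are reproducible and recover a smooth field", {
  toy <- make_toy_inversion(n = 9)
  cfg <- gibbs_config(n_draws = 120, burn_in = 30)
  p1 <- run_gibbs(toy$obs, toy$reg, config = cfg, seed = 17)
  p2 <- run_gibbs(toy$obs, toy$reg, config = cfg, seed = 17)
  expect_identical(p1$t_hat, p2$t_hat)
  expect_identical(p1$beta_chain, p2$beta_chain)
  # posterior mean beats the unregularized inverse on noisy data
  err_post <- sqrt(mean((p1$t_hat - toy$t_true)^2))
  n <- toy$n
  uxm <- matrix(toy$obs$uh[1:(n * n)], n)
  uym <- matrix(toy$obs$uh[n * n + 1:(n * n)], n)
  raw <- apply_inverse_unregularized(uxm, uym, toy$kern)
  err_raw <- sqrt(mean((c(as.vector(raw$tx), as.vector(raw$ty)) - toy$t_true)^2))
  expect_lt(err_post, err_raw)
  expect_true(all(is.finite(p1$sigma_t)) && all(p1$sigma_t >= 0))
  expect_gt(effective_sample_size(p1$beta_chain), 5)
})

test_that("heteroskedastic prior reduces to the standard one for uniform noise", {
  reg <- build_regularizer(6, 6, "laplacian")
  s2 <- rep(0.25, 72)
  het <- heteroskedastic_prior(reg, s2)
  expect_equal(het$P, reg$P / 0.25, tolerance = 1e-12)
  # non-uniform variance: high-noise points get weaker effective precision
  s2b <- rep(c(0.01, 1), each = 36)
  hb <- heteroskedastic_prior(reg, s2b)
  expect_gt(mean(diag(hb$P)[1:36]), mean(diag(hb$P)[37:72]))
  expect_error(heteroskedastic_prior(reg, rep(0, 72)), "positive")
})
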