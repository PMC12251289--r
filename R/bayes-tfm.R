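# Hierarchical Bayesian traction inversion.  Displacement observations uh
# (stacked ux then uy, micrometres) are modelled as uh = M t + e_beta + e_m
# with a global model-error precision beta (hyperparameter), the PIV
# measurement variances Sigma_PIV on the diagonal, and a smoothness prior
# on t with precision alpha L'L built from the discrete Laplacian.  Both
# hyperparameters carry Gamma hyperpriors and the posterior is explored with
# a hybrid Gibbs sampler: exact Gaussian draws for t, an exact Gamma draw
# for alpha, and numerical inverse-transform sampling for beta.

#' Discrete Laplacian regularizer on the window grid
#'
#' 5-point stencil with mirror (Neumann) boundaries, applied independently
#' to each traction component.  Row sums are zero, so constant fields carry
#' no prior energy, and the prior quadratic form is \code{|Lt|^2 = t'L'Lt}.
#'
#' @param ny,nx grid dimensions (windows per side).
#' @param variant \code{"laplacian"} or \code{"identity"}.
#' @return object of class \code{regularizer}: the per-component operator
#'   \code{L} (\code{Nw x Nw}), its normal matrix \code{P = L'L} expanded to
#'   both components (\code{2Nw x 2Nw}), grid dims and variant tag.
#' @export
build_regularizer <- function(ny, nx, variant = c("laplacian", "identity")) {
  variant <- match.arg(variant)
  nw <- ny * nx
  if (variant == "identity") {
    L <- diag(nw)
  } else {
    L <- matrix(0, nw, nw)
    id <- function(i, j) (j - 1L) * ny + i
    for (j in seq_len(nx)) for (i in seq_len(ny)) {
      r <- id(i, j)
      nbr <- c(if (i > 1) id(i - 1, j), if (i < ny) id(i + 1, j),
               if (j > 1) id(i, j - 1), if (j < nx) id(i, j + 1))
      L[r, nbr] <- 1
      L[r, r] <- -length(nbr)       # mirror boundary: missing neighbours fold
    }
  }
  P1 <- crossprod(L)
  P <- matrix(0, 2 * nw, 2 * nw)
  P[1:nw, 1:nw] <- P1
  P[nw + 1:nw, nw + 1:nw] <- P1
  structure(list(L = L, P = P, ny = ny, nx = nx, variant = variant),
            class = "regularizer")
}

#' Heteroskedastic prior variant
#'
#' Scales the prior precision pointwise by the inverse PIV variance,
#' symmetrised as \code{Sigma^{-1/2} P Sigma^{-1/2}}, so that high-noise
#' regions receive weaker effective regularization per unit alpha.
#'
#' @param reg a \code{\link{build_regularizer}} result.
#' @param sigma2 PIV variance vector (length \code{2Nw}), strictly positive.
#' @return a \code{regularizer} with the scaled precision.
#' @export
heteroskedastic_prior <- function(reg, sigma2) {
  stopifnot(inherits(reg, "regularizer"), length(sigma2) == nrow(reg$P))
  if (any(sigma2 <= 0)) stop("heteroskedastic prior needs strictly positive Sigma_PIV")
  w <- 1 / sqrt(sigma2)
  P <- t(reg$P * w) * w               # W P W with W diagonal
  out <- reg
  out$P <- (P + t(P)) / 2
  out$variant <- "heteroskedastic"
  out
}

#' Observation model for the Bayesian inversion
#'
#' @param uh stacked displacement vector (ux then uy), micrometres.
#' @param sigma2 stacked PIV variance vector, micrometres^2 (>= 0).
#' @param op a \code{\link{assemble_dense_operator}} result.
#' @return object of class \code{tfm_observation}.
#' @export
observation_model <- function(uh, sigma2, op) {
  stopifnot(inherits(op, "dense_operator"))
  n <- nrow(op$M)
  stopifnot(length(uh) == n, length(sigma2) == n, all(sigma2 >= 0))
  structure(list(uh = as.numeric(uh), sigma2 = as.numeric(sigma2),
                 M = op$M, n = n, nw = n / 2L, op = op),
            class = "tfm_observation")
}

#' Gaussian log-likelihood of the displacement observations
#'
#' \code{log N(uh; Mt, Lambda)} with \code{Lambda = beta^{-1} I + Sigma_PIV}
#' (diagonal).
#'
#' @param t stacked traction vector (Pa).
#' @param beta global model-error precision (> 0).
#' @param obs a \code{\link{observation_model}}.
#' @return scalar log-density.
#' @export
likelihood_logpdf <- function(t, beta, obs) {
  stopifnot(beta > 0)
  lam <- 1 / beta + obs$sigma2
  if (any(lam <= 0)) stop("non-positive Lambda entry")
  r <- obs$uh - obs$M %*% t
  -obs$nw * log(2 * pi) - 0.5 * sum(log(lam)) - 0.5 * sum(r^2 / lam)
}

#' Conditional draw of the traction field
#'
#' Exact Gaussian draw from \code{N(S M' Lambda^{-1} uh, S)} with
#' \code{S = (M' Lambda^{-1} M + alpha P)^{-1}}, via Cholesky of the
#' precision.
#'
#' @param alpha,beta hyperparameter values.
#' @param obs a \code{\link{observation_model}}.
#' @param reg a \code{\link{build_regularizer}} result.
#' @return list with \code{draw} and the conditional \code{mean}.
#' @export
sample_t_conditional <- function(alpha, beta, obs, reg) {
  w <- 1 / (1 / beta + obs$sigma2)
  A <- crossprod(obs$M * sqrt(w)) + alpha * reg$P
  R <- tryCatch(chol(A), error = function(e)
    stop("posterior precision not positive definite"))
  b <- crossprod(obs$M, w * obs$uh)
  mean <- backsolve(R, backsolve(R, b, transpose = TRUE))
  draw <- mean + backsolve(R, rnorm(obs$n))
  list(draw = as.numeric(draw), mean = as.numeric(mean))
}

#' Conditional draw of the smoothness hyperparameter alpha
#'
#' \code{Gamma(Nw + theta_a, 0.5 |Lt|^2 + phi_a)} (shape/rate).
#'
#' @param t stacked traction vector.
#' @param reg regularizer.
#' @param obs observation model (for Nw).
#' @param theta_a,phi_a Gamma hyperprior shape and rate.
#' @return alpha draw.
#' @export
sample_alpha_conditional <- function(t, reg, obs, theta_a = 1, phi_a = 1e-5) {
  rate <- 0.5 * sum(t * (reg$P %*% t)) + phi_a
  rgamma(1, shape = obs$nw + theta_a, rate = rate)
}

#' Conditional draw of the model-error precision beta
#'
#' The conditional density has no closed form when Sigma_PIV varies, so it
#' is evaluated on a log-spaced grid around its maximum (coarse bracket,
#' then \code{ngrid} points spanning \code{+- 4} decades), normalised by the
#' trapezoid rule, and sampled by inverting the numerical CDF.
#'
#' @param t stacked traction vector.
#' @param obs observation model.
#' @param theta_b,phi_b Gamma hyperprior shape and rate.
#' @param beta_init centre of the coarse bracket.
#' @param ngrid fine grid size.
#' @return beta draw.
#' @export
sample_beta_conditional <- function(t, obs, theta_b = 1, phi_b = 1e-5,
                                    beta_init = 1, ngrid = 400) {
  r2 <- as.numeric(obs$uh - obs$M %*% t)^2
  beta_grid_sample(r2, obs$sigma2, theta_b, phi_b, beta_init, ngrid,
                   runif(1))
}

# log p(beta | t, uh) up to a constant
beta_logpost <- function(beta, r2, sigma2, theta_b, phi_b) {
  lam <- 1 / beta + sigma2
  -0.5 * sum(log(lam)) - 0.5 * sum(r2 / lam) +
    (theta_b - 1) * log(beta) - phi_b * beta
}

# shared grid construction + inverse-CDF draw given a uniform variate
beta_grid_sample <- function(r2, sigma2, theta_b, phi_b, beta_init, ngrid, u) {
  lp <- function(lb) vapply(lb, function(x)
    beta_logpost(exp(x), r2, sigma2, theta_b, phi_b), numeric(1))
  centre <- log(beta_init)
  for (attempt in 1:3) {
    coarse <- seq(centre - 8 * log(10), centre + 8 * log(10), length.out = 81)
    v <- lp(coarse)
    centre <- coarse[which.max(v)]
    if (which.max(v) != 1 && which.max(v) != length(v)) break
  }
  grid_l <- seq(centre - 4 * log(10), centre + 4 * log(10), length.out = ngrid)
  lv <- lp(grid_l)
  dens <- exp(lv - max(lv))
  if (dens[1] > 1e-3 || dens[ngrid] > 1e-3) {   # widen once if mass at edges
    grid_l <- seq(centre - 6 * log(10), centre + 6 * log(10), length.out = ngrid)
    lv <- lp(grid_l)
    dens <- exp(lv - max(lv))
  }
  beta <- exp(grid_l)
  dbeta <- diff(beta)
  seg <- (dens[-1] + dens[-ngrid]) / 2 * dbeta
  cdf <- c(0, cumsum(seg))
  tot <- cdf[ngrid]
  if (!is.finite(tot) || tot <= 0) stop("degenerate beta conditional")
  keep <- c(TRUE, diff(cdf) > 0)       # flat zero-density stretches
  stats::approx(cdf[keep] / tot, beta[keep], xout = u, rule = 2)$y
}

#' Exact posterior mean with clamped hyperparameters
#'
#' Solves \code{(M' Lambda^{-1} M + alpha P) t = M' Lambda^{-1} uh}.  With
#' \code{Sigma_PIV = 0} this equals the Tikhonov solution with
#' \code{lambda = alpha / beta}.
#'
#' @inheritParams sample_t_conditional
#' @return stacked traction vector (Pa).
#' @export
posterior_mean_clamped <- function(alpha, beta, obs, reg) {
  w <- 1 / (1 / beta + obs$sigma2)
  A <- crossprod(obs$M * sqrt(w)) + alpha * reg$P
  as.numeric(solve(A, crossprod(obs$M, w * obs$uh)))
}

#' Posterior covariance with clamped hyperparameters
#'
#' \code{S = (M' Lambda^{-1} M + alpha P)^{-1}}; used for the uncertainty
#' saturation analysis and tests of the variance bounds.
#'
#' @inheritParams sample_t_conditional
#' @return covariance matrix.
#' @export
spost_matrix <- function(alpha, beta, obs, reg) {
  w <- 1 / (1 / beta + obs$sigma2)
  solve(crossprod(obs$M * sqrt(w)) + alpha * reg$P)
}

#' Gibbs sampler configuration
#'
#' @param n_draws total chain length Nd.
#' @param burn_in discarded initial draws (default 50).
#' @param alpha0,beta0 optional initial hyperparameter values; when
#'   \code{NULL} they are set from the data (\code{beta0} from the median
#'   PIV variance or the displacement variance, \code{alpha0} so that
#'   \code{alpha0/beta0} sits at the Tikhonov L-curve corner).
#' @param beta_grid_n fine grid size for the beta conditional.
#' @param fix_alpha,fix_beta clamp a hyperparameter at its initial value
#'   (used to recover the fixed-regularization limit).
#' @param keep_draws retain the post-burn-in traction draws.
#' @return object of class \code{gibbs_config}.
#' @export
gibbs_config <- function(n_draws = 300, burn_in = 50, alpha0 = NULL,
                         beta0 = NULL, beta_grid_n = 400,
                         fix_alpha = FALSE, fix_beta = FALSE,
                         keep_draws = TRUE) {
  stopifnot(n_draws > burn_in, burn_in >= 0)
  structure(list(n_draws = as.integer(n_draws), burn_in = as.integer(burn_in),
                 alpha0 = alpha0, beta0 = beta0,
                 beta_grid_n = as.integer(beta_grid_n),
                 fix_alpha = fix_alpha, fix_beta = fix_beta,
                 keep_draws = keep_draws),
            class = "gibbs_config")
}

#' Gamma hyperprior parameters
#'
#' Non-informative defaults: shape 1, rate 1e-5 for both hyperparameters.
#'
#' @param theta_alpha,phi_alpha,theta_beta,phi_beta Gamma shape/rate pairs.
#' @return list of hyperprior parameters.
#' @export
hyper_priors <- function(theta_alpha = 1, phi_alpha = 1e-5,
                         theta_beta = 1, phi_beta = 1e-5) {
  stopifnot(theta_alpha > 0, phi_alpha > 0, theta_beta > 0, phi_beta > 0)
  list(theta_alpha = theta_alpha, phi_alpha = phi_alpha,
       theta_beta = theta_beta, phi_beta = phi_beta)
}

#' Run the hybrid Gibbs sampler
#'
#' Cycles t (exact Gaussian) -> alpha (exact Gamma) -> beta (numerical
#' inverse-transform) for \code{n_draws} iterations and summarises the
#' post-burn-in draws: posterior mean, componentwise and total standard
#' deviation, and the circular standard deviation of the draw directions at
#' each grid point.
#'
#' @param obs a \code{\link{observation_model}}.
#' @param reg a \code{\link{build_regularizer}} result.
#' @param hyper a \code{\link{hyper_priors}} list.
#' @param config a \code{\link{gibbs_config}}.
#' @param seed optional RNG seed.
#' @return object of class \code{traction_posterior}: vectors \code{t_hat},
#'   \code{sigma_tx}, \code{sigma_ty}, \code{sigma_t}, \code{angular_sd}
#'   (all length \code{Nw} per-point quantities except \code{t_hat}, length
#'   \code{2Nw}), hyperparameter chains, and optionally the draws.
#' @export
run_gibbs <- function(obs, reg, hyper = hyper_priors(),
                      config = gibbs_config(), seed = NULL) {
  stopifnot(inherits(obs, "tfm_observation"), inherits(reg, "regularizer"))
  if (!is.null(seed)) set.seed(seed)
  beta0 <- config$beta0
  if (is.null(beta0)) {
    med <- stats::median(obs$sigma2[obs$sigma2 > 0])
    beta0 <- if (is.finite(med) && med > 0) 1 / med else 1 / stats::var(obs$uh)
  }
  alpha0 <- config$alpha0
  if (is.null(alpha0)) {
    lc <- l_curve(obs, tikhonov_config(regularizer_obj = reg))
    alpha0 <- lc$lambda_corner * beta0
  }
  res <- gibbs_chain(obs$M, reg$P, obs$uh, obs$sigma2,
                     hyper$theta_alpha, hyper$phi_alpha,
                     hyper$theta_beta, hyper$phi_beta,
                     alpha0, beta0,
                     config$n_draws, config$burn_in, config$beta_grid_n,
                     config$fix_alpha, config$fix_beta)
  draws <- res$draws                       # (Nd - itb) x 2Nw
  nw <- obs$nw
  t_hat <- colMeans(draws)
  sd_all <- apply(draws, 2, stats::sd)
  sigma_tx <- sd_all[1:nw]
  sigma_ty <- sd_all[nw + 1:nw]
  ang <- vapply(seq_len(nw), function(i)
    circular_sd(draws[, i], draws[, nw + i]), numeric(1))
  out <- list(t_hat = t_hat,
              sigma_tx = sigma_tx, sigma_ty = sigma_ty,
              sigma_t = sqrt(sigma_tx^2 + sigma_ty^2),
              angular_sd = ang,
              alpha_chain = as.numeric(res$alpha),
              beta_chain = as.numeric(res$beta),
              alpha0 = alpha0, beta0 = beta0,
              n_draws = config$n_draws, burn_in = config$burn_in,
              nw = nw)
  if (config$keep_draws) out$draws <- draws
  class(out) <- "traction_posterior"
  out
}

#' Effective sample size of a chain (autocorrelation-based)
#'
#' Simple initial-positive-sequence estimator used for convergence
#' diagnostics of the hyperparameter chains.
#'
#' @param x numeric chain.
#' @return effective sample size estimate.
#' @export
effective_sample_size <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(n)
  ac <- stats::acf(x, plot = FALSE, lag.max = min(n - 1, 200))$acf[-1]
  pos <- which(ac < 0)
  if (length(pos)) ac <- ac[seq_len(pos[1] - 1)]
  n / (1 + 2 * sum(ac))
}
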