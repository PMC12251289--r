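# End-to-end protocol on the synthetic heteroskedastic benchmark:
# simulate -> PIV-UQ -> Bayesian inversion, with the classical Tikhonov
# solutions (lambda at the benchmark's own L-curve corner and at the
# corners of homoskedastic low/high-noise calibration runs) evaluated on
# the same observation for comparison.

#' Run PIV-UQ on a benchmark and assemble the Bayesian observation
#'
#' @param bench a \code{\link{build_benchmark}} result.
#' @param seed RNG seed for the bootstrap.
#' @return list with the PIV-UQ result (\code{pivuq}), the
#'   \code{\link{observation_model}} (\code{obs}, micrometre units), the
#'   dense operator and the PIV grid dims.
#' @export
benchmark_observation <- function(bench, seed = 1) {
  cfg <- bench$config
  pc <- piv_config(cfg$WL, cfg$WS)
  res <- run_piv_uq(bench$pair, pc, piv_uq_config(n_B = cfg$n_B), seed = seed)
  f <- res$field
  spacing_um <- cfg$WS * cfg$pixel_size
  if (f$nx != f$ny) stop("benchmark expects a square PIV grid")
  kern <- build_spectral_kernel(bench$substrate, f$nx, spacing_um)
  op <- assemble_dense_operator(kern)
  ps <- cfg$pixel_size
  uh <- c(as.vector(f$ux), as.vector(f$uy)) * ps
  sigma2 <- c(as.vector(res$uncertainty$sigma_ux),
              as.vector(res$uncertainty$sigma_uy))^2 * ps^2
  list(pivuq = res, obs = observation_model(uh, sigma2, op),
       kernel = kern, nx = f$nx, ny = f$ny, spacing_um = spacing_um)
}

#' Full benchmark protocol: TFM-UQ against Tikhonov baselines
#'
#' Builds the heteroskedastic benchmark, runs PIV-UQ and the hybrid Gibbs
#' inversion, determines the Tikhonov regularization weights lambda_D (the
#' benchmark's own L-curve corner), lambda_L and lambda_H (corners of
#' homoskedastic simulations at the high and low bead densities of the
#' gradient's edges), solves the three Laplacian-regularized baselines, and
#' evaluates all methods against the ground truth.
#'
#' @param seed master seed; stage seeds are fanned out from it.
#' @param config a \code{\link{benchmark_config}}.
#' @param gibbs a \code{\link{gibbs_config}}.
#' @param verbose print stage progress.
#' @return list of class \code{benchmark_report}: the benchmark, the
#'   observation bundle, the posterior, per-method traction fields and
#'   metrics, and the selected lambdas.
#' @export
run_benchmark_protocol <- function(seed = 1, config = benchmark_config(),
                                   gibbs = gibbs_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  seeds <- seed + c(build = 0L, piv = 1L, gibbs = 2L, lo = 3L, hi = 4L) * 1000L

  say("building benchmark images")
  bench <- build_benchmark(config, seed = seeds[["build"]])
  say("PIV-UQ on the heteroskedastic pair")
  ob <- benchmark_observation(bench, seed = seeds[["piv"]])
  obs <- ob$obs
  nx <- ob$nx; ny <- ob$ny; nw <- nx * ny
  reg <- build_regularizer(ny, nx, "laplacian")

  say("L-curve on the benchmark (lambda_D)")
  lc_D <- l_curve(obs, tikhonov_config(regularizer_obj = reg))
  lambda_D <- lc_D$lambda_corner

  homo_lambda <- function(density, stage_seed) {
    cfg2 <- config
    cfg2$density_left <- cfg2$density_right <- density
    b2 <- build_benchmark(cfg2, seed = stage_seed)
    o2 <- benchmark_observation(b2, seed = stage_seed + 1L)
    l_curve(o2$obs, tikhonov_config(regularizer_obj = reg))$lambda_corner
  }
  say("L-curve corners of the homoskedastic calibration runs")
  lambda_L <- homo_lambda(config$density_left, seeds[["lo"]])
  lambda_H <- homo_lambda(config$density_right, seeds[["hi"]])

  say("hybrid Gibbs inversion")
  post <- run_gibbs(obs, reg, config = gibbs, seed = seeds[["gibbs"]])

  to_mat <- function(v) matrix(v, ny, nx)
  fields <- list(
    tfm_uq = list(tx = to_mat(post$t_hat[1:nw]),
                  ty = to_mat(post$t_hat[nw + 1:nw]),
                  sigma_t = to_mat(post$sigma_t)),
    lambda_D = tik_field(obs, reg, lambda_D, ny, nx),
    lambda_L = tik_field(obs, reg, lambda_L, ny, nx),
    lambda_H = tik_field(obs, reg, lambda_H, ny, nx))

  truth <- bench$truth
  metrics <- lapply(fields, function(f)
    benchmark_metrics(f$tx, f$ty, truth$tx, truth$ty, sigma_t = f$sigma_t))
  metrics$true <- benchmark_metrics(truth$tx, truth$ty, truth$tx, truth$ty)

  structure(list(bench = bench, observation = ob, posterior = post,
                 fields = fields, metrics = metrics,
                 lambdas = c(D = lambda_D, L = lambda_L, H = lambda_H),
                 l_curve = lc_D, seed = seed),
            class = "benchmark_report")
}

tik_field <- function(obs, reg, lambda, ny, nx) {
  nw <- ny * nx
  t_hat <- solve_tikhonov(obs, tikhonov_config(lambda = lambda,
                                               regularizer_obj = reg))
  list(tx = matrix(t_hat[1:nw], ny, nx),
       ty = matrix(t_hat[nw + 1:nw], ny, nx),
       sigma_t = NULL)
}

#' Metrics table of a benchmark report
#'
#' One row per method with the summary metrics, in the layout used for
#' method comparison.
#'
#' @param report a \code{\link{run_benchmark_protocol}} result.
#' @return data.frame.
#' @export
metrics_table <- function(report) {
  m <- report$metrics
  rows <- c("true", "tfm_uq", "lambda_D", "lambda_L", "lambda_H")
  do.call(rbind, lapply(rows, function(r) {
    x <- m[[r]]
    data.frame(method = r, rms_error = x$rms_error,
               rms_sigma_t = x$rms_sigma_t,
               fg_mean = x$fg_mean, fg_max = x$fg_max,
               bg_mean = x$bg_mean, bg_max = x$bg_max,
               snr_t = x$snr_t)
  }))
}
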