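# Classical global Tikhonov regularization with L-curve corner selection,
# the baseline the adaptive Bayesian inversion is compared against.

#' Tikhonov configuration
#'
#' @param lambda regularization weight (> 0); may be \code{NULL} when only
#'   the L-curve is computed.
#' @param regularizer \code{"laplacian"} or \code{"identity"}.
#' @param lambda_grid log-spaced grid for the L-curve; \code{NULL} selects a
#'   default 40-point grid spanning 8 decades around a trace-based pivot.
#' @param regularizer_obj optionally a prebuilt \code{\link{build_regularizer}}
#'   (avoids rebuilding inside repeated calls).
#' @return object of class \code{tikhonov_config}.
#' @export
tikhonov_config <- function(lambda = NULL, regularizer = c("laplacian", "identity"),
                            lambda_grid = NULL, regularizer_obj = NULL) {
  regularizer <- match.arg(regularizer)
  if (!is.null(lambda)) stopifnot(lambda > 0)
  if (!is.null(lambda_grid)) stopifnot(!is.unsorted(lambda_grid), all(lambda_grid > 0))
  structure(list(lambda = lambda, regularizer = regularizer,
                 lambda_grid = lambda_grid, regularizer_obj = regularizer_obj),
            class = "tikhonov_config")
}

get_regularizer <- function(obs, config) {
  if (!is.null(config$regularizer_obj)) return(config$regularizer_obj)
  n <- obs$op$n
  build_regularizer(n, n, config$regularizer)
}

#' Solve the Tikhonov-regularized inversion
#'
#' \code{t = argmin |uh - Mt|^2 + lambda |Lt|^2} via the symmetric positive
#' definite normal equations.  The PIV variances are ignored (classical
#' homoskedastic baseline).
#'
#' @param obs a \code{\link{observation_model}}.
#' @param config a \code{\link{tikhonov_config}} with \code{lambda} set.
#' @return stacked traction vector (Pa).
#' @export
solve_tikhonov <- function(obs, config) {
  stopifnot(!is.null(config$lambda))
  reg <- get_regularizer(obs, config)
  A <- crossprod(obs$M) + config$lambda * reg$P
  as.numeric(solve(A, crossprod(obs$M, obs$uh)))
}

default_lambda_grid <- function(obs, reg, n_points = 40, decades = 8) {
  pivot <- sum(diag(crossprod(obs$M))) / sum(diag(reg$P))
  if (!is.finite(pivot) || pivot <= 0) pivot <- 1
  10^seq(log10(pivot) - decades / 2, log10(pivot) + decades / 2,
         length.out = n_points)
}

#' L-curve and maximum-curvature corner
#'
#' For each lambda on a log-spaced grid, records the data residual
#' \code{|uh - Mt|^2} and the prior seminorm \code{|Lt|^2}; the corner is
#' the point of maximum curvature of the log-log curve, estimated from a
#' smoothing-spline parameterization in log lambda.
#'
#' @param obs a \code{\link{observation_model}}.
#' @param config a \code{\link{tikhonov_config}}.
#' @return list with the \code{table} (lambda, residual, seminorm,
#'   curvature) and \code{lambda_corner}.
#' @export
l_curve <- function(obs, config = tikhonov_config()) {
  reg <- get_regularizer(obs, config)
  grid <- config$lambda_grid
  if (is.null(grid)) grid <- default_lambda_grid(obs, reg)
  if (length(grid) < 10) stop("L-curve needs at least 10 grid points")
  MtM <- crossprod(obs$M)
  Mtu <- crossprod(obs$M, obs$uh)
  res <- semi <- numeric(length(grid))
  for (i in seq_along(grid)) {
    t_i <- solve(MtM + grid[i] * reg$P, Mtu)
    res[i] <- sum((obs$uh - obs$M %*% t_i)^2)
    semi[i] <- sum(t_i * (reg$P %*% t_i))
  }
  lr <- log10(pmax(res, .Machine$double.xmin))
  ls <- log10(pmax(semi, .Machine$double.xmin))
  ll <- log10(grid)
  curv <- lcurve_curvature(ll, lr, ls)
  if (all(!is.finite(curv)) || max(curv, na.rm = TRUE) <= 0) {
    warning("degenerate L-curve: no corner found, returning grid midpoint")
    corner <- grid[ceiling(length(grid) / 2)]
  } else {
    # Curves can carry a second bend at the signal scale (larger lambda);
    # the L-curve corner proper is the transition out of the noise-dominated
    # branch, i.e. the lowest-lambda pronounced curvature maximum.
    n <- length(curv)
    is_max <- curv >= c(-Inf, curv[-n]) & curv >= c(curv[-1], -Inf)
    cand <- which(is_max & curv >= 0.3 * max(curv, na.rm = TRUE))
    corner <- grid[min(cand)]
  }
  list(table = data.frame(lambda = grid, residual = res, seminorm = semi,
                          curvature = curv),
       lambda_corner = corner)
}

# curvature of the (log residual, log seminorm) curve parameterized by
# log lambda, on spline-smoothed coordinates
lcurve_curvature <- function(ll, lr, ls) {
  sm <- function(y) {
    fit <- try(stats::smooth.spline(ll, y, spar = 0.4), silent = TRUE)
    if (inherits(fit, "try-error")) return(list(d1 = grad1(ll, y), d2 = grad2(ll, y)))
    list(d1 = stats::predict(fit, ll, deriv = 1)$y,
         d2 = stats::predict(fit, ll, deriv = 2)$y)
  }
  a <- sm(lr); b <- sm(ls)
  num <- a$d1 * b$d2 - b$d1 * a$d2
  den <- (a$d1^2 + b$d1^2)^1.5
  k <- abs(num) / pmax(den, .Machine$double.eps)
  # corners at the grid edges are artefacts of the window; suppress them
  k[c(1, 2, length(k) - 1, length(k))] <- 0
  k
}

grad1 <- function(x, y) {
  n <- length(x)
  c(diff(y)[1] / diff(x)[1],
    (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)]),
    diff(y)[n - 1] / diff(x)[n - 1])
}

grad2 <- function(x, y) {
  d1 <- grad1(x, y)
  grad1(x, d1)
}

#' Match a traction-magnitude percentile by bisection on lambda
#'
#' Finds the identity-regularizer lambda whose solution matches a target
#' field's 95th-percentile traction magnitude, the protocol used to pair
#' identity-regularized maps with their Laplacian counterparts.
#'
#' @param obs a \code{\link{observation_model}}.
#' @param target_field stacked traction vector whose percentile is matched.
#' @param percentile percentile of |t| to match (default 95).
#' @param tol relative matching tolerance.
#' @return list with \code{lambda} and the achieved \code{percentile_value}.
#' @export
match_percentile_lambda <- function(obs, target_field, percentile = 95,
                                    tol = 0.01) {
  nw <- obs$nw
  mag <- function(t) sqrt(t[1:nw]^2 + t[nw + 1:nw]^2)
  target <- stats::quantile(mag(target_field), percentile / 100, names = FALSE)
  cfg <- function(l) tikhonov_config(lambda = l, regularizer = "identity")
  pctl <- function(l) stats::quantile(mag(solve_tikhonov(obs, cfg(l))),
                                      percentile / 100, names = FALSE)
  lo <- 1e-12; hi <- 1e12
  plo <- pctl(lo); phi <- pctl(hi)
  if (!((plo - target) * (phi - target) <= 0))
    stop("no bracketing lambda for the requested percentile")
  f <- function(l) pctl(10^l) - target
  root <- stats::uniroot(f, c(log10(lo), log10(hi)), tol = 1e-3)$root
  lambda <- 10^root
  list(lambda = lambda, percentile_value = pctl(lambda), target = target)
}
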