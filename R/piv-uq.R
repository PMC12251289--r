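# Non-parametric bootstrap uncertainty for PIV displacement vectors.
# Pixel indices of each interrogation-window pair are resampled with
# replacement; unsampled pixels are blacked out (set to zero) so that each
# perturbed pair probes which pixels the correlation peak relies on.  Each
# window of a pair is resampled independently by default; a paired variant
# (same multiset on both windows) is available but locks onto the shared
# sparsity pattern at zero lag when window content is background-dominated.  The resulting displacement draws are screened
# with DBSCAN for outliers and multi-modality, and per-window standard
# deviations are reported.

#' PIV-UQ configuration
#'
#' @param n_B bootstrap iterations per window (>= 2).
#' @param dbscan_eps DBSCAN neighbourhood radius in px; default \code{WS/5}
#'   (resolved at run time when \code{NULL}).
#' @param dbscan_minpts DBSCAN minimum cluster size; default
#'   \code{ceiling(n_B/10)}.
#' @param bad_sigma_factor multiplier applied to the maximum valid sigma when
#'   filling invalidated windows.
#' @param weight_mode \code{"mask"} (default) blacks out unsampled pixels
#'   and keeps sampled ones at their original value; \code{"counts"}
#'   additionally multiplies intensities by the bootstrap multiplicity.
#'   The counts variant doubles the expected weight of aligned (zero-lag)
#'   pixel products under paired resampling, which can capture the
#'   correlation peak when displacements are within a few bead widths, so
#'   it is exposed only for sensitivity checks.
#' @param paired \code{FALSE} (default) resamples each window of the pair
#'   independently.  \code{TRUE} applies the same index multiset to both
#'   windows, perturbing only the correlation functional; however the shared
#'   sparsity pattern then correlates at zero lag and captures the draws
#'   whenever the window content is dominated by a bright background (e.g.
#'   heavily noise-clipped images), suppressing the reported uncertainty, so
#'   pairing is exposed for sensitivity checks only.
#' @param keep_draws retain the raw bootstrap draws in the output.
#' @return object of class \code{piv_uq_config}.
#' @export
piv_uq_config <- function(n_B = 50, dbscan_eps = NULL, dbscan_minpts = NULL,
                          bad_sigma_factor = 5, weight_mode = c("mask", "counts"),
                          paired = FALSE, keep_draws = FALSE) {
  stopifnot(n_B >= 2, bad_sigma_factor > 0)
  weight_mode <- match.arg(weight_mode)
  structure(list(n_B = as.integer(n_B), dbscan_eps = dbscan_eps,
                 dbscan_minpts = dbscan_minpts,
                 bad_sigma_factor = bad_sigma_factor,
                 weight_mode = weight_mode, paired = paired,
                 keep_draws = keep_draws),
            class = "piv_uq_config")
}

#' Bootstrap-perturb an interrogation-window pair
#'
#' Draws \code{n^2} pixel indices uniformly with replacement per window:
#' unsampled pixels are set to zero (black), sampled pixels keep their value
#' (or are weighted by their multiplicity in counts mode).
#'
#' @param w_ref,w_session equal-shape window matrices.
#' @param weight_mode,paired see \code{\link{piv_uq_config}}.
#' @return list with perturbed \code{ref} and \code{session} windows.
#' @export
bootstrap_window_pair <- function(w_ref, w_session,
                                  weight_mode = c("mask", "counts"),
                                  paired = FALSE) {
  stopifnot(identical(dim(w_ref), dim(w_session)))
  weight_mode <- match.arg(weight_mode)
  npix <- length(w_ref)
  draw <- function() {
    counts <- tabulate(sample.int(npix, npix, replace = TRUE), nbins = npix)
    w <- if (weight_mode == "counts") counts else as.numeric(counts > 0)
    dim(w) <- dim(w_ref)
    w
  }
  w1 <- draw()
  w2 <- if (paired) w1 else draw()
  list(ref = w_ref * w1, session = w_session * w2)
}

#' Bootstrap distribution of a window's displacement estimate
#'
#' Runs PIV on \code{n_B} independently perturbed copies of the window pair.
#'
#' @param w_ref,w_session window matrices.
#' @param n_B number of bootstrap iterations.
#' @param weight_mode,paired see \code{\link{piv_uq_config}}.
#' @return two-column matrix of displacement draws (px); rows from
#'   degenerate perturbed windows are \code{NA}.
#' @export
bootstrap_distribution <- function(w_ref, w_session, n_B,
                                   weight_mode = "mask", paired = FALSE) {
  draws <- matrix(NA_real_, n_B, 2)
  for (b in seq_len(n_B)) {
    pert <- bootstrap_window_pair(w_ref, w_session, weight_mode, paired)
    cc <- cross_correlate(pert$ref, pert$session)
    if (!cc$degenerate) draws[b, ] <- subpixel_peak(cc$surface)$u
  }
  draws
}

#' Density-based clustering (DBSCAN)
#'
#' Minimal DBSCAN for the small 2D draw sets produced by the bootstrap
#' (tens of points).  Points with at least \code{minpts} neighbours within
#' \code{eps} (self included) are core points; clusters are the connected
#' components of core points plus their border points; remaining points are
#' noise (cluster 0).
#'
#' @param x two-column point matrix.
#' @param eps neighbourhood radius.
#' @param minpts minimum neighbourhood size for a core point.
#' @return integer cluster labels (0 = noise).
#' @export
dbscan_cluster <- function(x, eps, minpts) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n == 0L) return(integer(0))
  d <- as.matrix(stats::dist(x))
  nb <- d <= eps
  core <- rowSums(nb) >= minpts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      if (!core[p]) next
      for (q in which(nb[p, ])) {
        if (labels[q] == 0L) {
          labels[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

#' Validate a bootstrap draw set by cluster analysis
#'
#' DBSCAN removes outliers; the window is invalidated when no cluster is
#' found or when two clusters are separated (minimum edge-to-edge distance)
#' by at least 20\% of the PIV window spacing, the multi-modality criterion.
#' Otherwise statistics are taken over the largest cluster.
#'
#' @param draws two-column matrix of displacement draws (px); \code{NA} rows
#'   are discarded first.
#' @param eps,minpts DBSCAN parameters.
#' @param WS PIV window spacing (px), scale of the separation criterion.
#' @return list with \code{valid}, the retained \code{draws} (largest
#'   cluster) and the full label vector.
#' @export
cluster_validate <- function(draws, eps, minpts, WS) {
  ok <- stats::complete.cases(draws)
  pts <- draws[ok, , drop = FALSE]
  if (nrow(pts) < minpts)
    return(list(valid = FALSE, draws = pts[0, , drop = FALSE], labels = integer(0)))
  labels <- dbscan_cluster(pts, eps, minpts)
  ncl <- max(labels)
  if (ncl == 0L)
    return(list(valid = FALSE, draws = pts[0, , drop = FALSE], labels = labels))
  if (ncl >= 2L) {
    for (a in seq_len(ncl - 1L)) for (b in (a + 1L):ncl) {
      pa <- pts[labels == a, , drop = FALSE]
      pb <- pts[labels == b, , drop = FALSE]
      sep <- min(proxy_cross_dist(pa, pb))
      if (sep >= 0.2 * WS)
        return(list(valid = FALSE, draws = pts[0, , drop = FALSE], labels = labels))
    }
  }
  main <- which.max(tabulate(labels, nbins = ncl))
  list(valid = TRUE, draws = pts[labels == main, , drop = FALSE], labels = labels)
}

proxy_cross_dist <- function(a, b) {
  out <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a)))
    out[i, ] <- sqrt((b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2)
  out
}

#' Circular standard deviation of 2D vector directions
#'
#' \code{sqrt(-2 ln Rbar)} where \code{Rbar} is the mean resultant length of
#' the unit direction vectors.  Zero-length vectors are dropped.
#'
#' @param vx,vy vector components.
#' @return circular standard deviation in radians (\code{NA} if no usable
#'   vectors).
#' @export
circular_sd <- function(vx, vy) {
  r <- sqrt(vx^2 + vy^2)
  keep <- is.finite(r) & r > 0
  if (!any(keep)) return(NA_real_)
  cx <- mean(vx[keep] / r[keep]); cy <- mean(vy[keep] / r[keep])
  rbar <- min(sqrt(cx^2 + cy^2), 1)
  sqrt(-2 * log(max(rbar, .Machine$double.xmin)))
}

#' Run PIV with bootstrap uncertainty quantification
#'
#' Nominal PIV first, then a per-window bootstrap whose draws are screened
#' by \code{\link{cluster_validate}}.  Per-window componentwise standard
#' deviations over the main cluster give the uncertainty map; invalidated
#' windows get \code{bad_sigma_factor} times the maximum valid sigma and a
#' median-filled displacement (3x3 neighbourhood, iterated until filled).
#'
#' @param pair an \code{\link{image_pair}}.
#' @param config a \code{\link{piv_config}}.
#' @param uq a \code{\link{piv_uq_config}}.
#' @param seed optional RNG seed.
#' @return list with the (filled) \code{field} (\code{deformation_field})
#'   and \code{uncertainty}: matrices \code{sigma_ux}, \code{sigma_uy},
#'   \code{sigma_total} (px), \code{angular_sd} (rad), logical \code{valid},
#'   and optionally the raw \code{draws}.
#' @export
run_piv_uq <- function(pair, config, uq = piv_uq_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  field <- run_piv(pair, config)
  eps <- if (is.null(uq$dbscan_eps)) config$WS / 5 else uq$dbscan_eps
  minpts <- if (is.null(uq$dbscan_minpts)) ceiling(uq$n_B / 10) else uq$dbscan_minpts

  g <- extract_windows(pair$ref, config)
  ny <- g$ny; nx <- g$nx
  s_ux <- s_uy <- ang <- matrix(NA_real_, ny, nx)
  valid <- matrix(TRUE, ny, nx)
  draws_store <- if (uq$keep_draws) vector("list", ny * nx) else NULL

  for (j in seq_len(nx)) {
    cols <- g$starts_x[j]:(g$starts_x[j] + g$WL - 1L)
    for (i in seq_len(ny)) {
      rows <- g$starts_y[i]:(g$starts_y[i] + g$WL - 1L)
      if (field$degenerate[i, j]) { valid[i, j] <- FALSE; next }
      dr <- bootstrap_distribution(pair$ref[rows, cols],
                                   pair$session[rows, cols],
                                   uq$n_B, uq$weight_mode, uq$paired)
      if (uq$keep_draws) draws_store[[(j - 1L) * ny + i]] <- dr
      cv <- cluster_validate(dr, eps, minpts, config$WS)
      if (!cv$valid || nrow(cv$draws) < 2L) {
        valid[i, j] <- FALSE
        next
      }
      s_ux[i, j] <- stats::sd(cv$draws[, 1])
      s_uy[i, j] <- stats::sd(cv$draws[, 2])
      ang[i, j] <- circular_sd(cv$draws[, 1], cv$draws[, 2])
    }
  }

  if (!any(valid)) stop("all PIV windows invalidated; image pair unusable")
  fmax_x <- max(s_ux[valid], na.rm = TRUE)
  fmax_y <- max(s_uy[valid], na.rm = TRUE)
  s_ux[!valid] <- uq$bad_sigma_factor * fmax_x
  s_uy[!valid] <- uq$bad_sigma_factor * fmax_y
  field$ux <- median_fill(field$ux, valid)
  field$uy <- median_fill(field$uy, valid)

  unc <- list(sigma_ux = s_ux, sigma_uy = s_uy,
              sigma_total = sqrt(s_ux^2 + s_uy^2),
              angular_sd = ang, valid = valid,
              eps = eps, minpts = minpts, n_B = uq$n_B,
              bad_sigma_factor = uq$bad_sigma_factor)
  if (uq$keep_draws) unc$draws <- draws_store
  list(field = field, uncertainty = unc)
}

# Replace entries where valid is FALSE by the median of their 3x3 valid
# neighbourhood, iterating so enclosed holes eventually fill.
median_fill <- function(m, valid) {
  todo <- !valid
  out <- m
  guard <- 0L
  while (any(todo) && guard < 100L) {
    guard <- guard + 1L
    progressed <- FALSE
    for (idx in which(todo)) {
      i <- ((idx - 1L) %% nrow(m)) + 1L
      j <- ((idx - 1L) %/% nrow(m)) + 1L
      ri <- max(1L, i - 1L):min(nrow(m), i + 1L)
      rj <- max(1L, j - 1L):min(ncol(m), j + 1L)
      nb <- out[ri, rj][!todo[ri, rj]]
      if (length(nb)) {
        out[i, j] <- stats::median(nb)
        todo[i, j] <- FALSE
        progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  out
}

#' Bootstrap convergence diagnostic (coefficient of variation)
#'
#' For each candidate number of bootstrap iterations, the per-window sigma
#' estimate is recomputed \code{repeats} times with fresh seeds; the CoV per
#' window is \code{sd/mean} of those estimates, and the median CoV over
#' windows is reported.  CoV decreasing towards zero indicates a converged
#' choice of \code{n_B}.
#'
#' @param pair an \code{\link{image_pair}}.
#' @param config a \code{\link{piv_config}}.
#' @param n_B_list candidate bootstrap sizes.
#' @param repeats independent repetitions per candidate (>= 2).
#' @param seed RNG seed.
#' @return data.frame with \code{n_B} and \code{median_cov}.
#' @export
cov_convergence <- function(pair, config, n_B_list = c(5, 10, 20, 40),
                            repeats = 4, seed = 1) {
  stopifnot(repeats >= 2)
  out <- data.frame(n_B = n_B_list, median_cov = NA_real_)
  for (k in seq_along(n_B_list)) {
    sig <- NULL
    for (r in seq_len(repeats)) {
      res <- run_piv_uq(pair, config, piv_uq_config(n_B = n_B_list[k]),
                        seed = seed + 1000L * k + r)
      s <- res$uncertainty$sigma_total
      s[!res$uncertainty$valid] <- NA
      sig <- cbind(sig, as.vector(s))
    }
    cov_w <- apply(sig, 1, function(v) {
      v <- v[is.finite(v)]
      if (length(v) < 2 || mean(v) == 0) return(NA_real_)
      stats::sd(v) / mean(v)
    })
    out$median_cov[k] <- stats::median(cov_w, na.rm = TRUE)
  }
  out
}
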