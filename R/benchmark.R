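# Synthetic heteroskedastic TFM benchmark: four Gaussian traction islands
# drive a finite-thickness substrate; bead images encode a left-to-right
# bead-density gradient plus uniform pixel noise, so PIV uncertainty grows
# across the field of view while the ground truth stays known.

#' Gaussian traction-island field
#'
#' Sum of radially Gaussian islands, each \code{tp exp(-r^2 / (2 s^2))}
#' oriented along its unit direction vector.
#'
#' @param centers two-column matrix of island centres (micrometres).
#' @param tp peak traction per island, Pa (recycled).
#' @param s island width, micrometres (recycled).
#' @param directions two-column matrix of unit direction vectors (recycled
#'   by row).
#' @return evaluator function: given x, y vectors (micrometres) returns a
#'   list with \code{tx}, \code{ty} (Pa).
#' @export
traction_islands <- function(centers, tp = 500, s = 15, directions) {
  centers <- matrix(centers, ncol = 2)
  directions <- matrix(directions, ncol = 2)
  k <- nrow(centers)
  tp <- rep_len(tp, k); s <- rep_len(s, k)
  stopifnot(all(tp >= 0), all(s > 0))
  dn <- sqrt(rowSums(directions^2))
  directions <- directions / dn
  function(x, y) {
    tx <- ty <- numeric(length(x)) * 0
    dim(tx) <- dim(ty) <- dim(x)
    for (i in seq_len(k)) {
      g <- tp[i] * exp(-((x - centers[i, 1])^2 + (y - centers[i, 2])^2) /
                         (2 * s[i]^2))
      tx <- tx + g * directions[i, 1]
      ty <- ty + g * directions[i, 2]
    }
    list(tx = tx, ty = ty)
  }
}

#' Default four-island benchmark traction field
#'
#' One island per quadrant at (+-L/4, +-L/4), peak 500 Pa, width 15
#' micrometres, pointing towards the vertical midline (left islands +x,
#' right islands -x).
#'
#' @param domain_side domain side L, micrometres.
#' @param tp,s island peak (Pa) and width (micrometres).
#' @return evaluator as in \code{\link{traction_islands}}.
#' @export
four_island_field <- function(domain_side, tp = 500, s = 15) {
  L <- domain_side
  cx <- c(L / 4, 3 * L / 4, L / 4, 3 * L / 4)
  cy <- c(L / 4, L / 4, 3 * L / 4, 3 * L / 4)
  dirs <- cbind(c(1, -1, 1, -1), 0)
  traction_islands(cbind(cx, cy), tp = tp, s = s, directions = dirs)
}

#' Benchmark configuration
#'
#' Defaults reproduce the heteroskedastic validation study: 1024 px image,
#' E = 5 kPa, nu = 0.45, SNR = 50 dB, bead density ramp from 8e-3 (left) to
#' 8e-4 (right) beads/px^2, pixel size 0.3462 um/px (calibrated so the RMS
#' of the ground-truth field is 75 Pa over the domain), substrate thickness
#' 50 um, PIV windows WL = 64, WS = 32.
#'
#' @param image_side image side in px.
#' @param pixel_size micrometres per px.
#' @param E,nu,h substrate parameters (Pa, -, micrometres).
#' @param snr_db image SNR.
#' @param density_left,density_right bead densities at the image edges
#'   (beads/px^2); equal values give a homoskedastic image.
#' @param bead_sigma bead profile width, px.
#' @param tp,s island peak (Pa) and width (micrometres).
#' @param WL,WS PIV window size and spacing, px.
#' @param n_B bootstrap iterations.
#' @param fine_grid forward-solve grid resolution (points per side).
#' @return list of class \code{benchmark_config}.
#' @export
benchmark_config <- function(image_side = 1024, pixel_size = 0.3462,
                             E = 5000, nu = 0.45, h = 50, snr_db = 50,
                             density_left = 8e-3, density_right = 8e-4,
                             bead_sigma = 1.5, tp = 500, s = 15,
                             WL = 64, WS = WL / 2, n_B = 50,
                             fine_grid = 256) {
  structure(as.list(environment()), class = "benchmark_config")
}

#' Build the synthetic benchmark: images plus ground truth
#'
#' Evaluates the four-island traction field, forward-solves the substrate
#' displacement on a fine periodic grid, displaces randomly placed beads
#' accordingly, and renders a noisy reference/session image pair.  Ground
#' truth is returned on the PIV window-centre grid used downstream.
#'
#' @param config a \code{\link{benchmark_config}}.
#' @param seed RNG seed.
#' @return list of class \code{tfm_benchmark}: the \code{pair}
#'   (\code{\link{image_pair}}), \code{truth} (grid coordinates in um and
#'   px, \code{tx}, \code{ty} in Pa, \code{ux}, \code{uy} in um on the PIV
#'   grid), the \code{substrate}, the traction evaluator and the config.
#' @export
build_benchmark <- function(config = benchmark_config(), seed = 1) {
  set.seed(seed)
  cfg <- config
  L <- cfg$image_side * cfg$pixel_size
  substrate <- substrate_model(cfg$E, cfg$nu, cfg$h)
  field_fun <- four_island_field(L, tp = cfg$tp, s = cfg$s)

  # forward solve on a fine periodic grid
  nf <- cfg$fine_grid
  spacing_f <- L / nf
  xs <- (seq_len(nf) - 0.5) * spacing_f
  gx <- matrix(xs, nf, nf, byrow = TRUE)
  gy <- matrix(xs, nf, nf)
  tr <- field_fun(gx, gy)
  kern_f <- build_spectral_kernel(substrate, nf, spacing_f)
  uf <- apply_forward(tr$tx, tr$ty, kern_f)

  disp_fun <- function(pos_px) {
    # bead positions px -> um, bilinear lookup of (ux, uy) um -> px
    px <- pos_px[, 1] * cfg$pixel_size
    py <- pos_px[, 2] * cfg$pixel_size
    cbind(bilinear_at(uf$ux, xs, px, py),
          bilinear_at(uf$uy, xs, px, py)) / cfg$pixel_size
  }

  shape <- c(cfg$image_side, cfg$image_side)
  dens <- linear_density(cfg$density_left, cfg$density_right, cfg$image_side)
  beads <- generate_bead_field(shape, dens, bead_sigma = cfg$bead_sigma)
  ref <- render_beads(beads, shape)
  moved <- apply_displacement(beads, displacement_from_function(disp_fun), shape)
  session <- render_beads(moved, shape)
  ref <- add_pixel_noise(ref, cfg$snr_db)
  session <- add_pixel_noise(session, cfg$snr_db)
  pair <- image_pair(ref, session, cfg$pixel_size)

  # ground truth on the PIV window-centre grid
  g <- extract_windows(ref, piv_config(cfg$WL, cfg$WS))
  cx_um <- g$cx * cfg$pixel_size
  cy_um <- g$cy * cfg$pixel_size
  gxx <- matrix(cx_um, g$ny, g$nx, byrow = TRUE)
  gyy <- matrix(cy_um, g$ny, g$nx)
  tr_g <- field_fun(gxx, gyy)
  truth <- list(cx_um = cx_um, cy_um = cy_um, cx_px = g$cx, cy_px = g$cy,
                tx = tr_g$tx, ty = tr_g$ty,
                ux = matrix(bilinear_at(uf$ux, xs, as.vector(gxx), as.vector(gyy)),
                            g$ny, g$nx),
                uy = matrix(bilinear_at(uf$uy, xs, as.vector(gxx), as.vector(gyy)),
                            g$ny, g$nx),
                nx = g$nx, ny = g$ny)

  structure(list(pair = pair, truth = truth, substrate = substrate,
                 traction_fun = field_fun, domain_side = L,
                 config = cfg, seed = seed),
            class = "tfm_benchmark")
}

# bilinear interpolation of a matrix field sampled at coordinates `xs` (both
# axes), clamped at the border; field[i, j] is at (x = xs[j], y = xs[i])
bilinear_at <- function(field, xs, px, py) {
  n <- length(xs)
  h <- xs[2] - xs[1]
  fx <- pmin(pmax((px - xs[1]) / h, 0), n - 1)
  fy <- pmin(pmax((py - xs[1]) / h, 0), n - 1)
  j0 <- pmin(floor(fx), n - 2); i0 <- pmin(floor(fy), n - 2)
  wx <- fx - j0; wy <- fy - i0
  j0 <- j0 + 1; i0 <- i0 + 1
  f00 <- field[cbind(i0, j0)]; f01 <- field[cbind(i0, j0 + 1)]
  f10 <- field[cbind(i0 + 1, j0)]; f11 <- field[cbind(i0 + 1, j0 + 1)]
  (1 - wy) * ((1 - wx) * f00 + wx * f01) + wy * ((1 - wx) * f10 + wx * f11)
}

#' RMS magnitude of the benchmark ground-truth traction over the domain
#'
#' Evaluated on the fine image-resolution grid; with the default
#' calibration this is the 75 Pa foreground threshold.
#'
#' @param config a \code{\link{benchmark_config}}.
#' @param n evaluation grid resolution per side.
#' @return RMS in Pa.
#' @export
truth_rms <- function(config = benchmark_config(), n = 256) {
  L <- config$image_side * config$pixel_size
  xs <- (seq_len(n) - 0.5) * (L / n)
  gx <- matrix(xs, n, n, byrow = TRUE)
  gy <- matrix(xs, n, n)
  tr <- four_island_field(L, tp = config$tp, s = config$s)(gx, gy)
  sqrt(mean(tr$tx^2 + tr$ty^2))
}
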