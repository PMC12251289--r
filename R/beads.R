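#' @useDynLib tfmuq, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rpois runif rnorm sd median rgamma quantile var fft
#'   smooth.spline predict mvfft binom.test cor uniroot approx
NULL

# Saturation level of the synthetic camera, in arbitrary units.  All images
# are clipped to [0, SATURATION]; the image SNR definition is anchored to it.
SATURATION <- 1000

#' Convert image signal-to-noise ratio to pixel-noise standard deviation
#'
#' The image SNR (dB) is defined against the bead saturation intensity of
#' 1000 a.u.: \code{SNR = 20 log10(1000 / sigma_px)}.
#'
#' @param snr_db signal-to-noise ratio in dB.
#' @return pixel noise standard deviation in intensity units (a.u.).
#' @export
snr_to_sigma <- function(snr_db) {
  stopifnot(is.numeric(snr_db))
  SATURATION * 10^(-snr_db / 20)
}

#' @rdname snr_to_sigma
#' @param sigma_px pixel noise standard deviation (a.u.).
#' @export
sigma_to_snr <- function(sigma_px) {
  stopifnot(sigma_px > 0)
  20 * log10(SATURATION / sigma_px)
}

#' Construct a bead field
#'
#' A bead field is the set of continuous sub-pixel centroid positions of
#' synthetic fluorescent beads, together with their common Gaussian profile
#' width and peak intensity.
#'
#' @param centroids two-column matrix of (x, y) positions in pixel units
#'   (0-based continuous coordinates).
#' @param peak_intensity peak intensity of a bead, a.u. (default saturation).
#' @param bead_sigma Gaussian profile width in pixels.
#' @return object of class \code{bead_field}.
#' @export
bead_field <- function(centroids, peak_intensity = SATURATION, bead_sigma = 1.5) {
  centroids <- matrix(as.numeric(centroids), ncol = 2,
                      dimnames = list(NULL, c("x", "y")))
  stopifnot(peak_intensity > 0, bead_sigma > 0)
  structure(list(centroids = centroids,
                 peak_intensity = peak_intensity,
                 bead_sigma = bead_sigma),
            class = "bead_field")
}

#' Randomly place synthetic beads with an x-dependent density profile
#'
#' Bead counts are Poisson distributed: the image is divided into vertical
#' strips and the count in each strip is drawn with mean
#' \code{density(x_strip_centre) * strip_area}; positions are uniform within
#' the strip.  A constant density therefore yields a homogeneous Poisson
#' process, and a density gradient yields the corresponding inhomogeneous one.
#'
#' @param image_shape integer vector \code{c(nrow, ncol)} in pixels.
#' @param density either a single number (beads per pixel^2) or a function of
#'   the x coordinate (px) returning the local density.
#' @param seed optional RNG seed.
#' @param strip_width strip discretisation of the density profile, px.
#' @param bead_sigma,peak_intensity bead profile parameters, see
#'   \code{\link{bead_field}}.
#' @return a \code{\link{bead_field}}.
#' @export
generate_bead_field <- function(image_shape, density, seed = NULL,
                                strip_width = 16, bead_sigma = 1.5,
                                peak_intensity = SATURATION) {
  stopifnot(length(image_shape) == 2, all(image_shape > 0))
  if (!is.null(seed)) set.seed(seed)
  nr <- image_shape[1]; nc <- image_shape[2]
  dens_fun <- if (is.function(density)) density else function(x) rep_len(density, length(x))
  edges <- seq(0, nc, by = strip_width)
  if (edges[length(edges)] < nc) edges <- c(edges, nc)
  xs <- ys <- numeric(0)
  for (i in seq_len(length(edges) - 1L)) {
    x0 <- edges[i]; x1 <- edges[i + 1L]
    d <- dens_fun((x0 + x1) / 2)
    if (length(d) != 1L || is.na(d) || d < 0)
      stop("bead density must be a non-negative scalar everywhere")
    n <- rpois(1L, d * (x1 - x0) * nr)
    if (n > 0) {
      xs <- c(xs, runif(n, x0, x1))
      ys <- c(ys, runif(n, 0, nr))
    }
  }
  bead_field(cbind(xs, ys), peak_intensity = peak_intensity,
             bead_sigma = bead_sigma)
}

#' Linear bead-density ramp along x
#'
#' Helper to build the left-to-right density gradients used to emulate
#' spatially heterogeneous image quality.
#'
#' @param from,to densities (beads/px^2) at the left and right image edge.
#' @param width image width in pixels.
#' @return function of x returning the local density.
#' @export
linear_density <- function(from, to, width) {
  stopifnot(from >= 0, to >= 0, width > 0)
  function(x) from + (to - from) * pmin(pmax(x / width, 0), 1)
}

#' Render a bead field into an intensity raster
#'
#' Each bead contributes \code{peak * exp(-r^2 / (2 sigma^2))} evaluated at
#' pixel centres; contributions add and the result is clipped at the
#' saturation level (1000 a.u.).
#'
#' @param field a \code{\link{bead_field}}.
#' @param image_shape \code{c(nrow, ncol)} pixels.
#' @param truncate profile truncation radius in units of \code{bead_sigma}.
#' @return numeric matrix of intensities in a.u.
#' @export
render_beads <- function(field, image_shape, truncate = 4) {
  stopifnot(inherits(field, "bead_field"), field$bead_sigma > 0)
  nr <- image_shape[1]; nc <- image_shape[2]
  img <- matrix(0, nr, nc)
  cen <- field$centroids
  if (nrow(cen) == 0L) return(img)
  sig <- field$bead_sigma
  rad <- ceiling(truncate * sig)
  for (b in seq_len(nrow(cen))) {
    bx <- cen[b, 1]; by <- cen[b, 2]
    c0 <- max(0L, floor(bx) - rad); c1 <- min(nc - 1L, ceiling(bx) + rad)
    r0 <- max(0L, floor(by) - rad); r1 <- min(nr - 1L, ceiling(by) + rad)
    if (c0 > c1 || r0 > r1) next
    dx <- (c0:c1) - bx
    dy <- (r0:r1) - by
    patch <- field$peak_intensity *
      outer(exp(-dy^2 / (2 * sig^2)), exp(-dx^2 / (2 * sig^2)))
    rows <- (r0:r1) + 1L; cols <- (c0:c1) + 1L
    img[rows, cols] <- img[rows, cols] + patch
  }
  pmin(img, SATURATION)
}

#' Add Gaussian pixel noise at a prescribed image SNR
#'
#' Adds i.i.d. Gaussian noise of standard deviation
#' \code{1000 * 10^(-snr_db/20)} and clips to the [0, 1000] a.u. range.
#'
#' @param image intensity raster (a.u.).
#' @param snr_db image signal-to-noise ratio in dB; \code{Inf} leaves the
#'   image unchanged.
#' @param seed optional RNG seed.
#' @return noisy raster, clipped to [0, 1000].
#' @export
add_pixel_noise <- function(image, snr_db, seed = NULL) {
  stopifnot(is.finite(snr_db) || is.infinite(snr_db))
  if (is.infinite(snr_db)) return(image)
  if (!is.null(seed)) set.seed(seed)
  s <- snr_to_sigma(snr_db)
  out <- image + matrix(rnorm(length(image), sd = s), nrow(image))
  pmin(pmax(out, 0), SATURATION)
}

# ---- displacement specifications -------------------------------------------

#' Displacement field specifications for synthetic deformation
#'
#' Three kinds of prescribed substrate deformation are supported:
#' a uniform translation, a linear (shear-type) field evaluated on normalised
#' coordinates, and an arbitrary field given by a function (used to displace
#' beads according to a forward-solved traction field).
#'
#' @param u length-2 displacement (px) for the uniform field.
#' @return object of class \code{displacement_spec}.
#' @export
displacement_uniform <- function(u = c(2, 0.6)) {
  stopifnot(length(u) == 2, all(is.finite(u)))
  structure(list(kind = "uniform", u = as.numeric(u)), class = "displacement_spec")
}

#' @rdname displacement_uniform
#' @param A 2x2 matrix mapping normalised coordinates (x0, y0) in [-1, 1] to a
#'   displacement in px.  The default reproduces a symmetric shear with
#'   amplitude \code{g = 20} px and angle \code{alpha = 45} degrees:
#'   \code{diag(sin(a) g cos(a)^2, cos(a) g sin(a)^2)}.
#' @param g,alpha_deg shear amplitude (px) and angle (degrees) used to build
#'   the default matrix when \code{A} is missing.
#' @export
displacement_linear <- function(A = NULL, g = 20, alpha_deg = 45) {
  if (is.null(A)) {
    a <- alpha_deg * pi / 180
    A <- diag(c(sin(a) * g * cos(a)^2, cos(a) * g * sin(a)^2))
  }
  A <- matrix(as.numeric(A), 2, 2)
  structure(list(kind = "linear", A = A), class = "displacement_spec")
}

#' @rdname displacement_uniform
#' @param fun function taking a two-column (x, y) px matrix and returning a
#'   two-column displacement matrix in px.
#' @export
displacement_from_function <- function(fun) {
  stopifnot(is.function(fun))
  structure(list(kind = "function", fun = fun), class = "displacement_spec")
}

#' Evaluate a displacement specification at given positions
#'
#' @param spec a \code{displacement_spec}.
#' @param pos two-column (x, y) matrix, px.
#' @param image_shape image extent, used to normalise coordinates for the
#'   linear kind (x0, y0 in [-1, 1] across the image).
#' @return two-column displacement matrix, px.
#' @export
eval_displacement <- function(spec, pos, image_shape = NULL) {
  stopifnot(inherits(spec, "displacement_spec"))
  pos <- matrix(as.numeric(pos), ncol = 2)
  switch(spec$kind,
    uniform = matrix(spec$u, nrow(pos), 2, byrow = TRUE),
    linear = {
      stopifnot(!is.null(image_shape))
      x0 <- 2 * pos[, 1] / (image_shape[2] - 1) - 1
      y0 <- 2 * pos[, 2] / (image_shape[1] - 1) - 1
      t(spec$A %*% rbind(x0, y0))
    },
    "function" = spec$fun(pos),
    stop("unknown displacement kind: ", spec$kind)
  )
}

#' Displace bead centroids according to a prescribed deformation field
#'
#' The field is evaluated at the pre-displacement bead positions (forward
#' warp of the centroids).  Beads displaced out of the frame are dropped.
#'
#' @param field a \code{\link{bead_field}}.
#' @param spec a \code{displacement_spec}.
#' @param image_shape \code{c(nrow, ncol)} px.
#' @return displaced \code{bead_field}.
#' @export
apply_displacement <- function(field, spec, image_shape) {
  stopifnot(inherits(field, "bead_field"))
  cen <- field$centroids
  if (nrow(cen) == 0L) return(field)
  u <- eval_displacement(spec, cen, image_shape)
  new_cen <- cen + u
  keep <- new_cen[, 1] >= 0 & new_cen[, 1] <= image_shape[2] - 1 &
          new_cen[, 2] >= 0 & new_cen[, 2] <= image_shape[1] - 1
  bead_field(new_cen[keep, , drop = FALSE],
             peak_intensity = field$peak_intensity,
             bead_sigma = field$bead_sigma)
}

#' Image pair container
#'
#' Reference (stress-free) and session (loaded) intensity rasters with the
#' physical pixel size.
#'
#' @param ref,session intensity matrices of identical shape (a.u.).
#' @param pixel_size physical pixel size, micrometres per pixel.
#' @return object of class \code{image_pair}.
#' @export
image_pair <- function(ref, session, pixel_size) {
  stopifnot(identical(dim(ref), dim(session)), pixel_size > 0)
  structure(list(ref = ref, session = session, pixel_size = pixel_size),
            class = "image_pair")
}
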