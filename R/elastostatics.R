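# Finite-thickness Fourier elastostatic response for 2D traction force
# microscopy.  A flat, inertia-less, linearly elastic layer of Young's
# modulus E, Poisson ratio nu and thickness h is bonded at its base
# (u = 0 at z = 0) and loaded by in-plane tractions at the free surface
# z = h, where the normal stress vanishes.  Per wavenumber k the surface
# displacement responds to the surface traction through a 2x2 block
#   M(k) = g1(k) I + g2(k) [kx^2 kxky; kxky ky^2],
# whose transverse and longitudinal eigenvalues are the compliances
#   gT = tanh(kh) / (mu k)
#   gL = (1-nu) [ (3-4nu) sinh(kh)cosh(kh) + kh ] /
#        ( mu k [ (kh)^2 + 4(1-nu)^2 + (3-4nu) sinh(kh)^2 ] )
# (plane-strain layer solution; mu = E / (2(1+nu))).  Both compliances tend
# to h/mu in the long-wavelength limit kh -> 0 (pure shear) and to the
# Boussinesq half-space kernel for kh >> 1.  The implementation evaluates
# the exponentially rescaled forms so that no hyperbolic overflow occurs.

#' Substrate material model
#'
#' @param E Young's modulus, Pa.
#' @param nu Poisson ratio, in [0, 0.5) (the incompressible limit 0.5 makes
#'   the plane-strain factors degenerate and is rejected).
#' @param h substrate thickness, micrometres.
#' @return object of class \code{substrate_model} with the derived shear
#'   modulus \code{mu = E / (2 (1 + nu))} (Pa).
#' @export
substrate_model <- function(E, nu, h) {
  stopifnot(E > 0, h > 0, nu >= 0)
  if (nu >= 0.5) stop("nu must be < 0.5 (incompressible limit not supported)")
  structure(list(E = E, nu = nu, h = h, mu = E / (2 * (1 + nu))),
            class = "substrate_model")
}

# Transverse and longitudinal compliances (micrometre / Pa) for wavenumber
# magnitudes k (rad / micrometre).  k = 0 entries get the pure-shear limit.
layer_compliances <- function(k, substrate) {
  mu <- substrate$mu; nu <- substrate$nu; h <- substrate$h
  kh <- k * h
  gT <- ifelse(k > 0, tanh(kh) / (mu * pmax(k, .Machine$double.eps)), h / mu)
  # rescale by 4 exp(-2kh): 4 e^{-2kh} sinh cosh = 1 - e^{-4kh},
  # 4 e^{-2kh} sinh^2 = (1 - e^{-2kh})^2
  e2 <- exp(-2 * kh)
  num <- (1 - nu) * ((3 - 4 * nu) * (1 - e2^2) + 4 * kh * e2)
  den <- 4 * (kh^2 + 4 * (1 - nu)^2) * e2 + (3 - 4 * nu) * (1 - e2)^2
  gL <- ifelse(k > 0, num / (mu * pmax(k, .Machine$double.eps) * den), h / mu)
  list(gT = gT, gL = gL)
}

#' Build the spectral elastostatic kernel on a periodic grid
#'
#' Constructs the per-wavenumber 2x2 response blocks
#' \code{g1 I + g2 [kx^2, kxky; kxky, ky^2]} of the finite-thickness
#' elastic layer on the discrete Fourier grid of an \code{n x n} field with
#' physical spacing \code{spacing} (micrometres).  The zero-wavenumber block
#' is the pure-shear limit \code{(h/mu) I}.
#'
#' @param substrate a \code{\link{substrate_model}}.
#' @param n grid points per side.
#' @param spacing grid spacing, micrometres.
#' @return object of class \code{spectral_kernel} with wavenumber arrays and
#'   the scalar compliance fields \code{g1}, \code{g2} (and \code{f1},
#'   \code{f2} with \code{g1 = 1/f1}, \code{g2 = -f2/(f1 (f1 + k^2 f2))}).
#' @export
build_spectral_kernel <- function(substrate, n, spacing) {
  stopifnot(inherits(substrate, "substrate_model"), n >= 2, spacing > 0)
  f <- fft_freq(n) * 2 * pi / spacing      # rad / micrometre
  kx <- matrix(f, n, n, byrow = TRUE)      # x varies along columns
  ky <- matrix(f, n, n)
  k <- sqrt(kx^2 + ky^2)
  comp <- layer_compliances(k, substrate)
  g1 <- comp$gT
  g2 <- ifelse(k > 0, (comp$gL - comp$gT) / pmax(k, .Machine$double.eps)^2, 0)
  f1 <- 1 / g1
  f2 <- ifelse(k > 0, (1 / comp$gL - f1) / pmax(k, .Machine$double.eps)^2, 0)
  a11 <- g1 + g2 * kx^2
  a12 <- g2 * kx * ky
  a22 <- g1 + g2 * ky^2
  # For even n the Nyquist line aliases +k and -k; the odd coupling kx*ky
  # cannot be represented there and must vanish for a real-symmetric
  # real-space operator.
  if (n %% 2 == 0) {
    nyq <- n / 2 + 1
    a12[nyq, ] <- 0
    a12[, nyq] <- 0
  }
  structure(list(substrate = substrate, n = n, spacing = spacing,
                 kx = kx, ky = ky, k = k, g1 = g1, g2 = g2,
                 f1 = f1, f2 = f2, a11 = a11, a12 = a12, a22 = a22),
            class = "spectral_kernel")
}

# fftfreq in cycles per sample: 0, 1/n, ..., wrapping to negative.
fft_freq <- function(n) {
  i <- 0:(n - 1)
  ifelse(i <= floor((n - 1) / 2), i, i - n) / n
}

fft2 <- function(x) fft(x)
ifft2 <- function(x) fft(x, inverse = TRUE) / length(x)

#' Apply the forward elastostatic operator (traction to displacement)
#'
#' Per-wavenumber 2x2 multiplication of the traction transform by the
#' spectral kernel, with periodic boundary conditions.
#'
#' @param tx,ty traction component fields (Pa) on the kernel grid, matrices.
#' @param kernel a \code{\link{build_spectral_kernel}} result.
#' @return list with displacement component matrices \code{ux}, \code{uy}
#'   in micrometres.
#' @export
apply_forward <- function(tx, ty, kernel) {
  check_kernel_grid(tx, ty, kernel)
  tx_h <- fft2(tx); ty_h <- fft2(ty)
  a11 <- kernel$a11; a12 <- kernel$a12; a22 <- kernel$a22
  ux <- Re(ifft2(a11 * tx_h + a12 * ty_h))
  uy <- Re(ifft2(a12 * tx_h + a22 * ty_h))
  list(ux = ux, uy = uy)
}

#' Exact per-mode inversion (displacement to traction), unregularized
#'
#' Inverts each 2x2 kernel block directly.  This amplifies high-wavenumber
#' noise and is intended for round-trip tests and for demonstrating why
#' regularization is needed.
#'
#' @param ux,uy displacement component fields (micrometres) on the kernel grid.
#' @param kernel a \code{\link{build_spectral_kernel}} result.
#' @return list with traction component matrices \code{tx}, \code{ty} (Pa).
#' @export
apply_inverse_unregularized <- function(ux, uy, kernel) {
  check_kernel_grid(ux, uy, kernel)
  ux_h <- fft2(ux); uy_h <- fft2(uy)
  a11 <- kernel$a11; a12 <- kernel$a12; a22 <- kernel$a22
  det <- a11 * a22 - a12^2
  if (any(abs(det) < .Machine$double.xmin))
    stop("singular kernel block; cannot invert")
  tx <- Re(ifft2(( a22 * ux_h - a12 * uy_h) / det))
  ty <- Re(ifft2((-a12 * ux_h + a11 * uy_h) / det))
  list(tx = tx, ty = ty)
}

check_kernel_grid <- function(fx, fy, kernel) {
  if (!inherits(kernel, "spectral_kernel"))
    stop("kernel must be a spectral_kernel")
  if (!all(dim(fx) == kernel$n) || !all(dim(fy) == kernel$n))
    stop("field dimensions do not match the kernel grid")
  invisible(TRUE)
}

#' Assemble the dense real-space elastostatic operator
#'
#' Builds the real symmetric \code{2 Nw x 2 Nw} matrix acting on stacked
#' \code{(tx_1..tx_Nw, ty_1..ty_Nw)} vectors (column-major grid order) such
#' that \code{M \%*\% vec(t)} reproduces \code{\link{apply_forward}}.
#' Used by the Bayesian inversion, which needs explicit dense algebra.
#'
#' @param kernel a \code{\link{build_spectral_kernel}} result.
#' @param max_windows guard on the grid size for dense algebra.
#' @return object of class \code{dense_operator}: list with the matrix
#'   \code{M} (micrometre/Pa), the grid side \code{n} and \code{spacing}.
#' @export
assemble_dense_operator <- function(kernel, max_windows = 4000) {
  n <- kernel$n
  nw <- n * n
  if (nw > max_windows)
    stop("grid has ", nw, " windows; dense assembly capped at ", max_windows,
         " (use a coarser PIV grid)")
  a11 <- kernel$a11; a12 <- kernel$a12; a22 <- kernel$a22
  # Each scalar block is circulant in 2D: its dense form is determined by the
  # real-space point response (first column), giving M[p, q] = resp(p - q).
  M <- matrix(0, 2 * nw, 2 * nw)
  blocks <- list(a11, a12, a22)
  dense <- lapply(blocks, function(a) {
    resp <- Re(ifft2(a))              # response to a unit impulse at (1, 1)
    circulant2d(resp)
  })
  M[1:nw, 1:nw] <- dense[[1]]
  M[1:nw, nw + 1:nw] <- dense[[2]]
  M[nw + 1:nw, 1:nw] <- dense[[2]]
  M[nw + 1:nw, nw + 1:nw] <- dense[[3]]
  M <- (M + t(M)) / 2
  structure(list(M = M, n = n, spacing = kernel$spacing, kernel = kernel),
            class = "dense_operator")
}

# Dense matrix of a 2D circulant operator from its impulse response (the
# field produced by a unit source at grid position (1, 1)).
circulant2d <- function(resp) {
  n <- nrow(resp)
  nw <- n * n
  idx <- matrix(seq_len(nw), n, n)
  out <- matrix(0, nw, nw)
  for (q in seq_len(nw)) {
    qi <- (q - 1) %% n          # 0-based row of source
    qj <- (q - 1) %/% n         # 0-based col of source
    shifted <- resp[((seq_len(n) - 1 - qi) %% n) + 1,
                    ((seq_len(n) - 1 - qj) %% n) + 1]
    out[, q] <- as.vector(shifted)
  }
  out
}
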