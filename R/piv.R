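# Single-pass FFT cross-correlation particle image velocimetry on
# overlapping square interrogation windows.  Deliberately simple and
# swappable: the uncertainty machinery treats the PIV evaluation as a black
# box, so iterative/window-deformation schemes can be dropped in.

#' PIV configuration
#'
#' @param WL interrogation window side, pixels.
#' @param WS window spacing, pixels; defaults to \code{WL/2}, the usual
#'   Nyquist trade-off between resolution and cost.
#' @return object of class \code{piv_config}.
#' @export
piv_config <- function(WL, WS = WL / 2) {
  stopifnot(WL >= 4, WS > 0, WS <= WL)
  structure(list(WL = as.integer(WL), WS = as.integer(WS)),
            class = "piv_config")
}

#' Extract the interrogation-window grid
#'
#' Windows of side \code{WL} spaced \code{WS} px, fully inside the image;
#' partial windows at the edges are dropped.  Window centres are reported in
#' 0-based pixel coordinates at \code{start + WL/2}.
#'
#' @param image intensity matrix.
#' @param config a \code{\link{piv_config}}.
#' @return list with \code{nx}, \code{ny} (windows per side), \code{cx},
#'   \code{cy} (centre coordinate vectors, px) and \code{starts_x},
#'   \code{starts_y} (1-based R start indices).
#' @export
extract_windows <- function(image, config) {
  nr <- nrow(image); nc <- ncol(image)
  WL <- config$WL; WS <- config$WS
  if (WL > min(nr, nc)) stop("window size WL exceeds image side")
  nx <- floor((nc - WL) / WS) + 1L
  ny <- floor((nr - WL) / WS) + 1L
  sx <- (seq_len(nx) - 1L) * WS + 1L
  sy <- (seq_len(ny) - 1L) * WS + 1L
  list(nx = nx, ny = ny,
       cx = (sx - 1) + WL / 2, cy = (sy - 1) + WL / 2,
       starts_x = sx, starts_y = sy, WL = WL, WS = WS)
}

#' Circular FFT cross-correlation of an interrogation-window pair
#'
#' Windows are mean-subtracted, then correlated circularly via the FFT.
#' The returned surface is indexed by integer lag with the zero lag at
#' element [1, 1] and wrap-around semantics.
#'
#' @param w_ref,w_session equal-shape window matrices.
#' @return list with the real correlation \code{surface} and a
#'   \code{degenerate} flag (either window constant).
#' @export
cross_correlate <- function(w_ref, w_session) {
  stopifnot(identical(dim(w_ref), dim(w_session)))
  a <- w_session - mean(w_session)
  b <- w_ref - mean(w_ref)
  if (all(a == 0) || all(b == 0))
    return(list(surface = matrix(0, nrow(a), ncol(a)), degenerate = TRUE))
  surf <- Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE)) / length(a)
  list(surface = surf, degenerate = FALSE)
}

#' Sub-pixel peak location by 3-point Gaussian fit
#'
#' Finds the integer peak of the (wrapped) correlation surface and refines
#' each axis with the standard 3-point Gaussian estimator
#' \code{d = (ln Cm - ln Cp) / (2 (ln Cm - 2 ln C0 + ln Cp))}.  If a
#' neighbouring value is non-positive, the integer peak is returned for that
#' axis.
#'
#' @param surface correlation surface from \code{\link{cross_correlate}}.
#' @return list with the displacement \code{u = c(ux, uy)} in px (signed,
#'   wrap-corrected) and the peak value.
#' @export
subpixel_peak <- function(surface) {
  n <- nrow(surface); m <- ncol(surface)
  pk <- arrayInd(which.max(surface), dim(surface))
  pr <- pk[1]; pc <- pk[2]
  c0 <- surface[pr, pc]
  wrap <- function(i, n) ((i - 1) %% n) + 1
  gauss3 <- function(cm, c0, cp) {
    if (cm <= 0 || cp <= 0 || c0 <= 0) return(0)
    den <- log(cm) - 2 * log(c0) + log(cp)
    if (den >= 0) return(0)                      # not a local max in log space
    (log(cm) - log(cp)) / (2 * den)
  }
  dy <- gauss3(surface[wrap(pr - 1, n), pc], c0, surface[wrap(pr + 1, n), pc])
  dx <- gauss3(surface[pr, wrap(pc - 1, m)], c0, surface[pr, wrap(pc + 1, m)])
  # signed integer lags: index 1 is lag 0; indices beyond n/2 wrap negative
  iy <- pr - 1; if (iy > n / 2) iy <- iy - n
  ix <- pc - 1; if (ix > m / 2) ix <- ix - m
  list(u = c(ix + dx, iy + dy), peak = c0)
}

#' Run PIV on an image pair
#'
#' Per-window displacement by circular FFT cross-correlation with 3-point
#' Gaussian sub-pixel refinement.  The sign convention maps reference
#' coordinates to session coordinates (a bead moved by +u gives +u).
#'
#' @param pair an \code{\link{image_pair}}.
#' @param config a \code{\link{piv_config}}.
#' @return object of class \code{deformation_field}: window-centre grids
#'   (px and micrometres), displacement arrays \code{ux}, \code{uy}
#'   (matrices, px), and a \code{degenerate} logical matrix.
#' @export
run_piv <- function(pair, config) {
  stopifnot(inherits(pair, "image_pair"))
  g <- extract_windows(pair$ref, config)
  ux <- uy <- matrix(NA_real_, g$ny, g$nx)
  degen <- matrix(FALSE, g$ny, g$nx)
  for (j in seq_len(g$nx)) {
    cols <- g$starts_x[j]:(g$starts_x[j] + g$WL - 1L)
    for (i in seq_len(g$ny)) {
      rows <- g$starts_y[i]:(g$starts_y[i] + g$WL - 1L)
      cc <- cross_correlate(pair$ref[rows, cols], pair$session[rows, cols])
      if (cc$degenerate) {
        degen[i, j] <- TRUE
        ux[i, j] <- uy[i, j] <- 0
      } else {
        p <- subpixel_peak(cc$surface)
        ux[i, j] <- p$u[1]; uy[i, j] <- p$u[2]
      }
    }
  }
  structure(list(cx = g$cx, cy = g$cy,
                 cx_um = g$cx * pair$pixel_size, cy_um = g$cy * pair$pixel_size,
                 ux = ux, uy = uy, degenerate = degen,
                 WL = g$WL, WS = g$WS, nx = g$nx, ny = g$ny,
                 pixel_size = pair$pixel_size),
            class = "deformation_field")
}
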