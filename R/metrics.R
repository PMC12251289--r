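# Quantitative evaluation of recovered traction fields against ground
# truth: foreground/background decomposition at the true-field RMS
# threshold, summary metrics per method, pointwise traction SNR, and the
# PIV-UQ validation ensembles.

#' Foreground/background partition of the grid
#'
#' Foreground is where the true traction magnitude reaches the RMS of the
#' true field (the threshold); background is the complement.
#'
#' @param tx_true,ty_true true traction component matrices (Pa).
#' @return list with logical \code{fg}, \code{bg} masks and the
#'   \code{threshold} (Pa).
#' @export
foreground_background <- function(tx_true, ty_true) {
  mag <- sqrt(tx_true^2 + ty_true^2)
  thr <- sqrt(mean(mag^2))
  if (thr == 0) {
    warning("all-zero ground truth: empty foreground")
    fg <- mag > 0                      # all FALSE
  } else {
    fg <- mag >= thr
  }
  list(fg = fg, bg = !fg, threshold = thr)
}

#' Benchmark metrics for a recovered traction field
#'
#' RMS vector error against ground truth, RMS of the reported pointwise
#' uncertainty, foreground/background mean and max of the recovered
#' magnitude, and the scalar traction SNR (foreground mean over background
#' mean).  An inverse-variance weighted RMS error is available when the PIV
#' variances are supplied.
#'
#' @param tx_hat,ty_hat recovered traction component matrices (Pa).
#' @param tx_true,ty_true ground truth matrices (Pa).
#' @param sigma_t pointwise uncertainty matrix (Pa) or \code{NULL}.
#' @param weights optional positive weight matrix for the weighted RMS
#'   error (e.g. inverse PIV variance).
#' @return list of class \code{benchmark_metrics}.
#' @export
benchmark_metrics <- function(tx_hat, ty_hat, tx_true, ty_true,
                              sigma_t = NULL, weights = NULL) {
  if (!identical(dim(tx_hat), dim(tx_true)))
    stop("estimate and truth grids differ")
  fb <- foreground_background(tx_true, ty_true)
  err2 <- (tx_hat - tx_true)^2 + (ty_hat - ty_true)^2
  rms_error <- sqrt(mean(err2))
  rms_error_weighted <- if (is.null(weights)) NA_real_ else {
    stopifnot(all(weights > 0))
    sqrt(sum(weights * err2) / sum(weights))
  }
  mag <- sqrt(tx_hat^2 + ty_hat^2)
  fg_mean <- mean(mag[fb$fg]); fg_max <- if (any(fb$fg)) max(mag[fb$fg]) else NA
  bg_mean <- mean(mag[fb$bg]); bg_max <- if (any(fb$bg)) max(mag[fb$bg]) else NA
  structure(list(rms_error = rms_error,
                 rms_error_weighted = rms_error_weighted,
                 rms_sigma_t = if (is.null(sigma_t)) NA_real_
                               else sqrt(mean(sigma_t^2)),
                 fg_mean = fg_mean, fg_max = fg_max,
                 bg_mean = bg_mean, bg_max = bg_max,
                 snr_t = fg_mean / bg_mean,
                 threshold = fb$threshold),
            class = "benchmark_metrics")
}

#' Pointwise traction signal-to-noise map
#'
#' \code{|t_hat| / sigma_t} per grid point.
#'
#' @param tx_hat,ty_hat recovered traction components (Pa).
#' @param sigma_t pointwise posterior standard deviation (Pa), > 0.
#' @return matrix of SNR values.
#' @export
snr_t_map <- function(tx_hat, ty_hat, sigma_t) {
  if (any(sigma_t <= 0)) stop("sigma_t must be strictly positive")
  sqrt(tx_hat^2 + ty_hat^2) / sigma_t
}

#' PIV-UQ validation ensemble
#'
#' Repeats the synthetic image generation \code{N} times per (SNR, WL)
#' condition: the ensemble standard deviation of the nominal PIV estimates
#' (sigma_u,ens, the ground-truth uncertainty) is compared against the
#' per-image bootstrap estimate (sigma_u,PIV).  Returns the per-window
#' scatter and the RMS summary curves.
#'
#' @param image_side image side, px.
#' @param displacement a \code{displacement_spec}.
#' @param snr_list SNR conditions (dB).
#' @param WL_list interrogation window sizes (px).
#' @param N realizations per condition (>= 2).
#' @param density bead density (beads/px^2).
#' @param n_B bootstrap iterations per window.
#' @param seed RNG seed.
#' @param pixel_size micrometres per px (bookkeeping only).
#' @return list with \code{scatter} (data.frame: snr_db, WL, window index,
#'   sigma_ens, sigma_piv) and \code{rms} (data.frame: snr_db, WL,
#'   rms_sigma_ens, rms_sigma_piv).
#' @export
pivuq_validation_suite <- function(image_side = 256,
                                   displacement = displacement_uniform(),
                                   snr_list = c(15, 25, 40),
                                   WL_list = c(32, 64),
                                   N = 8, density = 8e-3, n_B = 30,
                                   seed = 1, pixel_size = 1) {
  stopifnot(N >= 2)
  shape <- c(image_side, image_side)
  scatter <- NULL
  rms <- NULL
  for (WL in WL_list) {
    cfg <- piv_config(WL)
    for (snr in snr_list) {
      ux_all <- uy_all <- sig_piv <- NULL
      for (r in seq_len(N)) {
        set.seed(seed + 7919L * r + 101L * round(snr) + WL)
        beads <- generate_bead_field(shape, density)
        ref <- render_beads(beads, shape)
        moved <- apply_displacement(beads, displacement, shape)
        session <- render_beads(moved, shape)
        pair <- image_pair(add_pixel_noise(ref, snr),
                           add_pixel_noise(session, snr), pixel_size)
        res <- run_piv_uq(pair, cfg, piv_uq_config(n_B = n_B))
        ok <- as.vector(res$uncertainty$valid)
        ux <- as.vector(res$field$ux); ux[!ok] <- NA
        uy <- as.vector(res$field$uy); uy[!ok] <- NA
        s <- as.vector(res$uncertainty$sigma_total); s[!ok] <- NA
        ux_all <- cbind(ux_all, ux)
        uy_all <- cbind(uy_all, uy)
        sig_piv <- cbind(sig_piv, s)
      }
      # ensemble statistics over valid measurements only; windows valid in
      # fewer than half the realizations are dropped (invalidated vectors
      # would otherwise contaminate the ground-truth uncertainty)
      n_ok <- rowSums(!is.na(sig_piv))
      keep <- n_ok >= N / 2
      vr <- function(m) apply(m, 1, stats::var, na.rm = TRUE)
      sd_ens <- sqrt(vr(ux_all) + vr(uy_all))
      sd_ens[!keep] <- NA
      piv_mean <- rowMeans(sig_piv, na.rm = TRUE)
      piv_mean[!keep] <- NA
      scatter <- rbind(scatter, data.frame(
        snr_db = snr, WL = WL, window = seq_along(sd_ens),
        sigma_ens = sd_ens, sigma_piv = piv_mean))
      rms <- rbind(rms, data.frame(
        snr_db = snr, WL = WL,
        rms_sigma_ens = sqrt(mean(sd_ens^2, na.rm = TRUE)),
        rms_sigma_piv = sqrt(mean(sig_piv[keep, ]^2, na.rm = TRUE)),
        valid_fraction = mean(n_ok) / N))
    }
  }
  list(scatter = scatter, rms = rms)
}
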