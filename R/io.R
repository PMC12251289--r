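# File interfaces: 16-bit TIFF image pairs with a JSON sidecar, CSV vector
# fields and metrics, JSON run manifests.  Intensities are stored as counts
# (saturation 1000 a.u. maps to the value 1000 in a 16-bit container).

TIFF_SCALE <- 65535

#' Write an image pair as two 16-bit TIFFs plus a JSON sidecar
#'
#' @param pair an \code{\link{image_pair}}.
#' @param prefix output path prefix; writes \code{<prefix>_ref.tif},
#'   \code{<prefix>_session.tif} and \code{<prefix>.json}.
#' @param meta optional named list merged into the sidecar.
#' @return invisibly, the written file paths.
#' @export
write_image_pair <- function(pair, prefix, meta = list()) {
  stopifnot(inherits(pair, "image_pair"))
  paths <- c(ref = paste0(prefix, "_ref.tif"),
             session = paste0(prefix, "_session.tif"),
             sidecar = paste0(prefix, ".json"))
  tiff::writeTIFF(pair$ref / TIFF_SCALE, paths[["ref"]], bits.per.sample = 16)
  tiff::writeTIFF(pair$session / TIFF_SCALE, paths[["session"]],
                  bits.per.sample = 16)
  side <- c(list(pixel_size_um = pair$pixel_size,
                 shape = dim(pair$ref), saturation_au = 1000), meta)
  jsonlite::write_json(side, paths[["sidecar"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Read an image pair written by \code{\link{write_image_pair}}
#'
#' @param prefix path prefix used when writing.
#' @return an \code{\link{image_pair}}.
#' @export
read_image_pair <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  rd <- function(p) tiff::readTIFF(p) * TIFF_SCALE
  image_pair(rd(paste0(prefix, "_ref.tif")),
             rd(paste0(prefix, "_session.tif")),
             pixel_size = side$pixel_size_um)
}

#' Write a deformation field (with optional uncertainty) as CSV
#'
#' Columns: x_px, y_px, ux_px, uy_px and, when uncertainty is given,
#' sigma_ux_px, sigma_uy_px, valid, angular_sd_rad.  A JSON sidecar records
#' WL, WS and the pixel size.
#'
#' @param field a \code{deformation_field} from \code{\link{run_piv}}.
#' @param path CSV output path (sidecar written next to it).
#' @param uncertainty optional uncertainty list from \code{\link{run_piv_uq}}.
#' @return invisibly, the CSV path.
#' @export
write_deformation_csv <- function(field, path, uncertainty = NULL) {
  grid <- expand.grid(y = seq_along(field$cy), x = seq_along(field$cx))
  df <- data.frame(x_px = field$cx[grid$x], y_px = field$cy[grid$y],
                   ux_px = as.vector(field$ux), uy_px = as.vector(field$uy))
  if (!is.null(uncertainty)) {
    df$sigma_ux_px <- as.vector(uncertainty$sigma_ux)
    df$sigma_uy_px <- as.vector(uncertainty$sigma_uy)
    df$valid <- as.vector(uncertainty$valid)
    df$angular_sd_rad <- as.vector(uncertainty$angular_sd)
  }
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(WL = field$WL, WS = field$WS,
                            pixel_size_um = field$pixel_size),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a traction summary as CSV
#'
#' Columns: x_um, y_um, tx_hat_Pa, ty_hat_Pa and, for Bayesian results,
#' sigma_tx, sigma_ty, sigma_t, angular_sd_rad, snr_t.
#'
#' @param report either a \code{traction_posterior} plus grid info, or a
#'   plain stacked traction vector.
#' @param cx_um,cy_um grid coordinate vectors (micrometres).
#' @param ny,nx grid dimensions.
#' @param path CSV output path.
#' @return invisibly, the path.
#' @export
write_traction_csv <- function(report, cx_um, cy_um, ny, nx, path) {
  nw <- ny * nx
  grid <- expand.grid(y = seq_len(ny), x = seq_len(nx))
  if (inherits(report, "traction_posterior")) {
    df <- data.frame(x_um = cx_um[grid$x], y_um = cy_um[grid$y],
                     tx_hat_Pa = report$t_hat[1:nw],
                     ty_hat_Pa = report$t_hat[nw + 1:nw],
                     sigma_tx = report$sigma_tx, sigma_ty = report$sigma_ty,
                     sigma_t = report$sigma_t,
                     angular_sd_rad = report$angular_sd)
    df$snr_t <- sqrt(df$tx_hat_Pa^2 + df$ty_hat_Pa^2) / df$sigma_t
  } else {
    t_hat <- as.numeric(report)
    df <- data.frame(x_um = cx_um[grid$x], y_um = cy_um[grid$y],
                     tx_hat_Pa = t_hat[1:nw], ty_hat_Pa = t_hat[nw + 1:nw])
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write ground truth (traction + displacement) as CSV
#'
#' Columns: x_um, y_um, tx_Pa, ty_Pa, ux_um, uy_um.
#'
#' @param truth the \code{truth} element of a \code{\link{build_benchmark}}.
#' @param path CSV output path.
#' @return invisibly, the path.
#' @export
write_truth_csv <- function(truth, path) {
  grid <- expand.grid(y = seq_len(truth$ny), x = seq_len(truth$nx))
  df <- data.frame(x_um = truth$cx_um[grid$x], y_um = truth$cy_um[grid$y],
                   tx_Pa = as.vector(truth$tx), ty_Pa = as.vector(truth$ty),
                   ux_um = as.vector(truth$ux), uy_um = as.vector(truth$uy))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write MCMC chains as CSV
#'
#' Hyperparameter chains always; traction draws optionally (they can be
#' large).
#'
#' @param posterior a \code{traction_posterior}.
#' @param prefix output prefix; writes \code{<prefix>_chains.csv} and
#'   optionally \code{<prefix>_draws.csv}.
#' @param draws also write the post-burn-in traction draws.
#' @return invisibly, the written paths.
#' @export
write_chains_csv <- function(posterior, prefix, draws = FALSE) {
  p1 <- paste0(prefix, "_chains.csv")
  utils::write.csv(data.frame(iteration = seq_along(posterior$alpha_chain),
                              alpha = posterior$alpha_chain,
                              beta = posterior$beta_chain),
                   p1, row.names = FALSE)
  out <- p1
  if (draws && !is.null(posterior$draws)) {
    p2 <- paste0(prefix, "_draws.csv")
    utils::write.csv(as.data.frame(posterior$draws), p2, row.names = FALSE)
    out <- c(out, p2)
  }
  invisible(out)
}

#' Run manifest
#'
#' JSON record of seeds, configuration and package version for
#' reproducibility of a pipeline run.
#'
#' @param path output JSON path.
#' @param seed master seed.
#' @param config named list of configuration values.
#' @param extra optional named list of additional entries.
#' @return invisibly, the path.
#' @export
write_manifest <- function(path, seed, config, extra = list()) {
  strip <- function(x) {
    if (is.function(x)) return(NULL)
    if (is.list(x)) return(Filter(Negate(is.null), lapply(x, strip)))
    x
  }
  man <- c(list(package = "tfmuq",
                version = as.character(utils::packageVersion("tfmuq")),
                seed = seed, timestamp = format(Sys.time(), tz = "UTC"),
                config = strip(unclass(config))), extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a run configuration from JSON or YAML
#'
#' @param path configuration file (\code{.json}, \code{.yml} or
#'   \code{.yaml}).
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
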