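# Phase-to-temperature reconstruction.
#
# Classical PRF thermometry subtracts a baseline phase image acquired before
# heating; referenceless thermometry estimates the baseline under the heated
# region by extrapolating a smooth fit to the surrounding (outer ROI) phase,
# so no pre-heating acquisition is needed and slow field drifts common to
# both regions cancel.

temperature_map <- function(delta_T, valid, method, frame, params,
                            n_saturated = 0L) {
  stopifnot(identical(dim(as.array(delta_T)), dim(as.array(valid))))
  if (any(!is.finite(delta_T[valid])))
    stop("delta_T must be finite on the validity mask")
  structure(list(delta_T = delta_T, valid = valid, method = method,
                 frame = frame, params = params,
                 n_saturated = as.integer(n_saturated)),
            class = "temperature_map")
}

#' @export
print.temperature_map <- function(x, ...) {
  rng <- range(x$delta_T[x$valid])
  cat(sprintf("<temperature_map> method=%s frame=%d dT=[%.2f, %.2f] degC (%d valid px)\n",
              x$method, x$frame, rng[1], rng[2], sum(x$valid)))
  invisible(x)
}

#' Classical PRF-shift temperature map
#'
#' Converts the wrap-safe phase difference between a target and a baseline
#' frame into a temperature change via
#' \deqn{\Delta T = \Delta\phi / (2\pi\,\gamma\,\alpha\,10^{-6}\,B_0\,TE),}
#' so that heating (which lowers the proton resonance frequency, alpha < 0)
#' yields positive \eqn{\Delta T}.  Only the principal value of the phase
#' difference is used; pixels whose difference sits at the \eqn{\pm\pi} wrap
#' boundary are counted and reported via a warning, never repaired.
#'
#' @param series an \code{image_series}.
#' @param baseline_frame,target_frame frame indices (1-based).
#' @param params a \code{prf_params}; defaults to the series' TE and B0 with
#'   the standard aqueous-tissue coefficient alpha = -0.01 ppm/degC.
#' @return a \code{temperature_map} valid everywhere, method
#'   \code{"classical_prf"}.
#' @export
classical_prf_map <- function(series, baseline_frame, target_frame,
                              params = NULL) {
  nf <- length(series$frames)
  for (ix in c(baseline_frame, target_frame))
    if (!(ix >= 1 && ix <= nf)) stop(sprintf("frame index %s out of 1..%d", ix, nf))
  if (is.null(params))
    params <- prf_params(field_strength = series$field_strength,
                         echo_time = series$echo_time)
  dphi <- phase_difference(series$frames[[target_frame]]$phase,
                           series$frames[[baseline_frame]]$phase)
  n_sat <- sum(abs(dphi) >= pi * (1 - 1e-9))
  if (n_sat > 0 && target_frame != baseline_frame)
    warning(sprintf("%d pixel(s) at the phase-wrap boundary; principal value passed through",
                    n_sat))
  dT <- dphi / prf_phase_factor(params)
  temperature_map(dT, valid = array(TRUE, dim(as.array(dT))),
                  method = "classical_prf", frame = target_frame,
                  params = params, n_saturated = n_sat)
}

#' Estimate the background phase under a heated region
#'
#' Fits the chosen interpolant to the phase of the outer (unheated) ROI,
#' with pixel coordinates expressed in physical mm, and extrapolates it
#' across the inner (heated) ROI.  For RBF kernels a degree-1 polynomial
#' tail is always attached here — extrapolation across the excised hole
#' must at minimum reproduce an affine background exactly, which a bare
#' Gaussian/multiquadric expansion cannot guarantee.
#'
#' @param phase 2D phase array in radians.
#' @param inner_mask,outer_mask disjoint logical masks; the fit uses
#'   \code{outer_mask} pixels and predicts over both.
#' @param interpolator an RBF kernel name (see \code{\link{fit_rbf}}) or an
#'   integer polynomial degree for a weighted least-squares fit.
#' @param pixel_spacing mm per pixel, length 2.
#' @param weights optional per-pixel weights for the polynomial fit (e.g.
#'   magnitude values); unit weights by default.
#' @param max_nodes,seed,shape_param passed to \code{\link{fit_rbf}}.
#' @param tail_degree polynomial tail degree attached to RBF fits.
#' @return list with \code{estimate} (array, NA outside inner/outer),
#'   \code{model}, \code{outer_residuals} (mean, sd, max_abs at the fit
#'   pixels) and \code{n_nodes_used}.
#' @export
estimate_background_phase <- function(phase, inner_mask, outer_mask,
                                      interpolator = "thin_plate_spline",
                                      pixel_spacing = c(1, 1),
                                      weights = NULL, max_nodes = 500L,
                                      seed = 1L, shape_param = "auto",
                                      tail_degree = 1L) {
  phase <- as.matrix(phase)
  if (!any(inner_mask)) stop("inner mask is empty")
  if (!any(outer_mask)) stop("outer mask is empty")
  if (any(inner_mask & outer_mask)) stop("inner and outer masks must be disjoint")

  to_mm <- function(mask) {
    ij <- which(mask, arr.ind = TRUE)
    cbind((ij[, 1] - 1) * pixel_spacing[1], (ij[, 2] - 1) * pixel_spacing[2])
  }
  Xout <- to_mm(outer_mask)
  f <- phase[outer_mask]

  if (is.character(interpolator)) {
    model <- fit_rbf(Xout, f, kernel = interpolator,
                     shape_param = shape_param, poly_degree = tail_degree,
                     max_nodes = max_nodes, seed = seed)
    predict_at <- function(P) evaluate_rbf(model, P)
  } else {
    degree <- as.integer(interpolator)
    w <- if (is.null(weights)) NULL else weights[outer_mask]
    model <- fit_polynomial_wls(Xout, f, weights = w, degree = degree)
    predict_at <- function(P) evaluate_polynomial(model, P)
  }

  est <- array(NA_real_, dim(phase))
  est[outer_mask] <- predict_at(Xout)
  est[inner_mask] <- predict_at(to_mm(inner_mask))
  res <- est[outer_mask] - f
  list(estimate = est, model = model,
       outer_residuals = list(mean = mean(res), sd = stats::sd(res),
                              max_abs = max(abs(res))),
       n_nodes_used = if (inherits(model, "rbf_model")) nrow(model$centers)
                      else nrow(Xout))
}

#' Referenceless temperature map
#'
#' Reconstructs \eqn{\Delta T} over the inner ROI from the difference
#' between the measured phase and the background phase extrapolated from the
#' outer ROI, converted exactly as in \code{\link{classical_prf_map}} —
#' no baseline acquisition is used.
#'
#' @param series an \code{image_series}.
#' @param target_frame frame index.
#' @param rois a \code{roi_label_map} with \code{inner_roi}/\code{outer_roi}.
#' @param interpolator kernel name or polynomial degree
#'   (see \code{\link{estimate_background_phase}}).
#' @param params a \code{prf_params}, defaulted from the series metadata.
#' @param slice slice index for 3D frames (default 1).
#' @param ... further fit options passed to
#'   \code{\link{estimate_background_phase}}.
#' @return a \code{temperature_map} whose validity mask is the inner ROI;
#'   method \code{"referenceless_rbf_<kernel>"} or
#'   \code{"referenceless_poly"}.
#' @export
referenceless_map <- function(series, target_frame, rois,
                              interpolator = "thin_plate_spline",
                              params = NULL, slice = 1L, ...) {
  nf <- length(series$frames)
  if (!(target_frame >= 1 && target_frame <= nf))
    stop(sprintf("frame index %s out of 1..%d", target_frame, nf))
  if (is.null(params))
    params <- prf_params(field_strength = series$field_strength,
                         echo_time = series$echo_time)
  ph <- series$frames[[target_frame]]$phase
  if (length(dim(as.array(ph))) == 3) ph <- as.array(ph)[, , slice]
  inner <- roi_mask(rois, "inner_roi")
  outer <- roi_mask(rois, "outer_roi")
  bg <- estimate_background_phase(ph, inner, outer,
                                  interpolator = interpolator,
                                  pixel_spacing = series$pixel_spacing[1:2],
                                  ...)
  dphi <- array(0, dim(as.matrix(ph)))
  dphi[inner] <- Arg(exp(1i * (ph[inner] - bg$estimate[inner])))
  dT <- array(NA_real_, dim(dphi))
  dT[inner] <- dphi[inner] / prf_phase_factor(params)
  method <- if (is.character(interpolator))
    paste0("referenceless_rbf_", interpolator) else "referenceless_poly"
  out <- temperature_map(dT, valid = inner, method = method,
                         frame = target_frame, params = params)
  out$background <- bg
  out
}

#' Single-pixel and neighbourhood temperature curves
#'
#' The console-style temperature plot: the \eqn{\Delta T} time course of one
#' pixel and of the mean over a small disc around it, sampled at the frame
#' interval.  Samples where the pixel (or the whole disc) falls outside a
#' map's validity mask are returned as \code{NA} and flagged, never as
#' silent zeros.
#'
#' @param maps list of \code{temperature_map}s in frame order.
#' @param point integer c(row, col), 1-based.
#' @param neighborhood_radius radius in pixels of the averaging disc
#'   (0 = single pixel).
#' @param frame_interval seconds between maps (default 3).
#' @return data.frame with \code{time_s}, \code{pixel_deltaT},
#'   \code{neighborhood_deltaT}, \code{pixel_valid}.
#' @export
temperature_curves <- function(maps, point, neighborhood_radius = 0,
                               frame_interval = 3) {
  shp <- dim(as.array(maps[[1]]$delta_T))
  if (point[1] < 1 || point[1] > shp[1] || point[2] < 1 || point[2] > shp[2])
    stop("point outside the map grid")
  rr <- seq_len(shp[1]); cc <- seq_len(shp[2])
  disc <- outer(rr - point[1], cc - point[2],
                function(a, b) sqrt(a^2 + b^2)) <= neighborhood_radius
  out <- data.frame(time_s = (seq_along(maps) - 1) * frame_interval,
                    pixel_deltaT = NA_real_, neighborhood_deltaT = NA_real_,
                    pixel_valid = FALSE)
  for (k in seq_along(maps)) {
    m <- maps[[k]]
    v <- m$valid
    if (isTRUE(v[point[1], point[2]])) {
      out$pixel_deltaT[k] <- m$delta_T[point[1], point[2]]
      out$pixel_valid[k] <- TRUE
    }
    sel <- disc & v
    if (any(sel)) out$neighborhood_deltaT[k] <- mean(m$delta_T[sel])
  }
  out
}

#' Write a temperature map as NIfTI with a JSON sidecar
#'
#' @param map a \code{temperature_map}.
#' @param path_prefix output path without extension; writes
#'   \code{<prefix>.nii} (delta-T, NA outside validity set to 0 with the
#'   mask in \code{<prefix>_valid.nii}) and \code{<prefix>.json}.
#' @return \code{path_prefix}, invisibly.
#' @export
write_temperature_map <- function(map, path_prefix) {
  dT <- map$delta_T
  dT[!map$valid] <- 0
  RNifti::writeNifti(RNifti::asNifti(dT), paste0(path_prefix, ".nii"))
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(map$valid), dim(as.array(map$valid)))),
                     paste0(path_prefix, "_valid.nii"))
  jsonlite::write_json(list(method = map$method, frame = map$frame,
                            n_saturated = map$n_saturated,
                            params = unclass(map$params)),
                       paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path_prefix)
}
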