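#' Construct a multi-frame magnitude + phase image series
#'
#' The central container for thermometry input: a time-ordered list of
#' complex-valued MR acquisitions stored as magnitude and wrapped phase,
#' together with the acquisition metadata needed for the PRF conversion.
#'
#' @param frames list of frames; each frame is a list with elements
#'   \code{magnitude} (nonnegative array) and \code{phase} (radians in
#'   \eqn{(-\pi, \pi]}), all congruent in shape (2D matrices or 3D arrays).
#' @param frame_interval seconds between successive frames (> 0).
#' @param echo_time gradient-echo TE in seconds (> 0).
#' @param field_strength main field B0 in tesla (> 0).
#' @param pixel_spacing in-plane pixel spacing in mm, length 2 (row, column),
#'   or length 3 when frames are 3D.
#' @param slice_locations optional slice positions in mm (3D frames).
#' @return an object of class \code{image_series}.
#' @export
image_series <- function(frames, frame_interval = 3, echo_time = 0.01,
                         field_strength = 1.5, pixel_spacing = c(1, 1),
                         slice_locations = NULL) {
  if (!is.list(frames) || length(frames) < 1)
    stop("`frames` must be a nonempty list")
  shp <- dim(as.array(frames[[1]]$magnitude))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    if (is.null(fr$magnitude) || is.null(fr$phase))
      stop(sprintf("frame %d lacks magnitude or phase", k))
    if (!identical(dim(as.array(fr$magnitude)), shp) ||
        !identical(dim(as.array(fr$phase)), shp))
      stop(sprintf("frame %d shape differs from frame 1", k))
    if (any(fr$magnitude < 0))
      stop(sprintf("frame %d: magnitude must be nonnegative", k))
    ph <- fr$phase
    if (any(ph <= -pi - 1e-9) || any(ph > pi + 1e-9))
      stop(sprintf("frame %d: phase outside (-pi, pi]", k))
  }
  if (!(frame_interval > 0)) stop("frame_interval must be > 0")
  if (!(echo_time > 0)) stop("echo_time must be > 0")
  if (!(field_strength > 0)) stop("field_strength must be > 0")
  if (any(pixel_spacing <= 0)) stop("pixel_spacing must be > 0")
  structure(list(frames = frames, frame_interval = frame_interval,
                 echo_time = echo_time, field_strength = field_strength,
                 pixel_spacing = pixel_spacing,
                 slice_locations = slice_locations),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  shp <- dim(as.array(x$frames[[1]]$magnitude))
  cat(sprintf("<image_series> %d frame(s), %s px, dt=%gs, TE=%gs, B0=%gT\n",
              length(x$frames), paste(shp, collapse = "x"),
              x$frame_interval, x$echo_time, x$field_strength))
  invisible(x)
}

#' Number of frames in a series
#' @param series an \code{image_series}.
#' @export
n_frames <- function(series) length(series$frames)

#' PRF conversion parameters
#'
#' Holds the constants of the proton-resonance-frequency shift model
#' \eqn{\Delta\phi = 2\pi \gamma \alpha B_0 TE \, \Delta T}: the thermal
#' coefficient alpha (ppm/degC, negative for aqueous tissue), the
#' gyromagnetic ratio gamma (Hz/T), the field strength (T) and the echo
#' time (s).
#'
#' @param alpha PRF thermal coefficient in ppm per degC; must be nonzero.
#' @param gamma gyromagnetic ratio in Hz per tesla.
#' @param field_strength tesla.
#' @param echo_time seconds.
#' @return object of class \code{prf_params}.
#' @export
prf_params <- function(alpha = -0.01, gamma = 42.576e6,
                       field_strength = 1.5, echo_time = 0.01) {
  if (alpha == 0) stop("alpha must be nonzero")
  if (!(gamma > 0)) stop("gamma must be > 0")
  if (!(field_strength > 0)) stop("field_strength must be > 0")
  if (!(echo_time > 0)) stop("echo_time must be > 0")
  structure(list(alpha = alpha, gamma = gamma,
                 field_strength = field_strength, echo_time = echo_time),
            class = "prf_params")
}

# radians of phase per degC of temperature change (negative for alpha < 0)
prf_phase_factor <- function(params) {
  2 * pi * params$gamma * params$alpha * 1e-6 *
    params$field_strength * params$echo_time
}

#' Wrap-safe phase subtraction
#'
#' Principal value of \code{phase_a - phase_b}, computed through the angle of
#' the complex ratio so that adding any multiple of \eqn{2\pi} to either
#' input leaves the result unchanged.  Output lies in \eqn{(-\pi, \pi]}.
#'
#' @param phase_a,phase_b congruent arrays of phase in radians.
#' @return array of the same shape.
#' @export
phase_difference <- function(phase_a, phase_b) {
  if (!identical(dim(as.array(phase_a)), dim(as.array(phase_b))))
    stop("phase arrays must have identical shapes")
  out <- Arg(exp(1i * (phase_a - phase_b)))
  dim(out) <- dim(phase_a)
  out
}

#' ROI label map for phantom thermometry
#'
#' An integer label image identifying the physical regions (phantom, skin
#' interface, gel pad; 0 = background) plus the named masks used by the
#' referenceless and SNR estimators: \code{inner_roi} (heated region),
#' \code{outer_roi} (surrounding baseline annulus) and \code{background_roi}
#' (pure-noise region for SNR).
#'
#' @param labels integer matrix/array of region codes.
#' @param codes named integer vector mapping region names to codes; must
#'   include \code{background}.
#' @param inner_roi,outer_roi,background_roi logical masks congruent with
#'   \code{labels}; \code{inner_roi} and \code{outer_roi} must be disjoint.
#' @return object of class \code{roi_label_map}.
#' @export
roi_label_map <- function(labels,
                          codes = c(background = 0L, phantom = 1L,
                                    skin_interface = 2L, gel_pad = 3L),
                          inner_roi = NULL, outer_roi = NULL,
                          background_roi = NULL) {
  labels <- as.array(labels)
  storage.mode(labels) <- "integer"
  if (is.null(names(codes)) || !"background" %in% names(codes))
    stop("`codes` must be a named vector including 'background'")
  for (nm in c("inner_roi", "outer_roi", "background_roi")) {
    m <- get(nm)
    if (!is.null(m) && !identical(dim(as.array(m)), dim(labels)))
      stop(sprintf("%s shape differs from label image", nm))
  }
  if (!is.null(inner_roi) && !is.null(outer_roi) &&
      any(inner_roi & outer_roi))
    stop("inner_roi and outer_roi must be disjoint")
  bg <- labels == codes[["background"]]
  for (nm in setdiff(names(codes), "background")) {
    if (any(bg & labels == codes[[nm]]))
      stop("background label overlaps an object label")  # unreachable w/ ints
  }
  structure(list(labels = labels, codes = codes, inner_roi = inner_roi,
                 outer_roi = outer_roi, background_roi = background_roi),
            class = "roi_label_map")
}

#' Extract a named mask from an ROI label map
#'
#' @param rois a \code{roi_label_map}.
#' @param name a region name in the code registry, or one of
#'   \code{"inner_roi"}, \code{"outer_roi"}, \code{"background_roi"}.
#' @return logical mask; an error if the mask is absent or empty.
#' @export
roi_mask <- function(rois, name) {
  if (name %in% c("inner_roi", "outer_roi", "background_roi")) {
    m <- rois[[name]]
    if (is.null(m)) stop(sprintf("mask '%s' is not defined", name))
  } else {
    if (!name %in% names(rois$codes))
      stop(sprintf("unknown region '%s'; known: %s", name,
                   paste(names(rois$codes), collapse = ", ")))
    m <- rois$labels == rois$codes[[name]]
  }
  if (!any(m)) stop(sprintf("mask '%s' is empty", name))
  m
}

#' Write an image series to a directory of NIfTI volumes
#'
#' Writes \code{magnitude.nii}, \code{phase.nii} (row x column x frame, or
#' row x column x slice x frame for 3D series) and a \code{meta.json}
#' sidecar carrying the timing and geometry metadata.
#'
#' @param series an \code{image_series}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nf <- length(series$frames)
  shp <- dim(as.array(series$frames[[1]]$magnitude))
  mag <- array(0, c(shp, nf)); ph <- array(0, c(shp, nf))
  idx <- slice.index(mag, length(dim(mag)))
  for (k in seq_len(nf)) {
    mag[idx == k] <- series$frames[[k]]$magnitude
    ph[idx == k] <- series$frames[[k]]$phase
  }
  pd <- c(series$pixel_spacing, rep(1, length(dim(mag)) - length(series$pixel_spacing)))
  magn <- RNifti::asNifti(mag); RNifti::pixdim(magn) <- pd
  phn <- RNifti::asNifti(ph); RNifti::pixdim(phn) <- pd
  RNifti::writeNifti(magn, file.path(dir, "magnitude.nii"))
  RNifti::writeNifti(phn, file.path(dir, "phase.nii"))
  meta <- list(frame_interval = series$frame_interval,
               echo_time = series$echo_time,
               field_strength = series$field_strength,
               pixel_spacing = series$pixel_spacing,
               slice_locations = series$slice_locations,
               n_frames = nf)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load an image series from NIfTI volumes
#'
#' Reads a series written by \code{\link{write_series}}, or any pair of
#' congruent NIfTI volumes whose last dimension indexes frames.  In the
#' \code{"real-imaginary"} layout the two volumes are interpreted as the
#' real and imaginary channels and converted to magnitude + wrapped phase.
#' Missing \code{frame_interval} metadata falls back to the 3 s frame
#' spacing typical of thermometry protocols, with a message.
#'
#' @param source a directory containing \code{magnitude.nii}/\code{phase.nii}
#'   (or \code{real.nii}/\code{imaginary.nii}) and optionally
#'   \code{meta.json}; or a named list of two file paths with names matching
#'   the layout.
#' @param layout \code{"phase-magnitude"} or \code{"real-imaginary"}.
#' @param echo_time,field_strength used when absent from the sidecar.
#' @return an \code{image_series}.
#' @export
load_series <- function(source, layout = c("phase-magnitude", "real-imaginary"),
                        echo_time = 0.01, field_strength = 1.5) {
  layout <- match.arg(layout)
  wanted <- if (layout == "phase-magnitude") c("magnitude", "phase")
            else c("real", "imaginary")
  meta <- NULL
  if (is.character(source) && length(source) == 1 && dir.exists(source)) {
    paths <- file.path(source, paste0(wanted, ".nii"))
    names(paths) <- wanted
    mj <- file.path(source, "meta.json")
    if (file.exists(mj)) meta <- jsonlite::read_json(mj, simplifyVector = TRUE)
  } else if (is.list(source)) {
    if (!all(wanted %in% names(source)))
      stop(sprintf("source list must have elements: %s",
                   paste(wanted, collapse = ", ")))
    paths <- unlist(source[wanted])
  } else stop("`source` must be a directory or a named list of file paths")
  miss <- wanted[!file.exists(paths)]
  if (length(miss))
    stop(sprintf("missing input volume(s): %s", paste(miss, collapse = ", ")))

  a <- as.array(RNifti::readNifti(paths[[1]]))
  b <- as.array(RNifti::readNifti(paths[[2]]))
  if (!identical(dim(a), dim(b)))
    stop("mixed geometries: the two volumes differ in shape")
  pixdim <- RNifti::pixdim(RNifti::readNifti(paths[[1]]))

  if (layout == "phase-magnitude") {
    mag <- a; ph <- b
    if (any(ph <= -pi - 1e-6) || any(ph > pi + 1e-6))
      stop("contradictory metadata: phase volume not in radians (-pi, pi]")
  } else {
    mag <- sqrt(a^2 + b^2)
    ph <- atan2(b, a)
    ph[ph <= -pi] <- pi
  }

  nd <- length(dim(mag))
  nf <- dim(mag)[nd]
  shp <- dim(mag)[-nd]
  idx <- slice.index(mag, nd)
  frames <- lapply(seq_len(nf), function(k) {
    m <- mag[idx == k]; p <- ph[idx == k]
    dim(m) <- shp; dim(p) <- shp
    list(magnitude = m, phase = p)
  })

  fi <- meta$frame_interval
  if (is.null(fi)) {
    message("frame_interval metadata absent; defaulting to 3 s")
    fi <- 3
  }
  spacing <- meta$pixel_spacing
  if (is.null(spacing)) spacing <- pixdim[seq_len(min(2, length(pixdim)))]
  if (!is.null(meta$pixel_spacing) &&
      any(abs(pixdim[seq_along(meta$pixel_spacing)] - meta$pixel_spacing) > 1e-4))
    stop("contradictory metadata: pixel_spacing in meta.json disagrees with NIfTI pixdim")
  image_series(frames,
               frame_interval = fi,
               echo_time = if (!is.null(meta$echo_time)) meta$echo_time else echo_time,
               field_strength = if (!is.null(meta$field_strength)) meta$field_strength else field_strength,
               pixel_spacing = spacing,
               slice_locations = meta$slice_locations)
}
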