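# Synthetic phantom and sonication generators.
#
# Emulates the bench setup used for focused-ultrasound safety experiments:
# a cylindrical tissue-mimicking phantom (105 mm diameter) resting on a thin
# skin layer over a gel pad, imaged as 16 mm slabs in 3 s temporal frames,
# with complex Gaussian acquisition noise (Rician magnitude, noisy phase)
# and a Gaussian focal hot spot whose temporal envelope follows the
# sonication schedule (~20 s heating, 85 s cooling).  Every generator is
# seed-deterministic and stores its ground truth for recovery testing.

#' Phantom simulation configuration
#'
#' Defaults reproduce the bench geometry: a 105 mm diameter phantom over a
#' thin skin layer and gel pad, 16 mm slab, 1 mm pixels on a 128x128 grid,
#' 3 s frames.  Region amplitudes (phantom 20, skin 3, gel 2 against unit
#' complex-noise sd) put the phantom around SNR 20 and the skin/gel layers
#' at SNR 2-4, matching the qualitative low-signal interface regime.
#'
#' @param diameter_mm phantom diameter.
#' @param skin_thickness_mm,gel_thickness_mm layer thicknesses below the
#'   phantom.
#' @param slab_thickness_mm acquisition slab thickness.
#' @param n_slices slices per slab (1 = 2D).
#' @param pixel_spacing_mm isotropic in-plane spacing.
#' @param matrix_size image matrix (square).
#' @param amp_phantom,amp_skin,amp_gel region signal amplitudes (a.u.).
#' @param noise_sd per-component complex Gaussian noise sd (> 0).
#' @param frame_interval_s seconds between frames.
#' @param echo_time_s,field_strength_T acquisition parameters for the PRF
#'   phase model.
#' @param bg_phase_coef background-phase coefficients in mm coordinates:
#'   length 3 affine \code{c(c0, c_row, c_col)} or length 6 quadratic
#'   \code{c(c0, c_row, c_col, c_rr, c_rc, c_cc)}.
#' @param phase_drift_rad_s spatially uniform linear phase drift.
#' @return object of class \code{phantom_config}.
#' @export
phantom_config <- function(diameter_mm = 105, skin_thickness_mm = 4,
                           gel_thickness_mm = 10, slab_thickness_mm = 16,
                           n_slices = 1L, pixel_spacing_mm = 1,
                           matrix_size = 128L, amp_phantom = 20,
                           amp_skin = 3, amp_gel = 2, noise_sd = 1,
                           frame_interval_s = 3, echo_time_s = 0.01,
                           field_strength_T = 1.5,
                           bg_phase_coef = c(0.1, 0.003, -0.002),
                           phase_drift_rad_s = 0) {
  geom <- c(diameter_mm, skin_thickness_mm, gel_thickness_mm,
            slab_thickness_mm, pixel_spacing_mm, matrix_size,
            frame_interval_s, echo_time_s, field_strength_T)
  if (any(geom <= 0)) stop("geometric and timing quantities must be > 0")
  if (any(c(amp_phantom, amp_skin, amp_gel) < 0))
    stop("amplitudes must be >= 0")
  if (!(noise_sd > 0)) stop("noise_sd must be > 0")
  if (!length(bg_phase_coef) %in% c(3, 6))
    stop("bg_phase_coef must have length 3 (affine) or 6 (quadratic)")
  structure(as.list(environment()), class = "phantom_config")
}

# region masks + mm coordinate grids for a config; phantom disc sits above
# horizontal skin and gel strips
phantom_geometry <- function(config) {
  n <- config$matrix_size
  sp <- config$pixel_spacing_mm
  rr <- matrix((seq_len(n) - 1) * sp, n, n)
  cc <- matrix((seq_len(n) - 1) * sp, n, n, byrow = TRUE)
  R <- config$diameter_mm / 2
  margin <- 4 * sp
  center <- c(margin + R, (n - 1) * sp / 2)
  dist_c <- sqrt((rr - center[1])^2 + (cc - center[2])^2)
  phantom <- dist_c <= R
  skin_top <- center[1] + R
  skin <- rr > skin_top & rr <= skin_top + config$skin_thickness_mm & !phantom
  gel <- rr > skin_top + config$skin_thickness_mm &
    rr <= skin_top + config$skin_thickness_mm + config$gel_thickness_mm & !phantom
  labels <- matrix(0L, n, n)
  labels[phantom] <- 1L; labels[skin] <- 2L; labels[gel] <- 3L
  # pure-noise corner rectangle for SNR, clear of all object labels
  bg_roi <- matrix(FALSE, n, n)
  k <- max(2L, round(16 / sp))
  bg_roi[seq_len(k), seq_len(k)] <- TRUE
  bg_roi <- bg_roi & labels == 0L
  list(rr = rr, cc = cc, labels = labels, center = center,
       background_roi = bg_roi)
}

bg_phase_field <- function(config, geom) {
  co <- config$bg_phase_coef
  ph <- co[1] + co[2] * geom$rr + co[3] * geom$cc
  if (length(co) == 6)
    ph <- ph + co[4] * geom$rr^2 + co[5] * geom$rr * geom$cc + co[6] * geom$cc^2
  ph
}

#' Generate a sonication schedule
#'
#' Durations and energies are drawn from truncated-positive normal
#' distributions with the stated moments; cooling is fixed.  Defaults match
#' a full treatment: 56 sonications of 20.0 +/- 2.9 s and 2353 +/- 611 J
#' with 85 s cooling.  Focus positions are drawn uniformly in a disc of
#' radius \code{focus_radius_mm} around the origin (relative mm).
#'
#' @param n number of sonications.
#' @param mean_duration,sd_duration heating duration moments (s).
#' @param cooling cooling interval (s).
#' @param mean_energy,sd_energy energy moments (J).
#' @param focus_radius_mm radius of the treated region for focus draws.
#' @param start start time of the first sonication (s).
#' @param seed integer seed.
#' @return data.frame of class \code{sonication_schedule} with columns
#'   \code{sonication, start_s, heat_s, cool_s, energy_J, focus_row_mm,
#'   focus_col_mm}.
#' @export
gen_sonication_schedule <- function(n = 56L, mean_duration = 20,
                                    sd_duration = 2.9, cooling = 85,
                                    mean_energy = 2353, sd_energy = 611,
                                    focus_radius_mm = 20, start = 0,
                                    seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  if (mean_duration <= 0 || mean_energy <= 0) stop("means must be positive")
  if (sd_duration < 0 || sd_energy < 0) stop("sds must be >= 0")
  with_seed(seed, {
    heat <- rnorm_pos(n, mean_duration, sd_duration)
    energy <- rnorm_pos(n, mean_energy, sd_energy)
    th <- runif(n, 0, 2 * pi)
    rad <- focus_radius_mm * sqrt(runif(n))
    starts <- start + c(0, cumsum(head(heat, -1) + cooling))
    out <- data.frame(sonication = seq_len(n), start_s = starts,
                      heat_s = heat, cool_s = rep(cooling, n),
                      energy_J = energy,
                      focus_row_mm = rad * cos(th),
                      focus_col_mm = rad * sin(th))
    class(out) <- c("sonication_schedule", "data.frame")
    out
  })
}

#' Gaussian focal hot-spot field
#'
#' Isotropic Gaussian temperature-rise field
#' \eqn{\Delta T(x) = peak \cdot \exp(-\|x - center\|^2 / 2\sigma^2)} on the
#' pixel grid (mm coordinates).
#'
#' @param matrix_size square grid size in pixels.
#' @param center_mm c(row, col) of the peak, in mm.
#' @param sigma_mm Gaussian width (> 0).
#' @param peak_deltaT peak temperature rise in degC.
#' @param pixel_spacing_mm mm per pixel.
#' @return matrix of \eqn{\Delta T} values.
#' @export
gen_hotspot_field <- function(matrix_size, center_mm, sigma_mm, peak_deltaT,
                              pixel_spacing_mm = 1) {
  if (!(sigma_mm > 0)) stop("sigma_mm must be > 0")
  extent <- (matrix_size - 1) * pixel_spacing_mm
  if (any(center_mm < 0) || any(center_mm > extent))
    stop("hot-spot center outside the grid")
  ax <- (seq_len(matrix_size) - 1) * pixel_spacing_mm
  rr <- matrix(ax, matrix_size, matrix_size)
  cc <- matrix(ax, matrix_size, matrix_size, byrow = TRUE)
  d2 <- (rr - center_mm[1])^2 + (cc - center_mm[2])^2
  peak_deltaT * exp(-d2 / (2 * sigma_mm^2))
}

# temporal amplitude envelope of a hot spot across frames
hotspot_envelope <- function(hotspot, times, heat_s, cool_s) {
  mode <- if (!is.null(hotspot$mode)) hotspot$mode else "envelope"
  if (!is.null(hotspot$amp_per_frame)) return(hotspot$amp_per_frame)
  if (mode == "static") {
    amp <- rep(hotspot$peak_deltaT, length(times))
    amp[1] <- 0  # first frame is an unheated baseline
    return(amp)
  }
  tr <- if (!is.null(hotspot$tau_rise)) hotspot$tau_rise else 10
  td <- if (!is.null(hotspot$tau_decay)) hotspot$tau_decay else 25
  amp <- numeric(length(times))
  heating <- times > 0 & times <= heat_s
  amp[heating] <- hotspot$peak_deltaT * (1 - exp(-times[heating] / tr))
  peak_reached <- hotspot$peak_deltaT * (1 - exp(-heat_s / tr))
  after <- times > heat_s
  amp[after] <- peak_reached * exp(-(times[after] - heat_s) / td)
  amp
}

#' Generate a synthetic phantom image series with ground truth
#'
#' Per frame, the noiseless complex image is
#' \code{amplitude * exp(i * (background_phase + drift*t + prf_phase(dT)))};
#' independent Gaussian noise of sd \code{config$noise_sd} is added to the
#' real and imaginary channels, and magnitude/wrapped phase are extracted.
#' The returned truth record stores the background phase field, the
#' \eqn{\Delta T} field of every frame, the drift rate and the noise sd, so
#' every downstream error metric can be computed without re-generation.
#'
#' @param config a \code{phantom_config}.
#' @param n_frames number of temporal frames (frame 1 is unheated).
#' @param hotspot \code{NULL} for an unheated phantom, or a list with
#'   \code{center_mm} (c(row, col), must fall inside the phantom),
#'   \code{sigma_mm}, \code{peak_deltaT} and optionally \code{mode}
#'   (\code{"envelope"} heat/cool dynamics or \code{"static"}),
#'   \code{tau_rise}, \code{tau_decay}, or an explicit \code{amp_per_frame}.
#' @param schedule optional \code{sonication_schedule}; its first entry
#'   sets the heating/cooling windows of the envelope (defaults 20 s / 85 s).
#' @param noiseless set \code{TRUE} to skip the noise draw.
#' @param seed integer seed.
#' @return list with \code{series} (\code{image_series}), \code{rois}
#'   (\code{roi_label_map} with inner/outer/background ROIs) and
#'   \code{truth} (background phase, per-frame \code{deltaT} fields,
#'   envelope amplitudes, noise sd, PRF params).
#' @export
gen_phantom_series <- function(config = phantom_config(), n_frames = 10L,
                               hotspot = NULL, schedule = NULL,
                               noiseless = FALSE, seed = 1L) {
  geom <- phantom_geometry(config)
  n <- config$matrix_size
  sp <- config$pixel_spacing_mm
  amp <- matrix(0, n, n)
  amp[geom$labels == 1L] <- config$amp_phantom
  amp[geom$labels == 2L] <- config$amp_skin
  amp[geom$labels == 3L] <- config$amp_gel
  bg <- bg_phase_field(config, geom)
  params <- prf_params(field_strength = config$field_strength_T,
                       echo_time = config$echo_time_s)
  fac <- prf_phase_factor(params)
  times <- (seq_len(n_frames) - 1) * config$frame_interval_s

  heat_s <- 20; cool_s <- 85
  if (!is.null(schedule)) {
    heat_s <- schedule$heat_s[1]; cool_s <- schedule$cool_s[1]
  }

  roi_center <- geom$center; roi_radius <- 16
  unit_field <- NULL; amps <- rep(0, n_frames)
  if (!is.null(hotspot)) {
    ctr_px <- round(hotspot$center_mm / sp) + 1
    inside <- ctr_px[1] >= 1 && ctr_px[1] <= n && ctr_px[2] >= 1 &&
      ctr_px[2] <= n && geom$labels[ctr_px[1], ctr_px[2]] == 1L
    if (!inside) stop("hot spot centered outside the phantom region")
    unit_field <- gen_hotspot_field(n, hotspot$center_mm, hotspot$sigma_mm,
                                    1, sp)
    amps <- hotspot_envelope(hotspot, times, heat_s, cool_s)
    roi_center <- hotspot$center_mm
    roi_radius <- 3.5 * hotspot$sigma_mm
  }

  # inner ROI: heated disc dilated by 2 px; outer: annulus 8 px wide
  dist_roi <- sqrt((geom$rr - roi_center[1])^2 + (geom$cc - roi_center[2])^2)
  inner <- dist_roi <= roi_radius + 2 * sp
  outer <- dist_roi > roi_radius + 2 * sp & dist_roi <= roi_radius + 10 * sp
  rois <- roi_label_map(geom$labels, inner_roi = inner, outer_roi = outer,
                        background_roi = geom$background_roi)

  deltaT <- vector("list", n_frames)
  frames <- with_seed(seed, lapply(seq_len(n_frames), function(k) {
    dT <- if (is.null(unit_field)) matrix(0, n, n) else unit_field * amps[k]
    ph <- bg + config$phase_drift_rad_s * times[k] + fac * dT
    z <- amp * exp(1i * ph)
    if (!noiseless)
      z <- z + complex(real = rnorm(n * n, 0, config$noise_sd),
                       imaginary = rnorm(n * n, 0, config$noise_sd))
    deltaT[[k]] <<- dT
    list(magnitude = matrix(Mod(z), n, n), phase = matrix(Arg(z), n, n))
  }))

  series <- image_series(frames, frame_interval = config$frame_interval_s,
                         echo_time = config$echo_time_s,
                         field_strength = config$field_strength_T,
                         pixel_spacing = rep(sp, 2))
  list(series = series, rois = rois,
       truth = list(background_phase = bg, deltaT = deltaT,
                    envelope = amps, times = times,
                    noise_sd = if (noiseless) 0 else config$noise_sd,
                    drift_rad_s = config$phase_drift_rad_s,
                    params = params))
}

#' Simulate interferometric probe temperature time series
#'
#' Two optical probes sampled at \code{sample_rate} Hz: during each
#' sonication's heating window the temperature rises toward a per-probe,
#' per-sonication asymptote as \eqn{A(1 - e^{-t/\tau_r})} and decays as
#' \eqn{e^{-t/\tau_d}} afterwards, superposed across sonications on the
#' ambient level, plus Gaussian measurement noise.  The asymptote scales
#' with sonication energy and a seeded per-sonication coupling factor;
#' probe 1 (under the treated region centre) receives the larger gain.
#'
#' @param schedule a \code{sonication_schedule}.
#' @param gains length-2 per-probe temperature gains in degC (probe 1 first;
#'   defaults keep gain 1 > gain 2).
#' @param tau_rise,tau_decay exponential time constants (s, > 0).
#' @param ambient baseline temperature (degC).
#' @param noise_sd measurement noise sd (degC).
#' @param coupling_cv coefficient of variation of the per-sonication
#'   coupling factor (shared by both probes).
#' @param sample_rate samples per second (>= 1).
#' @param seed integer seed.
#' @return list of two data.frames (\code{probe_id, time_s, temp_C}) of
#'   class \code{sonication_timeseries}, with the schedule attached as an
#'   attribute.
#' @export
gen_probe_timeseries <- function(schedule, gains = c(8, 3), tau_rise = 8,
                                 tau_decay = 30, ambient = 20,
                                 noise_sd = 0.05, coupling_cv = 0.3,
                                 sample_rate = 1, seed = 1L) {
  if (length(gains) != 2 || any(gains < 0)) stop("two nonnegative gains required")
  if (tau_rise <= 0 || tau_decay <= 0) stop("time constants must be > 0")
  if (sample_rate < 1) stop("sample_rate must be >= 1 Hz")
  ns <- nrow(schedule)
  t_end <- schedule$start_s[ns] + schedule$heat_s[ns] + schedule$cool_s[ns]
  tt <- seq(0, ceiling(t_end * sample_rate) / sample_rate, by = 1 / sample_rate)
  with_seed(seed, {
    coupling <- rnorm_pos(ns, 1, coupling_cv)
    erel <- schedule$energy_J / mean(schedule$energy_J)
    out <- lapply(1:2, function(k) {
      temp <- rep(ambient, length(tt))
      for (s in seq_len(ns)) {
        A <- gains[k] * erel[s] * coupling[s]
        t0 <- schedule$start_s[s]; D <- schedule$heat_s[s]
        rel <- tt - t0
        heating <- rel > 0 & rel <= D
        temp[heating] <- temp[heating] + A * (1 - exp(-rel[heating] / tau_rise))
        peak <- A * (1 - exp(-D / tau_rise))
        after <- rel > D
        temp[after] <- temp[after] + peak * exp(-(rel[after] - D) / tau_decay)
      }
      if (noise_sd > 0) temp <- temp + rnorm(length(tt), 0, noise_sd)
      df <- data.frame(probe_id = k, time_s = tt, temp_C = temp)
      class(df) <- c("sonication_timeseries", "data.frame")
      df
    })
    attr(out, "schedule") <- schedule
    out
  })
}
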