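test_that("classical map is zero at the baseline and inverts the forward model", {
  sim <- gen_phantom_series(small_config(), n_frames = 3,
                            hotspot = small_hotspot(), noiseless = TRUE,
                            seed = 1)
  m0 <- classical_prf_map(sim$series, 1, 1)
  expect_true(all(m0$delta_T == 0))
  m <- classical_prf_map(sim$series, 1, 2)
  expect_lt(max(abs(m$delta_T - sim$truth$deltaT[[2]])), 1e-6)
  expect_error(classical_prf_map(sim$series, 1, 99), "frame index")
})

test_that("delta-T is invariant to TE rescaling with compensated phase", {
  # doubling TE doubles the phase per degree; the conversion must cancel it
  dT <- gen_hotspot_field(32, c(15, 15), 5, 10, 1)
  mk <- function(te) {
    par <- prf_params(echo_time = te)
    fac <- fustherm:::prf_phase_factor(par)
    frames <- list(list(magnitude = matrix(1, 32, 32),
                        phase = matrix(0, 32, 32)),
                   list(magnitude = matrix(1, 32, 32),
                        phase = Arg(exp(1i * fac * dT))))
    classical_prf_map(image_series(frames, echo_time = te), 1, 2)
  }
  expect_equal(mk(0.01)$delta_T, mk(0.02)$delta_T, tolerance = 1e-9)
})

test_that("background-phase estimation reproduces smooth fields over the hole", {
  sim <- gen_phantom_series(small_config(noise_sd = 1e-9), n_frames = 2,
                            noiseless = TRUE, seed = 1)
  ph <- sim$series$frames[[2]]$phase
  inner <- roi_mask(sim$rois, "inner_roi")
  outer <- roi_mask(sim$rois, "outer_roi")
  # zero phase -> zero estimate
  est0 <- estimate_background_phase(matrix(0, 64, 64), inner, outer,
                                    interpolator = "linear",
                                    pixel_spacing = c(2, 2))
  expect_lt(max(abs(est0$estimate[inner])), 1e-10)
  # affine phase: every kernel and a degree-1 polynomial recover it exactly
  truth <- sim$truth$background_phase
  for (itp in list("linear", "thin_plate_spline", "multiquadric",
                   "gaussian", 1L)) {
    est <- estimate_background_phase(ph, inner, outer, interpolator = itp,
                                     pixel_spacing = c(2, 2), seed = 5)
    expect_lt(max(abs(est$estimate[inner] - truth[inner])), 1e-8)
    expect_lt(est$outer_residuals$max_abs, 1e-8)
  }
  expect_error(estimate_background_phase(ph, inner & FALSE, outer), "empty")
  expect_error(estimate_background_phase(ph, inner, inner), "disjoint")
})

test_that("a confined hot-spot bump does not leak into the background fit", {
  sim <- gen_phantom_series(small_config(), n_frames = 2,
                            hotspot = small_hotspot(peak = 12),
                            noiseless = TRUE, seed = 1)
  ph <- sim$series$frames[[2]]$phase
  est <- estimate_background_phase(ph, roi_mask(sim$rois, "inner_roi"),
                                   roi_mask(sim$rois, "outer_roi"),
                                   interpolator = "linear",
                                   pixel_spacing = c(2, 2))
  inner <- roi_mask(sim$rois, "inner_roi")
  # estimate tracks the stored affine background, not the heated phase
  expect_lt(max(abs(est$estimate[inner] - sim$truth$background_phase[inner])),
            5e-3)
  expect_gt(max(abs(ph[inner] - sim$truth$background_phase[inner])), 0.1)
})

test_that("referenceless maps recover injected heating and stay null unheated", {
  sim0 <- gen_phantom_series(small_config(), n_frames = 2, noiseless = TRUE,
                             seed = 2)
  sim16 <- gen_phantom_series(small_config(), n_frames = 2,
                              hotspot = small_hotspot(peak = 16),
                              noiseless = TRUE, seed = 2)
  truth_peak <- max(sim16$truth$deltaT[[2]])
  for (k in referenceless_kernels) {
    m0 <- referenceless_map(sim0$series, 2, sim0$rois, interpolator = k,
                            seed = 3)
    expect_lt(max(abs(m0$delta_T[m0$valid])), 0.01)
    m <- referenceless_map(sim16$series, 2, sim16$rois, interpolator = k,
                           seed = 3)
    expect_lt(abs(max(m$delta_T[m$valid]) - truth_peak), 0.1)
    expect_equal(m$method, paste0("referenceless_rbf_", k))
  }
})

test_that("classical and referenceless maps agree in the noiseless affine limit", {
  # a tight hot spot whose tail is negligible beyond the inner ROI, so the
  # outer annulus is genuinely unheated
  sim <- gen_phantom_series(small_config(), n_frames = 2,
                            hotspot = small_hotspot(peak = 10, sigma = 3),
                            noiseless = TRUE, seed = 4)
  inner <- roi_mask(sim$rois, "inner_roi")
  mc <- classical_prf_map(sim$series, 1, 2)
  for (k in referenceless_kernels) {
    mr <- referenceless_map(sim$series, 2, sim$rois, interpolator = k,
                            seed = 3)
    expect_lt(max(abs(mr$delta_T[inner] - mc$delta_T[inner])), 1e-3)
  }
})

test_that("recovered peak scales linearly with the injected amplitude", {
  peaks <- c(4, 8, 16)
  rec <- vapply(peaks, function(p) {
    sim <- gen_phantom_series(small_config(), n_frames = 2,
                              hotspot = small_hotspot(peak = p),
                              noiseless = TRUE, seed = 5)
    m <- referenceless_map(sim$series, 2, sim$rois,
                           interpolator = "thin_plate_spline", seed = 3)
    max(m$delta_T[m$valid])
  }, numeric(1))
  expect_lt(abs(rec[3] / rec[1] - 4), 0.04)   # 4x within 1%
  expect_lt(abs(rec[2] / rec[1] - 2), 0.02)   # 2x within 1%
})

test_that("null-case referenceless spread grows as magnitude SNR drops", {
  sds <- c(0.5, 2, 8)  # phantom amplitude 20 -> SNR 40, 10, 2.5
  spread <- vapply(sds, function(sg) {
    reps <- vapply(1:20, function(r) {
      sim <- gen_phantom_series(small_config(noise_sd = sg), n_frames = 2,
                                seed = 1000 + r)
      m <- referenceless_map(sim$series, 2, sim$rois, interpolator = "linear",
                             max_nodes = 200, seed = 3)
      sd(m$delta_T[m$valid])
    }, numeric(1))
    mean(reps)
  }, numeric(1))
  expect_true(all(diff(spread) > 0))
})

test_that("temperature curves follow the console conventions", {
  sim <- gen_phantom_series(small_config(), n_frames = 8,
                            hotspot = list(center_mm = c(60, 62),
                                           sigma_mm = 6, peak_deltaT = 12,
                                           tau_rise = 6, tau_decay = 20),
                            noiseless = TRUE, seed = 6)
  maps <- lapply(seq_len(8), function(k) classical_prf_map(sim$series, 1, k))
  pt <- c(31, 32)  # pixel at the hot-spot centre (60/2+1, 62/2+1)
  cur <- temperature_curves(maps, pt, neighborhood_radius = 2,
                            frame_interval = sim$series$frame_interval)
  expect_equal(which.max(cur$pixel_deltaT), which.max(sim$truth$envelope))
  # radius 0 degenerates to the single-pixel curve
  cur0 <- temperature_curves(maps, pt, neighborhood_radius = 0)
  expect_equal(cur0$pixel_deltaT, cur0$neighborhood_deltaT)
  # constant maps give constant curves
  cmap <- maps[[1]]; cmap$delta_T[] <- 1.5
  curc <- temperature_curves(list(cmap, cmap), pt)
  expect_equal(curc$pixel_deltaT, c(1.5, 1.5))
  # a point outside the validity mask is flagged, not silently zero
  rmap <- referenceless_map(sim$series, 5, sim$rois, interpolator = "linear",
                            seed = 3)
  curna <- temperature_curves(list(rmap), c(1, 1))
  expect_false(curna$pixel_valid[1])
  expect_true(is.na(curna$pixel_deltaT[1]))
})
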