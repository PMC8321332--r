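test_that("per-sonication maxima handle flat, analytic and shifted traces", {
  sch <- gen_sonication_schedule(n = 2, sd_duration = 0, sd_energy = 0,
                                 seed = 1)
  flat <- data.frame(time_s = seq(0, 300), temp_C = 21)
  expect_equal(max_rise_per_sonication(flat, sch)$delta_T_max, c(0, 0))

  pr <- gen_probe_timeseries(sch, gains = c(6, 2), tau_rise = 8,
                             noise_sd = 0, coupling_cv = 0, seed = 1)
  rises <- max_rise_per_sonication(pr[[1]], sch)
  expect_equal(rises$delta_T_max[1], 6 * (1 - exp(-20 / 8)), tolerance = 1e-9)
  # invariance to a constant offset of the whole trace
  shifted <- pr[[1]]; shifted$temp_C <- shifted$temp_C + 7.3
  expect_equal(max_rise_per_sonication(shifted, sch), rises)
  # windows outside the sampled range are named
  expect_error(max_rise_per_sonication(flat[1:50, ], sch), "sonication 1")
})

test_that("weak and strong sonication regimes are separated by the maxima", {
  sch <- gen_sonication_schedule(n = 1, sd_duration = 0, sd_energy = 0,
                                 seed = 1)
  strong <- gen_probe_timeseries(sch, gains = c(16 / (1 - exp(-20 / 8)), 1),
                                 tau_rise = 8, noise_sd = 0, coupling_cv = 0,
                                 seed = 1)
  weak <- gen_probe_timeseries(sch, gains = c(1, 0.5), tau_rise = 8,
                               noise_sd = 0, coupling_cv = 0, seed = 1)
  expect_equal(max_rise_per_sonication(strong[[1]], sch)$delta_T_max, 16,
               tolerance = 1e-9)
  expect_lt(max_rise_per_sonication(weak[[1]], sch)$delta_T_max, 1)
})

test_that("exact signed-rank p-values match exhaustive enumeration", {
  # constant positive shift, n = 10: smallest attainable two-sided p
  a <- rnorm(10) + 100
  expect_equal(wilcoxon_signed_rank(a, a - 5)$p_value, 2 / 2^10)
  # random paired fixtures, n = 8, against the bitmask oracle
  for (s in 1:10) {
    set.seed(s)
    x <- rnorm(8); y <- rnorm(8)
    got <- wilcoxon_signed_rank(x, y)
    expect_equal(got$p_value, oracle_signrank_p(x, y))
    expect_equal(got$method, "exact_enumeration")
  }
  # tie-free exact p agrees with the stats implementation
  for (s in 1:5) {
    set.seed(100 + s)
    x <- rnorm(12); y <- rnorm(12)
    expect_equal(wilcoxon_signed_rank(x, y)$p_value,
                 stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value)
  }
  expect_error(wilcoxon_signed_rank(1:10, 1:10), "degenerate")
  expect_error(wilcoxon_signed_rank(c(1, 2, 3, 4), c(0, 0, 0, 0)), "fewer")
})

test_that("large samples switch to the corrected normal approximation", {
  set.seed(7)
  x <- rnorm(40); y <- rnorm(40, 0.3)
  got <- wilcoxon_signed_rank(x, y)
  expect_equal(got$method, "normal_approximation")
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                            correct = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("method comparison flags degeneracy and validates names", {
  sim <- gen_phantom_series(small_config(), n_frames = 7,
                            hotspot = small_hotspot(peak = 10), seed = 41)
  res <- compare_methods(sim$series, sim$rois, methods = "classical_prf",
                         reference = "classical_prf")
  expect_true(res$summary$degenerate)
  expect_true(all(res$per_frame$classical_prf_error == 0))
  expect_error(compare_methods(sim$series, sim$rois, methods = "kriging"),
               "unknown method")
  expect_error(compare_methods(sim$series, sim$rois, methods = character(0)),
               "nonempty")
})

test_that("error curves are antisymmetric under method/reference swap", {
  sim <- gen_phantom_series(small_config(), n_frames = 6,
                            hotspot = small_hotspot(peak = 10), seed = 42)
  fwd <- compare_methods(sim$series, sim$rois,
                         methods = "referenceless_rbf_linear",
                         reference = "classical_prf", seed = 2)
  rev <- compare_methods(sim$series, sim$rois, methods = "classical_prf",
                         reference = "referenceless_rbf_linear", seed = 2)
  expect_equal(fwd$summary$bias, -rev$summary$bias, tolerance = 1e-10)
  expect_equal(fwd$per_frame$referenceless_rbf_linear_error,
               -rev$per_frame$classical_prf_error, tolerance = 1e-10)
})

test_that("a well-posed noiseless fixture yields unbiased linear-RBF maps", {
  sim <- gen_phantom_series(small_config(), n_frames = 7,
                            hotspot = small_hotspot(peak = 10),
                            noiseless = TRUE, seed = 43)
  res <- compare_methods(sim$series, sim$rois,
                         methods = "referenceless_rbf_linear",
                         reference = "classical_prf", seed = 2)
  expect_lt(abs(res$summary$bias), 0.1)
  expect_lt(res$summary$rmse, 0.1)
})

test_that("a mismatched low-degree polynomial overestimates the temperature", {
  # curved background phase (positive curvature) with an affine fit: the
  # extrapolated background overshoots under the hole, and with a negative
  # PRF coefficient that reads as spurious heating
  cfg <- small_config(noise_sd = 0.5,
                      bg_phase_coef = c(0.1, 0.003, -0.002,
                                        2e-5, 0, 2e-5))
  sim <- gen_phantom_series(cfg, n_frames = 7, seed = 44)
  res <- compare_methods(sim$series, sim$rois,
                         methods = "referenceless_poly", reference = "truth",
                         truth = sim$truth, poly_degree = 1, seed = 2)
  expect_gt(res$summary$bias, 0)
  expect_lt(res$summary$p_value, 0.05)
})

test_that("the study pipeline is deterministic and bookkeeps correctly", {
  cfg <- list(seed = 5, n_sonications = 2L, n_frames = 5L,
              matrix_size = 64L, pixel_spacing = 2,
              kernels = "linear", test_sonications = integer(0))
  d1 <- file.path(tempdir(), "study_a")
  d2 <- file.path(tempdir(), "study_b")
  r1 <- run_study(cfg, out_dir = d1, figures = FALSE, verbose = FALSE)
  r2 <- run_study(cfg, out_dir = d2, figures = FALSE, verbose = FALSE)
  expect_identical(readLines(file.path(d1, "summary.json")),
                   readLines(file.path(d2, "summary.json")))
  expect_equal(length(r1$summary$max_rise$probe1), 2)
  expect_equal(length(r1$summary$max_rise$probe2), 2)
  expect_true(file.exists(file.path(d1, "comparison_summary.csv")))
  expect_true(file.exists(file.path(d1, "map_classical.nii")))
})
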