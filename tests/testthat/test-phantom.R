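small_pp <- function(...) {
  phantom_params(extents = c(32L, 32L, 24L),
                 lv_centre = c(12, 16, 12), lv_semiaxes = c(5, 5, 7),
                 rv_centre = c(22, 16, 12), rv_semiaxes = c(4, 5, 7),
                 ...)
}

test_that("gamma-variate curve is zero pre-arrival and peaks at amplitude", {
  p <- gamma_variate_params(t0 = 1.2, alpha = 3, beta = 2, amplitude = 300)
  expect_equal(gamma_variate(c(-5, 0, 1.2), p), c(0, 0, 0))
  expect_equal(gamma_variate(1.2 + 3 * 2, p), 300)
  # fine-grid scan: argmax within one step of the analytic peak t0 + alpha*beta
  tt <- seq(0, 40, by = 0.01)
  expect_lt(abs(tt[which.max(gamma_variate(tt, p))] - 7.2), 0.011)
  # curve values never exceed the amplitude
  expect_lte(max(gamma_variate(tt, p)), 300 + 1e-9)
  expect_error(gamma_variate_params(0, -1, 2, 100), "positive")
  expect_error(gamma_variate_params(0, 1, 0, 100), "positive")
  expect_error(gamma_variate_params(0, 1, 1, -5), ">= 0")
})

test_that("phantom geometry and protocol invariants hold", {
  pp <- small_pp(seed = 1L)
  ph <- generate_phantom(pp)
  expect_identical(n_phases(ph$series), pp$n_phases)
  expect_identical(length(ph$series$times), 20L)
  expect_true(all(diff(ph$series$times) > 0))
  # 17 dynamic phases at RR 0.8 s plus late ones 10/20/35 s after the window
  expect_equal(ph$series$times[1:17], (0:16) * 0.8)
  expect_equal(ph$series$times[18:20], 12.8 + c(10, 20, 35))
  # geometry validation
  expect_error(phantom_params(extents = c(16L, 16L, 16L),
                              lv_centre = c(8, 8, 8), lv_semiaxes = c(10, 4, 4),
                              rv_centre = c(14, 8, 8), rv_semiaxes = c(1, 1, 1)),
               "outside the grid")
  expect_error(phantom_params(extents = c(32L, 32L, 24L),
                              lv_centre = c(12, 16, 12), lv_semiaxes = c(5, 5, 7),
                              rv_centre = c(16, 16, 12), rv_semiaxes = c(4, 5, 7)),
               "overlap")
  expect_error(small_pp(n_phases = 1L), ">= 2")
  expect_error(small_pp(noise_sigma = -1), ">= 0")
})

test_that("identical seeds give voxel-identical phantoms; seeds differ otherwise", {
  a <- generate_phantom(small_pp(seed = 42L))
  b <- generate_phantom(small_pp(seed = 42L))
  c <- generate_phantom(small_pp(seed = 43L))
  for (k in c(1L, 10L, 20L)) {
    expect_identical(a$series$phases[[k]]$values, b$series$phases[[k]]$values)
  }
  expect_false(identical(a$series$phases[[1]]$values, c$series$phases[[1]]$values))
  # and the generator leaves the global RNG stream alone
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_phantom(small_pp(seed = 7L)))
  expect_identical(runif(1), before)
})

test_that("noiseless phantom matches its own ground truth voxel for voxel", {
  pp <- small_pp(seed = 1L, noise_sigma = 0)
  ph <- generate_phantom(pp)
  expect_identical(ph$truth$lv_peak_phase, 10L)
  expect_identical(ph$truth$rv_peak_phase, 1L)
  # every LV voxel carries exactly the sampled LV curve
  lv_mask <- lvphase:::ellipsoid_mask(pp$extents, pp$lv_centre, pp$lv_semiaxes)
  idx <- which(lv_mask)[c(1, 50, 200)]
  for (i in idx) {
    tc <- vapply(ph$series$phases, function(v) v$values[i], numeric(1))
    expect_equal(tc, ph$truth$chamber_hu$lv_hu)
    expect_identical(which.max(tc), 10L)
  }
  # first-phase LV voxels sit inside the 30-150 HU eligibility window
  first <- ph$series$phases[[1]]$values
  expect_true(all(first[lv_mask] >= 30 & first[lv_mask] <= 150))
  # first-phase RV voxels sit far above it (contrast already high)
  rv_mask <- lvphase:::ellipsoid_mask(pp$extents, pp$rv_centre, pp$rv_semiaxes)
  expect_true(all(first[rv_mask] > 150))
})

test_that("default-noise phantom is recovered end to end at matrix size 16", {
  ph <- generate_phantom(phantom_params(seed = 2026L))
  res <- detect_lv_phase(ph$series, detection_params(matrix_size = 16L))
  expect_identical(res$detected_phase, ph$truth$lv_peak_phase)
})

test_that("the early-scan scenario lets the RV steal the vote", {
  # RV drawn larger than the LV, as it typically appears in axial sections
  pp <- phantom_params(extents = c(32L, 32L, 24L),
                       lv_centre = c(11, 16, 12), lv_semiaxes = c(4, 4, 6),
                       rv_centre = c(24, 16, 12), rv_semiaxes = c(6, 6, 8),
                       seed = 8L, pre_rv_arrival = TRUE)
  ph <- generate_phantom(pp)
  # the RV bolus now arrives after acquisition start: first-phase RV voxels
  # are eligible and their earlier, stronger peak outvotes the LV
  res <- detect_lv_phase(ph$series, detection_params(matrix_size = 16L))
  expect_false(is.na(res$detected_phase))
  expect_lt(abs(res$detected_phase - ph$truth$rv_peak_phase), 2)
  expect_true(res$detected_phase < ph$truth$lv_peak_phase)
})

test_that("phantom plotting returns a ggplot of the chamber curves", {
  ph <- generate_phantom(small_pp(seed = 1L))
  expect_s3_class(autoplot(ph), "ggplot")
})
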