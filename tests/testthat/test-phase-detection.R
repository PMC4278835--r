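test_that("temporal extremum finds the per-voxel maximum, earliest on ties", {
  ext <- temporal_extremum(voxel_series(c(40, 80, 120, 60)))
  expect_equal(ext$max_values$values[1, 1, 1], 120)
  expect_identical(ext$argmax_phases[1, 1, 1], 3L)

  tie <- temporal_extremum(voxel_series(c(50, 50, 50)))
  expect_equal(tie$max_values$values[1, 1, 1], 50)
  expect_identical(tie$argmax_phases[1, 1, 1], 1L)

  v <- ct_volume(array(0, c(2, 2, 2)))
  expect_error(temporal_extremum(ct_series(list(v))), "at least 2 phases")

  set.seed(31)
  s <- rand_series(c(3, 3, 3), 5)
  ext <- temporal_extremum(s)
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    tc <- vapply(s$phases, function(p) p$values[i, j, k], numeric(1))
    expect_equal(ext$max_values$values[i, j, k], max(tc))
    expect_identical(ext$argmax_phases[i, j, k], which.max(tc))
  }
})

test_that("voting requires the eligibility window and the increase rule", {
  # voxel A: first 40, max 120 at phase 2 (3x first) -> votes for phase 2
  # voxel B: first 100, max 150 < 2*100 -> no vote
  mk <- function(a, b) ct_volume(array(c(a, b), dim = c(2, 1, 1)))
  s <- ct_series(list(mk(40, 100), mk(120, 150), mk(90, 120)))
  ext <- temporal_extremum(s)
  h <- build_phase_histogram(ext, s$phases[[1]],
                             detection_params(increase_mode = "relative",
                                              increase_value = 1.0))
  expect_equal(h$votes, c(0L, 1L, 0L))

  # a first-phase value of 200 HU never votes, whatever the time course
  s2 <- ct_series(list(mk(200, 200), mk(900, 210), mk(800, 500)))
  h2 <- build_phase_histogram(temporal_extremum(s2), s2$phases[[1]],
                              detection_params())
  expect_equal(sum(h2$votes), 0L)

  # window bounds are inclusive on both ends
  s3 <- ct_series(list(mk(30, 150), mk(100, 400), mk(60, 300)))
  h3 <- build_phase_histogram(temporal_extremum(s3), s3$phases[[1]],
                              detection_params())
  expect_equal(sum(h3$votes), 2L)

  # absolute mode: max >= first + increase_value, inclusively
  s4 <- voxel_series(c(100, 180, 150))
  h4 <- build_phase_histogram(temporal_extremum(s4), s4$phases[[1]],
                              detection_params(increase_mode = "absolute",
                                               increase_value = 80))
  expect_equal(h4$votes, c(0L, 1L, 0L))
  h5 <- build_phase_histogram(temporal_extremum(s4), s4$phases[[1]],
                              detection_params(increase_mode = "absolute",
                                               increase_value = 80.5))
  expect_equal(sum(h5$votes), 0L)
})

test_that("histogram totals match a brute-force count of qualifying voxels", {
  set.seed(77)
  for (trial in 1:10) {
    s <- rand_series(c(4, 4, 4), 5, lo = -50, hu = 350)
    p <- detection_params(increase_value = 0.5)
    ext <- temporal_extremum(s)
    h <- build_phase_histogram(ext, s$phases[[1]], p)
    brute <- 0L
    for (i in 1:4) for (j in 1:4) for (k in 1:4) {
      tc <- vapply(s$phases, function(ph) ph$values[i, j, k], numeric(1))
      if (tc[1] >= 30 && tc[1] <= 150 && max(tc) >= tc[1] * 1.5) brute <- brute + 1L
    }
    expect_identical(sum(h$votes), brute)
  }
})

test_that("phase selection takes the fullest bin, earliest on ties, NA when empty", {
  expect_identical(select_phase(tibble::tibble(phase = 1:3, votes = c(0L, 5L, 5L))), 2L)
  expect_identical(select_phase(tibble::tibble(phase = 1:4, votes = c(0L, 0L, 0L, 0L))),
                   NA_integer_)
  # a one-vote margin decides, regardless of how tight it is
  expect_identical(select_phase(tibble::tibble(phase = 1:20,
                                               votes = c(rep(0L, 11), 8L, rep(0L, 4), 9L, 0L, 0L, 0L))),
                   17L)
})

test_that("full detection equals the nested-loop reference implementation", {
  set.seed(555)
  for (trial in 1:30) {
    dims <- sample(4:8, 3, replace = TRUE)
    p <- detection_params(
      increase_mode = sample(c("relative", "absolute"), 1),
      increase_value = sample(c(0.3, 1, 60), 1),
      matrix_size = sample(c(2L, 3L, dims[1]), 1)
    )
    s <- rand_series(dims, sample(3:6, 1), lo = -50, hu = 350)
    got <- detect_lv_phase(s, p)
    want <- naive_detect(s, p)
    expect_identical(got$shrink_factor, want$shrink_factor)
    expect_equal(got$histogram$votes, want$counts)
    expect_identical(got$detected_phase, want$detected_phase)
    expect_identical(got$eligible_voxels, sum(want$counts))
  }
})

test_that("matrix size equal to the input extent leaves the grid untouched", {
  set.seed(9)
  s <- rand_series(c(6, 6, 4), 4, lo = 0, hu = 300)
  a <- detect_lv_phase(s, detection_params(matrix_size = 6L))
  expect_identical(a$shrink_factor, 1L)
  # identical to running the vote directly on the unshrunken series
  ext <- temporal_extremum(s)
  h <- build_phase_histogram(ext, s$phases[[1]], detection_params(matrix_size = 6L))
  expect_equal(a$histogram$votes, h$votes)
  expect_identical(a$detected_phase, select_phase(h))
})

test_that("raising the increase threshold never gains votes in any bin", {
  set.seed(101)
  s <- rand_series(c(5, 5, 5), 5, lo = 0, hu = 400)
  ext <- temporal_extremum(s)
  for (mode in c("relative", "absolute")) {
    vals <- if (mode == "relative") c(0.2, 0.5, 1, 2) else c(20, 60, 120, 250)
    hists <- lapply(vals, function(iv) {
      build_phase_histogram(ext, s$phases[[1]],
                            detection_params(increase_mode = mode,
                                             increase_value = iv))$votes
    })
    for (i in seq_len(length(hists) - 1)) {
      expect_true(all(hists[[i + 1]] <= hists[[i]]))
    }
  }
})

test_that("strictly increasing voxel curves never vote for phase 1", {
  curves <- ct_series(lapply(1:5, function(ph) {
    ct_volume(array(40 + ph * 30, dim = c(3, 3, 3)))
  }))
  h <- build_phase_histogram(temporal_extremum(curves), curves$phases[[1]],
                             detection_params())
  expect_identical(h$votes[1], 0L)
  expect_identical(select_phase(h), 5L)
})

test_that("a first phase of uniform 0 HU yields an explicit no-detection", {
  zero <- ct_volume(array(0, c(4, 4, 4)))
  bright <- ct_volume(array(300, c(4, 4, 4)))
  res <- detect_lv_phase(ct_series(list(zero, bright, bright)),
                         detection_params(matrix_size = 4L))
  expect_identical(res$detected_phase, NA_integer_)
  expect_identical(res$eligible_voxels, 0L)
  expect_true(all(res$histogram$votes == 0L))
})

test_that("detection is deterministic across repeated runs", {
  ph <- generate_phantom(phantom_params(extents = c(32L, 32L, 24L),
                                        lv_centre = c(12, 16, 12),
                                        lv_semiaxes = c(5, 5, 7),
                                        rv_centre = c(22, 16, 12),
                                        rv_semiaxes = c(4, 5, 7),
                                        seed = 3L))
  r1 <- detect_lv_phase(ph$series, detection_params(matrix_size = 8L))
  r2 <- detect_lv_phase(ph$series, detection_params(matrix_size = 8L))
  expect_identical(r1$histogram, r2$histogram)
  expect_identical(r1$detected_phase, r2$detected_phase)
})

test_that("tidy and glance expose the histogram and summary", {
  ph <- generate_phantom(phantom_params(extents = c(32L, 32L, 24L),
                                        lv_centre = c(12, 16, 12),
                                        lv_semiaxes = c(5, 5, 7),
                                        rv_centre = c(22, 16, 12),
                                        rv_semiaxes = c(4, 5, 7),
                                        seed = 5L))
  res <- detect_lv_phase(ph$series, detection_params(matrix_size = 8L))
  td <- tidy(res)
  expect_identical(nrow(td), 20L)
  expect_identical(sum(td$detected), 1L)
  expect_identical(td$phase[td$detected], res$detected_phase)
  gl <- glance(res)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$detected_phase, res$detected_phase)
  expect_identical(gl$eligible_voxels, sum(td$votes))
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
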