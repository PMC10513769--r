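test_that("phantom generation is deterministic and bounded by the grid", {
  sp <- phantom_spec("sphere", radius_mm = 9, seed = 7)
  a <- make_phantom(sp)
  b <- make_phantom(sp)
  expect_identical(a$mask$labels, b$mask$labels)
  expect_error(make_phantom(phantom_spec("sphere", radius_mm = 30,
                                         shape = c(20L, 20L, 20L))),
               "grid")
})

test_that("voxelized solids match their closed-form volumes within 3% when
           at least 8 voxels across", {
  cases <- list(
    phantom_spec("sphere", radius_mm = 4.5, shape = c(16L, 16L, 16L)),
    phantom_spec("sphere", radius_mm = 10),
    phantom_spec("ellipsoid", semi_axes_mm = c(10, 10, 30),
                 shape = c(30L, 30L, 70L)),
    phantom_spec("box", side_mm = c(10, 10, 10), shape = c(18L, 18L, 18L)))
  for (sp in cases) {
    ph <- make_phantom(sp)
    v <- sum(ph$mask$labels) * prod(sp$spacing)
    expect_lt(abs(v - ph$truth$volume_mm3) / ph$truth$volume_mm3, 0.03)
  }
})

test_that("multifocal scenes carry per-focus closed forms and the shell
           fragment gap survives 26-connectivity", {
  ph <- make_phantom(phantom_spec(
    "multifocal", shape = c(64L, 40L, 40L),
    foci = list(list(center_mm = c(14, 20, 20), radius_mm = 9),
                list(center_mm = c(38, 14, 20), radius_mm = 6),
                list(center_mm = c(52, 28, 20), radius_mm = 4.5))))
  les <- extract_lesions(ph$mask)
  expect_length(les, 3L)
  vols <- sort(vapply(les, function(l) lesion_volume(l)$volume_mm3,
                      numeric(1)), decreasing = TRUE)
  truth <- sort(ph$truth$focus_volumes_mm3, decreasing = TRUE)
  expect_true(all(abs(vols - truth) / truth < 0.03))

  shell <- make_phantom(phantom_spec("fragmented_shell",
                                     shape = c(44L, 44L, 44L),
                                     n_fragments = 6L))
  frag <- extract_lesions(shell$mask)
  expect_length(frag, shell$truth$n_fragments)
  v <- sum(vapply(frag, function(l) lesion_volume(l)$volume_mm3, numeric(1)))
  expect_lt(abs(v - shell$truth$volume_mm3) / shell$truth$volume_mm3, 0.10)
})

test_that("growth series: analytic volume trace, trend labels and crossing
           indices follow the arithmetic", {
  base <- phantom_spec("sphere", radius_mm = 9, shape = c(40L, 40L, 40L))
  gs <- make_growth_series(base, growths = c(-0.2, 0.375, 0.05),
                           days = c(30, 120, 210, 300), os_days = 450,
                           thresholds = c(0.40))
  v0 <- 4 / 3 * pi * 9^3
  expect_equal(gs$truth$volumes_mm3, v0 * c(1, 0.8, 1.1, 1.155),
               tolerance = 1e-12)
  # 40% over the running minimum first fires at the 4th time point:
  # 1.155 / 0.8 = 1.44
  expect_equal(gs$truth$crossing$crossing_index, 4L)
  expect_equal(gs$truth$crossing$crossing_day, 300L)

  flat <- make_growth_series(base, growths = c(0, 0, 0),
                             days = c(30, 120, 210, 300), os_days = 450)
  mv <- vapply(flat$series$timepoints, function(tp)
    lesion_volume(extract_lesions(tp$mask_ref))$volume_mm3, numeric(1))
  expect_equal(unique(ranometry:::trend_labels(mv)), "constant")
  expect_true(all(!flat$truth$crossing$progressed))

  mono <- make_growth_series(base, growths = c(0.3, 0.3),
                             days = c(30, 120, 210), os_days = 400,
                             thresholds = 0.25)
  expect_equal(mono$truth$crossing$crossing_index, 2L)
})

test_that("measured phantom volumes recover the sampled cohort's ground
           truth crossing days end to end", {
  cohort <- sample_growth_cohort(n_series = 4L, seed = 11)
  for (gs in cohort) {
    vols <- vapply(gs$series$timepoints, function(tp)
      lesion_volume(extract_lesions(tp$mask_ref))$volume_mm3, numeric(1))
    days <- vapply(gs$series$timepoints, function(tp) tp$days_from_surgery,
                   integer(1))
    for (k in seq_len(nrow(gs$truth$crossing))) {
      row <- gs$truth$crossing[k, ]
      r <- compute_ttp(vols, metric = "volume", threshold = row$threshold,
                       days = days, os_days = gs$series$os_days,
                       nadir_mode = "auto")
      expect_equal(r$ttp_days, row$crossing_day)
      expect_equal(r$progressed, row$progressed)
    }
  }
})

test_that("rater tables realise their analytic expected ICC", {
  exact <- make_rater_table(30, 2, subject_sd = 1.5,
                            rater_offsets = c(0, 7), noise_sd = 0, seed = 2)
  expect_equal(icc_consistency(exact), 1.0, tolerance = 1e-9)
  half <- make_rater_table(500, 2, subject_sd = 1, noise_sd = 1, seed = 3)
  expect_lt(abs(icc_consistency(half) - 0.5), 0.05)
  expect_equal(attr(half, "expected_icc"), 0.5)
  null <- make_rater_table(500, 2, subject_sd = 0, noise_sd = 1, seed = 4)
  expect_lte(abs(icc_consistency(null)), 0.1)
})
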