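test_that("NIfTI round-trip preserves labels, spacing and origin", {
  ph <- make_phantom(phantom_spec("sphere", radius_mm = 6,
                                  shape = c(20L, 20L, 20L)))
  path <- tempfile(fileext = ".nii.gz")
  write_mask(ph$mask, path)
  back <- load_mask(path, enhancing = 1L)
  expect_identical(back$labels, ph$mask$labels)
  expect_equal(back$spacing, ph$mask$spacing)
  expect_equal(back$origin, ph$mask$origin)

  # anisotropic header spacing is preserved verbatim
  m <- seg_mask(array(as.integer(c(rep(0, 13), 1, rep(0, 13))), c(3, 3, 3)),
                spacing = c(0.5, 0.5, 3.0))
  p2 <- tempfile(fileext = ".nii.gz")
  write_mask(m, p2)
  expect_equal(load_mask(p2)$spacing, c(0.5, 0.5, 3.0))
})

test_that("label selection binarises exactly the enhancing class", {
  arr <- array(0L, c(8, 8, 8))
  arr[2:4, 2:4, 2:4] <- 2L
  arr[6:7, 6:7, 6:7] <- 3L
  path <- tempfile(fileext = ".nii.gz")
  write_mask(seg_mask(arr), path)
  got <- load_mask(path, label_map = c("2" = "enhancing", "3" = "edema"))
  expect_equal(sum(got$labels), 27L)
  expect_true(all(which(got$labels > 0) == which(arr == 2L)))
  expect_error(load_mask(path, label_map = c("2" = "edema")), "enhancing")
})

test_that("malformed volumes are rejected", {
  expect_error(load_mask(tempfile(fileext = ".nii")), "not found")
  p4 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0L, c(4, 4, 4, 2))), p4)
  expect_error(load_mask(p4), "3D")
  pf <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0.5, c(4, 4, 4))), pf)
  expect_error(load_mask(pf), "non-integer")
  expect_error(seg_mask(array(1L, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "positive")
  expect_error(seg_mask(array(-1L, c(2, 2, 2))), "non-negative")
})

test_that("iso-resampling is the identity at the native spacing and
           preserves physical volume of convex solids", {
  ph <- make_phantom(phantom_spec("sphere", radius_mm = 7,
                                  shape = c(20L, 20L, 20L)))
  expect_identical(resample_iso(ph$mask, 1)$labels, ph$mask$labels)

  # 10 mm cube sampled at (1, 1, 2) mm: volume within 5% of 1000 mm^3
  arr <- array(0L, c(16, 16, 8))
  arr[4:13, 4:13, 2:6] <- 1L  # 10 x 10 x 5 voxels = 10 x 10 x 10 mm
  cube <- seg_mask(arr, spacing = c(1, 1, 2))
  iso <- resample_iso(cube, 1)
  expect_equal(iso$spacing, c(1, 1, 1))
  expect_lt(abs(sum(iso$labels) - 1000) / 1000, 0.05)

  # anisotropic sphere keeps its physical volume within 5%
  sph <- make_phantom(phantom_spec("sphere", radius_mm = 8,
                                   shape = c(40L, 40L, 14L),
                                   spacing = c(0.5, 0.5, 1.5),
                                   center_mm = c(9.6, 9.7, 9.8)))
  v0 <- sum(sph$mask$labels) * prod(sph$mask$spacing)
  v1 <- sum(resample_iso(sph$mask, 1)$labels)
  expect_lt(abs(v1 - v0) / v0, 0.05)

  expect_identical(sum(resample_iso(seg_mask(array(0L, c(5, 5, 5)),
                                             spacing = c(1, 1, 2)),
                                    1)$labels), 0L)
})

test_that("manifest loading sorts, validates and aggregates row errors", {
  dir <- tempfile()
  dir.create(dir)
  for (f in c("a1.nii.gz", "a2.nii.gz", "a3.nii.gz", "b1.nii.gz",
              "b2.nii.gz", "b3.nii.gz"))
    write_mask(seg_mask(array(0L, c(4, 4, 4))), file.path(dir, f))
  man <- data.frame(
    patient_id = c("A", "A", "A", "B", "B", "B"),
    days_from_surgery = c(120L, 30L, 210L, 45L, 300L, 160L),
    mask_file = c("a2.nii.gz", "a1.nii.gz", "a3.nii.gz", "b1.nii.gz",
                  "b3.nii.gz", "b2.nii.gz"),
    os_days = c(400L, 400L, 400L, 500L, 500L, 500L),
    expert_rating = c("SD", NA, "PD", "SD", "PD", "SD"))
  csv <- file.path(dir, "manifest.csv")
  write.csv(man, csv, row.names = FALSE)
  cohort <- load_series(csv)
  expect_length(cohort, 2L)
  expect_equal(vapply(cohort$A$timepoints,
                      function(tp) tp$days_from_surgery, integer(1)),
               c(30L, 120L, 210L))
  expect_equal(cohort$A$os_days, 400L)
  expect_equal(cohort$A$timepoints[[3]]$expert_rating, "PD")

  bad <- man
  bad$days_from_surgery[2] <- 120L
  expect_error(load_series(bad, mask_dir = dir), "duplicate")
  bad2 <- man
  bad2$os_days[1] <- 999L
  expect_error(load_series(bad2, mask_dir = dir), "inconsistent")
  bad3 <- man
  bad3$mask_file[4] <- "missing.nii.gz"
  expect_error(load_series(bad3, mask_dir = dir), "not found")
})

test_that("series invariants are enforced", {
  tps <- list(timepoint_record(100), timepoint_record(40))
  s <- patient_series("X", tps, os_days = 150)
  expect_equal(vapply(s$timepoints, function(tp) tp$days_from_surgery,
                      integer(1)), c(40L, 100L))
  expect_error(patient_series("X", tps, os_days = 80), "os_days")
  expect_error(patient_series("X", list(timepoint_record(10),
                                        timepoint_record(10)), 99),
               "duplicate")
  expect_error(timepoint_record(-1), "non-negative")
  expect_error(timepoint_record(5, measurements = c(volume = -2)),
               "non-negative")
  expect_error(timepoint_record(5, expert_rating = "XX"), "one of")
})
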