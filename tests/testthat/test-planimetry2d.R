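# region rings of a single-slice 0/1 matrix (1 mm spacing unless given)
rings_of <- function(slc, sp = 1, sq = 1, step = 0.1) {
  ranometry:::slice_rings((slc > 0) * 1, sp, sq, step)
}

test_that("a single voxel contours as a diamond through the face midpoints", {
  m <- seg_mask(array(as.integer(c(rep(0, 13), 1, rep(0, 13))), c(3, 3, 3)))
  rings <- slice_contours(m, 2)
  expect_length(rings, 1L)
  v <- rings[[1]]
  # the four corner vertices of the 0.5-level diamond are retained exactly
  for (corner in list(c(0.5, 1), c(1.5, 1), c(1, 0.5), c(1, 1.5)))
    expect_true(any(abs(v[, 1] - corner[1]) < 1e-9 &
                    abs(v[, 2] - corner[2]) < 1e-9))
  expect_equal(max(dist(v)), 1.0, tolerance = 1e-9)

  les <- extract_lesions(m)[[1]]
  m2 <- measure_lesion_2d(les)
  expect_equal(m2$longest$length_mm, 1.0, tolerance = 1e-9)
  expect_equal(m2$perpendicular$length_mm, 1.0, tolerance = 1e-9)
  expect_equal(m2$product_mm2, 1.0, tolerance = 1e-9)
})

test_that("longest diameter of canonical shapes matches the all-pairs
           brute-force oracle", {
  # 10 x 10 solid square: longest chord runs between opposite chamfers
  sq <- matrix(0, 14, 14)
  sq[3:12, 3:12] <- 1
  rings <- rings_of(sq)
  d1 <- longest_inplane_diameter(rings)
  expect_equal(d1$length_mm, longest_chord_oracle(rings), tolerance = 1e-6)
  expect_gt(d1$length_mm, 13.0)
  expect_lt(d1$length_mm, 13.6)

  # 20 x 2 voxel bar: d1 ~ long diagonal, d2 ~ bar width
  bar <- matrix(0, 26, 8)
  bar[4:23, 4:5] <- 1
  rb <- rings_of(bar, step = 0.2)
  d1b <- longest_inplane_diameter(rb)
  expect_equal(d1b$length_mm, longest_chord_oracle(rb), tolerance = 1e-6)
  expect_gt(d1b$length_mm, 19.5)
  d2b <- perpendicular_diameter(d1b, rb)
  expect_equal(d2b$length_mm,
               longest_chord_oracle(rb, ref_dir = d1b$endpoints_mm[2, 1:2] -
                                      d1b$endpoints_mm[1, 1:2]),
               tolerance = 1e-6)
  expect_lt(d2b$length_mm, 3)
})

test_that("digital disk diameters are near-nominal with the max-seeking
           half-voxel bias bound", {
  n <- 26
  ctr <- c(12.3, 12.6)
  disk <- outer(seq_len(n) - 1, seq_len(n) - 1,
                function(i, j) (i - ctr[1])^2 + (j - ctr[2])^2 <= 100) * 1
  rings <- rings_of(disk, step = 0.2)
  d1 <- longest_inplane_diameter(rings)
  # nominal 20 mm; each endpoint can sit on a contour bump reaching up to
  # half a voxel beyond the analytic radius, so the hard upper bound is 21
  expect_gt(d1$length_mm, 19.6)
  expect_lt(d1$length_mm, 21.0)
  expect_equal(d1$length_mm, longest_chord_oracle(rings), tolerance = 1e-6)
  d2 <- perpendicular_diameter(d1, rings)
  expect_gt(d2$length_mm, 19.6)
  expect_lt(d2$length_mm, 21.0)
  u <- d1$endpoints_mm[2, 1:2] - d1$endpoints_mm[1, 1:2]
  v <- d2$endpoints_mm[2, 1:2] - d2$endpoints_mm[1, 1:2]
  ang <- acos(abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  expect_gte(90 - ang, -2 - 1e-9)
  expect_lte(90 - ang, 2 + 1e-9)
})

test_that("containment rejects chords that shortcut a C-shaped annulus", {
  n <- 24
  ctr <- c(11.4, 11.7)
  ang <- function(i, j) atan2(j - ctr[2], i - ctr[1])
  r2 <- function(i, j) (i - ctr[1])^2 + (j - ctr[2])^2
  cshape <- outer(seq_len(n) - 1, seq_len(n) - 1, function(i, j)
    r2(i, j) >= 36 & r2(i, j) <= 100 & abs(ang(i, j)) > 0.55) * 1
  rings <- rings_of(cshape, step = 0.2)
  d1 <- longest_inplane_diameter(rings)
  verts <- do.call(rbind, rings)
  span <- max(dist(verts))  # straight chord across the gap's mouth
  expect_lt(d1$length_mm, span - 1e-6)
  expect_equal(d1$length_mm, longest_chord_oracle(rings), tolerance = 1e-6)
  # every returned segment lies inside the region at fine sampling
  a <- d1$endpoints_mm[1, 1:2]
  b <- d1$endpoints_mm[2, 1:2]
  expect_true(chord_contained_oracle(a, b, rings, step = 0.05))
})

test_that("perpendicular diameter is absent when no vertex pair falls in
           the angle window", {
  # degenerate sliver: every contour vertex is collinear at 30 degrees, so
  # all candidate chords are parallel to the longest diameter and the
  # 90 +/- 2 degree window is empty
  t <- seq(0, 10, by = 0.25)
  line <- cbind(t * cos(pi / 6), t * sin(pi / 6))
  sliver <- list(rbind(line, line[rev(seq_len(nrow(line))), ]))
  d1 <- ranometry:::new_segment(rbind(line[1, ], line[nrow(line), ]))
  expect_equal(d1$length_mm, 10, tolerance = 1e-9)
  expect_null(perpendicular_diameter(d1, sliver))
  expect_equal(ranometry:::new_bidim(d1, NULL, "axial2d")$product_mm2, 0)
})

test_that("lexicographic optimisation over slices: sphere and ellipsoid
           phantoms measure at their central sections", {
  sph <- make_phantom(phantom_spec("sphere", radius_mm = 10,
                                   shape = c(32L, 32L, 32L)))
  les <- extract_lesions(sph$mask)[[1]]
  m <- measure_lesion_2d(les)
  expect_gt(m$product_mm2, 0.96 * 400)
  expect_lt(m$product_mm2, 1.085 * 400)
  # winning slice is near the equator (centre z = 15.75 mm -> slice 16 or 17)
  expect_true(m$longest$slice_index %in% 15:18)

  ell <- make_phantom(phantom_spec("ellipsoid", semi_axes_mm = c(15, 10, 5),
                                   shape = c(40L, 28L, 18L)))
  le <- extract_lesions(ell$mask)[[1]]
  me <- measure_lesion_2d(le)
  expect_lt(abs(me$longest$length_mm - 30) / 30, 0.03)
  expect_lt(abs(me$perpendicular$length_mm - 20) / 20, 0.03)
  expect_lt(abs(me$product_mm2 - 600) / 600, 0.06)
})

test_that("in-plane rotation changes disk-like diameters by less than 3%", {
  base <- phantom_spec("ellipsoid", semi_axes_mm = c(15, 10, 5),
                       shape = c(40L, 40L, 18L))
  rot <- phantom_spec("ellipsoid", semi_axes_mm = c(15, 10, 5),
                      shape = c(40L, 40L, 18L), rotation = 30)
  m0 <- measure_lesion_2d(extract_lesions(make_phantom(base)$mask)[[1]])
  m1 <- measure_lesion_2d(extract_lesions(make_phantom(rot)$mask)[[1]])
  expect_lt(abs(m1$longest$length_mm - m0$longest$length_mm) /
              m0$longest$length_mm, 0.03)
  expect_lt(abs(m1$perpendicular$length_mm - m0$perpendicular$length_mm) /
              m0$perpendicular$length_mm, 0.03)
})

test_that("dilation never decreases the longest diameter, and random
           regions match the oracle with perpendicularity in window", {
  for (seed in c(11, 12, 13)) {
    slc <- random_region_2d(seed)
    if (is.null(slc)) next
    arr <- array(as.integer(slc), c(dim(slc), 1L))
    mask <- seg_mask(arr)
    les <- extract_lesions(mask)[[1]]
    m <- measure_lesion_2d(les, step_mm = 0.5)
    rings <- rings_of(slc, step = 0.5)
    regs <- vapply(rings, function(r) attr(r, "region"), integer(1))
    best <- max(vapply(unique(regs), function(g)
      longest_chord_oracle(rings[regs == g]), numeric(1)))
    expect_equal(m$longest$length_mm, best, tolerance = 1e-6)
    if (!is.null(m$perpendicular)) {
      u <- m$longest$endpoints_mm[2, ] - m$longest$endpoints_mm[1, ]
      v <- m$perpendicular$endpoints_mm[2, ] - m$perpendicular$endpoints_mm[1, ]
      ang <- acos(abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
      expect_gte(ang, 88 - 1e-9)
      expect_lte(ang, 92 + 1e-9)
    }
    big <- measure_lesion_2d(extract_lesions(dilate_mask(mask))[[1]],
                             step_mm = 0.5)
    expect_gte(big$longest$length_mm, m$longest$length_mm - 1e-9)
  }
})
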