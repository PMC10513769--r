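# Programmatic fixtures: blobby random regions/lesions (Gaussian-smoothed
# noise thresholded at a level chosen to hit a target density) and helpers
# for building masks and writing series to disk.

smooth_noise_2d <- function(n, m, seed) {
  z <- with_test_seed(seed, matrix(rnorm(n * m), n, m))
  k <- outer(dnorm(-2:2, sd = 1.2), dnorm(-2:2, sd = 1.2))
  k <- k / sum(k)
  out <- matrix(0, n, m)
  for (di in -2:2) for (dj in -2:2) {
    src <- z[pmin(pmax(seq_len(n) + di, 1), n),
             pmin(pmax(seq_len(m) + dj, 1), m)]
    out <- out + k[di + 3, dj + 3] * src
  }
  out
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# largest 8-connected region of a random blobby 2D slice (<= nmax^2)
random_region_2d <- function(seed, nmax = 24, density = 0.25) {
  z <- smooth_noise_2d(nmax, nmax, seed)
  fg <- z >= quantile(z, 1 - density)
  lab <- array(ranometry:::label_components_cpp(as.logical(fg),
                                                c(nmax, nmax, 1L)),
               c(nmax, nmax))
  if (!any(lab > 0)) return(NULL)
  big <- which.max(tabulate(lab[lab > 0]))
  (lab == big) * 1
}

# blobby random 3D lesion inside a <= nmax^3 grid
random_lesion_3d <- function(seed, nmax = 12, density = 0.25) {
  z <- with_test_seed(seed, array(rnorm(nmax^3), rep(nmax, 3)))
  f <- ranometry:::smooth_box3_cpp(as.numeric(z), dim(z))
  f <- ranometry:::smooth_box3_cpp(f, dim(z))
  fg <- array(f >= quantile(f, 1 - density), dim(z))
  m <- seg_mask(array(as.integer(fg), dim(z)))
  les <- extract_lesions(m)
  if (!length(les)) return(NULL)
  les[[1]]
}

mask_from_array <- function(arr, spacing = c(1, 1, 1)) {
  seg_mask(array(as.integer(arr), dim(arr)), spacing = spacing)
}

# 6-connected morphological dilation of a lesion's parent-grid foreground
dilate_mask <- function(mask) {
  fg <- mask$labels > 0L
  d <- dim(fg)
  out <- fg
  shift <- function(a, ax, by) {
    sel <- lapply(d, seq_len)
    sel[[ax]] <- pmin(pmax(sel[[ax]] - by, 1L), d[ax])  # clamped: no wrap
    a[sel[[1]], sel[[2]], sel[[3]], drop = FALSE]
  }
  for (ax in 1:3) for (by in c(-1L, 1L))
    out <- out | shift(fg, ax, by)
  seg_mask(array(as.integer(out), d), spacing = mask$spacing,
           axial_axis = mask$axial_axis)
}

# write a growth series' in-memory masks plus a manifest CSV to a directory
write_series_fixture <- function(gs, dir,
                                 expert_ratings = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  days <- vapply(gs$series$timepoints, function(tp) tp$days_from_surgery,
                 integer(1))
  files <- sprintf("%s_d%04d.nii.gz", gs$series$patient_id, days)
  for (i in seq_along(files))
    write_mask(gs$series$timepoints[[i]]$mask_ref, file.path(dir, files[i]))
  man <- data.frame(patient_id = gs$series$patient_id,
                    days_from_surgery = days, mask_file = files,
                    os_days = gs$series$os_days)
  if (!is.null(expert_ratings)) man$expert_rating <- expert_ratings
  man
}
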