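#' Phantom specification
#'
#' Describes a synthetic lesion scene with analytically known geometry.
#' Voxelization uses the voxel-centre rule (a voxel is foreground iff its
#' centre lies inside the analytic solid), the convention consistent with
#' the 0.5-level contouring used by the measurement operators.  Identical
#' spec (and seed, where randomness is involved) gives identical output.
#'
#' @param kind `"sphere"`, `"ellipsoid"`, `"box"`, `"fragmented_shell"` or
#'   `"multifocal"`.
#' @param shape Grid dimensions in voxels (length 3).
#' @param spacing Voxel spacing in mm (length 3).
#' @param center_mm Centre of the solid in mm.  The default is the grid
#'   centre shifted by a quarter voxel per axis: a centre on a lattice
#'   symmetry point would align the solid's symmetry with the voxel grid
#'   and pair up the half-voxel contour spikes of the digital surface into
#'   artificially long antipodal chords, biasing diameter measurements
#'   upward.
#' @param radius_mm Sphere radius (kind `"sphere"`).
#' @param semi_axes_mm Length-3 semi-axes (kind `"ellipsoid"`).
#' @param side_mm Length-3 edge lengths (kind `"box"`).
#' @param rotation 3x3 rotation matrix, or a single angle in degrees for an
#'   in-plane (about the axial axis) rotation; `NULL` for axis-aligned.
#' @param cavity_radius_mm,thickness_mm,n_fragments,gap_mm,belt_deg
#'   Fragmented shell: fragments are azimuthal sectors of a spherical shell
#'   belt (polar range `90 +/- belt_deg` degrees) of the given inner radius
#'   and thickness around a resection-cavity-like core, separated by arc
#'   gaps of at least `gap_mm` so that 26-connectivity cannot merge them.
#' @param foci List of `list(center_mm=, radius_mm=)` spheres (kind
#'   `"multifocal"`; must be disjoint for the closed-form ground truth to
#'   hold).
#' @param axial_axis Axial array axis of the generated mask.
#' @param seed Integer seed recorded in the spec (generation itself is
#'   deterministic).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("sphere", "ellipsoid", "box",
                                  "fragmented_shell", "multifocal"),
                         shape = c(48L, 48L, 48L), spacing = c(1, 1, 1),
                         center_mm = NULL, radius_mm = 10,
                         semi_axes_mm = c(10, 10, 10),
                         side_mm = c(10, 10, 10), rotation = NULL,
                         cavity_radius_mm = 10, thickness_mm = 4,
                         n_fragments = 6L, gap_mm = NULL, belt_deg = 30,
                         foci = NULL, axial_axis = 3L, seed = 1L) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  if (is.null(center_mm)) center_mm <- ((shape - 1) / 2 + 0.25) * spacing
  if (is.null(gap_mm)) gap_mm <- 4 * max(spacing)
  if (is.numeric(rotation) && length(rotation) == 1L) {
    th <- rotation * pi / 180
    rotation <- diag(3)
    ip <- setdiff(1:3, axial_axis)
    rotation[ip, ip] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  }
  structure(list(kind = kind, shape = shape, spacing = spacing,
                 center_mm = as.numeric(center_mm), radius_mm = radius_mm,
                 semi_axes_mm = as.numeric(semi_axes_mm),
                 side_mm = as.numeric(side_mm), rotation = rotation,
                 cavity_radius_mm = cavity_radius_mm,
                 thickness_mm = thickness_mm,
                 n_fragments = as.integer(n_fragments), gap_mm = gap_mm,
                 belt_deg = belt_deg, foci = foci,
                 axial_axis = as.integer(axial_axis),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# mm coordinates of all voxel centres, n x 3
grid_centres <- function(shape, spacing) {
  cbind(rep((seq_len(shape[1]) - 1) * spacing[1],
            times = shape[2] * shape[3]),
        rep(rep((seq_len(shape[2]) - 1) * spacing[2], each = shape[1]),
            times = shape[3]),
        rep((seq_len(shape[3]) - 1) * spacing[3], each = shape[1] * shape[2]))
}

#' Generate a phantom mask with analytic ground truth
#'
#' @param spec A [phantom_spec].
#' @return List with `mask` (a binary [seg_mask]) and `truth`: closed-form
#'   `volume_mm3`, and where analytic, axial diameters `d1_2d`/`d2_2d`
#'   (longest axial in-plane diameter and its perpendicular), free 3D
#'   diameters `d1_3d`/`d2_3d`, `sphericity`, and per-focus volumes for
#'   multifocal scenes.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  pts <- sweep(grid_centres(spec$shape, spec$spacing), 2, spec$center_mm)
  truth <- list()
  inside <- switch(spec$kind,
    sphere = {
      r <- spec$radius_mm
      truth$volume_mm3 <- 4 / 3 * pi * r^3
      truth$d1_2d <- truth$d2_2d <- truth$d1_3d <- truth$d2_3d <- 2 * r
      truth$sphericity <- 1
      rowSums(pts^2) <= r^2
    },
    ellipsoid = {
      ax <- spec$semi_axes_mm
      q <- if (is.null(spec$rotation)) pts else pts %*% spec$rotation
      truth$volume_mm3 <- 4 / 3 * pi * prod(ax)
      s <- sort(ax, decreasing = TRUE)
      truth$d1_3d <- 2 * s[1]
      truth$d2_3d <- 2 * s[2]
      aligned_or_inplane <- is.null(spec$rotation) ||
        all(abs(spec$rotation[spec$axial_axis, -spec$axial_axis]) < 1e-12)
      if (aligned_or_inplane) {
        ip <- sort(ax[setdiff(1:3, spec$axial_axis)], decreasing = TRUE)
        truth$d1_2d <- 2 * ip[1]
        truth$d2_2d <- 2 * ip[2]
      }
      rowSums(sweep(q, 2, ax, "/")^2) <= 1
    },
    box = {
      s <- spec$side_mm
      q <- if (is.null(spec$rotation)) pts else pts %*% spec$rotation
      truth$volume_mm3 <- prod(s)
      truth$sphericity <- pi^(1 / 3) * (6 * prod(s))^(2 / 3) /
        (2 * (s[1] * s[2] + s[1] * s[3] + s[2] * s[3]))
      abs(q[, 1]) <= s[1] / 2 & abs(q[, 2]) <= s[2] / 2 &
        abs(q[, 3]) <= s[3] / 2
    },
    multifocal = {
      stopifnot(length(spec$foci) >= 1L)
      truth$focus_volumes_mm3 <- vapply(spec$foci, function(f)
        4 / 3 * pi * f$radius_mm^3, numeric(1))
      truth$volume_mm3 <- sum(truth$focus_volumes_mm3)
      ins <- rep(FALSE, nrow(pts))
      ctr <- grid_centres(spec$shape, spec$spacing)
      for (f in spec$foci)
        ins <- ins | rowSums(sweep(ctr, 2, f$center_mm)^2) <= f$radius_mm^2
      ins
    },
    fragmented_shell = {
      r1 <- spec$cavity_radius_mm
      r2 <- r1 + spec$thickness_mm
      nf <- spec$n_fragments
      th_lo <- (90 - spec$belt_deg) * pi / 180
      th_hi <- (90 + spec$belt_deg) * pi / 180
      gap_angle <- spec$gap_mm / r1
      sector <- 2 * pi / nf
      stopifnot(sector > gap_angle)
      cover <- sector - gap_angle
      truth$volume_mm3 <- nf * cover / (2 * pi) * 2 * pi / 3 *
        (r2^3 - r1^3) * (cos(th_lo) - cos(th_hi))
      truth$n_fragments <- nf
      a <- spec$axial_axis
      ip <- setdiff(1:3, a)
      rho <- sqrt(rowSums(pts^2))
      polar <- acos(pmin(pmax(pts[, a] / pmax(rho, 1e-12), -1), 1))
      azim <- atan2(pts[, ip[2]], pts[, ip[1]]) %% (2 * pi)
      in_sector <- (azim %% sector) <= cover
      rho >= r1 & rho <= r2 & polar >= th_lo & polar <= th_hi & in_sector
    })
  lab <- array(as.integer(inside), spec$shape)
  if (!any(lab > 0)) stop("phantom contains no voxels; enlarge it or the grid")
  idx <- which(lab > 0L, arr.ind = TRUE)
  if (any(idx == 1L) || any(sweep(idx, 2, spec$shape) == 0L))
    stop("phantom touches the grid boundary; enlarge the grid")
  list(mask = seg_mask(lab, spacing = spec$spacing,
                       axial_axis = spec$axial_axis,
                       source = paste0("phantom:", spec$kind)),
       truth = truth, spec = spec)
}

# first index whose value reaches (1 + threshold) x running minimum of all
# earlier values; NA when the trace never crosses
crossing_index <- function(trace, threshold) {
  for (t in seq_along(trace)[-1])
    if (trace[t] >= (1 + threshold) * min(trace[seq_len(t - 1)]))
      return(t)
  NA_integer_
}

#' Phantom growth series with exact threshold-crossing ground truth
#'
#' Builds a longitudinal series of sphere phantoms whose true volumes
#' follow `V_t = V_0 * prod(1 + g_i)` (radii scale with the cube root), and
#' returns, for any threshold, the exact first index at which the
#' cumulative growth from the running minimum crosses it.
#'
#' @param baseline A sphere [phantom_spec] for the baseline time point.
#' @param growths Per-follow-up volume growth fractions (> -1).
#' @param days Days from surgery, one per time point (baseline first).
#' @param os_days Overall survival in days.
#' @param thresholds Thresholds for which crossing indices are tabulated
#'   (default the RANO pair 0.25 and 0.40).
#' @return List with `series` (a [patient_series] whose time points hold
#'   in-memory masks) and `truth`: `volumes_mm3`, `spd2d_mm2` (true
#'   `(2r)^2` products), `radii_mm`, and `crossing`, a data.frame of
#'   threshold, crossing index and crossing day (`NA` / OS when never).
#' @export
make_growth_series <- function(baseline, growths, days, os_days,
                               thresholds = c(0.25, 0.40)) {
  stopifnot(inherits(baseline, "phantom_spec"), baseline$kind == "sphere",
            all(growths > -1), length(days) == length(growths) + 1L)
  factors <- cumprod(c(1, 1 + growths))
  radii <- baseline$radius_mm * factors^(1 / 3)
  masks <- lapply(radii, function(r) {
    sp <- baseline
    sp$radius_mm <- r
    ph <- make_phantom(sp)
    ph$mask
  })
  if (any(vapply(masks, function(m) sum(m$labels), numeric(1)) < 1))
    stop("growth series shrank below one voxel")
  vols <- 4 / 3 * pi * radii^3
  tps <- lapply(seq_along(days), function(i)
    timepoint_record(days[i], mask_ref = masks[[i]]))
  crossing <- do.call(rbind, lapply(thresholds, function(th) {
    ci <- crossing_index(vols, th)
    data.frame(threshold = th, crossing_index = ci,
               crossing_day = if (is.na(ci)) as.integer(os_days)
                              else as.integer(days[ci]),
               progressed = !is.na(ci))
  }))
  list(series = patient_series("phantom", tps, os_days),
       truth = list(volumes_mm3 = vols, spd2d_mm2 = (2 * radii)^2,
                    radii_mm = radii, crossing = crossing))
}

#' Sample a phantom growth cohort
#'
#' Draws deterministic (seeded) sphere growth series for end-to-end
#' time-to-progression validation.  Steps are drawn from three regimes --
#' shrinkage (volume factor 0.7), plateau (1.0) and growth (2.0) -- with
#' shrink/plateau phases always preceding growth, so every relative
#' increase over the running minimum is far from the RANO thresholds
#' (either below 1 or at least +100%) and the analytic crossing index is
#' unambiguous even under the <= 3% voxelization error of the masks.  A
#' fraction of the series never grow and must return TTP = OS.
#'
#' @param n_series Number of series.
#' @param seed Integer seed.
#' @param n_follow Follow-ups per series (baseline excluded).
#' @param p_nonprogress Probability that a series never progresses.
#' @return List of [make_growth_series()] results.
#' @export
sample_growth_cohort <- function(n_series = 20L, seed = 1L, n_follow = 4L,
                                 p_nonprogress = 0.2) {
  with_seed(seed, {
    lapply(seq_len(n_series), function(i) {
      r0 <- runif(1, 8, 10)
      n_shrink <- sample(0:2, 1)
      progresses <- runif(1) >= p_nonprogress
      growths <- c(rep(-0.3, n_shrink),
                   rep(0, max(0, sample(0:1, 1))),
                   if (progresses) rep(1.0, 1))
      growths <- c(growths, rep(0, max(0L, n_follow - length(growths))))
      growths <- growths[seq_len(n_follow)]
      days <- as.integer(round(cumsum(c(runif(1, 25, 40),
                                        runif(n_follow, 70, 110)))))
      os <- days[length(days)] + as.integer(round(runif(1, 100, 250)))
      base <- phantom_spec("sphere", shape = c(44L, 44L, 44L),
                           radius_mm = r0, seed = seed + i)
      gs <- make_growth_series(base, growths, days, os)
      gs$patient_id <- sprintf("P%03d", i)
      gs$series$patient_id <- gs$patient_id
      gs
    })
  })
}

#' Synthetic rater table with analytic expected ICC
#'
#' Scores are `subject effect + rater offset + noise`; the expected
#' consistency ICC is `subject_sd^2 / (subject_sd^2 + noise_sd^2)` (rater
#' offsets do not enter, which is exactly why the consistency variant is
#' used for response assessment).
#'
#' @param n_subjects,k_raters Table dimensions.
#' @param subject_sd,noise_sd Standard deviations (>= 0).
#' @param rater_offsets Length-`k_raters` vector of constant offsets.
#' @param seed Integer seed.
#' @return Numeric matrix with attribute `"expected_icc"`.
#' @export
make_rater_table <- function(n_subjects, k_raters, subject_sd = 1,
                             rater_offsets = rep(0, k_raters), noise_sd = 0,
                             seed = 1L) {
  stopifnot(subject_sd >= 0, noise_sd >= 0,
            length(rater_offsets) == k_raters)
  scores <- with_seed(seed, {
    subj <- rnorm(n_subjects, sd = subject_sd)
    noise <- matrix(if (noise_sd > 0) rnorm(n_subjects * k_raters,
                                            sd = noise_sd) else 0,
                    n_subjects, k_raters)
    outer(subj, rep(1, k_raters)) +
      outer(rep(1, n_subjects), rater_offsets) + noise
  })
  attr(scores, "expected_icc") <-
    if (subject_sd == 0 && noise_sd == 0) NA_real_
    else subject_sd^2 / (subject_sd^2 + noise_sd^2)
  scores
}
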