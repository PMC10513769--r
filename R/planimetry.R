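#' @title Automated bidimensional (Macdonald) measurement
#' @description Per-lesion 2D measurement on axial slices: the longest
#'   diameter lying entirely inside the enhancement, found by exhaustive
#'   search over sub-voxel contour vertices across all slices, and the
#'   largest fully contained perpendicular diameter on the same slice and
#'   region, within an angular tolerance of 90 +/- `tol_deg` degrees.
#' @name planimetry2d
NULL

new_segment <- function(endpoints, slice_index = NA_integer_,
                        region_id = NA_integer_) {
  endpoints <- matrix(as.numeric(endpoints), nrow = 2)
  structure(list(endpoints_mm = endpoints,
                 length_mm = sqrt(sum((endpoints[2, ] - endpoints[1, ])^2)),
                 slice_index = as.integer(slice_index),
                 region_id = as.integer(region_id)),
            class = "diameter_segment")
}

#' @export
print.diameter_segment <- function(x, ...) {
  cat(sprintf("<diameter_segment> %.3f mm%s\n", x$length_mm,
              if (!is.na(x$slice_index))
                sprintf(" (slice %d)", x$slice_index) else ""))
  invisible(x)
}

# canonical endpoint order (lexicographic), used for deterministic output
order_endpoints <- function(ep) {
  cmp <- ep[1, ] - ep[2, ]
  first <- cmp[which(abs(cmp) > 1e-12)[1]]
  if (!is.na(first) && first > 0) ep[2:1, , drop = FALSE] else ep
}

segment_key <- function(ep) as.vector(t(order_endpoints(ep)))

# d1 (and its perpendicular d2) for the rings of ONE in-slice region.
# Ties in d1 (within tie_eps) are resolved toward the chord admitting the
# largest perpendicular diameter, then lexicographically by endpoints.
measure_region_2d <- function(rings, contain_step = 0.2, tol_deg = 2,
                              tie_eps = 1e-6, max_ties = 64L) {
  verts <- do.call(rbind, rings)
  if (is.null(verts) || nrow(verts) < 2L) {
    p <- if (is.null(verts)) c(0, 0) else verts[1, ]
    return(list(d1 = new_segment(rbind(p, p)), d2 = NULL))
  }
  ties <- longest_chord2d_cpp(verts, rings, contain_step, NULL, 0, tie_eps)
  if (nrow(ties) == 0L)
    return(list(d1 = new_segment(rbind(verts[1, ], verts[1, ])), d2 = NULL))
  if (nrow(ties) > max_ties) ties <- ties[seq_len(max_ties), , drop = FALSE]
  best <- NULL
  for (r in seq_len(nrow(ties))) {
    ep <- verts[ties[r, 1:2], , drop = FALSE]
    dir <- ep[2, ] - ep[1, ]
    perp <- longest_chord2d_cpp(verts, rings, contain_step, dir, tol_deg,
                                tie_eps)
    d2len <- if (nrow(perp) > 0L) perp[1, 3] else -1
    cand <- list(d1len = ties[r, 3], d2len = d2len, ep = ep,
                 perp_ep = if (nrow(perp) > 0L)
                   verts[perp[1, 1:2], , drop = FALSE] else NULL)
    if (is.null(best) || cand$d2len > best$d2len + 1e-12 ||
        (abs(cand$d2len - best$d2len) <= 1e-12 &&
         isTRUE(vector_less(segment_key(cand$ep), segment_key(best$ep)))))
      best <- cand
  }
  d1 <- new_segment(order_endpoints(best$ep))
  d2 <- if (!is.null(best$perp_ep))
    new_segment(order_endpoints(best$perp_ep)) else NULL
  list(d1 = d1, d2 = d2)
}

vector_less <- function(a, b) {
  d <- a - b
  i <- which(abs(d) > 1e-12)[1]
  !is.na(i) && d[i] < 0
}

#' Longest fully contained in-plane diameter of one region
#'
#' Exhaustive search over all pairs of (sub-voxel resampled) contour
#' vertices of one in-slice region for the longest segment that lies
#' entirely inside the region.  Containment is verified by sampling the
#' segment interior at steps of at most `contain_step` mm and testing each
#' sample against the region polygon (outer boundary and holes, even-odd
#' rule), so chords that shortcut across concavities or holes are rejected.
#'
#' @param contours List of closed polygons (n x 2 mm matrices) of one
#'   region, as produced by [slice_contours()] (outer boundary first is not
#'   required).
#' @param contain_step Containment sampling step in mm (default 0.2).
#' @param tol_deg Perpendicular angular tolerance used only to resolve ties
#'   between equally long candidates (default 2).
#' @return A `diameter_segment`; zero length for a degenerate single-point
#'   region.
#' @export
longest_inplane_diameter <- function(contours, contain_step = 0.2,
                                     tol_deg = 2) {
  measure_region_2d(contours, contain_step = contain_step,
                    tol_deg = tol_deg)$d1
}

#' Largest perpendicular diameter
#'
#' The longest fully contained segment between contour vertices of the same
#' region whose angle to the longest diameter lies within 90 +/- `tol_deg`
#' degrees.  The perpendicular is not required to intersect the longest
#' diameter; only the angle window and containment are enforced.
#'
#' @param longest A `diameter_segment` with positive length.
#' @param contours Contours of the same region (see
#'   [longest_inplane_diameter()]).
#' @param tol_deg Angular tolerance in degrees (default 2, i.e. 90 +/- 2).
#' @param contain_step Containment sampling step in mm.
#' @return A `diameter_segment`, or `NULL` when no contained vertex pair
#'   satisfies the angle window.
#' @export
perpendicular_diameter <- function(longest, contours, tol_deg = 2,
                                   contain_step = 0.2) {
  stopifnot(inherits(longest, "diameter_segment"), longest$length_mm > 0)
  verts <- do.call(rbind, contours)
  dir <- longest$endpoints_mm[2, 1:2] - longest$endpoints_mm[1, 1:2]
  perp <- longest_chord2d_cpp(verts, contours, contain_step, dir, tol_deg,
                              1e-6)
  if (nrow(perp) == 0L) return(NULL)
  new_segment(order_endpoints(verts[perp[1, 1:2], , drop = FALSE]),
              slice_index = longest$slice_index,
              region_id = longest$region_id)
}

new_bidim <- function(longest, perpendicular, mode, lesion_id = NA_integer_) {
  product <- if (is.null(perpendicular)) 0 else
    longest$length_mm * perpendicular$length_mm
  structure(list(longest = longest, perpendicular = perpendicular,
                 product_mm2 = product, mode = mode,
                 lesion_id = as.integer(lesion_id)),
            class = "bidim_measurement")
}

#' @export
print.bidim_measurement <- function(x, ...) {
  cat(sprintf("<bidim_measurement %s> d1 = %.3f mm, d2 = %s, product = %.3f mm^2\n",
              x$mode, x$longest$length_mm,
              if (is.null(x$perpendicular)) "absent"
              else sprintf("%.3f mm", x$perpendicular$length_mm),
              x$product_mm2))
  invisible(x)
}

#' Bidimensional Macdonald measurement of one lesion
#'
#' Maximises the longest contained diameter over all axial slices and
#' in-slice regions of the lesion (lexicographic optimisation: longest
#' diameter first, then the largest perpendicular diameter on the winning
#' slice and region), and records slice index and endpoint coordinates for
#' inspection.  If one 3D lesion is cut into several in-slice regions, each
#' region is measured independently and cross-region chords are never
#' considered (they would leave the enhancement).
#'
#' @param lesion A `lesion` from [extract_lesions()].
#' @param parent The parent [seg_mask] (optional; spacing and axial axis are
#'   carried by the lesion itself).
#' @param step_mm Contour arc-length resampling step in mm (default 0.1).
#' @param contain_step Containment sampling step in mm (default 0.2).
#' @param tol_deg Perpendicular angular tolerance in degrees (default 2).
#' @return A `bidim_measurement` with mode `"axial2d"`; endpoints are 3D mm
#'   coordinates in the parent voxel frame.
#' @export
measure_lesion_2d <- function(lesion, parent = NULL, step_mm = 0.1,
                              contain_step = 0.2, tol_deg = 2) {
  stopifnot(inherits(lesion, "lesion"))
  la <- lesion_array(lesion, pad = 1L)
  a <- lesion$axial_axis
  inplane <- setdiff(1:3, a)
  sp <- lesion$spacing
  lo <- lesion$bbox[1, ] - 1L  # cropped slice k maps to parent index k + lo[a] - 1
  best <- NULL
  for (k in seq_len(la$dim[a])) {
    idx <- list(quote(expr = ), quote(expr = ), quote(expr = ))
    idx[[a]] <- k
    slc <- do.call(`[`, c(list(la$arr), idx, list(drop = FALSE)))
    slc <- array(slc, dim(slc)[inplane])
    if (!any(slc > 0)) next
    rings_all <- slice_rings(slc, sp[inplane[1]], sp[inplane[2]], step_mm)
    if (!length(rings_all)) next
    regs <- vapply(rings_all, function(r) attr(r, "region"), integer(1))
    for (reg in unique(regs)) {
      rings <- rings_all[regs == reg]
      vb <- apply(do.call(rbind, rings), 2, range)
      diag <- sqrt(sum((vb[2, ] - vb[1, ])^2))
      if (!is.null(best) && diag < best$mr$d1$length_mm - 1e-6) next
      mr <- measure_region_2d(rings, contain_step = contain_step,
                              tol_deg = tol_deg)
      cand <- list(mr = mr, k = k, reg = reg)
      if (is.null(best)) { best <- cand; next }
      d1n <- mr$d1$length_mm; d1b <- best$mr$d1$length_mm
      d2n <- if (is.null(mr$d2)) -1 else mr$d2$length_mm
      d2b <- if (is.null(best$mr$d2)) -1 else best$mr$d2$length_mm
      if (d1n > d1b + 1e-6 ||
          (d1n > d1b - 1e-6 && d2n > d2b + 1e-12))
        best <- cand
    }
  }
  to3d <- function(seg, k) {
    if (is.null(seg)) return(NULL)
    ep <- matrix(NA_real_, 2, 3)
    ep[, inplane] <- sweep(seg$endpoints_mm, 2, la$offset_mm[inplane], "+")
    ep[, a] <- la$offset_mm[a] + (k - 1) * sp[a]
    new_segment(ep, slice_index = k + lo[a] - 1L, region_id = best$reg)
  }
  new_bidim(to3d(best$mr$d1, best$k), to3d(best$mr$d2, best$k),
            mode = "axial2d", lesion_id = lesion$lesion_id)
}
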