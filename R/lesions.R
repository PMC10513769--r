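#' Split an enhancing mask into separate lesions
#'
#' Lesions are connected components of the binary foreground under
#' 26-connectivity: voxels touching by a face, an edge or a corner belong to
#' the same lesion (the contrapositive of the separation rule used for
#' automated bidimensional measurement, under which a lesion counts as
#' separate only if its voxels touch no other lesion at faces, edges or
#' corners).  In a single-slice grid this degenerates to 8-connectivity
#' in-plane.  Lesions are returned in decreasing voxel-count order, ties
#' broken by the first voxel in array (column-major) raster order, so
#' lesion ids are reproducible.
#'
#' @param mask A [seg_mask]; any positive label is foreground.
#' @return A list of `lesion` objects (empty for an empty mask).  Each
#'   lesion carries `lesion_id`, `voxels` (n x 3 matrix of 1-based array
#'   indices), `n_voxels`, `spacing`, `parent_dim`, `centroid_mm` and
#'   `bbox` (2 x 3 index ranges).
#' @export
extract_lesions <- function(mask) {
  stopifnot(inherits(mask, "seg_mask"))
  fg <- mask_foreground(mask)
  if (!any(fg)) return(list())
  lab <- label_components_cpp(as.logical(fg), dim(fg))
  pos <- which(lab > 0L)
  comp <- lab[pos]
  vox <- arrayInd(pos, dim(fg))
  sizes <- tabulate(comp)
  # components were labelled in raster order of their first voxel, so the
  # label itself is the lexicographic tie-break
  ord <- order(-sizes, seq_along(sizes))
  lesions <- vector("list", length(ord))
  for (r in seq_along(ord)) {
    v <- vox[comp == ord[r], , drop = FALSE]
    lesions[[r]] <- structure(list(
      lesion_id = r,
      voxels = v,
      n_voxels = nrow(v),
      spacing = mask$spacing,
      parent_dim = dim(fg),
      axial_axis = mask$axial_axis,
      centroid_mm = colMeans((v - 1) * rep(mask$spacing, each = nrow(v))),
      bbox = apply(v, 2, range)),
      class = "lesion")
  }
  lesions
}

#' @export
print.lesion <- function(x, ...) {
  cat(sprintf("<lesion %d> %d voxels, centroid (%s) mm\n", x$lesion_id,
              x$n_voxels, paste(format(x$centroid_mm, digits = 4),
                                collapse = ", ")))
  invisible(x)
}

#' Binary mask of a single lesion
#'
#' @param lesion A `lesion` from [extract_lesions()].
#' @param parent The [seg_mask] the lesion was extracted from.
#' @return A binary [seg_mask] with only this lesion's voxels set.
#' @export
lesion_mask <- function(lesion, parent) {
  stopifnot(inherits(lesion, "lesion"), inherits(parent, "seg_mask"))
  d <- dim(parent$labels)
  if (!identical(as.integer(lesion$parent_dim), as.integer(d)))
    stop("lesion was not extracted from this parent grid")
  if (any(lesion$voxels < 1L) || any(lesion$voxels > rep(d, each = nrow(lesion$voxels))))
    stop("lesion indices outside the parent grid")
  lab <- array(0L, d)
  lab[lesion$voxels] <- 1L
  seg_mask(lab, spacing = parent$spacing, origin = parent$origin,
           axial_axis = parent$axial_axis, source = parent$source)
}

# cropped 0/1 array of one lesion with `pad` background layers;
# offset_mm gives the parent-frame mm position of array voxel (1,1,1)
lesion_array <- function(lesion, pad = 1L) {
  lo <- lesion$bbox[1, ] - pad
  hi <- lesion$bbox[2, ] + pad
  d <- hi - lo + 1L
  arr <- array(0, d)
  arr[sweep(lesion$voxels, 2, lo - 1L)] <- 1
  list(arr = arr, offset_mm = (lo - 1) * lesion$spacing, dim = d)
}
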