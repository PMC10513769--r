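#' Segmentation mask in physical space
#'
#' A 3D integer label grid with voxel spacing (mm), a physical origin and a
#' designated axial (through-plane, superior-inferior) array axis.  All
#' geometry in the package is computed in millimetres with a voxel-centre
#' convention: the centre of voxel `(i, j, k)` (1-based) lies at
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param labels 3D array of non-negative integers (0 = background).
#' @param spacing Numeric length-3, voxel size per axis in mm (all > 0).
#' @param origin Numeric length-3, physical position of voxel (1,1,1) in mm.
#' @param axial_axis Which array axis is through-plane (1, 2 or 3).
#' @param source Provenance string (file path or description).
#' @return An object of class `seg_mask`.
#' @export
seg_mask <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     axial_axis = 3L, source = NA_character_) {
  if (length(dim(labels)) != 3L) stop("`labels` must be a 3D array")
  if (is.logical(labels)) labels <- array(as.integer(labels), dim(labels))
  if (!is.integer(labels)) {
    if (any(abs(labels - round(labels)) > 1e-6, na.rm = TRUE))
      stop("`labels` must be integer-valued")
    labels <- array(as.integer(round(labels)), dim(labels))
  }
  if (any(labels < 0L)) stop("labels must be non-negative")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm)")
  axial_axis <- as.integer(axial_axis)
  if (!axial_axis %in% 1:3) stop("`axial_axis` must be 1, 2 or 3")
  structure(list(labels = labels, spacing = spacing,
                 origin = as.numeric(origin), axial_axis = axial_axis,
                 source = source),
            class = "seg_mask")
}

#' @export
print.seg_mask <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<seg_mask> %d x %d x %d voxels, spacing %s mm, axial axis %d\n",
              d[1], d[2], d[3],
              paste(format(x$spacing, digits = 4), collapse = " x "),
              x$axial_axis))
  cat(sprintf("  foreground voxels: %d\n", sum(x$labels > 0L)))
  invisible(x)
}

#' @export
dim.seg_mask <- function(x) dim(x$labels)

# logical foreground array
mask_foreground <- function(mask) mask$labels > 0L

#' Load a NIfTI label map as a binary enhancing mask
#'
#' Reads a NIfTI volume with integer labels, optionally reorients it to the
#' canonical RAS axis order (so the third array axis is superior-inferior),
#' and binarises it: voxels whose label is mapped to the contrast-enhancing
#' class become foreground, every other label is background.  Segmentation
#' tools disagree on numeric label codes, so the mapping is always explicit.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param label_map Named character vector mapping label values to class
#'   names, e.g. `c("1" = "enhancing", "2" = "edema")`; labels mapped to
#'   `"enhancing"` form the foreground.  Overrides `enhancing`.
#' @param enhancing Integer vector of enhancing label values (default 1).
#' @param reorient Reorient to RAS axis order on load (default `TRUE`); with
#'   conventional axial acquisitions the axial axis is then axis 3.
#' @param axial_axis Optional override of the axial axis index.
#' @return A binary [seg_mask] (labels 0/1).
#' @export
load_mask <- function(path, label_map = NULL, enhancing = 1L,
                      reorient = TRUE, axial_axis = NULL) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  img <- RNifti::readNifti(path)
  has_form <- tryCatch(attr(RNifti::xform(img), "code") > 0,
                       error = function(e) FALSE)
  if (isTRUE(reorient) && isTRUE(has_form))
    RNifti::orientation(img) <- "RAS"
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop("expected a 3D label volume, got ", length(dim(arr)), " dimensions: ", path)
  if (any(abs(arr - round(arr)) > 1e-6))
    stop("non-integer voxel values; not a label map: ", path)
  arr <- round(arr)
  if (!is.null(label_map)) {
    enhancing <- as.numeric(names(label_map)[label_map == "enhancing"])
    if (!length(enhancing))
      stop("label_map does not map any label to class 'enhancing'")
  }
  fg <- array(as.integer(arr %in% as.numeric(enhancing)), dim(arr))
  spacing <- as.numeric(RNifti::pixdim(img))[1:3]
  xf <- tryCatch(RNifti::xform(img), error = function(e) NULL)
  origin <- if (!is.null(xf)) as.numeric(xf[1:3, 4]) else c(0, 0, 0)
  if (is.null(axial_axis)) {
    axial_axis <- if (!is.null(xf)) which.max(abs(xf[3, 1:3])) else 3L
  }
  seg_mask(fg, spacing = spacing, origin = origin,
           axial_axis = axial_axis, source = normalizePath(path))
}

#' Write a segmentation mask to NIfTI
#'
#' @param mask A [seg_mask].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "seg_mask"))
  xf <- diag(c(mask$spacing, 1))
  xf[1:3, 4] <- mask$origin
  img <- RNifti::asNifti(mask$labels)
  RNifti::pixdim(img) <- mask$spacing   # writeNifti scales the forms by pixdim
  img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
  img <- RNifti::`qform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a label mask to isotropic voxels
#'
#' Nearest-neighbour resampling of the label grid to an isotropic voxel size,
#' preserving the physical extent to within one voxel.  The standard
#' preprocessing convention is 1 mm isotropic voxels; all measurement
#' operators also work at native anisotropic spacing, so resampling is
#' optional.
#'
#' @param mask A [seg_mask].
#' @param target_mm Target isotropic voxel size in mm (> 0).
#' @return A resampled [seg_mask] with spacing `c(t, t, t)`.
#' @export
resample_iso <- function(mask, target_mm = 1) {
  stopifnot(inherits(mask, "seg_mask"), is.numeric(target_mm), target_mm > 0)
  sp <- mask$spacing
  d <- dim(mask$labels)
  nd <- pmax(1L, as.integer(round(d * sp / target_mm)))
  idx <- lapply(1:3, function(a) {
    x <- (seq_len(nd[a]) - 1) * target_mm          # new voxel-centre positions
    j <- as.integer(floor(x / sp[a] + 0.5)) + 1L   # nearest source voxel,
    # half-way points resolved upward so replication counts stay uniform
    pmin(pmax(j, 1L), d[a])
  })
  lab <- mask$labels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  seg_mask(lab, spacing = rep(target_mm, 3), origin = mask$origin,
           axial_axis = mask$axial_axis, source = mask$source)
}
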