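#' Construct a binary label volume
#'
#' A `label_volume` is the image currency of the package: a 3D array of 0/1
#' labels together with its voxel spacing in millimetres and the index of the
#' axial (slice) axis. Clinical FLAIR acquisitions in this setting are strongly
#' anisotropic (in-plane ~0.4-1 mm, slices 5-6 mm), so the spacing travels with
#' the voxel grid and every metric operation (dilation radii, distances,
#' volumes) consumes it.
#'
#' @param voxels 3D array coercible to 0/1 (logical or numeric in \{0,1\}).
#' @param spacing Numeric length-3, voxel edge lengths in mm, all > 0.
#' @param axial_axis Index (1-3) of the slice axis. Default: the axis with the
#'   largest spacing, since thick slices dominate in-plane resolution here.
#' @return An object of class `label_volume` with elements `voxels` (logical
#'   array), `spacing` and `axial_axis`.
#' @examples
#' v <- label_volume(array(0L, c(4, 4, 2)), spacing = c(1, 1, 6))
#' v$axial_axis
#' @export
label_volume <- function(voxels, spacing, axial_axis = NULL) {
  if (length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3D array, got ", length(dim(voxels)), " dimensions")
  }
  if (any(dim(voxels) < 1L)) stop("all dimensions must be positive")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive finite mm lengths")
  }
  vals <- unique(as.vector(voxels))
  if (!all(vals %in% c(0, 1, TRUE, FALSE))) {
    stop("label values must all be 0 or 1; binarize with a threshold first")
  }
  vox <- array(as.logical(voxels), dim = dim(voxels))
  if (is.null(axial_axis)) axial_axis <- which.max(spacing)
  axial_axis <- as.integer(axial_axis)
  if (!axial_axis %in% 1:3) stop("`axial_axis` must be 1, 2 or 3")
  structure(
    list(voxels = vox, spacing = spacing, axial_axis = axial_axis),
    class = "label_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf(
    "<label_volume> %s voxels, spacing %s mm, axial axis %d, %d foreground\n",
    paste(dim(x$voxels), collapse = "x"),
    paste(format(x$spacing, trim = TRUE), collapse = "x"),
    x$axial_axis, sum(x$voxels)
  ))
  invisible(x)
}

#' @export
dim.label_volume <- function(x) dim(x$voxels)

#' Number of foreground voxels
#' @param vol A `label_volume`.
#' @return Integer count of voxels labeled 1.
#' @export
n_foreground <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  sum(vol$voxels)
}

#' Read a NIfTI file as a binary label volume
#'
#' Reads a 3D NIfTI image (`.nii` or `.nii.gz`), binarizes it with a strict
#' threshold (`value > threshold` is foreground), and takes the voxel spacing
#' from the header. No reorientation or resampling is performed: the partition
#' and all volumes are computed on the stored grid, which is correct as long
#' as the axial axis is identified (by default the axis of maximum spacing,
#' the thick-slice axis in this regime).
#'
#' @param path Path to a NIfTI file.
#' @param threshold Binarization cut; voxels strictly above it become
#'   foreground. Default 0.5, suited to probabilistic masks stored in [0,1].
#' @param axial_axis Optional override for the slice axis (1-3).
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, threshold = 0.5, axial_axis = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(as.array(img)[, , , 1], dim = d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L) {
    stop("expected a 3D volume, got ", length(d), "D in ", path)
  }
  spacing <- abs(RNifti::pixdim(img))[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("non-positive voxel spacing in NIfTI header of ", path)
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    stop("`threshold` must be a scalar >= 0")
  }
  label_volume(as.array(img) > threshold, spacing = spacing,
               axial_axis = axial_axis)
}

#' Write a label volume to NIfTI
#'
#' @param vol A [label_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param values Optional integer array of the same shape to write instead of
#'   the 0/1 mask (used for combined PVH=1/DWMH=2 label maps).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path, values = NULL) {
  stopifnot(inherits(vol, "label_volume"))
  arr <- if (is.null(values)) {
    array(as.integer(vol$voxels), dim = dim(vol$voxels))
  } else {
    stopifnot(identical(dim(values), dim(vol$voxels)))
    array(as.integer(values), dim = dim(values))
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Bundle a subject's brain, ventricle and WMH masks
#'
#' Validates that the three co-registered masks live on one grid: identical
#' shapes (exact) and identical spacing (within 1e-4 mm). Ventricle voxels
#' outside the brain mask raise a warning, not an error, since segmentation
#' models occasionally disagree at the brain boundary; an empty brain mask is
#' an error because volume normalization divides by brain volume.
#'
#' @param brain,ventricles,wmh [label_volume()] objects.
#' @param subject_id Opaque subject identifier.
#' @return An object of class `mask_bundle`.
#' @export
mask_bundle <- function(brain, ventricles, wmh, subject_id = "subject") {
  vols <- list(brain = brain, ventricles = ventricles, wmh = wmh)
  for (nm in names(vols)) {
    if (!inherits(vols[[nm]], "label_volume")) {
      stop("`", nm, "` must be a label_volume")
    }
  }
  ref <- dim(brain$voxels)
  for (nm in c("ventricles", "wmh")) {
    if (!identical(dim(vols[[nm]]$voxels), ref)) {
      stop("shape mismatch: `", nm, "` is ",
           paste(dim(vols[[nm]]$voxels), collapse = "x"),
           " but `brain` is ", paste(ref, collapse = "x"))
    }
    if (any(abs(vols[[nm]]$spacing - brain$spacing) > 1e-4)) {
      stop("spacing mismatch: `", nm, "` differs from `brain` by more than 1e-4 mm")
    }
  }
  if (!any(brain$voxels)) stop("brain mask is empty")
  if (any(ventricles$voxels & !brain$voxels)) {
    warning("ventricle mask extends outside the brain mask")
  }
  structure(
    list(brain = brain, ventricles = ventricles, wmh = wmh,
         subject_id = subject_id),
    class = "mask_bundle"
  )
}

#' @export
print.mask_bundle <- function(x, ...) {
  cat(sprintf(
    "<mask_bundle> subject '%s': brain %d, ventricles %d, wmh %d voxels\n",
    x$subject_id, sum(x$brain$voxels), sum(x$ventricles$voxels),
    sum(x$wmh$voxels)
  ))
  invisible(x)
}

#' Volume of one voxel in millilitres
#'
#' @param vol A [label_volume()].
#' @return Scalar voxel volume in mL (product of spacings / 1000).
#' @examples
#' voxel_volume_ml(label_volume(array(0L, c(2, 2, 2)), c(0.5, 0.5, 6)))
#' @export
voxel_volume_ml <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  prod(vol$spacing) / 1000
}
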