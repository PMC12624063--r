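#' Parameters of the periventricular/deep separation
#'
#' @param pv_distance_mm Radius of the periventricular shell in mm. Default
#'   10, the distance rule widely used to delimit periventricular white
#'   matter.
#' @param pv_fraction Overlap fraction above which a boundary-spanning lesion
#'   component is assigned wholly to PVH. Default 0.6; the comparison is
#'   strict (`> pv_fraction`), so a component with exactly 60% of its area in
#'   the shell is split voxelwise. Values 0.5-0.9 are the usual ablation
#'   range.
#' @param connectivity In-plane connectivity for per-slice component
#'   labeling: 4 or 8 (default 8).
#' @return An object of class `separation_params`.
#' @export
separation_params <- function(pv_distance_mm = 10, pv_fraction = 0.6,
                              connectivity = 8) {
  if (!is.numeric(pv_distance_mm) || length(pv_distance_mm) != 1L ||
      pv_distance_mm <= 0) {
    stop("`pv_distance_mm` must be a positive scalar")
  }
  if (!is.numeric(pv_fraction) || length(pv_fraction) != 1L ||
      pv_fraction <= 0 || pv_fraction > 1) {
    stop("`pv_fraction` must lie in (0, 1]")
  }
  if (!connectivity %in% c(4L, 8L)) stop("`connectivity` must be 4 or 8")
  structure(
    list(pv_distance_mm = pv_distance_mm, pv_fraction = pv_fraction,
         connectivity = as.integer(connectivity)),
    class = "separation_params"
  )
}

#' Anisotropic ellipsoidal structuring element
#'
#' Integer voxel offsets (di, dj, dk) whose physical displacement satisfies
#' (di*sx)^2 + (dj*sy)^2 + (dk*sz)^2 <= radius_mm^2. Dilating with this single
#' 3D element is equivalent to thresholding the anisotropic Euclidean distance
#' transform at `radius_mm`, and its central plane (dk = 0) is the in-plane
#' disk, so it also contains the union of separate 2D and 3D expansions.
#'
#' @param spacing mm spacing triple.
#' @param radius_mm dilation radius in mm.
#' @return Integer matrix with columns di, dj, dk.
#' @export
pv_structuring_element <- function(spacing, radius_mm) {
  stopifnot(length(spacing) == 3L, all(spacing > 0), radius_mm > 0)
  r <- floor(radius_mm / spacing)
  off <- as.matrix(expand.grid(di = -r[1]:r[1], dj = -r[2]:r[2],
                               dk = -r[3]:r[3]))
  d2 <- (off[, 1] * spacing[1])^2 + (off[, 2] * spacing[2])^2 +
    (off[, 3] * spacing[3])^2
  out <- off[d2 <= radius_mm^2 + 1e-9, , drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

#' Build the periventricular (PV) mask
#'
#' Expands the lateral-ventricle mask by `pv_distance_mm` with a spacing-aware
#' morphological dilation and subtracts the original ventricle voxels,
#' leaving the shell of voxels whose centers lie within the distance of some
#' ventricle voxel center.
#'
#' @param ventricles Ventricle [label_volume()] (nonempty).
#' @param params A [separation_params()].
#' @return PV shell as a [label_volume()], disjoint from the ventricles.
#' @export
build_pv_mask <- function(ventricles, params = separation_params()) {
  stopifnot(inherits(ventricles, "label_volume"),
            inherits(params, "separation_params"))
  if (!any(ventricles$voxels)) stop("ventricle mask is empty")
  sp <- reorder_spacing(ventricles)
  vox <- axial_last(ventricles$voxels, ventricles$axial_axis)
  se <- pv_structuring_element(sp, params$pv_distance_mm)
  span <- apply(abs(se), 2, max)
  if (all(span >= dim(vox))) {
    warning("structuring element spans the whole grid in every axis")
  }
  dil <- dilate_mask_cpp(as.vector(vox), dim(vox), se)
  dil <- array(dil, dim = dim(vox)) & !vox
  label_volume(axial_restore(dil, ventricles$axial_axis),
               spacing = ventricles$spacing,
               axial_axis = ventricles$axial_axis)
}

# permute so the axial axis is the third array dimension (and back)
axial_last <- function(arr, axial_axis) {
  if (axial_axis == 3L) return(arr)
  perm <- switch(axial_axis, `1` = c(2, 3, 1), `2` = c(1, 3, 2))
  aperm(arr, perm)
}

axial_restore <- function(arr, axial_axis) {
  if (axial_axis == 3L) return(arr)
  perm <- switch(axial_axis, `1` = c(3, 1, 2), `2` = c(1, 3, 2))
  aperm(arr, perm)
}

reorder_spacing <- function(vol) {
  a <- vol$axial_axis
  c(vol$spacing[setdiff(1:3, a)], vol$spacing[a])
}

#' Label in-plane connected components of a WMH mask
#'
#' Each axial slice is labeled independently (components are never merged
#' across slices, mirroring slice-wise visual reading of thick-slice FLAIR)
#' with 4- or 8-connectivity in plane.
#'
#' @param wmh WMH [label_volume()].
#' @param params A [separation_params()].
#' @return A list with `labels` (integer array in the input orientation;
#'   0 = background, components numbered from 1 uniquely across slices) and
#'   `components`, a data.frame with one row per component: `component`,
#'   `slice_index`, `area_vox`.
#' @export
extract_components <- function(wmh, params = separation_params()) {
  stopifnot(inherits(wmh, "label_volume"),
            inherits(params, "separation_params"))
  vox <- axial_last(wmh$voxels, wmh$axial_axis)
  lab <- array(label_slices_cpp(as.vector(vox), dim(vox),
                                params$connectivity),
               dim = dim(vox))
  if (max(lab) == 0L) {
    comps <- data.frame(component = integer(), slice_index = integer(),
                        area_vox = integer())
  } else {
    idx <- which(lab > 0L)
    slice_of_voxel <- ((idx - 1L) %/% (dim(vox)[1] * dim(vox)[2])) + 1L
    comp_id <- lab[idx]
    area <- as.integer(tabulate(comp_id))
    slice_index <- as.integer(tapply(slice_of_voxel, comp_id, `[`, 1L))
    comps <- data.frame(component = seq_along(area),
                        slice_index = slice_index, area_vox = area)
  }
  list(labels = axial_restore(lab, wmh$axial_axis), components = comps)
}

#' Classify one lesion component against the PV mask
#'
#' Decision rule for a per-slice connected WMH component: entirely inside the
#' PV shell it is PVH; entirely outside, DWMH; spanning the boundary it is
#' assigned wholly to PVH when strictly more than `pv_fraction` of its voxels
#' fall inside the shell, and otherwise split voxelwise (in-shell voxels to
#' PVH, the rest to DWMH).
#'
#' @param area_vox Component voxel count (>= 1).
#' @param in_pv_vox Number of those voxels inside the PV mask.
#' @param params A [separation_params()].
#' @return One of `"PVH"`, `"DWMH"`, `"split"`.
#' @export
classify_component <- function(area_vox, in_pv_vox,
                               params = separation_params()) {
  stopifnot(area_vox >= 1, in_pv_vox >= 0, in_pv_vox <= area_vox)
  if (in_pv_vox == area_vox) return("PVH")
  if (in_pv_vox == 0) return("DWMH")
  if (in_pv_vox / area_vox > params$pv_fraction) "PVH" else "split"
}

#' Separate a WMH mask into periventricular and deep components
#'
#' Orchestrates the full partition: build the PV shell from the ventricles,
#' label WMH components per axial slice, and classify each component with the
#' overlap rule. Every WMH voxel ends up in exactly one of the PVH or DWMH
#' masks.
#'
#' @param bundle A [mask_bundle()].
#' @param params A [separation_params()].
#' @return An object of class `separation_result`: `pvh_mask`, `dwmh_mask`,
#'   `pv_mask` ([label_volume()]s), and `components`, a data.frame with
#'   columns `component`, `slice_index`, `area_vox`, `in_pv_vox`, `assigned`.
#' @export
separate <- function(bundle, params = separation_params()) {
  stopifnot(inherits(bundle, "mask_bundle"),
            inherits(params, "separation_params"))
  wmh <- bundle$wmh
  pvh <- array(FALSE, dim(wmh$voxels))
  dwmh <- array(FALSE, dim(wmh$voxels))
  cc <- extract_components(wmh, params)
  comps <- cc$components

  if (nrow(comps) > 0L) {
    pv <- build_pv_mask(bundle$ventricles, params)
    idx <- which(cc$labels > 0L)
    comp_id <- cc$labels[idx]
    in_pv <- pv$voxels[idx]
    in_pv_count <- as.integer(rowsum(as.integer(in_pv), comp_id))
    comps$in_pv_vox <- in_pv_count[comps$component]
    comps$assigned <- vapply(
      seq_len(nrow(comps)),
      function(i) classify_component(comps$area_vox[i], comps$in_pv_vox[i],
                                     params),
      character(1)
    )
    whole_pvh <- comps$component[comps$assigned == "PVH"]
    to_pvh <- comp_id %in% whole_pvh |
      (comps$assigned[comp_id] == "split" & in_pv)
    pvh[idx[to_pvh]] <- TRUE
    dwmh[idx[!to_pvh]] <- TRUE
  } else {
    if (any(bundle$ventricles$voxels)) {
      pv <- build_pv_mask(bundle$ventricles, params)
    } else {
      pv <- label_volume(array(FALSE, dim(wmh$voxels)), wmh$spacing,
                         wmh$axial_axis)
    }
    comps$in_pv_vox <- integer()
    comps$assigned <- character()
  }

  structure(
    list(
      pvh_mask = label_volume(pvh, wmh$spacing, wmh$axial_axis),
      dwmh_mask = label_volume(dwmh, wmh$spacing, wmh$axial_axis),
      pv_mask = pv,
      components = comps,
      params = params
    ),
    class = "separation_result"
  )
}

#' @export
print.separation_result <- function(x, ...) {
  cat(sprintf(
    "<separation_result> PVH %d, DWMH %d voxels; %d components (%d split)\n",
    sum(x$pvh_mask$voxels), sum(x$dwmh_mask$voxels), nrow(x$components),
    sum(x$components$assigned == "split")
  ))
  invisible(x)
}

#' Summarize lesion and brain volumes
#'
#' Converts voxel counts to millilitres and normalizes the lesion volumes by
#' total brain volume; the resulting dimensionless volume ratios are the
#' grading features, robust to inter-individual differences in head size.
#'
#' @param result A `separation_result` from [separate()].
#' @param bundle The [mask_bundle()] it came from.
#' @return An object of class `volume_summary`: `pvh_ml`, `dwmh_ml`,
#'   `brain_ml`, `pvh_ratio`, `dwmh_ratio`.
#' @export
summarize_volumes <- function(result, bundle) {
  stopifnot(inherits(result, "separation_result"),
            inherits(bundle, "mask_bundle"))
  vv <- voxel_volume_ml(bundle$brain)
  brain_ml <- sum(bundle$brain$voxels) * vv
  if (brain_ml <= 0) stop("brain volume is zero; cannot normalize")
  pvh_ml <- sum(result$pvh_mask$voxels) * vv
  dwmh_ml <- sum(result$dwmh_mask$voxels) * vv
  structure(
    list(pvh_ml = pvh_ml, dwmh_ml = dwmh_ml, brain_ml = brain_ml,
         pvh_ratio = pvh_ml / brain_ml, dwmh_ratio = dwmh_ml / brain_ml),
    class = "volume_summary"
  )
}

#' @export
print.volume_summary <- function(x, ...) {
  cat(sprintf(
    "<volume_summary> PVH %.3f mL (ratio %.5f), DWMH %.3f mL (ratio %.5f), brain %.1f mL\n",
    x$pvh_ml, x$pvh_ratio, x$dwmh_ml, x$dwmh_ratio, x$brain_ml
  ))
  invisible(x)
}
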