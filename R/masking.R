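#' Subject-level activation mask
#'
#' A voxel enters a subject's mask when its temporal-mean intensity is
#' strictly greater than the mean of those temporal means over all voxels.
#' This is the pre-ICA "activation above the grand mean" rule; ties are
#' excluded. The rule is invariant to positive affine rescaling of the
#' intensities, so each subject can be masked on its own scanner scale.
#'
#' @param scan A [subject_scan()].
#' @return A `brain_mask`: logical 3D `include` array plus the fixed voxel
#'   enumeration `voxel_index` (ascending linear index, x fastest).
#' @export
subject_mask <- function(scan) {
  stopifnot(inherits(scan, "subject_scan"))
  d <- dim(scan$data)
  tmean <- rowMeans(matrix(scan$data, prod(d[1:3]), d[4]))
  include <- tmean > mean(tmean)
  if (!any(include)) {
    abort(sprintf("scan '%s': empty mask (volume has no voxel above the grand mean)",
                  scan$subject_id))
  }
  new_brain_mask(array(include, d[1:3]))
}

#' Cohort group mask
#'
#' Intersection of subject-level masks: a voxel is retained only when it is
#' included for every subject. This is the cohort-common mask on which group
#' ICA operates.
#'
#' @param masks List of `brain_mask` objects on a shared grid.
#' @return A `brain_mask`.
#' @export
group_mask <- function(masks) {
  stopifnot(length(masks) >= 1L, all(vapply(masks, inherits, TRUE, "brain_mask")))
  ref <- dim(masks[[1]]$include)
  inc <- masks[[1]]$include
  for (m in masks[-1]) {
    if (!all(dim(m$include) == ref)) abort("masks do not share a grid")
    inc <- inc & m$include
  }
  if (!any(inc)) {
    sizes <- vapply(masks, function(m) m$n_voxels, 1L)
    abort(sprintf("empty group mask; per-subject mask sizes: %s",
                  paste(sizes, collapse = ", ")))
  }
  new_brain_mask(inc)
}

new_brain_mask <- function(include) {
  structure(
    list(include = include,
         voxel_index = which(include),
         n_voxels = sum(include),
         grid = dim(include)),
    class = "brain_mask"
  )
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask> %s grid, %d / %d voxels included\n",
              paste(x$grid, collapse = "x"), x$n_voxels, prod(x$grid)))
  invisible(x)
}

#' Extract the masked voxels-by-time matrix of a scan
#'
#' @param scan A [subject_scan()].
#' @param mask A `brain_mask` on the scan's grid.
#' @return A T x K numeric matrix (timepoints by masked voxels), in the
#'   mask's fixed voxel enumeration.
#' @export
masked_matrix <- function(scan, mask) {
  stopifnot(inherits(scan, "subject_scan"), inherits(mask, "brain_mask"))
  d <- dim(scan$data)
  if (!all(d[1:3] == mask$grid)) {
    abort(sprintf("scan '%s' grid does not match mask grid", scan$subject_id))
  }
  t(matrix(scan$data, prod(d[1:3]), d[4])[mask$voxel_index, , drop = FALSE])
}

#' Write a mask as a binary NIfTI volume
#'
#' @param mask A `brain_mask`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param affine Optional 4x4 voxel-to-mm matrix stored in the header.
#' @return The path, invisibly.
#' @export
write_mask_nifti <- function(mask, path, affine = NULL) {
  img <- RNifti::asNifti(array(as.integer(mask$include), mask$grid))
  RNifti::writeNifti(img, path)
  invisible(path)
}
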