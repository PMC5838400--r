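#' Construct a subject scan
#'
#' Bundles one subject's preprocessed 4D resting fMRI volume with its spatial
#' affine, repetition time and (optionally) realignment motion parameters.
#'
#' @param subject_id Character scalar identifying the subject.
#' @param data 4D numeric array (x, y, z, t) in scanner units.
#' @param affine 4x4 voxel-to-mm matrix. Defaults to an identity-orientation
#'   affine with 3 mm voxels.
#' @param tr Repetition time in seconds (> 0).
#' @param motion Optional t x 6 matrix of realignment parameters
#'   (3 translations in mm, 3 rotations in radians).
#'
#' @return An object of class `subject_scan`.
#' @export
subject_scan <- function(subject_id, data, affine = NULL, tr = 2,
                         motion = NULL) {
  if (!is.character(subject_id) || length(subject_id) != 1L) {
    abort("subject_id must be a single string")
  }
  d <- dim(data)
  if (length(d) != 4L) abort(sprintf("scan '%s': data must be 4D", subject_id))
  if (d[4] < 2L) {
    abort(sprintf("scan '%s': needs at least 2 timepoints, got %d",
                  subject_id, d[4]))
  }
  if (any(!is.finite(data))) {
    abort(sprintf("scan '%s': contains non-finite values", subject_id))
  }
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0) {
    abort(sprintf("scan '%s': tr must be a positive scalar", subject_id))
  }
  if (is.null(affine)) affine <- diag(c(3, 3, 3, 1))
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L))) {
    abort(sprintf("scan '%s': affine must be a 4x4 matrix", subject_id))
  }
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != d[4] || ncol(motion) != 6L) {
      abort(sprintf("scan '%s': motion must be %d x 6", subject_id, d[4]))
    }
    if (any(!is.finite(motion))) {
      abort(sprintf("scan '%s': motion contains non-finite values", subject_id))
    }
  }
  structure(
    list(subject_id = subject_id, data = data, affine = affine,
         tr = tr, motion = motion),
    class = "subject_scan"
  )
}

#' @export
print.subject_scan <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<subject_scan> %s: %d x %d x %d grid, %d volumes, TR %g s%s\n",
              x$subject_id, d[1], d[2], d[3], d[4], x$tr,
              if (is.null(x$motion)) "" else ", with motion parameters"))
  invisible(x)
}

#' @export
dim.subject_scan <- function(x) dim(x$data)

# shared-grid validation across a cohort; errors name the offending subject
check_shared_grid <- function(scans) {
  ref <- dim(scans[[1]]$data)[1:3]
  for (s in scans) {
    d <- dim(s$data)[1:3]
    if (!all(d == ref)) {
      abort(sprintf(
        "scan '%s' grid %s does not match cohort grid %s",
        s$subject_id, paste(d, collapse = "x"), paste(ref, collapse = "x")))
    }
  }
  invisible(ref)
}
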