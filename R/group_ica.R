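#' Subject-level PCA reduction
#'
#' First stage of temporal-concatenation group ICA: the masked, per-voxel
#' centered T x K data matrix is projected onto its top principal temporal
#' components, reducing the time dimension from T to `order`.
#'
#' @param scan A [subject_scan()].
#' @param mask A `brain_mask`.
#' @param order Number of principal components retained (<= T).
#' @return An `order` x K matrix with attributes `eigenvalues` (all T temporal
#'   eigenvalues of the voxel-averaged covariance) and `retained_variance`.
#' @export
reduce_subject <- function(scan, mask, order) {
  X <- masked_matrix(scan, mask)
  ti <- nrow(X)
  if (order > ti) {
    abort(sprintf("scan '%s': PCA order %d exceeds %d timepoints",
                  scan$subject_id, order, ti))
  }
  Xc <- sweep(X, 2L, colMeans(X))
  # eigendecompose the small T x T outer-product matrix
  e <- eigen(tcrossprod(Xc) / ncol(Xc), symmetric = TRUE)
  red <- t(e$vectors[, seq_len(order), drop = FALSE]) %*% Xc
  structure(red,
            eigenvalues = e$values,
            retained_variance = sum(e$values[seq_len(order)]) / sum(e$values))
}

#' Estimate group spatial components
#'
#' Second-stage PCA of the stacked subject-reduced data followed by ICA
#' unmixing; the resulting spatially independent maps are the cohort-common
#' components S_agg. Each map is sign-fixed to positive skewness.
#'
#' @param reduced_stack (N * order) x K matrix of row-bound subject
#'   reductions.
#' @param n_components Number of components to extract.
#' @param seed Integer seed controlling the random unmixing initialisation.
#' @param algorithm `"infomax"` (default) or `"fastica"`.
#' @param maxit,tol Iteration cap and convergence tolerance of the unmixing.
#' @return A `n_components` x K matrix (class attributes record convergence).
#' @export
estimate_group_components <- function(reduced_stack, n_components, seed = 1L,
                                      algorithm = c("infomax", "fastica"),
                                      maxit = 2000L, tol = 1e-6) {
  algorithm <- match.arg(algorithm)
  if (nrow(reduced_stack) < n_components) {
    abort(sprintf("stacked reduction has %d rows < %d components",
                  nrow(reduced_stack), n_components))
  }
  K <- ncol(reduced_stack)
  Xc <- reduced_stack - rowMeans(reduced_stack)
  e <- eigen(tcrossprod(Xc) / K, symmetric = TRUE)
  ev <- e$values[seq_len(n_components)]
  if (any(ev <= .Machine$double.eps * max(e$values))) {
    abort("group PCA is rank deficient at the requested model order")
  }
  # whiten: rows of Z are uncorrelated with unit variance over voxels
  Z <- diag(1 / sqrt(ev), n_components) %*%
    t(e$vectors[, seq_len(n_components), drop = FALSE]) %*% Xc

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  fit <- switch(algorithm,
                infomax = ica_infomax(Z, maxit = maxit, tol = tol),
                fastica = ica_fastica(Z, maxit = maxit, tol = tol))
  if (!fit$converged) {
    abort(sprintf("%s did not converge in %d iterations (last tol target %g)",
                  algorithm, fit$iterations, tol))
  }
  sf <- fix_signs(fit$W %*% Z)
  structure(sf$S,
            algorithm = algorithm,
            iterations = fit$iterations,
            converged = fit$converged)
}

#' Back-reconstruct subject maps and time courses
#'
#' Dual (spatial-temporal) regression against the group maps: the subject's
#' time courses A_i are the least-squares fit of the masked data onto the
#' group spatial maps, and the subject maps S_i are then the least-squares
#' fit of the data onto A_i. Both span the whole group mask.
#'
#' @param scan A [subject_scan()].
#' @param mask The group `brain_mask`.
#' @param s_agg C x K group component maps.
#' @return List with `maps` (C x K) and `timecourses` (T x C).
#' @export
back_reconstruct <- function(scan, mask, s_agg) {
  X <- masked_matrix(scan, mask)
  if (ncol(X) != ncol(s_agg)) {
    abort(sprintf("scan '%s': %d masked voxels but group maps have %d",
                  scan$subject_id, ncol(X), ncol(s_agg)))
  }
  Xc <- sweep(X, 2L, colMeans(X))
  StS <- tcrossprod(s_agg)
  if (rcond(StS) < 1e-12) abort("group maps are rank deficient over the mask")
  A <- Xc %*% t(s_agg) %*% chol2inv(chol(StS))
  AtA <- crossprod(A)
  if (rcond(AtA) < 1e-12) {
    abort(sprintf("scan '%s': time courses are rank deficient", scan$subject_id))
  }
  S <- chol2inv(chol(AtA)) %*% t(A) %*% Xc
  list(maps = S, timecourses = A)
}

#' Temporal-concatenation group spatial ICA with back-reconstruction
#'
#' Runs the full decomposition: per-subject PCA reduction, group PCA, ICA
#' unmixing into group maps, and dual-regression recovery of subject maps and
#' time courses.
#'
#' @param cohort An `rsn_cohort` from [load_cohort()] or [simulate_cohort()].
#' @param mask Optional group `brain_mask`; computed from the cohort's
#'   subject masks when `NULL`.
#' @param n_components Number of group components (75 at full scale).
#' @param subject_order Per-subject PCA order; defaults to
#'   `min(T - 1, ceiling(1.5 * n_components))`.
#' @inheritParams estimate_group_components
#' @return A `group_decomposition` with elements `s_agg` (C x K), `maps`
#'   (list of C x K per subject), `timecourses` (list of T x C), `mask`,
#'   `subject_ids`, `tr`.
#' @export
group_ica <- function(cohort, mask = NULL, n_components = 75L, seed = 1L,
                      algorithm = c("infomax", "fastica"),
                      subject_order = NULL, maxit = 2000L, tol = 1e-6) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(cohort, "rsn_cohort"))
  scans <- cohort$scans
  if (is.null(mask)) {
    mask <- group_mask(lapply(scans, subject_mask))
  }
  t_min <- min(vapply(scans, function(s) dim(s$data)[4], 1L))
  if (is.null(subject_order)) {
    subject_order <- min(t_min - 1L, ceiling(1.5 * n_components))
  }
  if (subject_order > t_min) {
    abort(sprintf("subject PCA order %d exceeds shortest scan (%d volumes)",
                  subject_order, t_min))
  }
  rsn_log("group_ica", "N=%d K=%d order=%d C=%d algorithm=%s seed=%d",
          length(scans), mask$n_voxels, subject_order, n_components,
          algorithm, seed)
  reduced <- lapply(scans, reduce_subject, mask = mask, order = subject_order)
  stack <- do.call(rbind, reduced)
  s_agg <- estimate_group_components(stack, n_components, seed = seed,
                                     algorithm = algorithm,
                                     maxit = maxit, tol = tol)
  br <- lapply(scans, back_reconstruct, mask = mask, s_agg = s_agg)
  structure(
    list(s_agg = unclass_matrix(s_agg),
         maps = lapply(br, `[[`, "maps"),
         timecourses = lapply(br, `[[`, "timecourses"),
         mask = mask,
         subject_ids = vapply(scans, `[[`, "", "subject_id"),
         tr = scans[[1]]$tr,
         n_components = as.integer(n_components),
         subject_order = as.integer(subject_order),
         algorithm = attr(s_agg, "algorithm"),
         iterations = attr(s_agg, "iterations"),
         seed = as.integer(seed)),
    class = "group_decomposition"
  )
}

unclass_matrix <- function(x) {
  attributes(x) <- attributes(x)["dim"]
  x
}

#' Standardize component maps to zero mean and unit population variance
#'
#' ICA leaves map scale arbitrary, and the Euclidean deviation metric is
#' scale-sensitive; standardising every map over the K masked voxels puts
#' subject and group maps on a common footing before any metric is applied.
#'
#' @param maps C x K matrix of maps (rows are components).
#' @return The standardized matrix.
#' @export
standardize_maps <- function(maps) {
  t(apply(maps, 1L, standardize_vec, what = "component map"))
}

#' Greedy component matching by absolute correlation
#'
#' Pairs rows of `est` with rows of `truth` by repeatedly taking the pair
#' with the largest absolute correlation among unassigned rows. Used to
#' compare decompositions with known ground-truth maps, where component order
#' and sign are arbitrary.
#'
#' @param est,truth Matrices with the same number of columns.
#' @return Tibble with `est`, `truth`, `abs_cor` columns, one row per match.
#' @export
match_components <- function(est, truth) {
  cm <- abs(cor(t(est), t(truth)))
  n <- min(nrow(est), nrow(truth))
  out <- vector("list", n)
  for (k in seq_len(n)) {
    idx <- arrayInd(which.max(cm), dim(cm))
    out[[k]] <- tibble::tibble(est = idx[1], truth = idx[2],
                               abs_cor = cm[idx[1], idx[2]])
    cm[idx[1], ] <- -Inf
    cm[, idx[2]] <- -Inf
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$truth)
}

#' @export
print.group_decomposition <- function(x, ...) {
  cat(sprintf(
    "<group_decomposition> %d subjects, %d components over %d voxels (%s, %d iterations)\n",
    length(x$subject_ids), x$n_components, x$mask$n_voxels,
    x$algorithm, x$iterations))
  invisible(x)
}

#' @describeIn group_ica Per-component summary: map skewness, kurtosis and the
#'   mean subject-to-group map correlation.
#' @param x A `group_decomposition`.
#' @param ... Unused.
#' @method tidy group_decomposition
#' @export
tidy.group_decomposition <- function(x, ...) {
  C <- x$n_components
  purrr::map_dfr(seq_len(C), function(j) {
    g <- x$s_agg[j, ]
    z <- (g - mean(g)) / sd(g)
    subj_cor <- vapply(x$maps, function(m) cor(m[j, ], g), 1.0)
    tibble::tibble(
      component = j,
      skewness = mean(z^3),
      kurtosis = mean(z^4) - 3,
      mean_subject_cor = mean(subj_cor)
    )
  })
}

#' @describeIn group_ica One-row decomposition summary.
#' @method glance group_decomposition
#' @export
glance.group_decomposition <- function(x, ...) {
  tibble::tibble(
    n_subjects = length(x$subject_ids),
    n_components = x$n_components,
    n_voxels = x$mask$n_voxels,
    subject_order = x$subject_order,
    algorithm = x$algorithm,
    iterations = x$iterations,
    seed = x$seed
  )
}
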