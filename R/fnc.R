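#' Post-process one component time course
#'
#' Applies, in order: (1) linear detrending (least-squares line removed);
#' (2) motion correction — residualisation on the six realignment regressors
#' when supplied, skipped otherwise; (3) despiking — samples deviating more
#' than `despike_thresh` robust SD (1.4826 x MAD) from an
#' `despike_window`-point moving median are replaced by that median; and
#' (4) zero-phase (forward-backward) Butterworth band-pass filtering.
#'
#' @param a Numeric time course (length >= 20).
#' @param tr Repetition time in seconds.
#' @param motion Optional T x 6 motion-parameter matrix.
#' @param band Pass band in Hz, `c(low, high)` with
#'   `0 < low < high < 1/(2 tr)`.
#' @param despike_window Moving-median window length (odd; default 11).
#' @param despike_thresh Spike threshold in robust SD units (default 3).
#' @param filter_order Butterworth order (default 5).
#' @return The filtered time course (same length).
#' @export
postprocess_timecourse <- function(a, tr, motion = NULL,
                                   band = c(0.01, 0.08),
                                   despike_window = 11L,
                                   despike_thresh = 3,
                                   filter_order = 5L) {
  n <- length(a)
  if (n < 20L) abort("time course must have at least 20 samples")
  ny <- 1 / (2 * tr)
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < ny)) {
    abort(sprintf("band [%g, %g] Hz infeasible for TR %g s (Nyquist %g Hz)",
                  band[1], band[2], tr, ny))
  }
  tt <- seq_len(n)
  # (1) remove least-squares line
  X <- cbind(1, tt)
  a <- a - X %*% solve(crossprod(X), crossprod(X, a))
  a <- drop(a)
  # (2) motion regressors
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n || ncol(motion) != 6L) {
      abort(sprintf("motion must be %d x 6", n))
    }
    M <- cbind(1, motion)
    a <- drop(a - M %*% solve(crossprod(M), crossprod(M, a)))
  }
  # (3) despike against a moving median
  med <- runmed(a, despike_window, endrule = "median")
  resid <- a - med
  s <- mad(resid)  # 1.4826 * median absolute deviation
  if (s > 0) {
    spikes <- abs(resid) > despike_thresh * s
    a[spikes] <- med[spikes]
  }
  # (4) zero-phase Butterworth band-pass
  bf <- signal::butter(filter_order, band / ny, type = "pass")
  signal::filtfilt(bf, a)
}

#' Subject FNC matrix from component time courses
#'
#' Selects the requested components, post-processes each time course with
#' [postprocess_timecourse()], and forms the matrix of pairwise Pearson
#' correlations (unit diagonal) — the subject's functional network
#' connectivity.
#'
#' @param a_subj T x C matrix of subject time courses (columns are
#'   components).
#' @param component_ids Integer indices of the components entering FNC
#'   (defaults to all columns).
#' @param tr Repetition time in seconds.
#' @param subject_id Identifier stored in the result.
#' @inheritParams postprocess_timecourse
#' @return A raw `connectivity_matrix`.
#' @export
fnc_matrix <- function(a_subj, component_ids = NULL, tr, motion = NULL,
                       band = c(0.01, 0.08), subject_id = "subject", ...) {
  a_subj <- as.matrix(a_subj)
  if (is.null(component_ids)) component_ids <- seq_len(ncol(a_subj))
  if (any(component_ids < 1L | component_ids > ncol(a_subj))) {
    abort("component_ids out of range")
  }
  sel <- a_subj[, component_ids, drop = FALSE]
  proc <- apply(sel, 2L, postprocess_timecourse, tr = tr, motion = motion,
                band = band, ...)
  sds <- apply(proc, 2L, sd)
  if (any(sds == 0)) {
    abort(sprintf("subject '%s': constant post-processed time course for component %d",
                  subject_id, component_ids[which(sds == 0)[1]]))
  }
  vals <- cor(proc)
  diag(vals) <- 1
  new_connectivity_matrix(vals, component_ids, normalized = FALSE,
                          subject_id = subject_id)
}

#' FNC matrices for every subject of a decomposition
#'
#' @param dec A `group_decomposition`.
#' @param component_ids Components entering FNC (e.g. the 50 of 75 kept
#'   after artifact review); defaults to all.
#' @param motion Optional named list of T x 6 motion matrices keyed by
#'   subject id.
#' @inheritParams fnc_matrix
#' @return A named list of raw `connectivity_matrix` objects in cohort order.
#' @export
fnc_cohort <- function(dec, component_ids = NULL, motion = NULL,
                       band = c(0.01, 0.08), ...) {
  stopifnot(inherits(dec, "group_decomposition"))
  out <- purrr::imap(setNames(dec$timecourses, dec$subject_ids),
                     function(a, id) {
                       fnc_matrix(a, component_ids = component_ids, tr = dec$tr,
                                  motion = motion[[id]], band = band,
                                  subject_id = id, ...)
                     })
  out
}

new_connectivity_matrix <- function(values, component_ids, normalized,
                                    subject_id = NA_character_) {
  if (max(abs(values - t(values))) > 1e-12) {
    abort("connectivity matrix is not symmetric")
  }
  structure(
    list(values = values, component_ids = as.integer(component_ids),
         normalized = normalized, subject_id = subject_id),
    class = "connectivity_matrix"
  )
}

#' Construct a connectivity matrix object
#'
#' Wraps an existing symmetric correlation (or Fisher-z) matrix, e.g. one
#' read back from disk, in the class used throughout the package.
#'
#' @param values J x J symmetric numeric matrix.
#' @param component_ids Component indices labelling rows/columns.
#' @param normalized `FALSE` for raw correlations, `TRUE` for Fisher-z.
#' @param subject_id Optional subject identifier.
#' @return A `connectivity_matrix`.
#' @export
connectivity_matrix <- function(values, component_ids = seq_len(nrow(values)),
                                normalized = FALSE,
                                subject_id = NA_character_) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) abort("values must be square")
  if (!normalized) {
    if (any(abs(values[upper.tri(values)]) > 1)) {
      abort("raw correlations must lie in [-1, 1]")
    }
  }
  new_connectivity_matrix(values, component_ids, normalized, subject_id)
}

#' Fisher r-to-z normalization of an FNC matrix
#'
#' Applies `atanh` to every off-diagonal correlation and sets the diagonal
#' to 0 — the variance-stabilising "FNC z-score" convention. Strictly
#' monotone and odd in r.
#'
#' @param cm A raw `connectivity_matrix`.
#' @return A normalized `connectivity_matrix`.
#' @export
normalize_fnc <- function(cm) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  if (cm$normalized) abort("matrix is already normalized")
  v <- cm$values
  off <- v[upper.tri(v) | lower.tri(v)]
  if (any(abs(off) >= 1)) {
    abort("off-diagonal |r| = 1: Fisher z is infinite")
  }
  z <- atanh(v)
  diag(z) <- 0
  new_connectivity_matrix(z, cm$component_ids, normalized = TRUE,
                          subject_id = cm$subject_id)
}

#' Cohort mean FNC (reference pattern)
#'
#' Elementwise mean of the subjects' connectivity matrices — the
#' cohort-common reference C-bar. With `groups`, the larger group is first
#' randomly subsampled (seeded) to the smaller group's size so both
#' contribute equally; the retained subjects are recorded in the
#' `"retained"` attribute.
#'
#' @param cs List of `connectivity_matrix` objects in a homogeneous
#'   normalization state.
#' @param groups Optional two-level vector (e.g. diagnosis) along `cs`
#'   requesting a balanced reference.
#' @param seed Seed for the balancing subsample.
#' @return A `connectivity_matrix` (subject id `"mean"`).
#' @export
mean_fnc <- function(cs, groups = NULL, seed = 1L) {
  stopifnot(length(cs) >= 2L,
            all(vapply(cs, inherits, TRUE, "connectivity_matrix")))
  norm_states <- unname(vapply(cs, `[[`, TRUE, "normalized"))
  if (length(unique(norm_states)) != 1L) {
    abort("cannot average matrices with mixed normalization states")
  }
  keep <- seq_along(cs)
  if (!is.null(groups)) {
    if (length(groups) != length(cs)) abort("groups must match cs in length")
    lev <- unique(groups)
    if (length(lev) != 2L) abort("groups must have exactly two levels")
    idx1 <- which(groups == lev[1])
    idx2 <- which(groups == lev[2])
    n <- min(length(idx1), length(idx2))
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(seed)
    keep <- sort(c(sample(idx1, n), sample(idx2, n)))
  }
  vals <- Reduce(`+`, lapply(cs[keep], `[[`, "values")) / length(keep)
  out <- new_connectivity_matrix(vals, cs[[1]]$component_ids,
                                 normalized = norm_states[1],
                                 subject_id = "mean")
  attr(out, "retained") <- vapply(cs[keep], `[[`, "", "subject_id")
  out
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s: %d x %d (%s)\n",
              x$subject_id, nrow(x$values), ncol(x$values),
              if (x$normalized) "Fisher-z" else "raw correlation"))
  invisible(x)
}

#' @describeIn connectivity_matrix Long tibble of the distinct connections
#'   (strict upper triangle).
#' @param x A `connectivity_matrix`.
#' @param ... Unused.
#' @method tidy connectivity_matrix
#' @export
tidy.connectivity_matrix <- function(x, ...) {
  J <- nrow(x$values)
  ut <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble::tibble(
    component_a = x$component_ids[ut[, 1]],
    component_b = x$component_ids[ut[, 2]],
    value = x$values[ut]
  )
}
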