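#' Deviation metrics between a subject pattern and a reference pattern
#'
#' Three scalar measures of how far a subject-level pattern `x` (an RSN map
#' over masked voxels, or a vectorized FNC matrix) lies from the
#' cohort-common reference `ref`:
#'
#' * `euclidean_variability()`: the Euclidean distance
#'   \eqn{\sqrt{\sum_k (x_k - r_k)^2}} — larger means more deviant.
#' * `pearson_variability()`: the sample Pearson correlation — smaller
#'   (less similar) means more deviant.
#' * `kl_variability()`: the Kullback-Leibler divergence
#'   \eqn{\sum_m Q(x)_m \log (Q(x)_m / Q(ref)_m)} between intensity
#'   histograms Q built on shared equal-width bins spanning the pooled range
#'   of both inputs, with a pseudocount added to every bin before
#'   normalisation (natural-log units).
#'
#' @param x,ref Numeric vectors of equal length (>= 2), finite.
#' @param bins Number of histogram bins M for the KL metric (default 100).
#' @param pseudocount Count added to every histogram bin before
#'   normalisation, so that empty reference bins do not make the divergence
#'   undefined.
#' @return A numeric scalar.
#' @name variability_metrics
NULL

check_metric_inputs <- function(x, ref) {
  if (length(x) != length(ref)) {
    abort(sprintf("vectors differ in length (%d vs %d)", length(x), length(ref)))
  }
  if (length(x) < 2L) abort("vectors must have length >= 2")
  if (any(!is.finite(x)) || any(!is.finite(ref))) {
    abort("inputs must be finite")
  }
  invisible(NULL)
}

#' @rdname variability_metrics
#' @export
euclidean_variability <- function(x, ref) {
  check_metric_inputs(x, ref)
  sqrt(sum((x - ref)^2))
}

#' @rdname variability_metrics
#' @export
pearson_variability <- function(x, ref) {
  check_metric_inputs(x, ref)
  xc <- x - mean(x)
  rc <- ref - mean(ref)
  den <- sqrt(sum(xc^2)) * sqrt(sum(rc^2))
  if (den == 0) abort("correlation undefined for constant input")
  sum(xc * rc) / den
}

#' @rdname variability_metrics
#' @export
kl_variability <- function(x, ref, bins = 100L, pseudocount = 1) {
  check_metric_inputs(x, ref)
  if (bins < 2L) abort("bins must be >= 2")
  if (pseudocount <= 0) abort("pseudocount must be > 0")
  pooled <- range(c(x, ref))
  if (pooled[1] == pooled[2]) {
    abort("degenerate histogram: all values identical in both vectors")
  }
  edges <- seq(pooled[1], pooled[2], length.out = bins + 1L)
  p <- hist_probs(x, edges, bins, pseudocount)
  q <- hist_probs(ref, edges, bins, pseudocount)
  sum(p * log(p / q))
}

hist_probs <- function(v, edges, bins, pseudocount) {
  idx <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = bins) + pseudocount
  counts / sum(counts)
}

#' Per-subject, per-component RSN variability table
#'
#' Applies the requested deviation metrics between every back-reconstructed
#' subject map and the corresponding group map. Maps are standardized to
#' zero mean and unit population variance over the masked voxels first
#' (disable with `standardize = FALSE`); on standardized maps the Euclidean
#' and Pearson features obey the exact law
#' \eqn{\rho_{ED} = \sqrt{2K(1 - \rho_{PC})}}.
#'
#' @param dec A `group_decomposition`.
#' @param metrics Character vector from `c("euclidean", "pearson", "kl")`, or
#'   `"all"`.
#' @param standardize Standardize maps before measuring (default `TRUE`).
#' @inheritParams variability_metrics
#' @return A long tibble with columns `subject_id`, `component`, `metric`,
#'   `value` (class `rsn_variability`).
#' @export
rsn_variability <- function(dec, metrics = "all", bins = 100L,
                            pseudocount = 1, standardize = TRUE) {
  stopifnot(inherits(dec, "group_decomposition"))
  metrics <- resolve_metrics(metrics)
  ref <- if (standardize) standardize_maps(dec$s_agg) else dec$s_agg
  C <- dec$n_components
  rows <- purrr::imap(dec$maps, function(m, i) {
    mm <- if (standardize) standardize_maps(m) else m
    purrr::map(seq_len(C), function(j) {
      vals <- vapply(metrics, function(mt) {
        tryCatch(
          apply_metric(mt, mm[j, ], ref[j, ], bins, pseudocount),
          error = function(e) {
            abort(sprintf("metric '%s' failed for subject '%s', component %d: %s",
                          mt, dec$subject_ids[i], j, conditionMessage(e)))
          })
      }, 1.0)
      tibble::tibble(subject_id = dec$subject_ids[i], component = j,
                     metric = metrics, value = unname(vals))
    })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("rsn_variability", class(out))
  attr(out, "n_voxels") <- dec$mask$n_voxels
  attr(out, "target") <- "rsn"
  out
}

#' Per-subject FNC variability
#'
#' Vectorizes each subject's connectivity matrix and the cohort reference to
#' their strict upper triangles (D = J(J-1)/2 distinct connections; D = 1225
#' for J = 50) and applies the deviation metrics between them.
#'
#' @param c_subj List of `connectivity_matrix` objects, one per subject.
#' @param c_ref The reference `connectivity_matrix` (e.g. from [mean_fnc()]).
#' @inheritParams rsn_variability
#' @return A tibble with columns `subject_id`, `metric`, `value`
#'   (class `rsn_variability`).
#' @export
fnc_variability <- function(c_subj, c_ref, metrics = "all", bins = 100L,
                            pseudocount = 1) {
  stopifnot(length(c_subj) >= 1L,
            all(vapply(c_subj, inherits, TRUE, "connectivity_matrix")),
            inherits(c_ref, "connectivity_matrix"))
  metrics <- resolve_metrics(metrics)
  J <- nrow(c_ref$values)
  ref_vec <- upper_vec(c_ref$values)
  rows <- purrr::map(c_subj, function(cm) {
    if (nrow(cm$values) != J) {
      abort(sprintf("subject '%s': connectivity matrix is %d x %d, reference is %d x %d",
                    cm$subject_id, nrow(cm$values), ncol(cm$values), J, J))
    }
    if (!identical(cm$normalized, c_ref$normalized)) {
      abort(sprintf("subject '%s': normalization state differs from reference",
                    cm$subject_id))
    }
    v <- upper_vec(cm$values)
    vals <- vapply(metrics, function(mt)
      apply_metric(mt, v, ref_vec, bins, pseudocount), 1.0)
    tibble::tibble(subject_id = cm$subject_id, metric = metrics,
                   value = unname(vals))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("rsn_variability", class(out))
  attr(out, "n_connections") <- J * (J - 1L) / 2L
  attr(out, "target") <- "fnc"
  out
}

resolve_metrics <- function(metrics) {
  all_m <- c("euclidean", "pearson", "kl")
  if (identical(metrics, "all")) return(all_m)
  bad <- setdiff(metrics, all_m)
  if (length(bad)) abort(sprintf("unknown metric(s): %s", paste(bad, collapse = ", ")))
  metrics
}

apply_metric <- function(metric, x, ref, bins, pseudocount) {
  switch(metric,
         euclidean = euclidean_variability(x, ref),
         pearson = pearson_variability(x, ref),
         kl = kl_variability(x, ref, bins = bins, pseudocount = pseudocount))
}

# strict upper triangle, column-major order
upper_vec <- function(m) m[upper.tri(m)]

#' Widen a variability table to subjects x components
#'
#' @param tbl An `rsn_variability` tibble from [rsn_variability()].
#' @param metric Which metric to extract.
#' @return A tibble with one row per subject and one column per component.
#' @export
variability_matrix <- function(tbl, metric = "euclidean") {
  stopifnot("component" %in% names(tbl))
  tbl |>
    dplyr::filter(.data$metric == !!metric) |>
    dplyr::select("subject_id", "component", "value") |>
    tidyr::pivot_wider(names_from = "component", names_prefix = "IC",
                       values_from = "value")
}
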