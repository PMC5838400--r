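#' Weighted global efficiency of an FNC graph
#'
#' Treats the raw connectivity matrix as a weighted undirected graph with
#' connection strengths W = |r| (diagonal zeroed) and connection lengths
#' L = 1/W. Shortest weighted path lengths d_jk are computed between every
#' pair of nodes; the nodal efficiency of node j is the mean of 1/d_jk over
#' the other nodes, and the global efficiency is the mean of the nodal
#' efficiencies — the inverse harmonic mean of the pairwise minimum path
#' lengths. Unreachable pairs contribute 0.
#'
#' @param cm A raw (non-Fisher-z) `connectivity_matrix` with J >= 2 nodes.
#' @return An `efficiency_result` with `nodal` (J-vector), `global`, and the
#'   weight scheme descriptor.
#' @export
global_efficiency <- function(cm) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  if (cm$normalized) {
    abort("global efficiency is defined on raw correlations, not Fisher-z")
  }
  W <- abs(cm$values)
  J <- nrow(W)
  if (J < 2L) abort("need at least 2 nodes")
  if (max(abs(W - t(W))) > 1e-10) abort("connectivity matrix is not symmetric")
  diag(W) <- 0
  L <- ifelse(W > 0, 1 / W, 0)  # zero entries = no edge
  g <- igraph::graph_from_adjacency_matrix(L, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, algorithm = "dijkstra")
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  nodal <- rowSums(inv) / (J - 1)
  structure(
    list(nodal = unname(nodal), global = mean(nodal),
         weight_scheme = "abs-correlation", subject_id = cm$subject_id),
    class = "efficiency_result"
  )
}

#' Per-subject global efficiency table
#'
#' @param cs List of raw `connectivity_matrix` objects (one per subject).
#' @return Tibble with `subject_id` and `global_efficiency`.
#' @export
efficiency_table <- function(cs) {
  purrr::map_dfr(cs, function(cm) {
    e <- global_efficiency(cm)
    tibble::tibble(subject_id = cm$subject_id,
                   global_efficiency = e$global)
  })
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf("<efficiency_result> %s: global %.4f over %d nodes (%s weights)\n",
              x$subject_id, x$global, length(x$nodal), x$weight_scheme))
  invisible(x)
}

#' @describeIn global_efficiency Nodal efficiencies as a tibble.
#' @param x An `efficiency_result`.
#' @param ... Unused.
#' @method tidy efficiency_result
#' @export
tidy.efficiency_result <- function(x, ...) {
  tibble::tibble(node = seq_along(x$nodal), nodal_efficiency = x$nodal)
}

#' @describeIn global_efficiency One-row summary.
#' @method glance efficiency_result
#' @export
glance.efficiency_result <- function(x, ...) {
  tibble::tibble(global_efficiency = x$global, n_nodes = length(x$nodal),
                 weight_scheme = x$weight_scheme)
}
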