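#' Heatmap of a connectivity matrix
#'
#' @param object A `connectivity_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot connectivity_matrix
#' @export
autoplot.connectivity_matrix <- function(object, ...) {
  J <- nrow(object$values)
  df <- tidyr::expand_grid(row = seq_len(J), col = seq_len(J))
  df$value <- object$values[cbind(df$row, df$col)]
  lab <- if (object$normalized) "Fisher z" else "r"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse(breaks = seq_len(J),
                             labels = object$component_ids) +
    ggplot2::scale_x_continuous(breaks = seq_len(J),
                                labels = object$component_ids) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", name = lab) +
    ggplot2::labs(x = "component", y = "component",
                  title = sprintf("FNC (%s)", object$subject_id)) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Nodal efficiency profile
#'
#' @param object An `efficiency_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot efficiency_result
#' @export
autoplot.efficiency_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$node),
                                   y = .data$nodal_efficiency)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = object$global, linetype = 2,
                        colour = "#b2182b") +
    ggplot2::labs(x = "node", y = "nodal efficiency",
                  title = sprintf("global efficiency %.3f", object$global)) +
    ggplot2::theme_minimal()
}

#' Distribution of variability features, optionally split by diagnosis
#'
#' Boxplots of the per-subject deviation values for each metric (and each
#' component, when the table is an RSN variability table with few
#' components).
#'
#' @param object An `rsn_variability` tibble.
#' @param covariates Optional covariate table providing `diagnosis` for
#'   group colouring.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rsn_variability
#' @export
autoplot.rsn_variability <- function(object, covariates = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(covariates)) {
    df$diagnosis <- factor(
      covariates$diagnosis[match(df$subject_id, covariates$subject_id)],
      levels = c(0, 1), labels = c("control", "patient"))
  }
  has_comp <- "component" %in% names(df)
  aes <- if (is.null(covariates)) {
    ggplot2::aes(x = if (has_comp) factor(.data$component) else .data$metric,
                 y = .data$value)
  } else {
    ggplot2::aes(x = if (has_comp) factor(.data$component) else .data$metric,
                 y = .data$value, fill = .data$diagnosis)
  }
  p <- ggplot2::ggplot(df, aes) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = if (has_comp) "component" else "metric",
                  y = "deviation from cohort pattern") +
    ggplot2::theme_minimal()
  if (has_comp) {
    p <- p + ggplot2::facet_wrap(~metric, scales = "free_y")
  }
  p
}
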