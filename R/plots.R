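#' @method autoplot prediction_map
#' @export
autoplot.prediction_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$label)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(
      background = "grey95", PanNET = "#8c5aa0", NNPP = "#d98ca6",
      stroma = "#efc4d4"), drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "tissue",
                  title = object$slide_id)
}

#' Plot a patch selection over its prediction map
#'
#' @param map A [prediction_map()].
#' @param selection Output of [select_patches()].
#' @return A ggplot showing the map with selected patches annotated by hop
#'   distance.
#' @export
plot_selection <- function(map, selection) {
  autoplot(map) +
    ggplot2::geom_text(
      data = selection,
      ggplot2::aes(x = .data$col, y = .data$row, label = .data$d),
      inherit.aes = FALSE, size = 3
    )
}

#' @method autoplot cell_graph
#' @export
autoplot.cell_graph <- function(object, node_color = "intensity",
                                attention = NULL, ...) {
  nodes <- object$nodes
  if (!is.null(attention)) nodes$attention <- attention
  col_var <- if (!is.null(attention)) "attention" else node_color
  edges <- object$edges
  seg <- tibble(
    x = nodes$x[edges$from], y = nodes$y[edges$from],
    xend = nodes$x[edges$to], yend = nodes$y[edges$to],
    weight = edges$weight
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$weight),
      color = "grey70") +
    ggplot2::scale_linewidth(range = c(0.1, 0.6), guide = "none") +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, color = .data[[col_var]],
                   size = .data$area)) +
    ggplot2::scale_size(range = c(1, 3), guide = "none") +
    ggplot2::scale_color_gradient(low = "#3b4cc0", high = "#b40426") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
}

#' Plot the node attention of a trained model on a graph
#'
#' @param model A trained [train_gnn()] model.
#' @param graph A cell-graph.
#' @param target_class Class to explain.
#' @return A ggplot of the graph coloured by [node_attention_map()] scores.
#' @export
plot_node_attention <- function(model, graph, target_class) {
  att <- node_attention_map(model, graph, target_class)
  autoplot(graph, attention = att) +
    ggplot2::labs(color = "attention",
                  title = sprintf("node attention for %s", target_class))
}

#' @method autoplot score_report
#' @export
autoplot.score_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_class,
                            c("precision", "recall", "f1"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = object$weighted_f1, linetype = 2) +
    ggplot2::labs(y = "percent", x = NULL,
                  caption = sprintf("dashed: weighted F1 = %.1f%%",
                                    object$weighted_f1))
}

#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object$runs,
                  ggplot2::aes(x = factor(.data$fold), y = .data$weighted_f1)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$summary$mean_weighted_f1,
                        linetype = 2) +
    ggplot2::labs(x = "fold", y = "case-level weighted F1 (%)")
}
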