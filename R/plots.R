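# ggplot2 display methods for the analysis objects.

#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate (1 - specificity)",
                  y = "True positive rate (sensitivity)",
                  title = sprintf("Empirical ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' @method autoplot method_map
#' @export
autoplot.method_map <- function(object, ...) {
  pts <- object$points
  aes <- if ("cluster" %in% names(pts)) {
    ggplot2::aes(x = .data$dim1, y = .data$dim2, colour = .data$cluster)
  } else {
    ggplot2::aes(x = .data$dim1, y = .data$dim2)
  }
  ggplot2::ggplot(pts, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$method), size = 2.5,
                       vjust = -0.8, show.legend = FALSE) +
    ggplot2::labs(x = "Dimension 1", y = "Dimension 2",
                  title = "Method similarity map (classical MDS)") +
    ggplot2::theme_minimal()
}

dendrogram_segments <- function(hc) {
  n <- length(hc$order)
  leaf_x <- setNames(seq_len(n), hc$order)
  centers <- numeric(nrow(hc$merge))
  heights <- numeric(nrow(hc$merge))
  segs <- list()
  node_pos <- function(id) {
    if (id < 0) c(x = unname(leaf_x[as.character(-id)]), h = 0)
    else c(x = centers[id], h = heights[id])
  }
  for (i in seq_len(nrow(hc$merge))) {
    a <- node_pos(hc$merge[i, 1]); b <- node_pos(hc$merge[i, 2])
    h <- hc$height[i]
    centers[i] <- (a["x"] + b["x"]) / 2
    heights[i] <- h
    segs[[length(segs) + 1]] <- tibble::tibble(
      x = c(a["x"], a["x"], b["x"]),
      xend = c(a["x"], b["x"], b["x"]),
      y = c(a["h"], h, a["h"] * 0 + b["h"]),
      yend = c(h, h, h))
  }
  dplyr::bind_rows(segs)
}

#' Dendrogram plot of the method clustering
#'
#' @param hc An `hclust` object (e.g. from [complete_linkage()]).
#' @param labels Show leaf labels? Default TRUE.
#' @return A ggplot.
#' @export
plot_dendrogram <- function(hc, labels = TRUE) {
  stopifnot(inherits(hc, "hclust"))
  segs <- dendrogram_segments(hc)
  p <- ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::labs(x = NULL, y = "Merge height (complete linkage)",
                  title = "Method dendrogram") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid.major.x = ggplot2::element_blank())
  if (labels) {
    lab <- tibble::tibble(x = seq_along(hc$order),
                          label = hc$labels[hc$order])
    p <- p + ggplot2::geom_text(data = lab,
                                ggplot2::aes(x = .data$x, y = 0,
                                             label = .data$label),
                                angle = 90, hjust = 1.05, size = 2.5) +
      ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.35, 0.05)))
  }
  p
}

#' Variable-importance bar chart of a fitted tree
#'
#' @param tree A [fit_greedy_tree()] object.
#' @return A ggplot.
#' @export
plot_importance <- function(tree) {
  imp <- variable_importance(tree)
  ggplot2::ggplot(imp, ggplot2::aes(x = stats::reorder(.data$field, .data$importance),
                                    y = .data$importance)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Normalized importance (%)") +
    ggplot2::theme_minimal()
}

#' @method autoplot discrimination_analysis
#' @export
autoplot.discrimination_analysis <- function(object, ...) {
  if (is.null(object$mds)) {
    abort("No similarity stage available (too few methods with finite profiles).")
  }
  autoplot(object$mds)
}
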