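## Optional figures. ggplot2 and pheatmap are Suggests-only; each function
## checks for them at call time.

#' Stacked bar chart of functionality-tag composition
#'
#' @param tag_summary a [summarize_tags()] tibble.
#' @return a ggplot object (tags on the x axis, up/down counts stacked).
#' @export
plot_tag_summary <- function(tag_summary) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    fm_config_error("plot_tag_summary requires the ggplot2 package")
  }
  long <- tidyr::pivot_longer(
    tag_summary[c("tag", "n_up", "n_down")],
    cols = c("n_up", "n_down"), names_to = "direction", values_to = "n")
  long$direction <- ifelse(long$direction == "n_up", "up", "down")
  long$tag <- factor(long$tag, levels = tag_summary$tag)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tag, y = .data$n,
                                     fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(up = "#b2182b", down = "#2166ac")) +
    ggplot2::labs(x = "functionality tag", y = "consensus features",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of the cross-study fold-change matrix
#'
#' Diverging colour scale around 0 on the log2 scale (blue = down, red = up)
#' with fluid/group annotation bars on the study columns.
#'
#' @param matrix a [build_matrix()] result.
#' @param ... passed on to [pheatmap::pheatmap()].
#' @return the pheatmap object, invisibly.
#' @export
plot_expression_heatmap <- function(matrix, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    fm_config_error("plot_expression_heatmap requires the pheatmap package")
  }
  ann <- as.data.frame(matrix$annotation[c("fluid", "group")])
  rownames(ann) <- matrix$annotation$study_id
  lim <- max(abs(matrix$values), na.rm = TRUE)
  breaks <- seq(-lim, lim, length.out = 101)
  cols <- grDevices::colorRampPalette(c("#2166ac", "white", "#b2182b"))(100)
  invisible(pheatmap::pheatmap(matrix$values, annotation_col = ann,
                               color = cols, breaks = breaks, ...))
}
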