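#' Plot a sweep result table
#'
#' Line plot of mean metric values against the swept variable, one line per
#' metric (or per arm for cleaning comparisons). Requires ggplot2.
#'
#' @param tbl sweep table from one of the sweep functions.
#' @param x variable for the horizontal axis (`"lambda"` or `"rho"`).
#' @param metrics metric columns to draw.
#' @return a ggplot object.
#' @export
plot_sweep <- function(tbl, x = "lambda",
                       metrics = c("acc", "sp", "sn", "f1")) {
  abort_if(!requireNamespace("ggplot2", quietly = TRUE),
           "ggplot2 is required for plotting")
  abort_if(!x %in% names(tbl), paste0("no column '", x, "' in table"))
  by <- intersect(c(x, "arm"), names(tbl))
  means <- stats::aggregate(tbl[metrics], by = tbl[by], FUN = mean, na.rm = TRUE)
  long <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(means[by], metric = m, value = means[[m]])
  }))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data[[x]], y = .data$value,
                                          color = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = x, y = "mean metric over test samples") +
    ggplot2::theme_minimal()
  if ("arm" %in% by) p <- p + ggplot2::facet_wrap(~arm)
  p
}
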