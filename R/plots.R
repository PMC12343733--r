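# Plot helpers: 2D embedding scatter plots for cluster reports and concept
# embeddings, written as PNG with base graphics so no display is needed.

#' Scatter plot of a 2D embedding
#'
#' @param embedding matrix with >= 2 columns (rows = points).
#' @param color integer/factor per point (cluster labels, outlier flags, ...).
#' @param path optional PNG path; when `NULL`, plots to the active device.
#' @param main plot title.
#' @export
plot_embedding <- function(embedding, color = NULL, path = NULL, main = "") {
  stopifnot(ncol(embedding) >= 2)
  col <- if (is.null(color)) "grey30" else as.integer(as.factor(color)) + 1L
  draw <- function() {
    graphics::plot(embedding[, 1], embedding[, 2], col = col, pch = 19,
                   xlab = "dim 1", ylab = "dim 2", main = main)
  }
  if (!is.null(path)) {
    grDevices::png(path, width = 640, height = 640)
    on.exit(grDevices::dev.off())
    draw()
  } else draw()
  invisible(path)
}

#' Plot a cluster report (spectral relevance clustering)
#' @param report a `cluster_report` from [spray()].
#' @param path optional PNG path.
#' @export
plot_cluster_report <- function(report, path = NULL) {
  plot_embedding(report$embedding, report$labels, path,
                 main = sprintf("spectral relevance clusters (k = %d)", report$k))
}
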