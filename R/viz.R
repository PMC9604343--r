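# Paired correlation heatmaps (control vs cancer) for one pathway.
# The colour scale is fixed to [-1, 1] with blue for positive and red for
# negative correlation, so the two panels are directly comparable; rows are
# not clustered or reordered.

#' Render side-by-side control/cancer correlation heatmaps
#'
#' Writes `<out_prefix>.svg` and `<out_prefix>.png`. Masked (invalid) cells
#' are drawn in neutral grey; gene labels appear on both axes; the diverging
#' scale is centred at 0 and pinned to `[-1, 1]`.
#'
#' @param pair A `corr_matrix_pair` (see [corr_matrix_pair()]).
#' @param out_prefix Path prefix for the image files (extension added).
#' @param width,height Device size in inches.
#' @return The ggplot object, invisibly; called for its file side effects.
#' @export
plot_correlation_pair <- function(pair, out_prefix, width = 10,
                                  height = 5) {
  stopifnot(inherits(pair, "corr_matrix_pair"))
  dir <- dirname(out_prefix)
  if (!dir.exists(dir)) {
    stop("output directory does not exist: ", dir, call. = FALSE)
  }
  df <- rbind(
    melt_cc(pair$cc_control, pair$genes, "control"),
    melt_cc(pair$cc_cancer, pair$genes, "cancer")
  )
  df$panel <- factor(df$panel, levels = c("control", "cancer"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_x, y = .data$gene_y,
                                        fill = .data$cc)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::scale_fill_gradient2(
      low = "#B2182B", mid = "#FFFFFF", high = "#2166AC",
      midpoint = 0, limits = c(-1, 1), na.value = "grey85",
      name = "CC"
    ) +
    ggplot2::scale_y_discrete(limits = rev(levels(df$gene_y))) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = pair$pathway, x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                          hjust = 1),
      panel.grid = ggplot2::element_blank()
    )
  for (ext in c("svg", "png")) {
    path <- paste0(out_prefix, ".", ext)
    if (ext == "svg") {
      grDevices::svg(path, width = width, height = height)
    } else {
      grDevices::png(path, width = width, height = height, units = "in",
                     res = 150)
    }
    tryCatch(print(p), finally = grDevices::dev.off())
  }
  invisible(p)
}

melt_cc <- function(cc, genes, panel) {
  data.frame(
    gene_x = factor(rep(genes, each = length(genes)), levels = genes),
    gene_y = factor(rep(genes, times = length(genes)), levels = genes),
    cc = as.vector(cc),
    panel = panel,
    stringsAsFactors = FALSE
  )
}
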