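# Rendering helpers for the association outputs: CPM box plots by
# disease group and abundance-vs-bile-acid-ratio scatters. Both return
# ggplot objects for the caller to style or ggsave().

#' Box plot of per-cluster CPM by sample group
#'
#' @param profiles long abundance table (rows from [normalize_cpm()]).
#' @param metadata sample metadata with `sample_id` and `group`.
#' @param cluster_id cluster to draw.
#' @param log_scale put CPM on a log10 axis (pseudocount 1).
#' @return a ggplot object.
#' @export
plot_abundance_box <- function(profiles, metadata, cluster_id,
                               log_scale = TRUE) {
  df <- profiles[profiles$cluster_id == cluster_id, ]
  df$group <- metadata$group[match(df$sample_id, metadata$sample_id)]
  df <- df[!is.na(df$group), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$cpm + 1)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = "reads per million + 1",
                  title = paste("baiE cluster", cluster_id)) +
    ggplot2::theme_classic()
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' Scatter of cluster abundance against the secondary/primary BA ratio
#'
#' Annotates the panel with the Spearman rho and p-value computed by
#' [spearman_cor()].
#'
#' @param abundance named numeric vector of per-sample CPM.
#' @param metadata sample metadata with bile-acid concentrations.
#' @param label cluster label for the title.
#' @return a ggplot object.
#' @export
plot_ba_scatter <- function(abundance, metadata, label = "all") {
  ratio <- ba_ratio(metadata)
  df <- data.frame(cpm = unname(abundance[metadata$sample_id]),
                   ratio = unname(ratio))
  df <- df[stats::complete.cases(df), ]
  ct <- spearman_cor(df$cpm, df$ratio, label = label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cpm + 1, y = .data$ratio)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "reads per million + 1",
                  y = "(DCA + LCA) / (CA + CDCA)",
                  title = sprintf("cluster %s: r = %.2f, p = %.2g",
                                  label, ct$rho, ct$p_value)) +
    ggplot2::theme_classic()
}
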