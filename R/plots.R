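# Figure rendering. Each plot_* function draws the figure for one analysis
# result onto the current graphics device; ggplot2 objects are printed.
# Every number shown in a figure is a column of the sibling CSV.

.draw <- function(p) if (inherits(p, "ggplot")) print(p) else invisible(p)

plot_detection_counts <- function(res) {
  .draw(ggplot2::ggplot(res,
          ggplot2::aes(x = factor(.data$times_detected),
                       y = .data$n_proteins)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~ paste0(.data$group, " (total ",
                                 .data$group_total, ")")) +
    ggplot2::labs(x = "detected in k samples", y = "proteins",
                  title = "Detection counts per group") +
    ggplot2::theme_bw())
}

plot_detected_per_sample <- function(res) {
  .draw(ggplot2::ggplot(res, ggplot2::aes(x = .data$sample,
                                          y = .data$n_detected)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$group_average),
                        linetype = "dashed", color = "gray40") +
    ggplot2::facet_wrap(~ paste0(.data$group, " (total ",
                                 .data$group_total, ")"),
                        scales = "free_x") +
    ggplot2::labs(x = NULL, y = "detected proteins",
                  title = "Detected proteins per sample") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1)))
}

# Classic circle Venn for <= 3 sets, otherwise bars over intersection regions.
plot_venn <- function(res, title = "Venn diagram") {
  style <- attr(res, "style")
  sets <- attr(res, "sets")
  if (identical(style, "classic") && length(sets) >= 1L) {
    k <- length(sets)
    centers <- switch(k,
                      matrix(c(0, 0), 1L),
                      rbind(c(-0.5, 0), c(0.5, 0)),
                      rbind(c(-0.5, -0.3), c(0.5, -0.3), c(0, 0.56)))
    graphics::plot.new()
    graphics::plot.window(xlim = c(-2, 2), ylim = c(-2, 2), asp = 1)
    graphics::title(main = title)
    graphics::symbols(centers[, 1L], centers[, 2L],
                      circles = rep(1, k), add = TRUE, inches = FALSE,
                      fg = c("firebrick", "steelblue", "darkgreen")[seq_len(k)])
    labpos <- list(
      one = rbind(c(0, 0)),
      two = rbind(c(-1, 0), c(1, 0), c(0, 0)),
      three = rbind(c(-1, -0.6), c(1, -0.6), c(0, 1.1),
                    c(0, -0.7), c(-0.6, 0.3), c(0.6, 0.3), c(0, 0)))
    pos <- labpos[[k]]
    # region order in res: single sets, then pairs, then triple
    for (r in seq_len(nrow(res))) {
      if (r <= nrow(pos)) {
        graphics::text(pos[r, 1L], pos[r, 2L], res$n_proteins[r])
      }
    }
    graphics::text(centers[, 1L], centers[, 2L] + 1.2, names(sets),
                   cex = 0.8)
  } else {
    .draw(ggplot2::ggplot(res,
            ggplot2::aes(x = stats::reorder(.data$region, -.data$n_proteins),
                         y = .data$n_proteins)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = "intersection region", y = "proteins",
                    title = title) +
      ggplot2::theme_bw() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1)))
  }
}

plot_pca_overview <- function(res) {
  ev <- attr(res, "explained_variance")
  .draw(ggplot2::ggplot(res, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                          color = .data$group)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * ev[1L]),
                  y = sprintf("PC2 (%.1f%%)", 100 * ev[2L]),
                  title = "PCA overview (complete-case proteins)") +
    ggplot2::theme_bw())
}

plot_intensity_histogram <- function(res) {
  .draw(ggplot2::ggplot(res,
          ggplot2::aes(x = (.data$bin_left + .data$bin_right) / 2,
                       y = .data$count, color = .data$sample)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$group_mean_intensity),
                        linetype = "dashed", color = "gray40") +
    ggplot2::facet_wrap(~ .data$group) +
    ggplot2::labs(x = "log2 intensity", y = "proteins",
                  title = "Intensity histogram per sample") +
    ggplot2::theme_bw())
}

plot_relative_sd <- function(res) {
  .draw(ggplot2::ggplot(res, ggplot2::aes(x = .data$mean_log2_intensity,
                                          y = .data$rsd_percent)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 10, color = "#c6dbef") +
    ggplot2::geom_hline(yintercept = 20, color = "#6baed6") +
    ggplot2::geom_hline(yintercept = 30, color = "#2171b5") +
    ggplot2::facet_wrap(~ paste0(.data$group, " (<10%: ", .data$n_below_10,
                                 ", <20%: ", .data$n_below_20,
                                 ", <30%: ", .data$n_below_30, ")")) +
    ggplot2::labs(x = "mean log2 intensity", y = "relative SD [%]",
                  title = "Relative standard deviation (above-threshold proteins)") +
    ggplot2::theme_bw())
}

plot_scatter_replicates <- function(res) {
  .draw(ggplot2::ggplot(res, ggplot2::aes(x = .data$sample_x,
                                          y = .data$sample_y,
                                          fill = .data$r_squared)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f",
                                                    .data$r_squared)),
                       size = 3) +
    ggplot2::facet_wrap(~ .data$group, scales = "free") +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(NA, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Replicate correlation (r squared)") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1)))
}

plot_experiment_comparison <- function(res) {
  comp <- res[res$category == "comparable", , drop = FALSE]
  .draw(ggplot2::ggplot(comp, ggplot2::aes(x = .data$mean_a,
                                           y = .data$mean_b)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "gray50") +
    ggplot2::facet_wrap(~ paste0(.data$group_a, " vs ", .data$group_b,
                                 "  (r2 = ", sprintf("%.3f",
                                                     .data$r_squared), ")")) +
    ggplot2::labs(x = "mean log2 intensity (first group)",
                  y = "mean log2 intensity (second group)",
                  title = "Experiment comparison (thresholded)") +
    ggplot2::theme_bw())
}

plot_rank <- function(res, group_name = "") {
  res$in_pathway <- !is.na(res$pathway)
  .draw(ggplot2::ggplot(res, ggplot2::aes(x = .data$rank_percentile,
                                          y = .data$mean_intensity)) +
    ggplot2::geom_point(data = res[!res$in_pathway, ], color = "gray60",
                        size = 0.6) +
    ggplot2::geom_point(data = res[res$in_pathway, ],
                        ggplot2::aes(color = .data$pathway), size = 1.6) +
    ggplot2::labs(x = "rank [%] (0 = highest intensity)",
                  y = "mean log2 intensity",
                  title = paste("Protein rank", group_name)) +
    ggplot2::theme_bw())
}

plot_pathway_analysis <- function(res) {
  long <- rbind(
    data.frame(pathway = res$pathway, protein = res$protein,
               group = res$group_a, intensity = res$mean_a),
    data.frame(pathway = res$pathway, protein = res$protein,
               group = res$group_b, intensity = res$mean_b))
  long <- unique(long)
  .draw(ggplot2::ggplot(long, ggplot2::aes(x = .data$group,
                                           y = .data$intensity)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~ paste(.data$pathway, .data$protein, sep = ": "),
                        scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean log2 intensity",
                  title = "Pathway protein intensities") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1)))
}

plot_go_analysis <- function(res) {
  .draw(ggplot2::ggplot(res, ggplot2::aes(x = .data$group,
                                          y = .data$n_term_detected)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("p=%.2g",
                                                    .data$p_value)),
                       hjust = -0.1, size = 2.8) +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~ paste0(.data$term, " (", .data$term_size,
                                 " entries)")) +
    ggplot2::labs(x = NULL, y = "detected proteins in term",
                  title = "GO term detection and enrichment") +
    ggplot2::theme_bw())
}

plot_volcano <- function(res) {
  comp <- res[res$category == "comparable" & !is.na(res$p_value), ,
              drop = FALSE]
  ua <- res[res$category == "unique_in_A", , drop = FALSE]
  ub <- res[res$category == "unique_in_B", , drop = FALSE]
  xr <- range(comp$log2_fc, 0, na.rm = TRUE)
  pad <- max(1, diff(xr) * 0.15)
  p <- ggplot2::ggplot(comp, ggplot2::aes(x = .data$log2_fc,
                                          y = .data$neg_log10_p)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$adj_p_value < 0.05),
                        size = 0.9, alpha = 0.6) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "gray60",
                                           `TRUE` = "firebrick"),
                                na.value = "gray60",
                                name = "adj. p < 0.05") +
    ggplot2::labs(x = paste0("log2 fold change (", attr(res, "name_a"),
                             " - ", attr(res, "name_b"), ")"),
                  y = "-log10(p-value)",
                  title = paste0("Volcano: ", attr(res, "name_a"), " vs ",
                                 attr(res, "name_b"))) +
    ggplot2::theme_bw()
  # unique proteins shown on each side at their group mean intensity,
  # rescaled into the p-value axis for display
  if (nrow(ua) + nrow(ub) > 0L) {
    ymax <- max(comp$neg_log10_p, 1, na.rm = TRUE)
    sidepts <- rbind(
      if (nrow(ua) > 0L) data.frame(x = xr[2L] + pad,
                                    y = .rescale(ua$mean_a, ymax)),
      if (nrow(ub) > 0L) data.frame(x = xr[1L] - pad,
                                    y = .rescale(ub$mean_b, ymax)))
    p <- p + ggplot2::geom_point(data = sidepts,
                                 ggplot2::aes(x = .data$x, y = .data$y),
                                 inherit.aes = FALSE,
                                 shape = 17, color = "darkorange")
  }
  ann <- comp[comp$annotated, , drop = FALSE]
  if (nrow(ann) > 0L) {
    p <- p + ggplot2::geom_text(data = ann,
                                ggplot2::aes(label = .data$protein),
                                size = 2.5, vjust = -0.6)
  }
  .draw(p)
}

.rescale <- function(v, ymax) {
  if (length(v) == 0L) return(numeric(0))
  r <- range(v, na.rm = TRUE)
  if (diff(r) == 0) return(rep(ymax / 2, length(v)))
  (v - r[1L]) / diff(r) * ymax
}
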