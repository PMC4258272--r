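#' Axis label with constrained-inertia percentage
#' @noRd
.axis_label <- function(result, axis) {
  pct <- 100 * result$singular_values[axis]^2 / result$inertia_constrained
  sprintf("Axis %d (%.1f%% of constrained inertia)", axis, pct)
}

.write_layer_tsv <- function(df, file, layer) {
  path <- paste0(sub("\\.[A-Za-z]+$", "", file), "_", layer, ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Triplot of a constrained ordination
#'
#' Overlays the three layers of a CCA solution on two chosen axes:
#' genes (WA principal scores, grey points), samples (principal scores,
#' coloured points) and differentiation programmes (biplot scores as
#' arrows from the origin). Arrows are rescaled by a single constant so
#' the longest arrow spans 80% of the sample-score range; the constant
#' is recorded in the figure caption and the exported TSVs hold the
#' unscaled scores. Every plotted layer is also written next to the
#' figure as `<file>_genes.tsv`, `<file>_samples.tsv`,
#' `<file>_programmes.tsv` — the plot is a view, the TSVs are the data
#' of record.
#'
#' @param result a constrained `cca_result` with >= 2 axes.
#' @param file output figure path (`.png`, `.svg` or `.pdf`).
#' @param axes integer pair of axis indices (default c(1, 2)).
#' @param highlight_genes optional gene ids drawn emphasized and
#'   labelled (gene-subset view).
#' @param sample_groups optional factor/character vector colouring the
#'   samples (defaults to sample names' class if available).
#' @return the ggplot object, invisibly; the figure and TSVs are
#'   written as a side effect.
#' @export
triplot <- function(result, file, axes = c(1, 2), highlight_genes = NULL,
                    sample_groups = NULL) {
  stopifnot(inherits(result, "cca_result"))
  if (length(result$singular_values) < 2) {
    stop("result has a single constrained axis; use score_plot_1d() instead")
  }
  if (any(axes > length(result$singular_values))) {
    stop("requested axes not present in result")
  }
  g <- data.frame(gene_id = rownames(result$gene_scores_wa_principal),
                  x = result$gene_scores_wa_principal[, axes[1]],
                  y = result$gene_scores_wa_principal[, axes[2]])
  s <- data.frame(sample_id = rownames(result$sample_scores_principal),
                  x = result$sample_scores_principal[, axes[1]],
                  y = result$sample_scores_principal[, axes[2]])
  s$group <- if (is.null(sample_groups)) "sample" else as.character(sample_groups)
  a <- data.frame(programme = rownames(result$biplot_scores),
                  x = result$biplot_scores[, axes[1]],
                  y = result$biplot_scores[, axes[2]])
  arrow_len <- sqrt(a$x^2 + a$y^2)
  span <- max(abs(c(s$x, s$y)))
  scale_const <- if (max(arrow_len) > 0) 0.8 * span / max(arrow_len) else 1

  p <- ggplot2::ggplot() +
    ggplot2::geom_point(data = g, ggplot2::aes(x = .data$x, y = .data$y),
                        colour = "grey70", size = 0.8) +
    ggplot2::geom_segment(
      data = a,
      ggplot2::aes(x = 0, y = 0, xend = .data$x * scale_const,
                   yend = .data$y * scale_const),
      colour = "blue",
      arrow = grid::arrow(length = grid::unit(0.2, "cm"))) +
    ggplot2::geom_text(
      data = a,
      ggplot2::aes(x = .data$x * scale_const, y = .data$y * scale_const,
                   label = .data$programme),
      colour = "blue", vjust = -0.5, size = 3) +
    ggplot2::geom_point(data = s,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$group), size = 2) +
    ggplot2::labs(x = .axis_label(result, axes[1]),
                  y = .axis_label(result, axes[2]),
                  colour = "sample group",
                  caption = sprintf("arrow scale constant: %.4g", scale_const)) +
    ggplot2::theme_bw()
  if (!is.null(highlight_genes)) {
    hg <- g[casefold(g$gene_id) %in% casefold(highlight_genes), , drop = FALSE]
    p <- p +
      ggplot2::geom_point(data = hg, ggplot2::aes(x = .data$x, y = .data$y),
                          colour = "red", size = 1.5) +
      ggplot2::geom_text(data = hg,
                         ggplot2::aes(x = .data$x, y = .data$y,
                                      label = .data$gene_id),
                         colour = "red", vjust = -0.7, size = 2.5)
  }
  ggplot2::ggsave(file, p, width = 7, height = 6)
  .write_layer_tsv(g, file, "genes")
  .write_layer_tsv(s, file, "samples")
  .write_layer_tsv(a, file, "programmes")
  invisible(p)
}

#' Strip plot of one-dimensional CCA sample scores
#'
#' Shows the per-sample scores of a single-variable ordination grouped
#' by sample label, annotated with the percentage of total inertia the
#' constrained axis explains. Scores are exported alongside as
#' `<file>_scores.tsv`.
#'
#' @param result a 1-axis `cca_result` (from [cca()] with one
#'   explanatory column).
#' @param file output figure path.
#' @param group_labels optional character vector of group labels per
#'   sample (empty/NULL puts all samples in one group).
#' @return the ggplot object, invisibly.
#' @export
score_plot_1d <- function(result, file, group_labels = NULL) {
  stopifnot(inherits(result, "cca_result"))
  scores <- result$sample_scores_principal[, 1L]
  df <- data.frame(sample_id = names(scores), score = unname(scores))
  df$group <- if (is.null(group_labels) || length(group_labels) == 0) {
    "all"
  } else as.character(group_labels)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$score)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, size = 2,
                         ggplot2::aes(colour = .data$group)) +
    ggplot2::labs(x = NULL, y = "CCA sample score (Axis 1)",
                  subtitle = sprintf("%.1f%% of total inertia explained",
                                     100 * result$percent_explained)) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_bw()
  ggplot2::ggsave(file, p, width = 6, height = 4)
  .write_layer_tsv(df, file, "scores")
  invisible(p)
}

#' Expression heatmap ordered by an ordination axis
#'
#' Selects the `top_fraction` of genes with largest absolute WA score on
#' the chosen axis, orders the rows by that score, and clusters the
#' sample columns (complete linkage on Euclidean distance) — rows keep
#' the ordination order, only columns are clustered. The plotted matrix
#' is exported as `<file>_matrix.tsv`.
#'
#' @param result a `cca_result`.
#' @param x the [expression_matrix()] the result was computed from.
#' @param file output figure path.
#' @param axis axis index (default 1).
#' @param top_fraction fraction of genes to show, in (0, 1].
#' @return invisibly, a list with the ordered `matrix`, the
#'   `gene_order` and the `column_order` used.
#' @export
heatmap_by_axis <- function(result, x, file, axis = 1, top_fraction = 0.02) {
  stopifnot(inherits(result, "cca_result"), inherits(x, "expression_matrix"))
  if (axis > length(result$singular_values)) stop("axis not present in result")
  if (top_fraction <= 0 || top_fraction > 1) {
    stop("top_fraction must be in (0, 1]")
  }
  wa <- result$gene_scores_wa_principal[, axis]
  n_top <- floor(top_fraction * length(wa))
  if (n_top < 1) stop("top_fraction selects zero genes")
  top <- order(-abs(wa))[seq_len(n_top)]
  top <- top[order(-wa[top])]            # rows ordered by axis score
  m <- x$values[top, , drop = FALSE]
  hc <- stats::hclust(stats::dist(t(m)), method = "complete")
  m <- m[, hc$order, drop = FALSE]

  df <- expand.grid(gene = factor(rownames(m), levels = rev(rownames(m))),
                    sample = factor(colnames(m), levels = colnames(m)))
  df$value <- as.vector(m[cbind(as.character(df$gene),
                                as.character(df$sample))])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$gene,
                                        fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", midpoint = mean(m)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "expression",
                  subtitle = sprintf(
                    "rows: top %.0f%% genes by |Axis %d| WA score; clustering column (samples) only",
                    100 * top_fraction, axis)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5),
                   axis.text.y = ggplot2::element_text(size = 5))
  ggplot2::ggsave(file, p, width = 6, height = 6)
  out_df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  .write_layer_tsv(out_df, file, "matrix")
  invisible(list(matrix = m, gene_order = rownames(m),
                 column_order = colnames(m)))
}
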