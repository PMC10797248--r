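# Static figures (ggplot2, Suggests): scree, Manhattan-like component
# summaries, embedding scatter.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_domain("ggplot2 is required for plotting")
  }
}

#' Scree plot of cumulative variance explained
#'
#' @param d A `decomposition`.
#' @param dims Dimensions to mark (default the classic 5/10/25/50/...
#'   grid, truncated to the spectrum).
#' @return A ggplot object.
#' @export
plot_scree <- function(d, dims = c(5, 10, 25, 50, 100, 150, 200)) {
  need_ggplot()
  dims <- dims[dims <= length(d$singular_spectrum)]
  tab <- scree_table(d, dims)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$K, y = 100 * .data$cumulative_variance)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "components", y = "cumulative variance explained (%)") +
    ggplot2::theme_minimal()
}

#' Manhattan-like plot of one component's SNP loadings
#'
#' @param d A `decomposition` with coordinates in its registry.
#' @param component Component index.
#' @param tails Tail convention for the loading p-values.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(d, component, tails = "two") {
  need_ggplot()
  tab <- manhattan_table(d, component, tails)
  tab$chrom <- factor(tab$chrom, levels = unique(tab$chrom))
  ggplot2::ggplot(tab, ggplot2::aes(x = seq_len(nrow(tab)), y = .data$neg_log10_p,
                                    colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = "SNP (genomic order)", y = expression(-log[10](p)),
                  title = rownames(d$snp_loadings)[component]) +
    ggplot2::theme_minimal()
}

#' Scatter plot of a 2-D trait-loading embedding
#'
#' @param emb An `embedding_result`.
#' @return A ggplot object.
#' @export
plot_embedding <- function(emb) {
  need_ggplot()
  df <- data.frame(dim1 = emb$coords[, 1], dim2 = emb$coords[, 2],
                   modality = emb$modality_labels %||% "trait")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                   colour = .data$modality)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2") +
    ggplot2::theme_minimal()
}
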