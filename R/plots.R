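#' Bar chart of the DBD family distribution
#'
#' @param family_sets Membership tibble ([classify_families()]).
#' @return A ggplot object.
#' @export
plot_family_distribution <- function(family_sets) {
  dist <- family_distribution(family_sets)
  dist$family <- factor(dist$family, levels = rev(dist$family))
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$n_members, y = .data$family)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "TFs in family", y = NULL,
                  title = "TF classification by DNA-binding domain family") +
    ggplot2::theme_minimal()
}

#' Heat map of the orthologue presence/absence matrix
#'
#' Tiles are ordered by the hierarchical clustering of rows (TFs) and
#' columns (species); green marks presence of at least one orthologue.
#'
#' @param object Presence tibble ([build_presence()]).
#' @param clustering Optional `presence_clustering`; computed when omitted.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot presence_matrix
#' @export
autoplot.presence_matrix <- function(object, clustering = NULL, ...) {
  plot_presence(object, clustering)
}

#' @rdname autoplot.presence_matrix
#' @param presence Presence tibble.
#' @export
plot_presence <- function(presence, clustering = NULL) {
  if (is.null(clustering) && nrow(presence) >= 2L) {
    clustering <- cluster_presence(presence)
  }
  long <- tidyr::pivot_longer(presence, -"gene_id",
                              names_to = "species", values_to = "present")
  if (!is.null(clustering)) {
    long$gene_id <- factor(long$gene_id, levels = clustering$row_order)
    long$species <- factor(long$species, levels = clustering$col_order)
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$species, y = .data$gene_id,
                                     fill = .data$present)) +
    ggplot2::geom_tile(colour = "grey90", linewidth = 0.1) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "forestgreen", `FALSE` = "white")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "orthologue") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1),
                   axis.text.y = ggplot2::element_blank())
}

#' Heat map of gene expression across tissues
#'
#' @param ge Gene-level expression table ([gene_expression()]).
#' @param genes Optional gene subset to display.
#' @return A ggplot object; fill is log10(FPKM + 1).
#' @export
plot_expression_heatmap <- function(ge, genes = NULL) {
  if (!is.null(genes)) {
    keep <- ge$gene_id %in% genes
    tis <- attr(ge, "tissues")
    ge <- ge[keep, , drop = FALSE]
    attr(ge, "tissues") <- tis
  }
  long <- tidyr::pivot_longer(ge, -"gene_id", names_to = "tissue",
                              values_to = "fpkm")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gene_id, y = .data$tissue,
                                     fill = log10(.data$fpkm + 1))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "red3") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log10(FPKM+1)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
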