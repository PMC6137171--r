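#' Tidy a pipeline run into one row per gene
#'
#' Combines the evidence class, conservation group and tissue-expression
#' breadth of every screened candidate into a single long table.
#'
#' @param x A `tf_pipeline` object.
#' @param ... Unused.
#' @return Tibble with `gene_id`, `assigned_class`, `rationale_code`,
#'   `orthologue`, `similarity`, `in_compendium`, `group`,
#'   `n_tissues_expressed`.
#' @method tidy tf_pipeline
#' @export
tidy.tf_pipeline <- function(x, ...) {
  pres <- ge_presence(x$gene_expression)
  ntis <- tibble(gene_id = rownames(pres),
                 n_tissues_expressed = as.integer(rowSums(pres)))
  x$candidates %>%
    mutate(in_compendium = .data$assigned_class %in% c("a", "b")) %>%
    left_join(x$groups[c("gene_id", "group")], by = "gene_id") %>%
    left_join(ntis, by = "gene_id")
}

#' One-row summary of a pipeline run
#'
#' @param x A `tf_pipeline` object.
#' @param ... Unused.
#' @return One-row tibble with the headline counts: screened genes,
#'   compendium size, class tallies, registry size, cofactor count and
#'   coexpressed-pair count.
#' @method glance tf_pipeline
#' @export
glance.tf_pipeline <- function(x, ...) {
  cls <- table(factor(x$candidates$assigned_class, levels = CANDIDATE_CLASSES))
  tibble(
    n_screened = length(unique(x$screened$gene_id)),
    n_class_a = as.integer(cls[["a"]]),
    n_class_b = as.integer(cls[["b"]]),
    n_class_c = as.integer(cls[["c"]]),
    n_class_y = as.integer(cls[["y"]]),
    n_compendium = nrow(x$compendium),
    n_registry_dbds = nrow(x$registry),
    n_tcofs = nrow(x$tcofs),
    n_pairs = nrow(x$pairs),
    n_pairs_coexpressed = x$coexpression_summary$n_coexpressed
  )
}

#' Tidy a presence clustering into merge heights
#'
#' @param x A `presence_clustering` object.
#' @param ... Unused.
#' @return Tibble of row-dendrogram merges: `step`, `height`, `size`.
#' @method tidy presence_clustering
#' @export
tidy.presence_clustering <- function(x, ...) {
  h <- x$row_hclust
  if (is.null(h)) return(tibble(step = integer(), height = numeric(), size = integer()))
  size <- integer(length(h$height))
  for (i in seq_along(h$height)) {
    size[i] <- sum(vapply(h$merge[i, ], function(k) {
      if (k < 0) 1L else size[k]
    }, integer(1)))
  }
  tibble(step = seq_along(h$height), height = h$height, size = size)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
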