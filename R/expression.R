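#' Gene-level expression from an isoform FPKM matrix
#'
#' Aggregates isoform FPKM to gene level (per tissue) by the maximum over a
#' gene's isoforms — a presence-oriented summary: a gene is expressed in a
#' tissue as soon as one of its isoforms is (`aggregate = "sum"` is
#' available for abundance-oriented use). A gene counts as expressed where
#' its FPKM exceeds `threshold`.
#'
#' @param fpkm Validated expression tibble ([read_fpkm()]).
#' @param aggregate `"max"` (default) or `"sum"`.
#' @param threshold Expression threshold; FPKM strictly greater counts as
#'   expressed (default 0).
#' @return Tibble `gene_id` plus one numeric column per tissue, with
#'   attributes `threshold` and `tissues`.
#' @export
gene_expression <- function(fpkm, aggregate = c("max", "sum"), threshold = 0) {
  aggregate <- match.arg(aggregate)
  fpkm <- validate_fpkm(fpkm)
  tissues <- setdiff(names(fpkm), c("isoform_id", "gene_id"))
  f <- if (aggregate == "max") max else sum
  out <- fpkm %>%
    group_by(.data$gene_id) %>%
    summarise(dplyr::across(dplyr::all_of(tissues), f), .groups = "drop") %>%
    arrange(.data$gene_id)
  attr(out, "threshold") <- threshold
  attr(out, "tissues") <- tissues
  out
}

ge_presence <- function(ge) {
  tissues <- attr(ge, "tissues")
  thr <- attr(ge, "threshold") %||% 0
  m <- as.matrix(ge[tissues]) > thr
  rownames(m) <- ge$gene_id
  m
}

#' Tissue-expression tallies
#'
#' Summary counts over a gene-level expression table, optionally restricted
#' to a gene set of interest: genes expressed in at least one tissue, in
#' every tissue (ubiquitous), in exactly one tissue (single-tissue), in an
#' intermediate number, and per-tissue expressed-gene counts. Ubiquitous,
#' single-tissue and intermediate genes partition the expressed genes.
#'
#' @param ge Gene-level expression ([gene_expression()]).
#' @param genes Optional character vector restricting the tally; genes of
#'   the set absent from the table are counted as `n_unmeasured`.
#' @return List with scalar tallies and a `per_tissue` tibble.
#' @export
expression_summary <- function(ge, genes = NULL) {
  if (!is.null(genes)) {
    n_unmeasured <- sum(!genes %in% ge$gene_id)
    ge_sub <- ge[ge$gene_id %in% genes, , drop = FALSE]
    attributes(ge_sub)[c("threshold", "tissues")] <- attributes(ge)[c("threshold", "tissues")]
    ge <- ge_sub
  } else {
    n_unmeasured <- 0L
  }
  m <- ge_presence(ge)
  ntis <- rowSums(m)
  list(
    n_genes = nrow(m),
    n_unmeasured = n_unmeasured,
    n_expressed = sum(ntis >= 1L),
    n_ubiquitous = sum(ntis == ncol(m)),
    n_single_tissue = sum(ntis == 1L),
    n_intermediate = sum(ntis > 1L & ntis < ncol(m)),
    n_tissues = ncol(m),
    per_tissue = tibble(tissue = colnames(m),
                        n_expressed = as.integer(unname(colSums(m))))
  )
}

#' TF–cofactor coexpression across tissues
#'
#' A pair is coexpressed in a tissue when both genes are expressed there
#' (FPKM above the threshold recorded on the expression table), and
#' coexpressed overall when that holds in at least one tissue. Pairs with a
#' member missing from the expression table are set aside and reported in
#' the `unmeasured_pairs` attribute rather than counted.
#'
#' @param pairs Tibble `tf`, `tcof` ([tcof_pairs()]).
#' @param ge Gene-level expression table ([gene_expression()]).
#' @return Tibble `tf`, `tcof`, `n_tissues`, `tissues` (list column),
#'   `coexpressed`, with attribute `unmeasured_pairs`.
#' @export
coexpression <- function(pairs, ge) {
  pairs <- as_tibble(pairs)
  check_columns(pairs, c("tf", "tcof"), "pair list")
  m <- ge_presence(ge)
  measurable <- pairs$tf %in% rownames(m) & pairs$tcof %in% rownames(m)
  unmeasured <- pairs[!measurable, , drop = FALSE]
  pairs <- pairs[measurable, , drop = FALSE]
  tiss <- colnames(m)
  sets <- lapply(seq_len(nrow(pairs)), function(i) {
    tiss[m[pairs$tf[i], ] & m[pairs$tcof[i], ]]
  })
  out <- pairs %>%
    mutate(n_tissues = lengths(sets), tissues = sets,
           coexpressed = lengths(sets) >= 1L)
  attr(out, "unmeasured_pairs") <- unmeasured
  attr(out, "n_tissue_cols") <- length(tiss)
  out
}

#' Summarise coexpression results
#'
#' @param cx Result of [coexpression()].
#' @return List: counts of pairs analysed / coexpressed in at least one
#'   tissue / in all tissues / in more than ten tissues, and per-TF and
#'   per-cofactor partner coexpression percentages (tibbles with
#'   `n_coexpressed`, `n_partners`, `pct_coexpressed`).
#' @export
coexpression_summary <- function(cx) {
  ntis_total <- attr(cx, "n_tissue_cols")
  per <- function(key) {
    cx %>%
      group_by(.data[[key]]) %>%
      summarise(n_coexpressed = sum(.data$coexpressed),
                n_partners = n(), .groups = "drop") %>%
      mutate(pct_coexpressed = pct(.data$n_coexpressed, .data$n_partners, 2)) %>%
      rename(gene_id = dplyr::all_of(key))
  }
  list(
    n_pairs = nrow(cx),
    n_unmeasured_pairs = nrow(attr(cx, "unmeasured_pairs") %||% tibble()),
    n_coexpressed = sum(cx$coexpressed),
    n_all_tissues = sum(cx$n_tissues == ntis_total),
    n_gt10_tissues = sum(cx$n_tissues > 10L),
    n_tfs_coexpressed = length(unique(cx$tf[cx$coexpressed])),
    n_tcofs_coexpressed = length(unique(cx$tcof[cx$coexpressed])),
    per_tf = per("tf"),
    per_tcof = per("tcof")
  )
}

#' Percentage with half-away-from-zero rounding
#'
#' `100 * numerator / denominator`, rounded to `decimals` places with ties
#' rounded away from zero (the convention of printed results tables, unlike
#' [round()]'s banker's rounding).
#'
#' @param numerator,denominator Counts; the denominator must be positive.
#' @param decimals Decimal places to keep (default 1).
#' @return Numeric percentage.
#' @export
#' @examples
#' pct(680, 865, 1)  # 78.6
#' pct(467, 865, 0)  # 54
pct <- function(numerator, denominator, decimals = 1L) {
  if (any(denominator <= 0)) {
    abort("pct: denominator must be positive", class = "tfc_value_error")
  }
  x <- 100 * numerator / denominator
  s <- 10^decimals
  sign(x) * floor(abs(x) * s + 0.5) / s
}
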