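#' Construct a reference TF census
#'
#' The reference census lists human genes with curation evidence classes:
#' `a` (experimental evidence of TF function), `b` (domain arrangement
#' equivalent to an a-class TF), `c` (possible TF without functional
#' evidence), `x` (known not to be a TF) and `other` (unclassified
#' DNA-binding-domain source).
#'
#' @param census Data frame with columns `gene_id`, `evidence_class`, `note`
#'   (`note` optional, defaults to `""`).
#' @return A validated census tibble.
#' @export
new_census <- function(census) {
  census <- as_tibble(census)
  if (!"note" %in% names(census)) census$note <- ""
  check_columns(census, c("gene_id", "evidence_class", "note"), "census")
  check_nonempty_ids(census$gene_id, "census")
  if (anyDuplicated(census$gene_id)) {
    abort("census: gene_id must be unique", class = "tfc_format_error")
  }
  bad <- setdiff(unique(census$evidence_class), CENSUS_CLASSES)
  if (length(bad) > 0L) {
    abort(sprintf("census: illegal evidence class(es): %s",
                  paste(bad, collapse = ", ")), class = "tfc_format_error")
  }
  census[c("gene_id", "evidence_class", "note")]
}

#' Apply literature-evidence reclassifications to a census
#'
#' Updates evidence classes for genes with new literature evidence of
#' transcriptional activity. By default only upward moves into class `a`
#' (from `b`, `c` or `other`) are permitted, since literature review adds
#' evidence rather than removing it; re-applying an update to a gene that
#' already carries the new class is a permitted no-op, so applying the same
#' update list twice is idempotent. Census membership never changes.
#'
#' @param census Census tibble ([new_census()]).
#' @param updates Data frame with columns `gene_id`, `new_class`, `citation`.
#' @param force Allow arbitrary class moves (default `FALSE`).
#' @return Updated census tibble with attribute `n_updated`, the number of
#'   entries whose class actually changed.
#' @export
#' @examples
#' cen <- new_census(data.frame(gene_id = "g1", evidence_class = "b", note = ""))
#' apply_updates(cen, data.frame(gene_id = "g1", new_class = "a", citation = "PMID:1"))
apply_updates <- function(census, updates, force = FALSE) {
  census <- new_census(census)
  updates <- as_tibble(updates)
  if (nrow(updates) == 0L) {
    attr(census, "n_updated") <- 0L
    return(census)
  }
  check_columns(updates, c("gene_id", "new_class", "citation"), "evidence updates")
  bad_class <- setdiff(unique(updates$new_class), CENSUS_CLASSES)
  if (length(bad_class) > 0L) {
    abort(sprintf("evidence updates: illegal class(es): %s",
                  paste(bad_class, collapse = ", ")), class = "tfc_format_error")
  }
  unknown <- setdiff(updates$gene_id, census$gene_id)
  if (length(unknown) > 0L) {
    abort(sprintf("evidence updates: unknown gene id(s): %s",
                  paste(unknown, collapse = ", ")), class = "tfc_value_error")
  }
  idx <- match(updates$gene_id, census$gene_id)
  old <- census$evidence_class[idx]
  noop <- old == updates$new_class
  if (!force) {
    legal <- noop | (updates$new_class == "a" & old %in% c("b", "c", "other"))
    if (any(!legal)) {
      abort(sprintf(
        "evidence updates: non-upward move(s) without force = TRUE: %s",
        paste(sprintf("%s (%s->%s)", updates$gene_id[!legal], old[!legal],
                      updates$new_class[!legal]), collapse = ", ")),
        class = "tfc_value_error")
    }
  }
  census$evidence_class[idx] <- updates$new_class
  census$note[idx[!noop]] <- updates$citation[!noop]
  attr(census, "n_updated") <- sum(!noop)
  census
}

#' Look up evidence classes in a census
#'
#' @param census Census tibble.
#' @param gene_id Character vector of gene ids.
#' @return Character vector of evidence classes, `"absent"` for ids not in
#'   the census.
#' @export
classify_lookup <- function(census, gene_id) {
  cls <- census$evidence_class[match(gene_id, census$gene_id)]
  cls[is.na(cls)] <- "absent"
  cls
}
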