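#' Classify TFs into DBD structural families
#'
#' Each TF is assigned to the structural family of every reliable DBD it
#' carries (C2H2 zinc-finger, Homeodomain, bZIP, HLH, ...). A TF with DBDs
#' from several families is a member of each — family sets may overlap.
#'
#' @param genes Gene-domain tibble restricted to the TFs to classify (e.g.
#'   the screened table filtered to the compendium).
#' @param registry Reliable-DBD registry; only registry hits count towards
#'   family membership.
#' @param family_map Curated tibble `interpro_id`, `family` mapping every
#'   registry DBD to exactly one family name.
#' @return Tibble `family`, `gene_id`, one row per membership (distinct).
#' @export
classify_families <- function(genes, registry, family_map) {
  family_map <- as_tibble(family_map)
  check_columns(family_map, c("interpro_id", "family"), "family map")
  dbd_hits <- genes %>%
    filter(!is.na(.data$interpro_id), .data$interpro_id %in% registry$interpro_id) %>%
    distinct(.data$gene_id, .data$interpro_id)
  missing <- setdiff(unique(dbd_hits$interpro_id), family_map$interpro_id)
  if (length(missing) > 0L) {
    abort(sprintf("classify_families: no family for accession(s): %s",
                  paste(missing, collapse = ", ")), class = "tfc_value_error")
  }
  dbd_hits %>%
    left_join(family_map, by = "interpro_id") %>%
    distinct(.data$family, .data$gene_id) %>%
    arrange(.data$family, .data$gene_id)
}

#' Collapse rare DBD families into "other"
#'
#' Families with fewer than `min_size` member TFs are merged into a single
#' `"other"` family. Memberships are preserved (the total multiset of
#' (gene, membership) pairs is unchanged up to the family label), and the
#' operation is idempotent.
#'
#' @param family_sets Membership tibble from [classify_families()].
#' @param min_size Minimum members for a family to stand alone (default 5).
#' @return Membership tibble with small families relabelled `"other"`.
#' @export
collapse_small_families <- function(family_sets, min_size = 5L) {
  sizes <- family_sets %>% count(.data$family, name = "n")
  small <- sizes$family[sizes$n < min_size & sizes$family != "other"]
  # memberships are relabelled, never merged, so the membership multiset is
  # conserved and a second collapse is a no-op
  family_sets %>%
    mutate(family = ifelse(.data$family %in% small, "other", .data$family)) %>%
    arrange(.data$family, .data$gene_id)
}

#' Family size distribution
#'
#' @param family_sets Membership tibble.
#' @return Tibble `family`, `n_members` sorted by decreasing size.
#' @export
family_distribution <- function(family_sets) {
  family_sets %>%
    distinct(.data$family, .data$gene_id) %>%
    count(.data$family, name = "n_members") %>%
    arrange(dplyr::desc(.data$n_members), .data$family)
}
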