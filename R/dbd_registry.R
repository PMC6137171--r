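#' Construct a TF-database snapshot
#'
#' A snapshot of an external TF database (e.g. DBD, AnimalTFDB, Cis-BP) for
#' one species: the genes it annotates as TFs and their InterPro domain
#' content. Used to extend the reliable DNA-binding-domain list by
#' intersection against the reference census.
#'
#' @param name Database name.
#' @param species `"human"` or `"mouse"`.
#' @param genes Data frame with columns `gene_id`, `interpro_id`,
#'   `entry_type`; a gene may appear with several domains. `interpro_id`
#'   may be `NA` for genes listed without domain annotation.
#' @return A snapshot tibble with `name`/`species` attributes.
#' @export
tf_db_snapshot <- function(name, species, genes) {
  species <- match.arg(species, c("human", "mouse"))
  genes <- as_tibble(genes)
  check_columns(genes, c("gene_id", "interpro_id", "entry_type"),
                sprintf("snapshot '%s'", name))
  check_nonempty_ids(genes$gene_id, sprintf("snapshot '%s'", name))
  hit <- !is.na(genes$interpro_id)
  if (any(hit & (is.na(genes$entry_type) | !genes$entry_type %in% c("domain", "family")))) {
    abort(sprintf("snapshot '%s': every referenced domain needs entry_type 'domain' or 'family'",
                  name), class = "tfc_format_error")
  }
  bad <- hit & !grepl("^IPR\\d{6}$", genes$interpro_id)
  if (any(bad)) {
    abort(sprintf("snapshot '%s': malformed InterPro accession(s): %s", name,
                  paste(unique(genes$interpro_id[bad]), collapse = ", ")),
          class = "tfc_format_error")
  }
  structure(genes, name = name, species = species,
            class = c("tf_db_snapshot", class(genes)))
}

#' Genes shared by all snapshots but novel to the census
#'
#' First removes from every snapshot the genes the census marks as known
#' non-TFs (class `x`), then intersects the snapshots' gene sets, and
#' finally drops genes already present in the census under any class. The
#' survivors are candidate carriers of novel reliable DBDs.
#'
#' @param snapshots List of [tf_db_snapshot()] objects, all of one species.
#' @param census Census tibble.
#' @return Sorted character vector of novel gene ids.
#' @export
intersect_novel_genes <- function(snapshots, census) {
  if (length(snapshots) < 2L) {
    abort("intersect_novel_genes: need at least two snapshots", class = "tfc_value_error")
  }
  species <- vapply(snapshots, attr, character(1), "species")
  if (length(unique(species)) != 1L) {
    abort("intersect_novel_genes: snapshots of mixed species", class = "tfc_value_error")
  }
  x_genes <- census$gene_id[census$evidence_class == "x"]
  gene_sets <- lapply(snapshots, function(s) setdiff(unique(s$gene_id), x_genes))
  shared <- Reduce(intersect, gene_sets)
  sort(setdiff(shared, census$gene_id))
}

#' Extract candidate reliable DBDs from novel genes
#'
#' Takes the union of InterPro entries found on the novel genes across the
#' snapshots, removes blacklisted (non-TF-associated) entries, and keeps
#' only entries curated as having a sequence-specific DNA-binding function.
#'
#' @param novel_genes Character vector from [intersect_novel_genes()].
#' @param snapshots The snapshots the genes came from.
#' @param domain_functions Curated table with columns `interpro_id`,
#'   `sequence_specific` (logical): whether the entry confers
#'   sequence-specific DNA binding.
#' @param blacklist Character vector of InterPro accessions found on genes
#'   with molecular functions other than transcription (see
#'   [non_tf_blacklist()]).
#' @param provenance Label recording which compilation round added the
#'   entries (e.g. `"human intersection"`).
#' @return Tibble of DBD entries: `interpro_id`, `entry_type`, `provenance`,
#'   `sequence_specific`.
#' @export
extract_candidate_dbds <- function(novel_genes, snapshots, domain_functions,
                                   blacklist = character(),
                                   provenance = "intersection") {
  hits <- bind_rows(lapply(snapshots, function(s) {
    as_tibble(s)[s$gene_id %in% novel_genes & !is.na(s$interpro_id),
                 c("interpro_id", "entry_type")]
  }))
  if (nrow(hits) == 0L) {
    return(tibble(interpro_id = character(), entry_type = character(),
                  provenance = character(), sequence_specific = logical()))
  }
  types <- hits %>% distinct(.data$interpro_id, .data$entry_type)
  if (anyDuplicated(types$interpro_id)) {
    dup <- types$interpro_id[duplicated(types$interpro_id)]
    abort(sprintf("extract_candidate_dbds: conflicting entry_type for: %s",
                  paste(unique(dup), collapse = ", ")), class = "tfc_format_error")
  }
  out <- types %>%
    filter(!.data$interpro_id %in% blacklist) %>%
    left_join(as_tibble(domain_functions)[c("interpro_id", "sequence_specific")],
              by = "interpro_id")
  if (anyNA(out$sequence_specific)) {
    abort(sprintf("extract_candidate_dbds: no curated function for: %s",
                  paste(out$interpro_id[is.na(out$sequence_specific)], collapse = ", ")),
          class = "tfc_value_error")
  }
  out %>%
    filter(.data$sequence_specific) %>%
    mutate(provenance = provenance) %>%
    select("interpro_id", "entry_type", "provenance", "sequence_specific") %>%
    arrange(.data$interpro_id)
}

#' Derive a non-TF domain blacklist
#'
#' Collects every InterPro entry occurring on a gene the census classifies
#' `x` (known non-TF) in any snapshot — such entries are not specific to
#' transcription — and appends an explicit curated list. The blacklist wins
#' over TF occurrence when a domain sits on both a TF and a non-TF gene.
#'
#' @param snapshots List of snapshots.
#' @param census Census tibble.
#' @param extra Additional accessions to blacklist.
#' @return Sorted character vector of accessions.
#' @export
non_tf_blacklist <- function(snapshots, census, extra = character()) {
  x_genes <- census$gene_id[census$evidence_class == "x"]
  on_x <- unlist(lapply(snapshots, function(s) {
    s$interpro_id[s$gene_id %in% x_genes & !is.na(s$interpro_id)]
  }))
  sort(unique(c(on_x, extra)))
}

#' Assemble a reliable-DBD registry
#'
#' Combines DBD entries from the reference census and from successive
#' database-intersection rounds into one registry, de-duplicating by
#' accession (the first provenance encountered is kept, so the reference
#' round should be listed first). Set union makes the result independent of
#' the order of later rounds.
#'
#' @param ... Tibbles of DBD entries (`interpro_id`, `entry_type`,
#'   `provenance`, `sequence_specific`).
#' @return Registry tibble sorted by accession.
#' @export
dbd_registry <- function(...) {
  entries <- bind_rows(...)
  if (nrow(entries) == 0L) {
    return(tibble(interpro_id = character(), entry_type = character(),
                  provenance = character(), sequence_specific = logical()))
  }
  check_columns(entries, c("interpro_id", "entry_type", "provenance", "sequence_specific"),
                "DBD registry")
  if (any(!grepl("^IPR\\d{6}$", entries$interpro_id))) {
    abort("DBD registry: accessions must match IPR followed by 6 digits",
          class = "tfc_format_error")
  }
  if (any(!entries$entry_type %in% c("domain", "family"))) {
    abort("DBD registry: entry_type must be 'domain' or 'family'",
          class = "tfc_format_error")
  }
  first <- entries[!duplicated(entries$interpro_id), ]
  conflict <- entries %>% distinct(.data$interpro_id, .data$entry_type) %>%
    count(.data$interpro_id) %>% filter(.data$n > 1L)
  if (nrow(conflict) > 0L) {
    abort(sprintf("DBD registry: conflicting entry_type for: %s",
                  paste(conflict$interpro_id, collapse = ", ")),
          class = "tfc_format_error")
  }
  first %>% arrange(.data$interpro_id)
}

#' Summarise a DBD registry by entry type
#'
#' @param registry Registry tibble.
#' @return One-row tibble with `n_domain`, `n_family`, `total`.
#' @export
#' @examples
#' reg <- dbd_registry(tibble::tibble(interpro_id = "IPR013087",
#'   entry_type = "domain", provenance = "reference census",
#'   sequence_specific = TRUE))
#' registry_summary(reg)
registry_summary <- function(registry) {
  tibble(
    n_domain = sum(registry$entry_type == "domain"),
    n_family = sum(registry$entry_type == "family"),
    total = nrow(registry)
  )
}

#' Write / read a DBD registry TSV
#'
#' @param registry Registry tibble.
#' @param path TSV path.
#' @return `path` (writer) or the registry tibble (reader).
#' @export
write_registry <- function(registry, path) {
  readr::write_tsv(registry, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    sequence_specific = readr::col_logical(),
    .default = readr::col_character()
  ), progress = FALSE)
  dbd_registry(out)
}
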