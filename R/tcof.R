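#' Default term configuration for the cofactor screen
#'
#' The Gene Ontology anchors of the cofactor screen: the nuclear cellular
#' component (GO:0005634), the transcription-related molecular-function and
#' biological-process term sets, the experimental GO evidence codes, and
#' the allowed molecular-interaction (MI) types.
#'
#' @return Named list with `cc_anchor`, `mf_terms`, `bp_terms`,
#'   `experimental_codes`, `allowed_mi`.
#' @export
default_term_config <- function() {
  list(
    cc_anchor = "GO:0005634",
    mf_terms = c("GO:0003713", "GO:0003712", "GO:0003714", "GO:0001221",
                 "GO:0001222", "GO:0001223", "GO:0033613", "GO:0070491"),
    bp_terms = c("GO:0006351", "GO:0045892", "GO:0045893", "GO:0006355",
                 "GO:0009299"),
    experimental_codes = c("EXP", "IDA", "IMP", "IGI", "IEP", "IPI"),
    allowed_mi = c("MI:0195", "MI:0407", "MI:0915")
  )
}

#' Read a term configuration from YAML
#'
#' @param path YAML file with any of the keys of [default_term_config()];
#'   missing keys fall back to the defaults.
#' @return Term configuration list.
#' @export
read_term_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- utils::modifyList(default_term_config(), cfg)
  validate_term_config(out)
}

validate_term_config <- function(cfg) {
  for (key in c("mf_terms", "bp_terms", "experimental_codes", "allowed_mi")) {
    if (length(cfg[[key]]) == 0L) {
      abort(sprintf("term config: '%s' must be non-empty", key),
            class = "tfc_config_error")
    }
  }
  if (length(cfg$cc_anchor) != 1L || !nzchar(cfg$cc_anchor)) {
    abort("term config: 'cc_anchor' must be a single GO id", class = "tfc_config_error")
  }
  cfg
}

#' Filter interactions by MI interaction type
#'
#' Keeps interactions whose type is in the allowed list (by default
#' covalent binding MI:0195, direct interaction MI:0407 and physical
#' association MI:0915). Per-type counts of the retained records are
#' attached as attribute `type_counts`.
#'
#' @param records Interaction tibble ([read_mitab()]).
#' @param allowed_types Character vector of MI accessions.
#' @return Filtered tibble with a `type_counts` attribute.
#' @export
filter_interactions <- function(records,
                                allowed_types = default_term_config()$allowed_mi) {
  out <- records[records$mi_type %in% allowed_types, , drop = FALSE]
  counts <- table(factor(out$mi_type, levels = sort(allowed_types)))
  attr(out, "type_counts") <- tibble(mi_type = names(counts),
                                     n = as.integer(counts))
  out
}

#' Candidate cofactors: non-TF interaction partners of TFs
#'
#' A candidate transcription cofactor is any protein interacting with at
#' least one TF of the compendium while not being a TF itself; TF–TF
#' interactions therefore contribute no candidates. Each candidate carries
#' the set of TFs it partners.
#'
#' @param records Filtered interaction tibble.
#' @param tf_set Character vector of TF ids (non-empty).
#' @return Tibble `protein_id`, `tf_partners` (list column),
#'   `n_tf_partners`.
#' @export
candidate_tcofs <- function(records, tf_set) {
  if (length(tf_set) == 0L) {
    abort("candidate_tcofs: tf_set is empty", class = "tfc_value_error")
  }
  a_tf <- records$id_a %in% tf_set
  b_tf <- records$id_b %in% tf_set
  edges <- bind_rows(
    tibble(protein_id = records$id_b[a_tf & !b_tf], tf = records$id_a[a_tf & !b_tf]),
    tibble(protein_id = records$id_a[b_tf & !a_tf], tf = records$id_b[b_tf & !a_tf])
  )
  if (nrow(edges) == 0L) {
    return(tibble(protein_id = character(), tf_partners = list(),
                  n_tf_partners = integer()))
  }
  edges %>%
    distinct() %>%
    group_by(.data$protein_id) %>%
    summarise(tf_partners = list(sort(unique(.data$tf))), .groups = "drop") %>%
    mutate(n_tf_partners = lengths(.data$tf_partners)) %>%
    arrange(.data$protein_id)
}

#' Sequential GO filter for candidate cofactors
#'
#' Mirrors the screen's narrative order: candidates must (1) be annotated
#' to the nuclear cellular component, then (2) to at least one listed
#' transcription-related biological process, then (3) to at least one
#' listed transcription-related molecular function. Annotations are used as
#' directly asserted — no ancestor closure over the ontology graph. The
#' per-stage survivor counts are attached as attribute `stage_counts` and
#' are monotone non-increasing.
#'
#' @param candidates Candidate tibble ([candidate_tcofs()]).
#' @param annotations GO annotation tibble ([read_gaf()]), keyed by the same
#'   identifier namespace as the candidates (apply [map_protein_ids()]
#'   first if the annotations are for another species' accessions).
#' @param term_config Term configuration ([default_term_config()]).
#' @return Surviving candidates with a `stage_counts` attribute (tibble
#'   `stage`, `n` for input/nucleus/biological process/molecular function).
#' @export
go_filter <- function(candidates, annotations, term_config = default_term_config()) {
  term_config <- validate_term_config(term_config)
  ann_of <- function(ids, aspect, terms) {
    sel <- annotations$aspect == aspect & annotations$go_id %in% terms
    ids[ids %in% annotations$protein_id[sel]]
  }
  ids0 <- candidates$protein_id
  ids1 <- ann_of(ids0, "CC", term_config$cc_anchor)
  ids2 <- ann_of(ids1, "BP", term_config$bp_terms)
  ids3 <- ann_of(ids2, "MF", term_config$mf_terms)
  out <- candidates[candidates$protein_id %in% ids3, , drop = FALSE]
  attr(out, "stage_counts") <- tibble(
    stage = c("input", "nucleus", "biological_process", "molecular_function"),
    n = c(length(ids0), length(ids1), length(ids2), length(ids3))
  )
  out
}

#' Classify cofactors by GO evidence
#'
#' Splits annotations into experimental (EXP, IDA, IMP, IGI, IEP, IPI) and
#' non-experimental evidence. With `N` = experimental evidence for nuclear
#' localization and `T` = experimental evidence for a listed
#' transcription-related molecular function, the confidence class is
#' `high_confidence` (N and T), `hypothetical_I` (T only), `hypothetical_II`
#' (N only) or `hypothetical_III` (neither). Biological-process evidence
#' does not enter the classification.
#'
#' @param tcofs Cofactors that passed [go_filter()].
#' @param annotations GO annotation tibble.
#' @param term_config Term configuration.
#' @return Input tibble plus a `confidence_class` column.
#' @export
classify_evidence <- function(tcofs, annotations, term_config = default_term_config()) {
  term_config <- validate_term_config(term_config)
  exp_codes <- term_config$experimental_codes
  ann_exp <- annotations[annotations$evidence_code %in% exp_codes, , drop = FALSE]
  n_ids <- unique(ann_exp$protein_id[ann_exp$aspect == "CC" &
                                       ann_exp$go_id %in% term_config$cc_anchor])
  t_ids <- unique(ann_exp$protein_id[ann_exp$aspect == "MF" &
                                       ann_exp$go_id %in% term_config$mf_terms])
  N <- tcofs$protein_id %in% n_ids
  T_ <- tcofs$protein_id %in% t_ids
  tcofs$confidence_class <- dplyr::case_when(
    N & T_ ~ "high_confidence",
    T_ & !N ~ "hypothetical_I",
    N & !T_ ~ "hypothetical_II",
    TRUE ~ "hypothetical_III"
  )
  tcofs
}

#' Map protein identifiers through an id-mapping table
#'
#' Re-keys a table (e.g. human GO annotations) onto another identifier
#' namespace (e.g. the focal species' gene ids) via a two-column mapping;
#' rows without a mapping are dropped, and one-to-many mappings duplicate
#' rows.
#'
#' @param tbl Tibble with a `protein_id` column.
#' @param id_map Tibble with columns `from`, `to`.
#' @return Re-keyed tibble.
#' @export
map_protein_ids <- function(tbl, id_map) {
  id_map <- as_tibble(id_map)
  check_columns(id_map, c("from", "to"), "id map")
  out <- dplyr::inner_join(tbl, id_map, by = c(protein_id = "from"),
                           relationship = "many-to-many")
  out$protein_id <- out$to
  out$to <- NULL
  out
}

#' TF–cofactor interaction pairs
#'
#' Flattens the candidate table into one row per TF–cofactor pair, the edge
#' list used by the coexpression analysis.
#'
#' @param tcofs Cofactor tibble with `protein_id` and `tf_partners`.
#' @return Tibble `tf`, `tcof`.
#' @export
tcof_pairs <- function(tcofs) {
  if (nrow(tcofs) == 0L) return(tibble(tf = character(), tcof = character()))
  tidyr::unnest(
    tibble(tcof = tcofs$protein_id, tf = tcofs$tf_partners),
    "tf"
  )[, c("tf", "tcof")] %>% arrange(.data$tf, .data$tcof)
}
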