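#' Run the full compendium pipeline on a world bundle
#'
#' Executes the curation stages in order — census update, reliable-DBD
#' registry compilation (reference entries plus the human and mouse
#' database-intersection rounds), DBD screening, evidence-class assignment,
#' compendium extraction — followed by the characterisation stages: DBD
#' family classification, cross-species conservation, cofactor
#' identification and tissue expression/coexpression. The analysis itself
#' is deterministic; randomness lives only in world generation.
#'
#' @param world A world bundle ([generate_world()]), or any list with the
#'   same `$data` tables.
#' @param threshold Arrangement-similarity threshold (default 0.8).
#' @param tau Conservation predominance threshold (default 0.9).
#' @param expression_threshold FPKM presence threshold (default 0).
#' @param cluster Also hierarchically cluster the presence matrix
#'   (default `TRUE`).
#' @return Object of class `tf_pipeline`: list of stage outputs plus a
#'   `manifest` tibble of per-stage input/output counts.
#' @export
run_pipeline <- function(world, threshold = 0.8, tau = 0.9,
                         expression_threshold = 0, cluster = TRUE) {
  d <- world$data
  stages <- list()
  log_stage <- function(stage, n_in, n_out) {
    stages[[length(stages) + 1L]] <<- tibble(stage = stage,
                                             n_in = n_in, n_out = n_out)
  }

  # 1. census update
  census <- apply_updates(d$census, d$census_updates)
  log_stage("census_update", nrow(d$census), attr(census, "n_updated"))

  # 2. reliable-DBD registry: reference entries + two intersection rounds
  blacklist <- non_tf_blacklist(c(d$human_snapshots, d$mouse_snapshots), census)
  round_entries <- function(snapshots, provenance) {
    novel <- intersect_novel_genes(snapshots, census)
    extract_candidate_dbds(novel, snapshots, d$domain_functions,
                           blacklist = blacklist, provenance = provenance)
  }
  registry <- dbd_registry(
    d$reference_dbds,
    round_entries(d$human_snapshots, "human intersection"),
    round_entries(d$mouse_snapshots, "mouse intersection")
  )
  log_stage("registry", nrow(d$reference_dbds), nrow(registry))

  # 3. DBD screening
  screened <- screen_for_dbds(d$genes, registry)
  screened_ids <- unique(screened$gene_id)
  log_stage("screen", length(unique(d$genes$gene_id)), length(screened_ids))

  # 4. evidence-class cascade
  candidates <- assign_classes(
    sort(screened_ids), screened, d$orthology, census, d$human_genes,
    evidence_updates = d$candidate_updates, hits = d$hits,
    threshold = threshold
  )
  comp <- compendium(candidates)
  log_stage("curation", length(screened_ids), nrow(comp))

  # families
  fam <- classify_families(screened[screened$gene_id %in% comp$gene_id, ],
                           registry, d$family_map)
  fam <- collapse_small_families(fam)
  log_stage("families", nrow(comp), length(unique(fam$family)))

  # conservation
  orth_all <- bind_rows(d$orthology, d$orthology_species %||% tibble())
  presence <- build_presence(sort(comp$gene_id), orth_all,
                             species_list = d$species,
                             focal = world$config$focal_species %||% NA_character_)
  groups <- assign_group(presence, d$clade_map, tau = tau,
                         focal = world$config$focal_species %||% NA_character_)
  clustering <- if (cluster && nrow(presence) >= 2L) cluster_presence(presence) else NULL
  log_stage("conservation", nrow(comp), length(unique(groups$group)))

  # cofactors
  filtered <- filter_interactions(d$interactions)
  log_stage("mi_filter", nrow(d$interactions), nrow(filtered))
  cand_tcofs <- candidate_tcofs(filtered, comp$gene_id)
  surv <- go_filter(cand_tcofs, d$annotations)
  tcofs <- classify_evidence(surv, d$annotations)
  log_stage("tcof", nrow(cand_tcofs), nrow(tcofs))
  pairs <- tcof_pairs(tcofs)

  # expression
  ge <- gene_expression(d$fpkm, threshold = expression_threshold)
  tf_expr <- expression_summary(ge, comp$gene_id)
  tcof_expr <- expression_summary(ge, tcofs$protein_id)
  cx <- coexpression(pairs, ge)
  cx_summary <- coexpression_summary(cx)
  log_stage("expression", nrow(pairs), cx_summary$n_coexpressed)

  structure(list(
    census = census,
    registry = registry,
    screened = screened,
    candidates = candidates,
    compendium = comp,
    partition = attr(comp, "partition"),
    families = fam,
    presence = presence,
    groups = groups,
    clustering = clustering,
    conservation = conservation_tallies(presence),
    interaction_type_counts = attr(filtered, "type_counts"),
    candidate_tcofs = cand_tcofs,
    tcof_stage_counts = attr(surv, "stage_counts"),
    tcofs = tcofs,
    pairs = pairs,
    gene_expression = ge,
    tf_expression = tf_expr,
    tcof_expression = tcof_expr,
    coexpression = cx,
    coexpression_summary = cx_summary,
    manifest = bind_rows(stages),
    parameters = list(threshold = threshold, tau = tau,
                      expression_threshold = expression_threshold,
                      seed = world$config$seed %||% NA_integer_)
  ), class = "tf_pipeline")
}

#' @export
print.tf_pipeline <- function(x, ...) {
  cat("TF compendium pipeline run\n")
  cat(sprintf("  screened genes:   %d\n", length(unique(x$screened$gene_id))))
  cat(sprintf("  compendium (a+b): %d\n", nrow(x$compendium)))
  cat(sprintf("  cofactors:        %d\n", nrow(x$tcofs)))
  cat(sprintf("  TF-cofactor pairs:%d\n", nrow(x$pairs)))
  invisible(x)
}

#' Compare a compendium against alternative TF sets
#'
#' Partitions the compendium by how many alternative databases also list
#' each TF (present in all, in exactly two, in exactly one, exclusive to the
#' compendium), and builds the reverse list — genes in at least one
#' alternative set but absent from the compendium — joined with the
#' curation rationale explaining their exclusion when available.
#'
#' @param comp Compendium tibble ([compendium()]) or character vector of ids.
#' @param alternative_sets Named list of character vectors.
#' @param candidates Optional classified-candidate tibble used to attach
#'   exclusion rationales to the reverse list.
#' @return List with `membership` (tibble `gene_id`, `n_in`, `bucket`),
#'   `buckets` (count per bucket) and `reverse` (tibble of non-compendium
#'   genes found in alternatives, with `assigned_class`/`rationale_code`
#'   when known).
#' @export
compare_sets <- function(comp, alternative_sets, candidates = NULL) {
  if (length(alternative_sets) < 1L) {
    abort("compare_sets: need at least one alternative set", class = "tfc_value_error")
  }
  ids <- if (is.character(comp)) comp else comp$gene_id
  n_alt <- length(alternative_sets)
  n_in <- unname(vapply(ids, function(g) {
    sum(vapply(alternative_sets, function(s) g %in% s, logical(1)))
  }, integer(1)))
  bucket <- dplyr::case_when(
    n_in == n_alt & n_alt >= 3L ~ "in_all",
    n_in == 2L ~ "in_two",
    n_in == 1L ~ "in_one",
    n_in == 0L ~ "exclusive",
    TRUE ~ "in_all"
  )
  membership <- tibble(gene_id = ids, n_in = n_in, bucket = bucket)
  reverse_ids <- setdiff(sort(unique(unlist(alternative_sets))), ids)
  reverse <- tibble(gene_id = reverse_ids)
  if (!is.null(candidates)) {
    reverse <- left_join(reverse,
                         candidates[c("gene_id", "assigned_class", "rationale_code")],
                         by = "gene_id")
  }
  list(
    membership = membership,
    buckets = membership %>% count(.data$bucket, name = "n"),
    reverse = reverse
  )
}

#' Compare pipeline output against a world's planted truth
#'
#' For every deterministic stage, counts exact agreement between the
#' intended (planted) labels and the labels the pipeline assigned:
#' screened gene set, evidence classes and rationales, compendium
#' membership, conservation groups, cofactor survival and confidence
#' classes, registry accessions, and per-pair coexpression tissue counts.
#'
#' @param world World bundle with `$truth`.
#' @param result A `tf_pipeline` object from [run_pipeline()] on that world.
#' @return Tibble `stage`, `n`, `n_agree`, `pct_agree`.
#' @export
recover_truth <- function(world, result) {
  tr <- world$truth
  row_ <- function(stage, n, n_agree) {
    tibble(stage = stage, n = as.integer(n), n_agree = as.integer(n_agree),
           pct_agree = if (n > 0) pct(n_agree, n, 2) else NA_real_)
  }
  screened_ids <- sort(unique(result$screened$gene_id))
  out <- list()
  out$screen <- row_("screen", length(tr$screened_ids),
                     length(intersect(tr$screened_ids, screened_ids)) -
                       length(setdiff(screened_ids, tr$screened_ids)))
  cand <- result$candidates[order(result$candidates$gene_id), ]
  stopifnot(identical(cand$gene_id, tr$classes$gene_id))
  out$class <- row_("evidence_class", nrow(cand),
                    sum(cand$assigned_class == tr$classes$class))
  out$rationale <- row_("rationale", nrow(cand),
                        sum(cand$rationale_code == tr$classes$rationale))
  comp_ids <- sort(result$compendium$gene_id)
  out$comp <- row_("compendium", length(tr$compendium_ids),
                   length(intersect(comp_ids, tr$compendium_ids)) -
                     length(setdiff(comp_ids, tr$compendium_ids)))
  out$registry <- row_("registry", nrow(tr$registry),
                       length(intersect(result$registry$interpro_id,
                                        tr$registry$interpro_id)) -
                         length(setdiff(result$registry$interpro_id,
                                        tr$registry$interpro_id)))
  g <- left_join(tr$groups, result$groups, by = "gene_id")
  out$groups <- row_("conservation_group", nrow(g),
                     sum(g$group.x == g$group.y, na.rm = TRUE))
  tc_truth <- tr$tcofs[tr$tcofs$stage == "pass", ]
  tc <- left_join(tc_truth, result$tcofs, by = "protein_id")
  out$tcof_set <- row_("tcof_set", nrow(tc_truth),
                       sum(!is.na(tc$confidence_class.y)) -
                         sum(!result$tcofs$protein_id %in% tc_truth$protein_id))
  out$tcof_class <- row_("tcof_confidence", nrow(tc_truth),
                         sum(tc$confidence_class.x == tc$confidence_class.y,
                             na.rm = TRUE))
  px <- left_join(tr$pair_coexpression, result$coexpression,
                  by = c("tf", "tcof"))
  out$coexp <- row_("pair_coexpression", nrow(px),
                    sum(px$n_tissues.x == px$n_tissues.y, na.rm = TRUE))
  bind_rows(out)
}
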