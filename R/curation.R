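#' Screen genes for reliable DNA-binding domains
#'
#' Retains every gene carrying at least one InterPro hit present in the
#' reliable-DBD registry. The result is a subset of the input rows with the
#' input order preserved (all hit rows of a retained gene are kept, including
#' non-registry hits, since the full domain arrangement is needed downstream).
#'
#' @param genes Gene-domain tibble ([read_gene_domains()]).
#' @param registry Reliable-DBD registry ([dbd_registry()]); must be non-empty.
#' @return Gene-domain tibble restricted to genes with at least one registry DBD.
#' @export
screen_for_dbds <- function(genes, registry) {
  if (nrow(registry) == 0L) {
    abort("screen_for_dbds: registry is empty", class = "tfc_value_error")
  }
  keep_ids <- unique(genes$gene_id[!is.na(genes$interpro_id) &
                                     genes$interpro_id %in% registry$interpro_id])
  genes[genes$gene_id %in% keep_ids, ]
}

#' Domain arrangement of a gene
#'
#' The ordered sequence of InterPro accessions along the protein: hits
#' sorted by start coordinate, with consecutive runs of the same accession
#' collapsed to a single token. Tandem repeats of *distinct* domains are
#' preserved (collapse is consecutive-identical, not global de-duplication).
#'
#' @param hits Tibble of domain hits for one gene, with columns
#'   `interpro_id` and `start` (`NA` hit rows, i.e. domain-less genes, give
#'   an empty arrangement).
#' @return Character vector of accession tokens (possibly empty).
#' @export
#' @examples
#' arrangement_of(tibble::tibble(interpro_id = c("IPR000001", "IPR000001"),
#'                               start = c(1L, 55L)))
arrangement_of <- function(hits) {
  hits <- hits[!is.na(hits$interpro_id), , drop = FALSE]
  if (nrow(hits) == 0L) return(character())
  ids <- hits$interpro_id[order(hits$start, hits$interpro_id)]
  ids[c(TRUE, ids[-1] != ids[-length(ids)])]
}

#' Arrangements for every gene in a table
#'
#' @param genes Gene-domain tibble.
#' @return Named list of token vectors, one per gene id.
#' @export
arrangements <- function(genes) {
  split_idx <- split(seq_len(nrow(genes)), genes$gene_id)
  lapply(split_idx, function(i) arrangement_of(genes[i, ]))
}

# Longest common subsequence length of two token vectors (O(nm) DP).
lcs_length <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) return(0L)
  prev <- integer(ny + 1L)
  for (i in seq_len(nx)) {
    cur <- integer(ny + 1L)
    for (j in seq_len(ny)) {
      cur[j + 1L] <- if (x[i] == y[j]) prev[j] + 1L else max(cur[j], prev[j + 1L])
    }
    prev <- cur
  }
  prev[ny + 1L]
}

#' Similarity between two domain arrangements
#'
#' Global alignment of the token sequences scoring match = 1 and
#' mismatch/indel = 0 (equivalently, the longest common subsequence),
#' normalised by the longer sequence length. The score is symmetric, equals
#' 1 exactly when the arrangements are identical, and is 0 when one
#' arrangement is empty and the other is not (two empty arrangements are
#' identical, hence 1).
#'
#' @param x,y Character vectors of arrangement tokens ([arrangement_of()]).
#' @return Similarity in `[0, 1]`.
#' @export
#' @examples
#' arrangement_similarity(c("A", "B", "C"), c("A", "C"))  # 2/3
arrangement_similarity <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx == 0L && ny == 0L) return(1)
  if (nx == 0L || ny == 0L) return(0)
  lcs_length(x, y) / max(nx, ny)
}

#' Assign an evidence class to one screened candidate
#'
#' Applies the manual-curation decision cascade to a DBD-screened gene:
#' \enumerate{
#'   \item pseudogenes are demoted to class `c` (`pseudogene`);
#'   \item a one2one/one2many orthologue that the census marks `x` (known
#'     non-TF) demotes to `c` (`non_tf_function`);
#'   \item an orthologue of census class `c` demotes to `c`
#'     (`orthologue_class_c`);
#'   \item orthologues of class `a`/`b`/`other` are compared by domain
#'     arrangement: the best-similarity orthologue decides — similarity at
#'     or above `threshold` confirms class `a` (orthologue class `a`) or `b`
#'     (orthologue class `b`/`other`), rationale `arrangement_match`; below
#'     threshold demotes to `c` (`arrangement_diverged`); orthologues with
#'     no domain data at all give `c` (`arrangement_unavailable`);
#'   \item candidates without a qualifying orthologue fall back to sequence
#'     similarity hits: a hit to a census `a`/`b` gene with arrangement
#'     similarity at or above threshold rescues to class `b`
#'     (`similarity_rescue`); a hit to a census `x` gene (or a gene on the
#'     manual exclusion list) demotes to `c` (`similar_to_non_tf`); otherwise
#'     the candidate is class `y` (`no_orthologue`);
#'   \item a literature evidence update naming the candidate overrides
#'     everything to class `a` (`literature_evidence`).
#' }
#' Only one2one and one2many relations qualify; many2many relations are
#' ignored.
#'
#' @param gene_id Candidate gene id (must have passed [screen_for_dbds()]).
#' @param genes Gene-domain tibble containing the candidate.
#' @param orthology Orthology relations ([read_orthology()]).
#' @param census Reference census.
#' @param human_genes Gene-domain tibble for the reference (human) genes;
#'   a gene present here with an empty hit list has "no domain data".
#'   An orthology relation targeting a gene absent from both this table and
#'   the census is an error.
#' @param evidence_updates Optional tibble `gene_id`, `new_class`, `citation`
#'   naming *candidate* genes with curated literature evidence.
#' @param hits Optional similarity-hit tibble `query_gene`, `subject_gene`,
#'   `score` for candidates without orthologues.
#' @param threshold Arrangement-similarity threshold in `[0, 1]`
#'   (default 0.8).
#' @param manual_exclusions Optional character vector of reference gene ids
#'   with known non-transcription functions.
#' @return One-row tibble: `gene_id`, `assigned_class`, `rationale_code`,
#'   `orthologue`, `similarity`.
#' @export
assign_class <- function(gene_id, genes, orthology, census, human_genes,
                         evidence_updates = NULL, hits = NULL, threshold = 0.8,
                         manual_exclusions = character()) {
  assign_classes(gene_id, genes, orthology, census, human_genes,
                 evidence_updates = evidence_updates, hits = hits,
                 threshold = threshold, manual_exclusions = manual_exclusions)
}

#' Assign evidence classes to all screened candidates
#'
#' Vectorised driver for [assign_class()]; see there for the cascade.
#'
#' @param candidate_ids Character vector of screened gene ids (defaults to
#'   every gene in `genes`).
#' @inheritParams assign_class
#' @return Tibble with one row per candidate: `gene_id`, `assigned_class`,
#'   `rationale_code`, `orthologue`, `similarity`.
#' @export
assign_classes <- function(candidate_ids, genes, orthology, census, human_genes,
                           evidence_updates = NULL, hits = NULL, threshold = 0.8,
                           manual_exclusions = character()) {
  stopifnot(threshold >= 0, threshold <= 1)
  census <- new_census(census)
  arr_cand <- arrangements(genes[genes$gene_id %in% candidate_ids, ])
  arr_ref <- arrangements(human_genes)
  ref_ids <- unique(human_genes$gene_id)

  orth <- as_tibble(orthology)
  orth <- orth[orth$source_gene %in% candidate_ids &
                 orth$homology_type %in% c("one2one", "one2many"), , drop = FALSE]
  unknown <- setdiff(orth$target_gene, union(ref_ids, census$gene_id))
  if (length(unknown) > 0L) {
    abort(sprintf("assign_classes: orthology references unknown reference gene(s): %s",
                  paste(unique(unknown), collapse = ", ")), class = "tfc_value_error")
  }
  orth$target_class <- classify_lookup(census, orth$target_gene)

  upd_ids <- if (!is.null(evidence_updates)) unique(evidence_updates$gene_id) else character()
  hits <- if (is.null(hits)) {
    tibble(query_gene = character(), subject_gene = character(), score = numeric())
  } else as_tibble(hits)

  biotype <- genes %>% distinct(.data$gene_id, .data$biotype)
  bio_of <- setNames(biotype$biotype, biotype$gene_id)

  one <- function(g) {
    res <- function(class, rationale, orthologue = NA_character_, similarity = NA_real_) {
      tibble(gene_id = g, assigned_class = class, rationale_code = rationale,
             orthologue = orthologue, similarity = similarity)
    }
    decide <- function() {
      # (1) pseudogene
      if (identical(unname(bio_of[[g]]), "pseudogene")) return(res("c", "pseudogene"))
      og <- orth[orth$source_gene == g, , drop = FALSE]
      if (nrow(og) > 0L) {
        # (2) orthologue known not to be a TF
        if (any(og$target_class == "x")) {
          tgt <- og$target_gene[og$target_class == "x"][1]
          return(res("c", "non_tf_function", orthologue = tgt))
        }
        # (3) orthologue of class c
        if (any(og$target_class == "c")) {
          tgt <- og$target_gene[og$target_class == "c"][1]
          return(res("c", "orthologue_class_c", orthologue = tgt))
        }
        qual <- og[og$target_class %in% c("a", "b", "other"), , drop = FALSE]
        if (nrow(qual) > 0L) {
          # (4) arrangement comparison against qualifying orthologues
          ref_arr <- lapply(qual$target_gene, function(t) arr_ref[[t]])
          has_data <- vapply(ref_arr, function(a) !is.null(a) && length(a) > 0L, logical(1))
          if (!any(has_data)) {
            return(res("c", "arrangement_unavailable", orthologue = qual$target_gene[1]))
          }
          qual <- qual[has_data, , drop = FALSE]
          sims <- vapply(seq_len(nrow(qual)), function(i) {
            arrangement_similarity(arr_cand[[g]], arr_ref[[qual$target_gene[i]]])
          }, numeric(1))
          ord <- order(-sims, match(qual$target_class, c("a", "b", "other")),
                       qual$target_gene)
          best <- ord[1]
          if (sims[best] >= threshold) {
            cls <- if (qual$target_class[best] == "a") "a" else "b"
            return(res(cls, "arrangement_match", qual$target_gene[best], sims[best]))
          }
          return(res("c", "arrangement_diverged", qual$target_gene[best], sims[best]))
        }
      }
      # (5) no qualifying orthologue: similarity-hit fallback
      hg <- hits[hits$query_gene == g, , drop = FALSE]
      if (nrow(hg) > 0L) {
        hg <- hg[order(-hg$score, hg$subject_gene), , drop = FALSE]
        hg$subject_class <- classify_lookup(census, hg$subject_gene)
        for (i in seq_len(nrow(hg))) {
          if (hg$subject_class[i] %in% c("a", "b")) {
            sim <- arrangement_similarity(arr_cand[[g]],
                                          arr_ref[[hg$subject_gene[i]]] %||% character())
            if (sim >= threshold) {
              return(res("b", "similarity_rescue", hg$subject_gene[i], sim))
            }
          }
        }
        non_tf <- hg$subject_class == "x" | hg$subject_gene %in% manual_exclusions
        if (any(non_tf)) {
          return(res("c", "similar_to_non_tf", hg$subject_gene[non_tf][1]))
        }
      }
      res("y", "no_orthologue")
    }
    out <- decide()
    # (6) curated literature evidence wins
    if (g %in% upd_ids) {
      out$assigned_class <- "a"
      out$rationale_code <- "literature_evidence"
    }
    out
  }
  bind_rows(lapply(candidate_ids, one))
}

#' Final TF compendium from classified candidates
#'
#' The compendium is the high-confidence subset: candidates assigned class
#' `a` or `b`. The per-class / per-rationale partition of *all* candidates
#' is attached as attribute `partition` (see [partition_report()]).
#'
#' @param candidates Classified candidates ([assign_classes()]).
#' @return Tibble of class-`a`/`b` candidates with a `partition` attribute.
#' @export
compendium <- function(candidates) {
  out <- candidates[candidates$assigned_class %in% c("a", "b"), , drop = FALSE]
  attr(out, "partition") <- partition_report(candidates)
  out
}

#' Partition report over classified candidates
#'
#' Counts candidates by assigned class and rationale, plus the stage totals
#' the curation narrative uses: genes screened, genes surviving the removal
#' of pseudogenes / non-TF orthologues / c-class orthologues
#' (`n_post_removal`), genes whose domain arrangement was actually compared
#' (`n_arrangement_eligible`), and the final compendium size.
#'
#' @param candidates Classified candidates.
#' @return List with `by_class`, `by_rationale` tibbles and scalar totals.
#' @export
partition_report <- function(candidates) {
  removal <- c("pseudogene", "non_tf_function", "orthologue_class_c")
  arrange_stage <- c("arrangement_match", "arrangement_diverged", "arrangement_unavailable")
  list(
    by_class = candidates %>% count(.data$assigned_class, name = "n"),
    by_rationale = candidates %>% count(.data$assigned_class, .data$rationale_code, name = "n"),
    n_screened = nrow(candidates),
    n_post_removal = sum(!candidates$rationale_code %in% removal),
    n_arrangement_eligible = sum(candidates$rationale_code %in% arrange_stage),
    n_compendium = sum(candidates$assigned_class %in% c("a", "b"))
  )
}
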