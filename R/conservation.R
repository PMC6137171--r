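#' Build a TF-by-species orthologue presence matrix
#'
#' Cell `(t, s)` is `TRUE` when at least one orthology relation links TF `t`
#' to any gene of species `s`. Relations targeting species outside
#' `species_list` are ignored with a warning. If the focal species is in
#' `species_list` its column is all-`TRUE` (a gene is trivially present in
#' its own genome).
#'
#' @param tf_ids Character vector of TF gene ids (matrix rows).
#' @param orthology Orthology relations with `source_gene`, `target_species`.
#' @param species_list Character vector of species labels (matrix columns).
#' @param focal Focal species label, or `NA` if not among the columns.
#' @return Tibble with `gene_id` plus one logical column per species.
#' @export
build_presence <- function(tf_ids, orthology, species_list, focal = NA_character_) {
  if (length(species_list) == 0L) {
    abort("build_presence: species_list is empty", class = "tfc_value_error")
  }
  orthology <- as_tibble(orthology)
  outside <- setdiff(unique(orthology$target_species), c(species_list, focal))
  if (length(outside) > 0L) {
    warn(sprintf("build_presence: ignoring relations to species outside the list: %s",
                 paste(outside, collapse = ", ")))
  }
  m <- matrix(FALSE, nrow = length(tf_ids), ncol = length(species_list),
              dimnames = list(tf_ids, species_list))
  rel <- orthology[orthology$source_gene %in% tf_ids &
                     orthology$target_species %in% species_list, , drop = FALSE]
  if (nrow(rel) > 0L) {
    m[cbind(match(rel$source_gene, tf_ids), match(rel$target_species, species_list))] <- TRUE
  }
  if (!is.na(focal) && focal %in% species_list) m[, focal] <- TRUE
  out <- dplyr::bind_cols(tibble(gene_id = tf_ids), as_tibble(m))
  class(out) <- c("presence_matrix", class(out))
  out
}

presence_to_matrix <- function(presence) {
  m <- as.matrix(presence[setdiff(names(presence), "gene_id")])
  storage.mode(m) <- "logical"
  rownames(m) <- presence$gene_id
  m
}

#' Hierarchically cluster a presence/absence matrix
#'
#' Rows (TFs) and columns (species) are clustered by agglomerative
#' average-linkage clustering on Jaccard distances between the binary
#' vectors. Rows are pre-sorted lexicographically by id so the result is
#' invariant to the input row order; a pair of identical binary vectors has
#' distance 0 and ends up in adjacent leaves. A constant matrix (all-true
#' or all-false) cannot be clustered and is returned in input order with a
#' warning.
#'
#' @param presence Presence tibble from [build_presence()] (at least 2 rows).
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return Object of class `presence_clustering`: list with `row_order` and
#'   `col_order` (label vectors), `row_hclust`, `col_hclust` (possibly
#'   `NULL` for the degenerate case), `distance` and `linkage`.
#' @export
cluster_presence <- function(presence, linkage = "average") {
  m <- presence_to_matrix(presence)
  if (nrow(m) < 2L) {
    abort("cluster_presence: need at least 2 rows", class = "tfc_value_error")
  }
  m <- m[order(rownames(m)), , drop = FALSE]
  if (all(m) || all(!m)) {
    warn("cluster_presence: constant matrix; returning input order")
    return(structure(list(row_order = presence$gene_id,
                          col_order = colnames(m),
                          row_hclust = NULL, col_hclust = NULL,
                          distance = "jaccard", linkage = linkage),
                     class = "presence_clustering"))
  }
  cl <- function(mat) {
    d <- jaccard_dist(mat)
    hclust(d, method = linkage)
  }
  rh <- cl(m)
  ch <- cl(t(m))
  structure(list(row_order = rh$labels[rh$order],
                 col_order = ch$labels[ch$order],
                 row_hclust = rh, col_hclust = ch,
                 distance = "jaccard", linkage = linkage),
            class = "presence_clustering")
}

# Jaccard distance on the rows of a logical matrix. Identical rows get
# distance 0, including all-false pairs (where the Jaccard ratio is 0/0).
jaccard_dist <- function(m) {
  mi <- matrix(as.integer(m), nrow = nrow(m), dimnames = dimnames(m))
  inter <- tcrossprod(mi)
  sums <- rowSums(mi)
  un <- outer(sums, sums, "+") - inter
  d <- ifelse(un == 0, 0, 1 - inter / un)
  stats::as.dist(d)
}

#' Export clustering dendrograms as newick strings
#'
#' @param clustering A `presence_clustering` object.
#' @return Named character vector with `rows` and `cols` newick trees
#'   (`NA` where the degenerate no-clustering case applies).
#' @export
clustering_newick <- function(clustering) {
  nw <- function(h) {
    if (is.null(h)) return(NA_character_)
    ape::write.tree(ape::as.phylo(h))
  }
  c(rows = nw(clustering$row_hclust), cols = nw(clustering$col_hclust))
}

#' Assign conservation groups from presence profiles
#'
#' For each TF, let the "present" set be the non-focal species where an
#' orthologue exists. The group is the smallest clade (Mammalia ⊂
#' Vertebrata ⊂ Metazoa ⊂ Eukaryota) containing at least a fraction `tau`
#' of the present species: `mammal_only` when that clade is Mammalia and it
#' contains *all* present species, `mammal_predominant` when it contains a
#' fraction in `[tau, 1)`, then `vertebrate`, `metazoa` and finally
#' `eukaryote` when no smaller clade qualifies. A TF with no orthologue
#' outside the focal species is `mammal_only` (it is exclusive to the focal
#' mammal). The focal species never enters the denominators, since its
#' presence is trivial.
#'
#' @param presence Presence tibble ([build_presence()]).
#' @param clade_map Tibble `species`, `clade` assigning each species its
#'   innermost clade (`Mammalia`, `Vertebrata`, `Metazoa`, `Eukaryota`);
#'   the chains are nested, so a Mammalia species is also counted inside
#'   Vertebrata and Metazoa.
#' @param tau Predominance threshold in `(0, 1]` (default 0.9).
#' @param focal Focal species column to exclude, if present.
#' @return Tibble `gene_id`, `group`, `n_present`, `tau`.
#' @export
assign_group <- function(presence, clade_map, tau = 0.9, focal = NA_character_) {
  stopifnot(tau > 0, tau <= 1)
  clade_levels <- c("Mammalia", "Vertebrata", "Metazoa", "Eukaryota")
  clade_map <- as_tibble(clade_map)
  check_columns(clade_map, c("species", "clade"), "clade map")
  species <- setdiff(names(presence), "gene_id")
  if (!is.na(focal)) species <- setdiff(species, focal)
  missing <- setdiff(species, clade_map$species)
  if (length(missing) > 0L) {
    abort(sprintf("assign_group: species missing from clade map: %s",
                  paste(missing, collapse = ", ")), class = "tfc_value_error")
  }
  innermost <- setNames(clade_map$clade, clade_map$species)[species]
  rank <- match(innermost, clade_levels)  # species in clade k iff rank <= k
  m <- presence_to_matrix(presence)[, species, drop = FALSE]
  grp <- character(nrow(m))
  npres <- integer(nrow(m))
  for (i in seq_len(nrow(m))) {
    pres_rank <- rank[m[i, ]]
    n <- length(pres_rank)
    npres[i] <- n
    if (n == 0L) {
      grp[i] <- "mammal_only"
      next
    }
    assigned <- "eukaryote"
    for (k in seq_along(clade_levels)) {
      frac <- sum(pres_rank <= k) / n
      if (frac >= tau) {
        assigned <- switch(clade_levels[k],
          Mammalia = if (frac == 1) "mammal_only" else "mammal_predominant",
          Vertebrata = "vertebrate",
          Metazoa = "metazoa",
          Eukaryota = "eukaryote")
        break
      }
    }
    grp[i] <- assigned
  }
  tibble(gene_id = presence$gene_id, group = grp, n_present = npres, tau = tau)
}

#' Special conservation tallies
#'
#' Brute-force-checkable counts over the presence matrix: TFs present in
#' every species, TFs present in exactly two species (counting the focal
#' column when present), and TFs absent from both human and mouse.
#'
#' @param presence Presence tibble.
#' @param human,mouse Column labels for human and mouse.
#' @return One-row tibble `n_all_species`, `n_exactly_two`,
#'   `n_absent_human_mouse`.
#' @export
conservation_tallies <- function(presence, human = "Homo sapiens",
                                 mouse = "Mus musculus") {
  m <- presence_to_matrix(presence)
  hm <- intersect(c(human, mouse), colnames(m))
  tibble(
    n_all_species = sum(rowSums(m) == ncol(m)),
    n_exactly_two = sum(rowSums(m) == 2L),
    n_absent_human_mouse = if (length(hm) > 0L) {
      sum(rowSums(m[, hm, drop = FALSE]) == 0L)
    } else NA_integer_
  )
}
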