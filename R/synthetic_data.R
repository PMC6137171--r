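# Seeded synthetic annotation worlds with planted ground truth.
#
# Truth-first generation: intended labels (candidate evidence classes,
# cofactor confidence classes, conservation groups, expression patterns) are
# sampled first, and the emitted annotation tables are synthesised to be
# consistent with them, so a correct pipeline recovers every label exactly.

SPECIES_CLADES <- tibble::tribble(
  ~species, ~clade,
  "Bos taurus", "Mammalia",
  "Homo sapiens", "Mammalia",
  "Mus musculus", "Mammalia",
  "Rattus norvegicus", "Mammalia",
  "Canis lupus familiaris", "Mammalia",
  "Sus scrofa", "Mammalia",
  "Ovis aries", "Mammalia",
  "Equus caballus", "Mammalia",
  "Macaca mulatta", "Mammalia",
  "Felis catus", "Mammalia",
  "Gallus gallus", "Vertebrata",
  "Danio rerio", "Vertebrata",
  "Xenopus tropicalis", "Vertebrata",
  "Anolis carolinensis", "Vertebrata",
  "Oryzias latipes", "Vertebrata",
  "Drosophila melanogaster", "Metazoa",
  "Caenorhabditis elegans", "Metazoa",
  "Ciona intestinalis", "Metazoa",
  "Saccharomyces cerevisiae", "Eukaryota",
  "Schizosaccharomyces pombe", "Eukaryota",
  "Arabidopsis thaliana", "Eukaryota"
)

TISSUES <- c("ampulla", "white_blood_cells", "cerebral_cortex", "car_con",
             "car_ips", "gallbladder", "heart", "jejunum", "kidney", "liver",
             "lymph_nodes", "pons", "muscle", "spleen")

FAMILY_NAMES <- c("C2H2 zinc-finger", "Homeodomain", "bZIP", "HLH", "Forkhead",
                  "Nuclear hormone receptor", "HMG", "ETS", "POU", "other")

# Run code under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

resample <- function(x, n, replace = FALSE) x[sample.int(length(x), n, replace = replace)]

#' Configuration of a synthetic annotation world
#'
#' Two presets are provided. `"tiny"` (about 200 genes, 40 screened
#' candidates, 24 compendium TFs, 15 cofactors) keeps unit tests fast;
#' `"paper_scale"` approximates the magnitudes of a full mammalian curation
#' run (about 24,600 genes, 1,525 screened, 865 compendium TFs, 781
#' cofactors, 14 tissues) for smoke tests. Any field can be overridden.
#'
#' @param seed Integer seed; the whole world is a deterministic function of
#'   the configuration.
#' @param preset `"tiny"` or `"paper_scale"`.
#' @param ... Named overrides of preset fields (see the source for the full
#'   list: `n_genes`, `class_counts`, `group_counts`, `tcof_class_counts`,
#'   `go_attrition`, `expression_profile`, `mi_type_mix`,
#'   `arrangement_divergence_rate`, `n_tissues`, ...).
#' @return A validated `world_config` list.
#' @export
world_config <- function(seed = 1L, preset = c("tiny", "paper_scale"), ...) {
  preset <- match.arg(preset)
  base <- if (preset == "tiny") {
    list(
      n_genes = 200L,
      n_census = 120L,
      census_class_mix = c(a = 40L, b = 30L, c = 15L, x = 20L, other = 15L),
      n_census_b_updates = 6L, n_census_c_updates = 2L,
      n_reference_dbd_domain = 2L, n_reference_dbd_family = 4L,
      n_novel_human_genes = 5L, n_novel_mouse_genes = 8L,
      class_counts = c(a = 12L, a_literature = 2L, b = 8L, b_rescue = 2L,
                       c_pseudogene = 2L, c_non_tf = 2L, c_orth_c = 2L,
                       c_diverged = 3L, c_unavailable = 2L,
                       c_similar_non_tf = 1L, y = 4L),
      group_counts = c(mammal_only = 4L, mammal_predominant = 4L,
                       vertebrate = 5L, metazoa = 7L, eukaryote = 4L),
      n_all_species = 2L, n_exactly_two = 1L,
      tcof_class_counts = c(high_confidence = 5L, hypothetical_I = 3L,
                            hypothetical_II = 4L, hypothetical_III = 3L),
      go_attrition = c(fail_cc = 3L, fail_bp = 2L, fail_mf = 2L),
      n_decoy_interactions = c(tf_tf = 3L, bad_mi = 5L, non_tf = 2L),
      expression_profile = list(
        tf = c(ubiquitous = 5L, single = 3L, intermediate = 11L, unexpressed = 5L),
        tcof = c(ubiquitous = 4L, single = 1L, intermediate = 7L, unexpressed = 3L)
      ),
      alt_overlap = c(in_all = 15L, in_two = 5L, in_one = 2L, exclusive = 2L),
      n_alt_extra = 4L
    )
  } else {
    list(
      n_genes = 24616L,
      n_census = 1651L,
      census_class_mix = c(a = 550L, b = 520L, c = 160L, x = 221L, other = 200L),
      n_census_b_updates = 86L, n_census_c_updates = 8L,
      n_reference_dbd_domain = 70L, n_reference_dbd_family = 57L,
      n_novel_human_genes = 26L, n_novel_mouse_genes = 1162L,
      class_counts = c(a = 516L, a_literature = 4L, b = 340L, b_rescue = 5L,
                       c_pseudogene = 70L, c_non_tf = 80L, c_orth_c = 69L,
                       c_diverged = 62L, c_unavailable = 95L,
                       c_similar_non_tf = 260L, y = 24L),
      group_counts = c(mammal_only = 59L, mammal_predominant = 55L,
                       vertebrate = 202L, metazoa = 467L, eukaryote = 82L),
      n_all_species = 15L, n_exactly_two = 4L,
      tcof_class_counts = c(high_confidence = 248L, hypothetical_I = 52L,
                            hypothetical_II = 214L, hypothetical_III = 267L),
      go_attrition = c(fail_cc = 252L, fail_bp = 60L, fail_mf = 45L),
      n_decoy_interactions = c(tf_tf = 60L, bad_mi = 150L, non_tf = 40L),
      expression_profile = list(
        tf = c(ubiquitous = 156L, single = 60L, intermediate = 464L, unexpressed = 185L),
        tcof = c(ubiquitous = 248L, single = 16L, intermediate = 345L, unexpressed = 172L)
      ),
      alt_overlap = c(in_all = 720L, in_two = 92L, in_one = 36L, exclusive = 17L),
      n_alt_extra = 120L
    )
  }
  common <- list(
    seed = as.integer(seed), preset = preset,
    species = SPECIES_CLADES$species, clade_map = SPECIES_CLADES,
    focal_species = "Bos taurus",
    n_tissues = length(TISSUES), tissues = TISSUES,
    mi_type_mix = c("MI:0915" = 0.90, "MI:0407" = 0.08, "MI:0195" = 0.02),
    arrangement_divergence_rate = NA_real_,
    similarity_threshold = 0.8, tau = 0.9
  )
  cfg <- utils::modifyList(c(base, common), list(...))
  validate_world_config(cfg)
}

validate_world_config <- function(cfg) {
  if (sum(cfg$class_counts) > cfg$n_genes) {
    abort("world_config: planted candidate count exceeds n_genes",
          class = "tfc_config_error")
  }
  n_comp <- sum(cfg$class_counts[c("a", "a_literature", "b", "b_rescue")])
  n_no_orth <- sum(cfg$class_counts[c("a_literature", "b_rescue")])
  if (sum(cfg$group_counts) != n_comp) {
    abort("world_config: group_counts must sum to the planted compendium size",
          class = "tfc_config_error")
  }
  if (cfg$group_counts[["mammal_only"]] < n_no_orth) {
    abort("world_config: mammal_only group must hold all no-orthologue TFs",
          class = "tfc_config_error")
  }
  if (sum(cfg$alt_overlap) != n_comp) {
    abort("world_config: alt_overlap must sum to the planted compendium size",
          class = "tfc_config_error")
  }
  for (k in c("tf", "tcof")) {
    p <- cfg$expression_profile[[k]]
    tot <- if (k == "tf") n_comp else sum(cfg$tcof_class_counts)
    if (sum(p) != tot) {
      abort(sprintf("world_config: expression_profile$%s must sum to %d", k, tot),
            class = "tfc_config_error")
    }
  }
  if (sum(cfg$census_class_mix) != cfg$n_census) {
    abort("world_config: census_class_mix must sum to n_census",
          class = "tfc_config_error")
  }
  if (abs(sum(cfg$mi_type_mix) - 1) > 1e-8) {
    abort("world_config: mi_type_mix must sum to 1", class = "tfc_config_error")
  }
  if (!is.na(cfg$arrangement_divergence_rate) &&
      (cfg$arrangement_divergence_rate < 0 || cfg$arrangement_divergence_rate > 1)) {
    abort("world_config: arrangement_divergence_rate must be in [0, 1]",
          class = "tfc_config_error")
  }
  structure(cfg, class = "world_config")
}

ipr_ids <- function(from, n) sprintf("IPR%06d", seq(from, length.out = n))

#' Generate a synthetic annotation world
#'
#' Emits every input table the pipeline consumes — gene/domain annotations,
#' reference census plus literature updates, TF-database snapshots and
#' curated domain functions, orthology (reference-species relations for
#' curation and a cross-species panel for conservation), similarity hits,
#' molecular-interaction records, GO annotations, an isoform FPKM matrix,
#' and alternative TF sets — together with the planted ground truth.
#' Identical configurations produce identical worlds.
#'
#' @param config A [world_config()].
#' @return List with elements `data` (named list of tibbles), `truth`
#'   (planted labels and tallies) and `config`.
#' @export
generate_world <- function(config) {
  if (!inherits(config, "world_config")) config <- validate_world_config(config)
  local_seed(config$seed, build_world(config))
}

build_world <- function(cfg) {
  ## ---- reliable DBDs and families -------------------------------------
  n_ref_dom <- cfg$n_reference_dbd_domain
  n_ref_fam <- cfg$n_reference_dbd_family
  novel_human_dbd <- "IPR013087"
  novel_mouse_dbd <- c("IPR001523", "IPR008122", "IPR008123", "IPR017114", "IPR007087")
  ref_dbds <- tibble(
    interpro_id = ipr_ids(100001, n_ref_dom + n_ref_fam),
    entry_type = rep(c("domain", "family"), c(n_ref_dom, n_ref_fam)),
    provenance = "reference census",
    sequence_specific = TRUE
  )
  registry_true <- dbd_registry(
    ref_dbds,
    tibble(interpro_id = novel_human_dbd, entry_type = "domain",
           provenance = "human intersection", sequence_specific = TRUE),
    tibble(interpro_id = novel_mouse_dbd, entry_type = "domain",
           provenance = "mouse intersection", sequence_specific = TRUE)
  )
  all_dbds <- registry_true$interpro_id
  noise_doms <- ipr_ids(200001, 12)          # never reliable
  blacklist_dom <- "IPR300001"               # occurs on a census-x gene
  nonspecific_dom <- "IPR300002"             # curated as not sequence-specific
  family_map <- tibble(
    interpro_id = all_dbds,
    family = FAMILY_NAMES[(seq_along(all_dbds) - 1L) %% length(FAMILY_NAMES) + 1L]
  )
  domain_functions <- bind_rows(
    tibble(interpro_id = all_dbds, sequence_specific = TRUE),
    tibble(interpro_id = c(blacklist_dom, nonspecific_dom), sequence_specific = FALSE)
  )
  type_of <- function(doms) {
    tp <- registry_true$entry_type[match(doms, registry_true$interpro_id)]
    tp[is.na(tp)] <- "domain"
    tp
  }

  ## ---- reference census and literature updates ------------------------
  census_ids <- sprintf("HSG%05d", seq_len(cfg$n_census))
  census_classes <- sample(rep(names(cfg$census_class_mix), cfg$census_class_mix))
  census <- new_census(tibble(gene_id = census_ids, evidence_class = census_classes,
                              note = ""))
  census_updates <- tibble(
    gene_id = c(resample(census_ids[census_classes == "b"], cfg$n_census_b_updates),
                resample(census_ids[census_classes == "c"], cfg$n_census_c_updates)),
    new_class = "a",
    citation = "literature review"
  )
  census_after <- apply_updates(census, census_updates)

  ## ---- TF-database snapshots ------------------------------------------
  snap_names <- c("DBDdb", "AnimalTFDB", "CisBP")
  make_round <- function(novel_prefix, n_novel, novel_dbds, species) {
    novel_genes <- sprintf("%s%04d", novel_prefix, seq_len(n_novel))
    # every novel gene carries the round's novel DBDs plus noise the curated
    # function table or the blacklist later removes
    novel_rows <- tidyr::crossing(gene_id = novel_genes,
                                  interpro_id = c(novel_dbds, blacklist_dom,
                                                  nonspecific_dom)) %>%
      mutate(entry_type = "domain")
    known <- census_ids[census_classes %in% c("a", "b")]
    x_genes <- census_ids[census_classes == "x"]
    snaps <- lapply(seq_along(snap_names), function(i) {
      n_known <- min(20L, length(known))
      known_rows <- tibble(
        gene_id = resample(known, n_known),
        interpro_id = resample(ref_dbds$interpro_id, n_known, replace = TRUE)
      ) %>% mutate(entry_type = type_of(.data$interpro_id))
      x_rows <- tibble(gene_id = resample(x_genes, min(5L, length(x_genes))),
                       interpro_id = blacklist_dom, entry_type = "domain")
      private <- tibble(gene_id = sprintf("%sPRIV%d_%04d", novel_prefix, i, 1:3),
                        interpro_id = NA_character_, entry_type = NA_character_)
      tf_db_snapshot(snap_names[i], species,
                     bind_rows(novel_rows, known_rows, x_rows, private))
    })
    list(snapshots = snaps, novel_genes = novel_genes)
  }
  human_round <- make_round("HTF", cfg$n_novel_human_genes, novel_human_dbd, "human")
  mouse_round <- make_round("MTF", cfg$n_novel_mouse_genes, novel_mouse_dbd, "mouse")

  ## ---- candidate genes and intended classes ---------------------------
  class_counts <- cfg$class_counts
  if (!is.na(cfg$arrangement_divergence_rate)) {
    # divergence converts orthologue-confirmed candidates into diverged ones
    for (cl_ in c("a", "b")) {
      n_move <- stats::rbinom(1L, class_counts[[cl_]], cfg$arrangement_divergence_rate)
      class_counts[[cl_]] <- class_counts[[cl_]] - n_move
      class_counts[["c_diverged"]] <- class_counts[["c_diverged"]] + n_move
    }
  }
  n_cand <- sum(class_counts)
  gene_ids <- sprintf("BTG%05d", seq_len(cfg$n_genes))
  cand_ids <- resample(gene_ids, n_cand)
  intended <- tibble(
    gene_id = sample(cand_ids),
    plant = rep(names(class_counts), class_counts)
  )
  plant_class <- c(a = "a", a_literature = "a", b = "b", b_rescue = "b",
                   c_pseudogene = "c", c_non_tf = "c", c_orth_c = "c",
                   c_diverged = "c", c_unavailable = "c", c_similar_non_tf = "c",
                   y = "y")
  plant_rationale <- c(a = "arrangement_match", a_literature = "literature_evidence",
                       b = "arrangement_match", b_rescue = "similarity_rescue",
                       c_pseudogene = "pseudogene", c_non_tf = "non_tf_function",
                       c_orth_c = "orthologue_class_c",
                       c_diverged = "arrangement_diverged",
                       c_unavailable = "arrangement_unavailable",
                       c_similar_non_tf = "similar_to_non_tf", y = "no_orthologue")
  intended$class <- unname(plant_class[intended$plant])
  intended$rationale <- unname(plant_rationale[intended$plant])

  # domain content: 1-3 reliable DBDs each; noise domains only on candidates
  # whose arrangement the cascade never compares
  cand_arr <- lapply(seq_len(n_cand), function(i) {
    doms <- resample(all_dbds, resample(1:3, 1L), replace = TRUE)
    doms[c(TRUE, doms[-1] != doms[-length(doms)])]
  })
  names(cand_arr) <- intended$gene_id
  gene_rows <- function(id, doms, biotype) {
    if (length(doms) == 0L) {
      return(tibble(gene_id = id, biotype = biotype, interpro_id = NA_character_,
                    entry_type = NA_character_, start = NA_integer_, end = NA_integer_))
    }
    starts <- cumsum(resample(40:80, length(doms), replace = TRUE))
    tibble(gene_id = id, biotype = biotype, interpro_id = doms,
           entry_type = type_of(doms),
           start = as.integer(starts),
           end = as.integer(starts + resample(30:60, length(doms), replace = TRUE)))
  }
  noise_ok <- c("c_pseudogene", "c_non_tf", "c_orth_c", "c_similar_non_tf", "y")
  cand_bio <- ifelse(intended$plant == "c_pseudogene", "pseudogene", "protein_coding")
  cand_tbl <- bind_rows(lapply(seq_len(n_cand), function(i) {
    rows <- gene_rows(intended$gene_id[i], cand_arr[[i]], cand_bio[i])
    if (intended$plant[i] %in% noise_ok && stats::runif(1) < 0.4) {
      s <- max(rows$end) + 20L
      rows <- bind_rows(rows, tibble(
        gene_id = intended$gene_id[i], biotype = cand_bio[i],
        interpro_id = resample(noise_doms, 1L), entry_type = "domain",
        start = s, end = s + 40L))
    }
    rows
  }))

  # background genes never carry reliable DBDs
  bg_ids <- setdiff(gene_ids, intended$gene_id)
  bg_bio <- sample(c("protein_coding", "pseudogene", "other"),
                   length(bg_ids), replace = TRUE, prob = c(0.8, 0.15, 0.05))
  bg_k <- sample(0:2, length(bg_ids), replace = TRUE)
  bg_row_idx <- rep(seq_along(bg_ids), bg_k)
  bg_starts <- sample(40:400, length(bg_row_idx), replace = TRUE)
  bg_tbl <- bind_rows(
    tibble(gene_id = bg_ids[bg_row_idx], biotype = bg_bio[bg_row_idx],
           interpro_id = resample(noise_doms, length(bg_row_idx), replace = TRUE),
           entry_type = "domain", start = as.integer(bg_starts),
           end = as.integer(bg_starts + 40L)),
    tibble(gene_id = bg_ids[bg_k == 0L], biotype = bg_bio[bg_k == 0L],
           interpro_id = NA_character_, entry_type = NA_character_,
           start = NA_integer_, end = NA_integer_)
  )
  genes <- bind_rows(cand_tbl, bg_tbl) %>%
    arrange(.data$gene_id, .data$start, .data$interpro_id)

  ## ---- curation support tables ----------------------------------------
  # arrangement-sensitive plants get a dedicated (never reused) census target
  used_targets <- character()
  pick_census <- function(classes, exclusive = FALSE) {
    pool <- census_after$gene_id[census_after$evidence_class %in% classes]
    if (exclusive) {
      pool <- setdiff(pool, used_targets)
      tgt <- resample(pool, 1L)
      used_targets <<- c(used_targets, tgt)
    } else {
      tgt <- resample(pool, 1L)
    }
    tgt
  }
  orth_rows <- list(); human_gene_rows <- list(); hit_rows <- list()
  cand_update_rows <- list()
  hsap <- "Homo sapiens"
  for (i in seq_len(n_cand)) {
    g <- intended$gene_id[i]; p <- intended$plant[i]; arr <- cand_arr[[g]]
    htype <- resample(c("one2one", "one2many"), 1L)
    add_orth <- function(tgt) {
      orth_rows[[length(orth_rows) + 1L]] <<- tibble(
        source_gene = g, target_gene = tgt, homology_type = htype,
        target_species = hsap)
    }
    add_human <- function(tgt, doms) {
      human_gene_rows[[length(human_gene_rows) + 1L]] <<-
        gene_rows(tgt, doms, "protein_coding")
    }
    if (p %in% c("a", "b", "c_pseudogene")) {
      tgt <- pick_census(if (p == "a") "a" else c("b", "other"), exclusive = TRUE)
      add_orth(tgt); add_human(tgt, arr)
    } else if (p == "c_non_tf") {
      tgt <- pick_census("x"); add_orth(tgt)
    } else if (p == "c_orth_c") {
      tgt <- pick_census("c"); add_orth(tgt)
    } else if (p == "c_diverged") {
      tgt <- pick_census(c("a", "b"), exclusive = TRUE); add_orth(tgt)
      other <- setdiff(all_dbds, arr)
      add_human(tgt, resample(other, min(2L, length(other))))
    } else if (p == "c_unavailable") {
      tgt <- pick_census(c("a", "b"), exclusive = TRUE); add_orth(tgt)
      add_human(tgt, character())
    } else if (p == "b_rescue") {
      tgt <- pick_census(c("a", "b"), exclusive = TRUE)
      hit_rows[[length(hit_rows) + 1L]] <- tibble(
        query_gene = g, subject_gene = tgt, score = round(stats::runif(1, 100, 500), 1))
      add_human(tgt, arr)
    } else if (p == "c_similar_non_tf") {
      tgt <- pick_census("x")
      hit_rows[[length(hit_rows) + 1L]] <- tibble(
        query_gene = g, subject_gene = tgt, score = round(stats::runif(1, 100, 500), 1))
    } else if (p == "a_literature") {
      cand_update_rows[[length(cand_update_rows) + 1L]] <- tibble(
        gene_id = g, new_class = "a", citation = "curated literature evidence")
    }
    # p == "y": no orthologue, no hits, nothing at all
  }
  orthology <- bind_rows(orth_rows)
  human_genes <- bind_rows(human_gene_rows) %>%
    distinct() %>%
    arrange(.data$gene_id, .data$start)
  candidate_updates <- if (length(cand_update_rows) > 0L) bind_rows(cand_update_rows) else
    tibble(gene_id = character(), new_class = character(), citation = character())
  hits <- if (length(hit_rows) > 0L) bind_rows(hit_rows) else
    tibble(query_gene = character(), subject_gene = character(), score = numeric())

  ## ---- conservation ----------------------------------------------------
  comp_ids <- intended$gene_id[intended$class %in% c("a", "b")]
  no_orth_comp <- intended$gene_id[intended$plant %in% c("a_literature", "b_rescue")]
  with_orth_comp <- setdiff(comp_ids, no_orth_comp)
  cl <- SPECIES_CLADES[SPECIES_CLADES$species != cfg$focal_species, ]
  mams <- cl$species[cl$clade == "Mammalia"]
  verts <- cl$species[cl$clade == "Vertebrata"]
  metas <- cl$species[cl$clade == "Metazoa"]
  mouse <- "Mus musculus"
  remaining <- cfg$group_counts
  remaining[["mammal_only"]] <- remaining[["mammal_only"]] - length(no_orth_comp)
  # no-orthologue compendium TFs are cattle-restricted: mammal_only, no
  # presence in human or mouse. Labels are truncated when a divergence rate
  # shrank the compendium below the configured group totals.
  grp_labels <- c(rep("mammal_only", length(no_orth_comp)),
                  rep(names(remaining), remaining))
  groups <- tibble(
    gene_id = c(no_orth_comp, sample(with_orth_comp)),
    group = grp_labels[seq_len(length(comp_ids))]
  )
  n_all <- cfg$n_all_species; n_two <- cfg$n_exactly_two
  present_set <- function(group, has_human, idx_in_group) {
    if (group == "mammal_only") {
      if (!has_human) {
        pool <- setdiff(mams, c(hsap, mouse))
        k <- if (idx_in_group <= n_two) 1L else resample(2:4, 1L)
        resample(pool, k)
      } else {
        c(hsap, resample(setdiff(mams, hsap), resample(1:6, 1L)))
      }
    } else if (group == "mammal_predominant") {
      c(mams, resample(verts, 1L))                       # 9 of 10 present are mammals
    } else if (group == "vertebrate") {
      c(hsap, resample(setdiff(mams, hsap), resample(4:8, 1L)), verts)
    } else if (group == "metazoa") {
      c(hsap, resample(setdiff(mams, hsap), resample(4:8, 1L)),
        resample(verts, resample(3:5, 1L)), metas)
    } else {                                             # eukaryote
      if (idx_in_group <= n_all) {
        cl$species
      } else {
        drop <- resample(setdiff(c(mams, verts, metas), hsap), resample(1:4, 1L))
        setdiff(cl$species, drop)
      }
    }
  }
  idx_by_group <- stats::ave(seq_len(nrow(groups)), groups$group, FUN = seq_along)
  species_orth <- list()
  for (i in seq_len(nrow(groups))) {
    g <- groups$gene_id[i]
    pres <- present_set(groups$group[i], g %in% with_orth_comp, idx_by_group[i])
    if (length(pres) == 0L) next
    species_orth[[length(species_orth) + 1L]] <- tibble(
      source_gene = g,
      target_gene = paste0(gsub("[^A-Za-z]", "", pres), "_G",
                           sample.int(99999L, length(pres), replace = TRUE)),
      homology_type = resample(c("one2one", "one2many", "many2many"),
                               length(pres), replace = TRUE),
      target_species = pres)
  }
  orthology_species <- bind_rows(species_orth)

  ## ---- interactions and GO annotations --------------------------------
  tcof_counts <- cfg$tcof_class_counts
  n_pass <- sum(tcof_counts)
  attr_counts <- cfg$go_attrition
  n_fail <- sum(attr_counts)
  tcof_ids <- sprintf("BTC%04d", seq_len(n_pass + n_fail))
  tcof_plant <- tibble(
    protein_id = sample(tcof_ids),
    stage = rep(c("pass", names(attr_counts)), c(n_pass, attr_counts))
  )
  tcof_plant$confidence_class <- NA_character_
  tcof_plant$confidence_class[tcof_plant$stage == "pass"] <-
    sample(rep(names(tcof_counts), tcof_counts))
  allowed_mi <- names(cfg$mi_type_mix)
  edges <- bind_rows(lapply(seq_len(nrow(tcof_plant)), function(i) {
    tibble(id_a = resample(comp_ids, resample(1:4, 1L)),
           id_b = tcof_plant$protein_id[i])
  }))
  edges$mi_type <- sample(allowed_mi, nrow(edges), replace = TRUE,
                          prob = cfg$mi_type_mix)
  dec <- cfg$n_decoy_interactions
  decoys <- bind_rows(
    tibble(id_a = resample(comp_ids, dec[["tf_tf"]], replace = TRUE),
           id_b = resample(comp_ids, dec[["tf_tf"]], replace = TRUE),
           mi_type = "MI:0915"),
    tibble(id_a = resample(comp_ids, dec[["bad_mi"]], replace = TRUE),
           id_b = sprintf("DEC%04d", seq_len(dec[["bad_mi"]])),
           mi_type = resample(c("MI:0403", "MI:0914"), dec[["bad_mi"]],
                              replace = TRUE)),
    tibble(id_a = sprintf("NTA%04d", seq_len(dec[["non_tf"]])),
           id_b = sprintf("NTB%04d", seq_len(dec[["non_tf"]])),
           mi_type = "MI:0915")
  )
  interactions <- bind_rows(edges, decoys) %>%
    mutate(source = "synthetic")
  interactions <- interactions[sample.int(nrow(interactions)), ]

  tc <- default_term_config()
  gaf_rows <- list()
  add_ann <- function(id, go, aspect, code) {
    gaf_rows[[length(gaf_rows) + 1L]] <<- tibble(
      protein_id = id, go_id = go, aspect = aspect, evidence_code = code)
  }
  for (i in seq_len(nrow(tcof_plant))) {
    id <- tcof_plant$protein_id[i]; st <- tcof_plant$stage[i]
    if (st == "fail_cc") {                # no nuclear annotation at all
      add_ann(id, resample(tc$bp_terms, 1L), "BP", "IEA")
      next
    }
    cc_code <- "IEA"; mf_code <- "IEA"
    if (st == "pass") {
      cls <- tcof_plant$confidence_class[i]
      if (cls %in% c("high_confidence", "hypothetical_II")) {
        cc_code <- resample(tc$experimental_codes, 1L)
      }
      if (cls %in% c("high_confidence", "hypothetical_I")) {
        mf_code <- resample(tc$experimental_codes, 1L)
      }
    }
    add_ann(id, tc$cc_anchor, "CC", cc_code)
    if (st != "fail_bp") add_ann(id, resample(tc$bp_terms, 1L), "BP", "IEA")
    if (st == "pass") add_ann(id, resample(tc$mf_terms, 1L), "MF", mf_code)
    if (st == "fail_mf") add_ann(id, "GO:0005515", "MF", "IEA")  # unrelated MF
  }
  annotations <- bind_rows(gaf_rows)

  ## ---- expression ------------------------------------------------------
  tissues <- cfg$tissues[seq_len(cfg$n_tissues)]
  nt <- length(tissues)
  pass_tcofs <- tcof_plant$protein_id[tcof_plant$stage == "pass"]
  pattern_for <- function(kind) {
    switch(kind,
           ubiquitous = tissues,
           single = resample(tissues, 1L),
           intermediate = resample(tissues, resample(2:(nt - 1L), 1L)),
           unexpressed = character())
  }
  plan_expression <- function(ids, profile) {
    kinds <- sample(rep(names(profile), profile))[seq_along(ids)]
    tibble(gene_id = ids, kind = kinds, tissue_set = lapply(kinds, pattern_for))
  }
  expr_plan <- bind_rows(plan_expression(comp_ids, cfg$expression_profile$tf),
                         plan_expression(pass_tcofs, cfg$expression_profile$tcof))
  fpkm <- bind_rows(lapply(seq_len(nrow(expr_plan)), function(i) {
    set <- expr_plan$tissue_set[[i]]
    vals1 <- setNames(rep(0, nt), tissues)
    vals1[set] <- round(stats::rlnorm(length(set), 1.5, 1), 2)
    rows <- tibble(isoform_id = paste0(expr_plan$gene_id[i], ".1"),
                   gene_id = expr_plan$gene_id[i], !!!as.list(vals1))
    if (length(set) > 1L && stats::runif(1) < 0.4) {
      sub <- resample(set, resample(seq_along(set), 1L))
      vals2 <- setNames(rep(0, nt), tissues)
      vals2[sub] <- round(stats::rlnorm(length(sub), 1.0, 1), 2)
      rows <- bind_rows(rows, tibble(isoform_id = paste0(expr_plan$gene_id[i], ".2"),
                                     gene_id = expr_plan$gene_id[i], !!!as.list(vals2)))
    }
    rows
  }))

  pairs <- interactions %>%
    filter(.data$mi_type %in% tc$allowed_mi,
           .data$id_a %in% comp_ids, .data$id_b %in% pass_tcofs) %>%
    distinct(tf = .data$id_a, tcof = .data$id_b) %>%
    arrange(.data$tf, .data$tcof)
  tset <- setNames(expr_plan$tissue_set, expr_plan$gene_id)
  measurable <- pairs$tcof %in% names(tset)
  pair_truth <- pairs[measurable, ]
  pair_truth$n_tissues <- vapply(seq_len(nrow(pair_truth)), function(i) {
    length(intersect(tset[[pair_truth$tf[i]]], tset[[pair_truth$tcof[i]]]))
  }, integer(1))

  ## ---- alternative TF databases ---------------------------------------
  ao <- cfg$alt_overlap
  memb <- tibble(gene_id = sample(comp_ids),
                 n_in = rep(c(3L, 2L, 1L, 0L),
                            ao[c("in_all", "in_two", "in_one", "exclusive")])[
                              seq_along(comp_ids)])
  alt_names <- c("DBDdb", "AnimalTFDB", "CisBP")
  # the reverse list mixes curated exclusions (class c/y, which carry a
  # rationale) with background genes never screened
  curated_pool <- setdiff(intended$gene_id[intended$class %in% c("c", "y")], comp_ids)
  n_curated <- min(ceiling(cfg$n_alt_extra / 2), length(curated_pool))
  extra <- c(resample(curated_pool, n_curated),
             resample(bg_ids, min(cfg$n_alt_extra - n_curated, length(bg_ids))))
  alt_sets <- lapply(seq_along(alt_names), function(j) {
    in_set <- vapply(seq_len(nrow(memb)), function(i) {
      n <- memb$n_in[i]
      if (n == 3L) TRUE else if (n == 0L) FALSE
      else j %in% (((i + seq_len(n)) %% 3L) + 1L)   # deterministic spread
    }, logical(1))
    sort(unique(c(memb$gene_id[in_set],
                  resample(extra, ceiling(length(extra) / 2)))))
  })
  names(alt_sets) <- alt_names

  ## ---- truth -----------------------------------------------------------
  truth <- list(
    screened_ids = sort(intended$gene_id),
    classes = intended[order(intended$gene_id),
                       c("gene_id", "class", "rationale", "plant")],
    compendium_ids = sort(comp_ids),
    registry = registry_true,
    registry_summary = registry_summary(registry_true),
    novel_human_genes = sort(human_round$novel_genes),
    novel_mouse_genes = sort(mouse_round$novel_genes),
    n_census_updated = cfg$n_census_b_updates + cfg$n_census_c_updates,
    groups = groups %>% arrange(.data$gene_id),
    tcofs = tcof_plant %>% arrange(.data$protein_id),
    expression = expr_plan %>%
      mutate(n_tissues = lengths(.data$tissue_set)) %>%
      select("gene_id", "kind", "n_tissues") %>% arrange(.data$gene_id),
    pair_coexpression = pair_truth,
    alt_membership = memb %>% arrange(.data$gene_id)
  )

  list(
    data = list(
      genes = genes,
      census = census,
      census_updates = census_updates,
      candidate_updates = candidate_updates,
      human_snapshots = human_round$snapshots,
      mouse_snapshots = mouse_round$snapshots,
      reference_dbds = ref_dbds,
      domain_functions = domain_functions,
      family_map = family_map,
      human_genes = human_genes,
      orthology = orthology,
      orthology_species = orthology_species,
      hits = hits,
      clade_map = cfg$clade_map,
      species = cfg$species,
      interactions = interactions,
      annotations = annotations,
      fpkm = fpkm,
      pairs = pairs,
      alt_sets = alt_sets
    ),
    truth = truth,
    config = cfg
  )
}

#' Write a synthetic world to disk
#'
#' Serialises every table of the bundle in the pipeline's external formats
#' (TSV, PSI-MITAB, GAF) plus the planted truth as JSON. A given
#' configuration always produces byte-identical files.
#'
#' @param world Result of [generate_world()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  d <- world$data
  write_gene_domains(d$genes, p("genes.tsv"))
  write_census(d$census, p("census.tsv"))
  readr::write_tsv(d$census_updates, p("census_updates.tsv"), progress = FALSE)
  readr::write_tsv(d$candidate_updates, p("candidate_updates.tsv"), progress = FALSE)
  for (i in seq_along(d$human_snapshots)) {
    readr::write_tsv(as_tibble(d$human_snapshots[[i]]),
                     p(sprintf("snapshot_human_%d.tsv", i)), na = "", progress = FALSE)
  }
  for (i in seq_along(d$mouse_snapshots)) {
    readr::write_tsv(as_tibble(d$mouse_snapshots[[i]]),
                     p(sprintf("snapshot_mouse_%d.tsv", i)), na = "", progress = FALSE)
  }
  readr::write_tsv(d$reference_dbds, p("reference_dbds.tsv"), progress = FALSE)
  readr::write_tsv(d$domain_functions, p("domain_functions.tsv"), progress = FALSE)
  readr::write_tsv(d$family_map, p("family_map.tsv"), progress = FALSE)
  write_gene_domains(d$human_genes, p("human_genes.tsv"))
  write_orthology(d$orthology, p("orthology.tsv"))
  write_orthology(d$orthology_species, p("orthology_species.tsv"))
  readr::write_tsv(d$hits, p("hits.tsv"), progress = FALSE)
  readr::write_tsv(d$clade_map, p("clade_map.tsv"), progress = FALSE)
  write_mitab(d$interactions, p("interactions.mitab"))
  write_gaf(d$annotations, p("annotations.gaf"))
  write_fpkm(d$fpkm, p("fpkm.tsv"))
  readr::write_tsv(d$pairs, p("pairs.tsv"), progress = FALSE)
  for (nm in names(d$alt_sets)) {
    readr::write_lines(d$alt_sets[[nm]], p(sprintf("alt_%s.txt", nm)))
  }
  truth <- world$truth
  truth$pair_coexpression <- as.data.frame(truth$pair_coexpression)
  truth$registry <- as.data.frame(truth$registry)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(dir)
}
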