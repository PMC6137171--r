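# Brute-force longest-common-subsequence by exhaustive enumeration of the
# subsequences of the shorter vector (used only on tiny token sets).
brute_lcs <- function(x, y) {
  if (length(x) > length(y)) { tmp <- x; x <- y; y <- tmp }
  is_subseq <- function(s, v) {
    j <- 1L
    for (el in v) if (j <= length(s) && identical(s[j], el)) j <- j + 1L
    j > length(s)
  }
  best <- 0L
  for (k in seq_along(x)) {
    for (idx in utils::combn(seq_along(x), k, simplify = FALSE)) {
      if (is_subseq(x[idx], y)) best <- max(best, k)
    }
  }
  best
}

test_that("DBD screening keeps exactly the genes carrying registry domains", {
  reg <- mini_registry(c("IPR000001", "IPR000002"))
  genes <- gd(list("g1", "protein_coding", "IPR000001", "domain", 1, 50),
              list("g2", "protein_coding", "IPR777777", "domain", 1, 50),
              list("g3", "protein_coding", NA_character_, NA_character_, NA, NA))
  out <- screen_for_dbds(genes, reg)
  expect_equal(unique(out$gene_id), "g1")
  expect_error(screen_for_dbds(genes, reg[0, ]), "empty")
})

test_that("screening a 200-gene world recovers the planted carriers exactly", {
  w <- tiny_world()
  reg <- w$truth$registry
  out <- screen_for_dbds(w$data$genes, reg)
  # brute-force scan oracle
  oracle <- unique(w$data$genes$gene_id[
    !is.na(w$data$genes$interpro_id) &
      w$data$genes$interpro_id %in% reg$interpro_id])
  expect_setequal(unique(out$gene_id), oracle)
  expect_setequal(unique(out$gene_id), w$truth$screened_ids)
  expect_equal(length(unique(out$gene_id)), 40L)
  # subset relation: every returned row is an input row
  expect_true(all(out$gene_id %in% w$data$genes$gene_id))
})

test_that("domain arrangements order by start and collapse consecutive repeats", {
  expect_equal(arrangement_of(tibble::tibble(
    interpro_id = c("IPR2", "IPR1"), start = c(60L, 1L))), c("IPR1", "IPR2"))
  expect_equal(arrangement_of(tibble::tibble(
    interpro_id = c("IPR1", "IPR1"), start = c(1L, 55L))), "IPR1")
  # tandem repeats of distinct domains are preserved
  expect_equal(arrangement_of(tibble::tibble(
    interpro_id = c("IPR1", "IPR2", "IPR1"), start = c(1L, 50L, 100L))),
    c("IPR1", "IPR2", "IPR1"))
  expect_equal(arrangement_of(tibble::tibble(
    interpro_id = character(), start = integer())), character())
})

test_that("arrangement similarity is a normalised alignment score", {
  expect_equal(arrangement_similarity(c("A", "B", "C"), c("A", "B", "C")), 1)
  expect_equal(arrangement_similarity(c("A", "B", "C"), c("A", "C")), 2 / 3)
  expect_equal(arrangement_similarity(character(), "A"), 0)
  expect_equal(arrangement_similarity(character(), character()), 1)
  # symmetry and the exhaustive-alignment oracle on all short token pairs
  set.seed(5)
  for (i in 1:60) {
    x <- sample(LETTERS[1:4], sample(1:4, 1), replace = TRUE)
    y <- sample(LETTERS[1:4], sample(1:4, 1), replace = TRUE)
    expected <- brute_lcs(x, y) / max(length(x), length(y))
    expect_equal(arrangement_similarity(x, y), expected)
    expect_equal(arrangement_similarity(y, x), arrangement_similarity(x, y))
    expect_equal(arrangement_similarity(x, y) == 1, identical(x, y))
  }
})

cascade_fixture <- function() {
  genes <- gd(list("b1", "protein_coding", "IPR000001", "domain", 1, 50),
              list("b1", "protein_coding", "IPR000002", "domain", 60, 120),
              list("b2", "pseudogene", "IPR000001", "domain", 1, 50),
              list("b3", "protein_coding", "IPR000001", "domain", 1, 50),
              list("b4", "protein_coding", "IPR000001", "domain", 1, 50))
  census <- new_census(tibble::tibble(
    gene_id = c("h1", "h2", "hx"), evidence_class = c("a", "c", "x"), note = ""))
  human <- gd(list("h1", "protein_coding", "IPR000001", "domain", 5, 60),
              list("h1", "protein_coding", "IPR000002", "domain", 70, 130),
              list("h2", "protein_coding", "IPR000001", "domain", 1, 50),
              list("hx", "protein_coding", "IPR000001", "domain", 1, 50))
  list(genes = genes, census = census, human = human)
}

test_that("the curation cascade assigns classes in the specified order", {
  f <- cascade_fixture()
  orth <- tibble::tibble(source_gene = "b1", target_gene = "h1",
                         homology_type = "one2one", target_species = "Homo sapiens")
  # identical arrangement to an a-class orthologue -> class a
  out <- assign_class("b1", f$genes, orth, f$census, f$human)
  expect_equal(out$assigned_class, "a")
  expect_equal(out$rationale_code, "arrangement_match")
  expect_equal(out$similarity, 1)

  # pseudogene wins over a perfect orthologue
  orth2 <- orth; orth2$source_gene <- "b2"
  out2 <- assign_class("b2", f$genes, orth2, f$census, f$human)
  expect_equal(out2$assigned_class, "c")
  expect_equal(out2$rationale_code, "pseudogene")

  # diverged arrangement (similarity 1/2 below 0.8) -> class c
  genes_div <- gd(list("b1", "protein_coding", "IPR000001", "domain", 1, 50))
  out3 <- assign_class("b1", genes_div, orth, f$census, f$human)
  expect_equal(out3$assigned_class, "c")
  expect_equal(out3$rationale_code, "arrangement_diverged")
  expect_equal(out3$similarity, 0.5)

  # orthologue of class c / class x
  orthc <- tibble::tibble(source_gene = "b3", target_gene = "h2",
                          homology_type = "one2many", target_species = "Homo sapiens")
  expect_equal(assign_class("b3", f$genes, orthc, f$census, f$human)$rationale_code,
               "orthologue_class_c")
  orthx <- orthc; orthx$target_gene <- "hx"
  expect_equal(assign_class("b3", f$genes, orthx, f$census, f$human)$rationale_code,
               "non_tf_function")

  # no orthologue, no hits -> class y
  out_y <- assign_class("b4", f$genes, orth[0, ], f$census, f$human)
  expect_equal(out_y$assigned_class, "y")
  expect_equal(out_y$rationale_code, "no_orthologue")

  # similarity hit to an a-class gene with matching arrangement rescues to b
  hits <- tibble::tibble(query_gene = "b4", subject_gene = "h1", score = 200)
  genes_b4 <- gd(list("b4", "protein_coding", "IPR000001", "domain", 1, 50),
                 list("b4", "protein_coding", "IPR000002", "domain", 60, 120))
  out_r <- assign_class("b4", genes_b4, orth[0, ], f$census, f$human, hits = hits)
  expect_equal(out_r$assigned_class, "b")
  expect_equal(out_r$rationale_code, "similarity_rescue")

  # hit to a known non-TF -> excluded as class c
  hits_x <- tibble::tibble(query_gene = "b4", subject_gene = "hx", score = 200)
  out_x <- assign_class("b4", f$genes, orth[0, ], f$census, f$human, hits = hits_x)
  expect_equal(out_x$rationale_code, "similar_to_non_tf")
  expect_equal(out_x$assigned_class, "c")

  # literature evidence overrides everything
  upd <- tibble::tibble(gene_id = "b4", new_class = "a", citation = "PMID:9")
  out_l <- assign_class("b4", f$genes, orth[0, ], f$census, f$human,
                        evidence_updates = upd)
  expect_equal(out_l$assigned_class, "a")
  expect_equal(out_l$rationale_code, "literature_evidence")

  # many2many relations are ignored
  orthm <- orth; orthm$homology_type <- "many2many"
  expect_equal(assign_class("b1", f$genes, orthm, f$census, f$human)$assigned_class,
               "y")

  # orthologue with no domain data at all -> arrangement unavailable
  human_nd <- gd(list("h1", "protein_coding", NA_character_, NA_character_, NA, NA))
  out_na <- assign_class("b1", f$genes, orth, f$census, human_nd)
  expect_equal(out_na$rationale_code, "arrangement_unavailable")

  # unknown reference gene in the orthology is an error
  orth_bad <- orth; orth_bad$target_gene <- "missing"
  expect_error(assign_class("b1", f$genes, orth_bad, f$census, f$human), "unknown")
})

test_that("classes partition candidates and the compendium filters a and b", {
  w <- tiny_world()
  res <- tiny_result()
  cand <- res$candidates
  expect_setequal(cand$assigned_class, c("a", "b", "c", "y"))
  expect_equal(nrow(cand), length(w$truth$screened_ids))
  p <- partition_report(cand)
  expect_equal(sum(p$by_class$n), p$n_screened)
  comp <- compendium(cand)
  expect_equal(nrow(comp), sum(cand$assigned_class %in% c("a", "b")))
  expect_equal(compendium(cand[0, ]) |> nrow(), 0L)
  counts <- table(c(a = "a", a = "a", b = "b", c = "c", c = "c", c = "c", y = "y"))
  toy <- tibble::tibble(gene_id = sprintf("g%d", 1:7),
                        assigned_class = c("a", "a", "b", "c", "c", "c", "y"),
                        rationale_code = "x", orthologue = NA, similarity = NA)
  expect_equal(nrow(compendium(toy)), 3L)
})

test_that("raising the threshold never promotes a candidate (monotonicity)", {
  w <- tiny_world()
  ids <- sort(unique(w$truth$screened_ids))
  screened <- screen_for_dbds(w$data$genes, w$truth$registry)
  run_thr <- function(thr) {
    assign_classes(ids, screened, w$data$orthology, w$data$census |>
                     apply_updates(w$data$census_updates),
                   w$data$human_genes, evidence_updates = w$data$candidate_updates,
                   hits = w$data$hits, threshold = thr)
  }
  lo <- run_thr(0.4); mid <- run_thr(0.8); hi <- run_thr(1.0)
  in_comp <- function(x) x$gene_id[x$assigned_class %in% c("a", "b")]
  # literature overrides are threshold-independent; all other promotions may
  # only be lost, never gained, as the threshold rises
  lit <- lo$gene_id[lo$rationale_code == "literature_evidence"]
  expect_true(all(setdiff(in_comp(hi), lit) %in% in_comp(mid)))
  expect_true(all(setdiff(in_comp(mid), lit) %in% in_comp(lo)))
  # determinism: identical inputs give identical output
  expect_equal(run_thr(0.8), mid)
})

test_that("assigned classes equal an independent re-evaluation of the cascade", {
  w <- tiny_world()
  res <- tiny_result()
  cand <- res$candidates[order(res$candidates$gene_id), ]
  # the truth table was planted before any file was synthesised, so exact
  # agreement re-derives every branch of the cascade
  expect_equal(cand$assigned_class, w$truth$classes$class)
  expect_equal(cand$rationale_code, w$truth$classes$rationale)
  p <- res$partition
  expect_equal(p$n_screened, 40L)
  expect_equal(p$n_compendium, 24L)
  expect_equal(p$n_post_removal,
               sum(!w$truth$classes$rationale %in%
                     c("pseudogene", "non_tf_function", "orthologue_class_c")))
})
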