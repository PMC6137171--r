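rec <- function(a, b, mi) tibble::tibble(id_a = a, id_b = b, mi_type = mi,
                                         source = "test")

test_that("interaction filtering keeps only the allowed MI types", {
  r <- rec(c("t1", "t1", "t2"), c("p1", "p2", "p3"),
           c("MI:0915", "MI:0403", "MI:0407"))
  out <- filter_interactions(r)
  expect_equal(out$mi_type, c("MI:0915", "MI:0407"))
  tc <- attr(out, "type_counts")
  expect_equal(sum(tc$n), nrow(out))
})

test_that("a planted 100-record mix keeps exactly the allowed records", {
  set.seed(31)
  allowed <- c("MI:0195", "MI:0407", "MI:0915")
  disallowed <- c("MI:0403", "MI:0914", "MI:0208")
  types <- c(sample(allowed, 37, replace = TRUE),
             sample(disallowed, 63, replace = TRUE))
  types <- sample(types)
  r <- rec(sprintf("a%03d", 1:100), sprintf("b%03d", 1:100), types)
  out <- filter_interactions(r)
  expect_equal(nrow(out), 37L)
  tc <- attr(out, "type_counts")
  planted <- table(factor(types[types %in% allowed], levels = sort(allowed)))
  expect_equal(stats::setNames(tc$n, tc$mi_type),
               stats::setNames(as.integer(planted), names(planted)))
})

test_that("candidates are non-TF partners of TFs; TF-TF pairs contribute none", {
  tf <- c("t1", "t2")
  r <- rec(c("t1", "t1", "t2", "p9"), c("p1", "t2", "p1", "p8"),
           rep("MI:0915", 4))
  cand <- candidate_tcofs(r, tf)
  expect_setequal(cand$protein_id, "p1")
  expect_setequal(cand$tf_partners[[1]], c("t1", "t2"))
  # brute-force edge scan oracle on a random edge list
  set.seed(32)
  tfs <- sprintf("t%02d", 1:6)
  prots <- c(tfs, sprintf("p%02d", 1:10))
  r2 <- rec(sample(prots, 50, TRUE), sample(prots, 50, TRUE), "MI:0915")
  cand2 <- candidate_tcofs(r2, tfs)
  oracle <- new.env()
  for (i in seq_len(nrow(r2))) {
    a <- r2$id_a[i]; b <- r2$id_b[i]
    if (a %in% tfs && !b %in% tfs) assign(b, union(mget(b, oracle,
      ifnotfound = list(character()))[[1]], a), oracle)
    if (b %in% tfs && !a %in% tfs) assign(a, union(mget(a, oracle,
      ifnotfound = list(character()))[[1]], b), oracle)
  }
  expect_setequal(cand2$protein_id, ls(oracle))
  for (p in cand2$protein_id) {
    expect_setequal(cand2$tf_partners[[match(p, cand2$protein_id)]], get(p, oracle))
  }
  expect_error(candidate_tcofs(r, character()), "empty")
})

test_that("the GO filter removes candidates stage by stage in narrative order", {
  cand <- tibble::tibble(protein_id = c("p1", "p2", "p3", "p4"),
                         tf_partners = list("t1", "t1", "t1", "t1"),
                         n_tf_partners = 1L)
  ann <- dplyr::bind_rows(
    tibble::tibble(protein_id = "p1", go_id = "GO:0005634", aspect = "CC",
                   evidence_code = "IDA"),
    tibble::tibble(protein_id = "p1", go_id = "GO:0006351", aspect = "BP",
                   evidence_code = "IEA"),
    tibble::tibble(protein_id = "p1", go_id = "GO:0003713", aspect = "MF",
                   evidence_code = "IDA"),
    # p2: nucleus but no listed BP -> removed at stage 2
    tibble::tibble(protein_id = "p2", go_id = "GO:0005634", aspect = "CC",
                   evidence_code = "IDA"),
    # p3: nucleus + BP but no listed MF -> removed at stage 3
    tibble::tibble(protein_id = "p3", go_id = "GO:0005634", aspect = "CC",
                   evidence_code = "IEA"),
    tibble::tibble(protein_id = "p3", go_id = "GO:0045892", aspect = "BP",
                   evidence_code = "IEA"))
  out <- go_filter(cand, ann)
  expect_equal(out$protein_id, "p1")
  sc <- attr(out, "stage_counts")
  expect_equal(sc$n, c(4L, 3L, 2L, 1L))
  expect_true(all(diff(sc$n) <= 0))          # monotone attrition
  bad <- default_term_config(); bad$bp_terms <- character()
  expect_error(go_filter(cand, ann, bad), "non-empty")
})

test_that("planted stage attrition is recovered exactly on a world", {
  w <- tiny_world()
  res <- tiny_result()
  sc <- res$tcof_stage_counts
  plant <- table(w$truth$tcofs$stage)
  n_cand <- nrow(w$truth$tcofs)
  expect_equal(sc$n[sc$stage == "input"], n_cand)
  expect_equal(sc$n[sc$stage == "nucleus"], n_cand - plant[["fail_cc"]])
  expect_equal(sc$n[sc$stage == "biological_process"],
               n_cand - plant[["fail_cc"]] - plant[["fail_bp"]])
  expect_equal(sc$n[sc$stage == "molecular_function"], plant[["pass"]])
})

test_that("evidence classification enumerates the four confidence classes", {
  tc <- default_term_config()
  tcofs <- tibble::tibble(protein_id = c("nt", "t_only", "n_only", "neither"),
                          tf_partners = list("t1", "t1", "t1", "t1"),
                          n_tf_partners = 1L)
  ann <- dplyr::bind_rows(
    tibble::tibble(protein_id = "nt", go_id = "GO:0005634", aspect = "CC",
                   evidence_code = "IDA"),
    tibble::tibble(protein_id = "nt", go_id = "GO:0003713", aspect = "MF",
                   evidence_code = "IPI"),
    tibble::tibble(protein_id = "t_only", go_id = "GO:0005634", aspect = "CC",
                   evidence_code = "IEA"),
    tibble::tibble(protein_id = "t_only", go_id = "GO:0003712", aspect = "MF",
                   evidence_code = "IMP"),
    tibble::tibble(protein_id = "n_only", go_id = "GO:0005634", aspect = "CC",
                   evidence_code = "EXP"),
    tibble::tibble(protein_id = "n_only", go_id = "GO:0003714", aspect = "MF",
                   evidence_code = "IEA"),
    tibble::tibble(protein_id = "neither", go_id = "GO:0005634", aspect = "CC",
                   evidence_code = "IEA"),
    tibble::tibble(protein_id = "neither", go_id = "GO:0070491", aspect = "MF",
                   evidence_code = "ISS"))
  out <- classify_evidence(tcofs, ann, tc)
  expect_equal(out$confidence_class,
               c("high_confidence", "hypothetical_I", "hypothetical_II",
                 "hypothetical_III"))
  # exactly one class each: classes partition the set
  expect_equal(length(unique(out$confidence_class)), 4L)
})

test_that("planted confidence classes and TF edges are recovered on a world", {
  w <- tiny_world()
  res <- tiny_result()
  truth <- w$truth$tcofs[w$truth$tcofs$stage == "pass", ]
  got <- res$tcofs[order(res$tcofs$protein_id), ]
  expect_equal(got$protein_id, truth$protein_id)
  expect_equal(got$confidence_class, truth$confidence_class)
  expect_equal(sum(table(got$confidence_class)), nrow(got))
  # every partner is a compendium TF and the edge count survives a recount
  expect_true(all(unlist(got$tf_partners) %in% res$compendium$gene_id))
  filtered <- filter_interactions(w$data$interactions)
  n_edges <- nrow(dplyr::distinct(dplyr::bind_rows(
    tibble::tibble(tf = filtered$id_a, p = filtered$id_b)[
      filtered$id_a %in% res$compendium$gene_id &
        filtered$id_b %in% got$protein_id, ],
    tibble::tibble(tf = filtered$id_b, p = filtered$id_a)[
      filtered$id_b %in% res$compendium$gene_id &
        filtered$id_a %in% got$protein_id, ])))
  expect_equal(nrow(res$pairs), n_edges)
})

test_that("identifier mapping re-keys annotation tables", {
  ann <- tibble::tibble(protein_id = c("P1", "P2"), go_id = "GO:0005634",
                        aspect = "CC", evidence_code = "IDA")
  map <- tibble::tibble(from = c("P1", "P1", "P3"), to = c("b1", "b2", "b3"))
  out <- map_protein_ids(ann, map)
  expect_setequal(out$protein_id, c("b1", "b2"))
})
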