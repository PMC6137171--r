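test_that("gene-domain reader groups rows per gene and validates intervals", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tbiotype\tinterpro_id\tentry_type\tstart\tend",
               "g1\tprotein_coding\tIPR000001\tdomain\t10\t60",
               "g1\tprotein_coding\tIPR000002\tfamily\t70\t120",
               "g2\tprotein_coding\tIPR000001\tdomain\t5\t40"), tsv)
  genes <- read_gene_domains(tsv)
  expect_equal(length(unique(genes$gene_id)), 2L)
  expect_equal(nrow(genes), 3L)
  # hits sorted by start within gene
  expect_equal(genes$start[genes$gene_id == "g1"], c(10L, 70L))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tbiotype\tinterpro_id\tentry_type\tstart\tend",
               "g1\tprotein_coding\tIPR000001\tdomain\t60\t10"), bad)
  expect_error(read_gene_domains(bad), "start > end")

  nocol <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tbiotype\tinterpro_id\tentry_type\tstart",
               "g1\tprotein_coding\tIPR000001\tdomain\t1"), nocol)
  expect_error(read_gene_domains(nocol), "end")

  noint <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tbiotype\tinterpro_id\tentry_type\tstart\tend",
               "g1\tprotein_coding\tIPR000001\tdomain\tten\t60"), noint)
  expect_error(read_gene_domains(noint), "line 2")
})

test_that("generated gene tables round-trip through write + read identically", {
  w <- tiny_world()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_domains(w$data$genes, path)
  back <- read_gene_domains(path)
  expect_equal(as.data.frame(back), as.data.frame(w$data$genes))
})

test_that("MITAB reader extracts bare MI codes and counts skipped lines", {
  path <- withr::local_tempfile(fileext = ".txt")
  good <- paste(c("uniprotkb:P1", "uniprotkb:P2", rep("-", 9),
                  'psi-mi:"MI:0915"(physical association)', "intact", "-", "-"),
                collapse = "\t")
  writeLines(good, path)
  rec <- read_mitab(path)
  expect_equal(rec$mi_type, "MI:0915")
  expect_equal(rec$id_a, "P1")
  expect_equal(attr(rec, "n_skipped"), 0L)

  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(), empty)
  expect_equal(nrow(read_mitab(empty)), 0L)

  # 10 lines, 2 malformed (truncated / bad type field)
  mixed <- withr::local_tempfile(fileext = ".txt")
  lines <- vapply(1:8, function(i) {
    paste(c(sprintf("uniprotkb:A%d", i), sprintf("uniprotkb:B%d", i), rep("-", 9),
            'psi-mi:"MI:0407"(direct interaction)', "intact", "-", "-"),
          collapse = "\t")
  }, character(1))
  lines <- c(lines, "uniprotkb:A9\tuniprotkb:B9\tbroken",
             paste(c("uniprotkb:A10", "uniprotkb:B10", rep("-", 9),
                     "not-an-mi-code", "intact", "-", "-"), collapse = "\t"))
  writeLines(lines, mixed)
  rec <- suppressWarnings(read_mitab(mixed))
  expect_equal(nrow(rec), 8L)
  expect_equal(attr(rec, "n_skipped"), 2L)
  expect_warning(read_mitab(mixed), "skipped 2")
})

test_that("MITAB records round-trip through the 15-column writer", {
  w <- tiny_world()
  path <- withr::local_tempfile(fileext = ".txt")
  write_mitab(w$data$interactions, path)
  back <- read_mitab(path)
  expect_equal(back[c("id_a", "id_b", "mi_type")],
               w$data$interactions[c("id_a", "id_b", "mi_type")],
               ignore_attr = TRUE)
})

test_that("GAF reader maps aspects, drops NOT annotations, keeps codes verbatim", {
  gaf_line <- function(id, go, aspect, code, qual = "involved_in") {
    paste(c("UniProtKB", id, id, qual, go, "PMID:1", code, "", aspect, "", "",
            "protein", "taxon:9913", "20170101", "UniProt", "", ""),
          collapse = "\t")
  }
  path <- withr::local_tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.2",
               gaf_line("P1", "GO:0005634", "C", "IDA"),
               gaf_line("P2", "GO:0003713", "F", "IEA"),
               gaf_line("P3", "GO:0006351", "P", "IMP"),
               gaf_line("P4", "GO:0005634", "C", "IDA", qual = "NOT|located_in")),
             path)
  ann <- read_gaf(path)
  expect_equal(nrow(ann), 3L)
  expect_equal(ann$aspect, c("CC", "MF", "BP"))
  expect_equal(ann$evidence_code, c("IDA", "IEA", "IMP"))
  expect_equal(attr(ann, "n_not_excluded"), 1L)
  expect_false("P4" %in% ann$protein_id)

  badaspect <- withr::local_tempfile(fileext = ".gaf")
  writeLines(gaf_line("P1", "GO:0005634", "Q", "IDA"), badaspect)
  expect_error(read_gaf(badaspect), "unknown aspect")
})

test_that("a 50-row GAF with 5 NOT-qualified rows yields 45 annotations", {
  w <- tiny_world()
  ann <- w$data$annotations
  n_keep <- 45L
  sub <- ann[rep_len(seq_len(nrow(ann)), n_keep), ]
  sub$protein_id <- sprintf("Q%02d", seq_len(n_keep))
  path <- withr::local_tempfile(fileext = ".gaf")
  write_gaf(sub, path)
  lines <- readLines(path)
  not_rows <- vapply(sprintf("N%02d", 1:5), function(id) {
    paste(c("UniProtKB", id, id, "NOT|located_in", "GO:0005634", "PMID:1",
            "IDA", "", "C", "", "", "protein", "taxon:9913", "20170101",
            "UniProt", "", ""), collapse = "\t")
  }, character(1))
  writeLines(c(lines, not_rows), path)
  back <- read_gaf(path)
  expect_equal(nrow(back), 45L)
  expect_equal(attr(back, "n_not_excluded"), 5L)
})

test_that("FPKM validation rejects negatives and duplicate isoforms", {
  ok <- tibble::tibble(isoform_id = c("i1", "i2"), gene_id = c("g1", "g1"),
                       liver = c(0, 2.5), heart = c(1, 0))
  expect_silent(validate_fpkm(ok))
  bad <- ok; bad$liver[1] <- -1
  expect_error(validate_fpkm(bad), "non-negative")
  dup <- ok; dup$isoform_id <- c("i1", "i1")
  expect_error(validate_fpkm(dup), "duplicated")
})
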