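#' Read a gene/domain annotation table
#'
#' Reads a BioMart-style TSV of gene annotations with InterPro domain hits.
#' Coordinates are 1-based inclusive amino-acid positions. Each gene occupies
#' one row per domain hit; a gene with no domain hits is represented by a
#' single row with empty domain fields, and is retained with an empty hit
#' list. Hits are returned sorted by gene id and start coordinate.
#'
#' @param path Path to a TSV with columns `gene_id`, `biotype`, `interpro_id`,
#'   `entry_type`, `start`, `end`. The domain columns may be blank for genes
#'   without annotated domains.
#' @return A tibble with one row per domain hit (plus one all-`NA` hit row per
#'   domain-less gene), columns `gene_id`, `biotype`, `interpro_id`,
#'   `entry_type`, `start`, `end`.
#' @export
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\tbiotype\tinterpro_id\tentry_type\tstart\tend",
#'              "g1\tprotein_coding\tIPR000001\tdomain\t1\t50"), tsv)
#' read_gene_domains(tsv)
read_gene_domains <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  check_columns(raw, c("gene_id", "biotype", "interpro_id", "entry_type", "start", "end"),
                "gene-domain table")
  check_nonempty_ids(raw$gene_id, "gene-domain table")
  blank <- function(x) is.na(x) | !nzchar(x)
  has_hit <- !blank(raw$interpro_id)
  for (col in c("start", "end")) {
    vals <- raw[[col]][has_hit]
    ints <- suppressWarnings(as.integer(vals))
    bad <- which(is.na(ints) | vals != ints)
    if (length(bad) > 0L) {
      # +1 for the header line
      abort(sprintf("gene-domain table: non-integer %s coordinate at line %d",
                    col, which(has_hit)[bad[1]] + 1L),
            class = "tfc_format_error")
    }
  }
  out <- raw %>%
    mutate(
      interpro_id = ifelse(blank(.data$interpro_id), NA_character_, .data$interpro_id),
      entry_type = ifelse(blank(.data$entry_type), NA_character_, .data$entry_type),
      start = suppressWarnings(as.integer(.data$start)),
      end = suppressWarnings(as.integer(.data$end))
    )
  validate_gene_domains(out)
  out %>% arrange(.data$gene_id, .data$start, .data$interpro_id)
}

#' Validate a gene/domain tibble
#'
#' Checks the invariants of the gene-domain representation: positive 1-based
#' inclusive coordinates with `start <= end`, a legal entry type on every hit,
#' and a single biotype per gene.
#'
#' @param genes A gene-domain tibble as produced by [read_gene_domains()].
#' @return The input, invisibly; errors describe the first violation found.
#' @export
validate_gene_domains <- function(genes) {
  check_columns(genes, c("gene_id", "biotype", "interpro_id", "entry_type", "start", "end"),
                "gene-domain table")
  hit <- !is.na(genes$interpro_id)
  if (any(is.na(genes$start[hit])) || any(is.na(genes$end[hit]))) {
    abort("gene-domain table: domain hit with missing coordinates",
          class = "tfc_format_error")
  }
  if (any(genes$start[hit] < 1L)) {
    abort("gene-domain table: coordinates must be positive (1-based)",
          class = "tfc_format_error")
  }
  bad <- which(genes$start[hit] > genes$end[hit])
  if (length(bad) > 0L) {
    abort(sprintf("gene-domain table: start > end for hit on gene %s",
                  genes$gene_id[hit][bad[1]]),
          class = "tfc_format_error")
  }
  if (any(is.na(genes$entry_type[hit]) | !genes$entry_type[hit] %in% c("domain", "family"))) {
    abort("gene-domain table: entry_type must be 'domain' or 'family' on every hit",
          class = "tfc_format_error")
  }
  nb <- genes %>% distinct(.data$gene_id, .data$biotype) %>% count(.data$gene_id)
  if (any(nb$n > 1L)) {
    abort("gene-domain table: conflicting biotypes for one gene_id",
          class = "tfc_format_error")
  }
  invisible(genes)
}

#' Write a gene/domain table
#'
#' Inverse of [read_gene_domains()]; writing then reading reproduces the
#' input tibble exactly.
#'
#' @param genes Gene-domain tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_domains <- function(genes, path) {
  validate_gene_domains(genes)
  out <- genes %>%
    arrange(.data$gene_id, .data$start, .data$interpro_id) %>%
    mutate(start = as.character(.data$start), end = as.character(.data$end))
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a PSI-MITAB interaction file
#'
#' Parses PSI-MITAB 2.5 through 2.7 by reading only the first 15 columns.
#' The interaction type (column 12) is reduced to a bare MI accession
#' (`MI:NNNN`); interactor identifiers (columns 1 and 2) are stripped of
#' their database prefix (`uniprotkb:P04637` becomes `P04637`).
#' Self-interactions are retained (downstream filters deal with them).
#' Lines whose interaction-type field carries no parseable MI code, or with
#' fewer than 15 columns, are skipped with a warning; the skip count is
#' available as `attr(x, "n_skipped")`.
#'
#' @param path Path to a MITAB file. Header/comment lines starting with `#`
#'   are ignored.
#' @return Tibble with columns `id_a`, `id_b`, `mi_type`, `source`, and an
#'   `n_skipped` attribute.
#' @export
read_mitab <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    out <- tibble(id_a = character(), id_b = character(),
                  mi_type = character(), source = character())
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  mi <- vapply(fields, function(f) {
    if (length(f) < 15L) return(NA_character_)
    m <- stringr::str_match(f[[12]], "MI:\\d{4}")[1, 1]
    m
  }, character(1))
  ok <- !is.na(mi)
  n_skipped <- sum(!ok)
  if (n_skipped > 0L) {
    warn(sprintf("read_mitab: skipped %d unparseable record(s)", n_skipped))
  }
  strip_ns <- function(x) sub("^[^:]+:", "", x)
  out <- tibble(
    id_a = strip_ns(vapply(fields[ok], `[[`, character(1), 1L)),
    id_b = strip_ns(vapply(fields[ok], `[[`, character(1), 2L)),
    mi_type = mi[ok],
    source = vapply(fields[ok], function(f) f[[13]], character(1))
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write interaction records as PSI-MITAB 2.5
#'
#' Emits 15-column MITAB lines with the interaction type in the standard
#' `psi-mi:"MI:NNNN"(label)` syntax; a round-trip through [read_mitab()]
#' reproduces the records.
#'
#' @param records Tibble with `id_a`, `id_b`, `mi_type` and optionally
#'   `source` columns.
#' @param path Output path.
#' @param namespace Database prefix used for the interactor identifier
#'   columns (default `"uniprotkb"`).
#' @return `path`, invisibly.
#' @export
write_mitab <- function(records, path, namespace = "uniprotkb") {
  check_columns(records, c("id_a", "id_b", "mi_type"), "interaction records")
  labels <- c("MI:0195" = "covalent binding", "MI:0407" = "direct interaction",
              "MI:0915" = "physical association", "MI:0403" = "colocalization",
              "MI:0914" = "association")
  lab <- unname(labels[records$mi_type])
  lab[is.na(lab)] <- "interaction"
  src <- if ("source" %in% names(records)) records$source else rep("-", nrow(records))
  lines <- vapply(seq_len(nrow(records)), function(i) {
    paste(c(
      paste0(namespace, ":", records$id_a[i]),
      paste0(namespace, ":", records$id_b[i]),
      "-", "-", "-", "-", "-", "-", "-", "-", "-",
      sprintf('psi-mi:"%s"(%s)', records$mi_type[i], lab[i]),
      src[i], "-", "-"
    ), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a GO annotation file (GAF 2.x)
#'
#' Reads GAF 2.1/2.2. The aspect letter (`C`, `F`, `P`) is mapped to the
#' ontology namespace (`CC`, `MF`, `BP`); evidence codes are preserved
#' verbatim; annotations carrying a `NOT` qualifier are excluded (the
#' exclusion count is attached as `attr(x, "n_not_excluded")`).
#'
#' @param path Path to a GAF file; lines starting with `!` are ignored.
#' @return Tibble with columns `protein_id`, `go_id`, `aspect`
#'   (`CC`/`MF`/`BP`) and `evidence_code`.
#' @export
read_gaf <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (length(lines) == 0L) {
    out <- tibble(protein_id = character(), go_id = character(),
                  aspect = character(), evidence_code = character())
    attr(out, "n_not_excluded") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 9L
  if (any(short)) {
    abort(sprintf("read_gaf: record with fewer than 9 columns at data line %d",
                  which(short)[1]), class = "tfc_format_error")
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  aspect_raw <- get(9L)
  aspect_map <- c(C = "CC", F = "MF", P = "BP")
  unknown <- !aspect_raw %in% names(aspect_map)
  if (any(unknown)) {
    abort(sprintf("read_gaf: unknown aspect '%s' at data line %d",
                  aspect_raw[unknown][1], which(unknown)[1]),
          class = "tfc_format_error")
  }
  qualifier <- get(4L)
  negated <- vapply(strsplit(qualifier, "|", fixed = TRUE),
                    function(q) any(q == "NOT"), logical(1))
  out <- tibble(
    protein_id = get(2L),
    go_id = get(5L),
    aspect = unname(aspect_map[aspect_raw]),
    evidence_code = get(7L)
  )[!negated, ]
  attr(out, "n_not_excluded") <- sum(negated)
  out
}

#' Write GO annotations as GAF 2.2
#'
#' @param annotations Tibble with `protein_id`, `go_id`, `aspect`
#'   (`CC`/`MF`/`BP`), `evidence_code`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(annotations, path) {
  check_columns(annotations, c("protein_id", "go_id", "aspect", "evidence_code"),
                "GO annotations")
  aspect_rev <- c(CC = "C", MF = "F", BP = "P")
  involved <- c(CC = "located_in", MF = "enables", BP = "involved_in")
  lines <- vapply(seq_len(nrow(annotations)), function(i) {
    a <- annotations$aspect[i]
    paste(c("UniProtKB", annotations$protein_id[i], annotations$protein_id[i],
            involved[[a]], annotations$go_id[i], "PMID:0000000",
            annotations$evidence_code[i], "", aspect_rev[[a]], "", "",
            "protein", "taxon:9913", "20170101", "UniProt", "", ""),
          collapse = "\t")
  }, character(1))
  readr::write_lines(c("!gaf-version: 2.2", lines), path)
  invisible(path)
}

#' Read an orthology relation table
#'
#' Compara-style TSV with one row per homology relation.
#'
#' @param path TSV with columns `source_gene`, `target_gene`, `homology_type`
#'   (`one2one`, `one2many`, `many2many`) and `target_species`.
#' @return Validated tibble of relations.
#' @export
read_orthology <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  check_columns(out, c("source_gene", "target_gene", "homology_type", "target_species"),
                "orthology table")
  bad <- setdiff(unique(out$homology_type), c("one2one", "one2many", "many2many"))
  if (length(bad) > 0L) {
    abort(sprintf("orthology table: illegal homology_type: %s",
                  paste(bad, collapse = ", ")), class = "tfc_format_error")
  }
  out
}

#' @rdname read_orthology
#' @param relations Orthology tibble.
#' @export
write_orthology <- function(relations, path) {
  readr::write_tsv(relations, path, progress = FALSE)
  invisible(path)
}

#' Read a reference TF census table
#'
#' @param path TSV with columns `gene_id`, `evidence_class`, `note`.
#' @return Validated census tibble (see [new_census()]).
#' @export
read_census <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  check_columns(out, c("gene_id", "evidence_class", "note"), "census table")
  out$note[is.na(out$note)] <- ""
  new_census(out)
}

#' @rdname read_census
#' @param census Census tibble.
#' @export
write_census <- function(census, path) {
  readr::write_tsv(census, path, progress = FALSE)
  invisible(path)
}

#' Read an FPKM expression matrix
#'
#' Isoform-level FPKM table: one row per isoform, one column per tissue.
#' FPKM values must be finite and non-negative; every isoform maps to
#' exactly one parent gene.
#'
#' @param path TSV with columns `isoform_id`, `gene_id`, then one numeric
#'   column per tissue.
#' @return Validated expression tibble.
#' @export
read_fpkm <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    isoform_id = readr::col_character(), gene_id = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  check_columns(out, c("isoform_id", "gene_id"), "FPKM matrix")
  validate_fpkm(out)
}

#' @rdname read_fpkm
#' @param fpkm Expression tibble.
#' @export
write_fpkm <- function(fpkm, path) {
  readr::write_tsv(fpkm, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_fpkm
#' @export
validate_fpkm <- function(fpkm) {
  check_columns(fpkm, c("isoform_id", "gene_id"), "FPKM matrix")
  tissues <- setdiff(names(fpkm), c("isoform_id", "gene_id"))
  if (length(tissues) == 0L) {
    abort("FPKM matrix: no tissue columns", class = "tfc_format_error")
  }
  check_nonempty_ids(fpkm$isoform_id, "FPKM matrix")
  if (anyDuplicated(fpkm$isoform_id)) {
    abort("FPKM matrix: duplicated isoform_id (each isoform maps to one gene)",
          class = "tfc_format_error")
  }
  vals <- as.matrix(fpkm[tissues])
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals < 0)) {
    abort("FPKM matrix: values must be finite and non-negative",
          class = "tfc_format_error")
  }
  fpkm
}
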