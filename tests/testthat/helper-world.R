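# Shared fixtures: one tiny synthetic world and its pipeline run, generated
# once per test session.

.fixtures <- new.env(parent = emptyenv())

tiny_world <- function(seed = 42L, ...) {
  key <- paste0("world_", seed, "_", paste(deparse(substitute(list(...))), collapse = ""))
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- generate_world(world_config(seed, "tiny", ...))
  }
  .fixtures[[key]]
}

tiny_result <- function(seed = 42L) {
  key <- paste0("result_", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- run_pipeline(tiny_world(seed))
  }
  .fixtures[[key]]
}

paper_world <- function(seed = 20260924L) {
  key <- paste0("paper_world_", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- generate_world(world_config(seed, "paper_scale"))
  }
  .fixtures[[key]]
}

# Naive agglomerative average-linkage clustering, independent of hclust:
# repeatedly merges the closest pair of clusters, recomputing average
# inter-cluster distances from the raw distance matrix.
naive_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1L)) {
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d - 1e-12) { best_d <- dd; best <- c(j, i) }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

pres_tbl <- function(m, ids = sprintf("t%02d", seq_len(nrow(m)))) {
  out <- dplyr::bind_cols(tibble::tibble(gene_id = ids),
                          tibble::as_tibble(m, .name_repair = "minimal"))
  class(out) <- c("presence_matrix", class(out))
  out
}

# Small literal gene-domain table builder.
gd <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(gene_id = r[[1]], biotype = r[[2]],
                   interpro_id = r[[3]], entry_type = r[[4]],
                   start = as.integer(r[[5]]), end = as.integer(r[[6]]))
  }))
}

mini_registry <- function(ids, types = "domain") {
  dbd_registry(tibble::tibble(interpro_id = ids,
                              entry_type = rep_len(types, length(ids)),
                              provenance = "reference census",
                              sequence_specific = TRUE))
}
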