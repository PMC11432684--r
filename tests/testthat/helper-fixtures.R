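# In-code fixture builders shared across test files.

# interaction_table from (nc_name, nc_type, target_name, target_type) rows
make_table <- function(..., organism = "Homo sapiens") {
  rows <- list(...)
  rec <- do.call(rbind, lapply(rows, function(r) {
    data.frame(interaction_id = NA_character_, nc_name = r[1], nc_type = r[2],
               target_name = r[3], target_type = r[4], organism = organism,
               evidence_class = "RNA-RNA", source = "test",
               stringsAsFactors = FALSE)
  }))
  interaction_table(rec)
}

# tripartite_network from typed node vectors and a from-to edge matrix
make_net <- function(seeds = character(), mirnas = character(),
                     lncs = character(), edges = NULL) {
  nodes <- data.frame(
    id = c(seeds, mirnas, lncs),
    node_type = c(rep("seed", length(seeds)), rep("miRNA", length(mirnas)),
                  rep("lncRNA", length(lncs))),
    stringsAsFactors = FALSE
  )
  e <- if (is.null(edges)) {
    data.frame(from = character(), to = character(), evidence_count = integer(),
               stringsAsFactors = FALSE)
  } else {
    data.frame(from = edges[, 1], to = edges[, 2],
               evidence_count = if (ncol(edges) >= 3) as.integer(edges[, 3]) else 1L,
               stringsAsFactors = FALSE)
  }
  tripartite_network(nodes, e, seed_set = gene_set(seeds, role = "seed"))
}

# NPInter-dialect TSV on disk
write_npinter_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- paste("interID", "ncName", "ncType", "tarName", "tarType",
                  "organism", "class", "datasource", sep = "\t")
  body <- vapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    paste(sprintf("NPI%03d", i), r[1], r[2], r[3], r[4],
          if (length(r) >= 5) r[5] else "Homo sapiens",
          "RNA-RNA", "test", sep = "\t")
  }, "")
  writeLines(c(header, body), path)
  path
}

# BioGRID tab3 TSV on disk; rows are c(symbolA, symbolB[, taxA, taxB])
write_biogrid_fixture <- function(rows, path = tempfile(fileext = ".txt")) {
  header <- paste("#BioGRID Interaction ID", "Official Symbol Interactor A",
                  "Official Symbol Interactor B", "Organism ID Interactor A",
                  "Organism ID Interactor B", "Experimental System", sep = "\t")
  body <- vapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    paste(sprintf("BG%03d", i), r[1], r[2],
          if (length(r) >= 3) r[3] else "9606",
          if (length(r) >= 4) r[4] else "9606",
          "Two-hybrid", sep = "\t")
  }, "")
  writeLines(c(header, body), path)
  path
}

# small ontology: chain A is_a B is_a C within biological_process, plus an
# isolated term and an obsolete term
write_obo_fixture <- function(path = tempfile(fileext = ".obo")) {
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:C", "name: root", "namespace: biological_process", "",
    "[Term]", "id: GO:B", "name: mid", "namespace: biological_process",
    "is_a: GO:C ! root", "",
    "[Term]", "id: GO:A", "name: leaf", "namespace: biological_process",
    "is_a: GO:B ! mid", "",
    "[Term]", "id: GO:PO", "name: part", "namespace: cellular_component",
    "relationship: part_of GO:C ! via part_of", "",
    "[Term]", "id: GO:LONE", "name: isolated", "namespace: molecular_function", "",
    "[Term]", "id: GO:OBS", "name: gone", "namespace: biological_process",
    "is_obsolete: true", ""
  ), path)
  path
}

# GAF 2.2 rows: list of c(gene, term, evidence[, qualifier])
write_gaf_fixture <- function(rows, path = tempfile(fileext = ".gaf")) {
  body <- vapply(rows, function(r) {
    paste("SIM", r[1], r[1], if (length(r) >= 4) r[4] else "involved_in",
          r[2], "SIM_REF:1", r[3], "", "P", "", "", "protein",
          "taxon:9606", "20260101", "SIM", "", "", sep = "\t")
  }, "")
  writeLines(c("!gaf-version: 2.2", body), path)
  path
}

# synthetic stand-in biomarker lists at given unique sizes, with planted
# duplicate, case-variant, whitespace and comment noise
write_standin_list <- function(n_unique, path = tempfile(fileext = ".txt"),
                               seed = 1L) {
  set.seed(seed)
  ids <- sprintf("MARKER%04d", seq_len(n_unique))
  noisy <- c(ids,
             tolower(sample(ids, min(5, n_unique))),     # case duplicates
             paste0("  ", sample(ids, min(5, n_unique)), " "),  # whitespace dups
             sample(ids, min(3, n_unique)))              # exact duplicates
  noisy <- sample(noisy)
  writeLines(c("# synthetic stand-in biomarker list", noisy, "", ""), path)
  path
}
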