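#' Interaction-table container
#'
#' Wraps a data frame of interaction records together with the dialect used
#' to read it and row-count provenance. The invariant
#' `read == kept + discarded` is enforced at construction.
#'
#' @param records data frame with columns `interaction_id`, `nc_name`,
#'   `nc_type`, `target_name`, `target_type`, `organism`, `evidence_class`,
#'   `source`.
#' @param dialect name of the column mapping used.
#' @param provenance list with `path`, `read`, `kept`, `discarded`, and a
#'   named integer vector `reasons` breaking down the discards.
#' @return an object of class `interaction_table`.
#' @export
interaction_table <- function(records, dialect = "manual",
                              provenance = list(path = NA_character_,
                                                read = nrow(records),
                                                kept = nrow(records),
                                                discarded = 0L,
                                                reasons = integer())) {
  stopifnot(is.data.frame(records))
  needed <- c("interaction_id", "nc_name", "nc_type", "target_name",
              "target_type", "organism", "evidence_class", "source")
  missing <- setdiff(needed, names(records))
  for (m in missing) records[[m]] <- NA_character_
  if (provenance$read != provenance$kept + provenance$discarded) {
    stop("interaction_table provenance violated: read != kept + discarded")
  }
  structure(
    list(records = records, dialect = dialect, provenance = provenance),
    class = "interaction_table"
  )
}

#' @export
print.interaction_table <- function(x, ...) {
  cat(sprintf("<interaction_table> %d records (dialect: %s)\n",
              nrow(x$records), x$dialect))
  cat(sprintf("  provenance: read %d, kept %d, discarded %d\n",
              x$provenance$read, x$provenance$kept, x$provenance$discarded))
  invisible(x)
}

read_tsv_raw <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character",
                    na.strings = NULL)
}

#' Read an NPInter-style ncRNA interaction table
#'
#' Reads a tab-separated interaction table in the column layout described by
#' `dialect` (defaults to the NPInter V5.0 header names), maps raw molecule
#' types onto the canonical vocabulary (`miRNA`/`lncRNA`/`other` for the
#' ncRNA side; `mRNA`/`protein`/`miRNA`/`lncRNA`/`other` for the target
#' side), and optionally restricts to one organism. Unrecognized type labels
#' are mapped to `"other"`, never dropped at read time; malformed rows
#' (empty molecule names) are counted as discarded with a reason, never
#' fatal.
#'
#' @param path path to the tab-separated file (header row required).
#' @param dialect an [npinter_dialect()] describing the column layout.
#' @param organism_filter species label matched case-insensitively against
#'   the organism column, or `NULL` to keep all organisms.
#' @param evidence_filter optional character vector of accepted
#'   `evidence_class` values (case-insensitive); `NULL` keeps every row.
#' @return an [interaction_table()].
#' @export
read_npinter <- function(path, dialect = npinter_dialect(),
                         organism_filter = "Homo sapiens",
                         evidence_filter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read_tsv_raw(path)
  need_cols <- unlist(dialect$columns[dialect$required])
  absent <- setdiff(need_cols, names(raw))
  if (length(absent) > 0) {
    stop(sprintf("dialect '%s': required column(s) missing from %s: %s",
                 dialect$name, path, paste(absent, collapse = ", ")))
  }
  pull <- function(field) {
    col <- dialect$columns[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else rep(NA_character_, nrow(raw))
  }
  rec <- data.frame(
    interaction_id = pull("interaction_id"),
    nc_name        = trimws(pull("nc_name")),
    nc_type        = map_type(pull("nc_type"), dialect$nc_type_map),
    target_name    = trimws(pull("target_name")),
    target_type    = map_type(pull("target_type"), dialect$target_type_map),
    organism       = pull("organism"),
    evidence_class = pull("evidence_class"),
    source         = pull("source"),
    stringsAsFactors = FALSE
  )
  n_read <- nrow(rec)
  reasons <- integer()
  keep <- rep(TRUE, n_read)

  bad_name <- !nzchar(rec$nc_name) | !nzchar(rec$target_name)
  if (any(bad_name)) reasons["empty identifier"] <- sum(bad_name)
  keep <- keep & !bad_name

  if (!is.null(organism_filter)) {
    off <- keep & !(tolower(trimws(rec$organism)) %in% tolower(trimws(organism_filter)))
    if (any(off)) reasons["organism filter"] <- sum(off)
    keep <- keep & !off
  }
  if (!is.null(evidence_filter)) {
    off <- keep & !(tolower(trimws(rec$evidence_class)) %in% tolower(trimws(evidence_filter)))
    if (any(off)) reasons["evidence filter"] <- sum(off)
    keep <- keep & !off
  }

  kept <- rec[keep, , drop = FALSE]
  rownames(kept) <- NULL
  interaction_table(
    kept, dialect = dialect$name,
    provenance = list(path = path, read = n_read, kept = nrow(kept),
                      discarded = n_read - nrow(kept), reasons = reasons)
  )
}

#' Read a plain-text biomarker list
#'
#' One identifier per line; blank lines and lines starting with `#` are
#' ignored. Members are deduplicated under case-folded, whitespace-stripped
#' comparison, keeping the first-seen spelling.
#'
#' @param path path to the list file.
#' @param role,label passed to [gene_set()].
#' @return a [gene_set()].
#' @export
read_gene_list <- function(path, role = "seed", label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    warning("gene list is empty: ", path)
  }
  gene_set(lines, role = role, label = label)
}

#' Read a BioGRID tab3 interaction table
#'
#' Keeps rows where both interactors pass the organism filter, uses official
#' gene symbols as the molecule names, sets both molecule types to
#' `"protein"` (BioGRID records gene-gene and protein-protein interactions),
#' and flags self-pairs in a `self_interaction` column rather than dropping
#' them.
#'
#' @param path path to a BioGRID tab3 tab-separated file.
#' @param organism_filter NCBI taxonomy id (e.g. `"9606"`) matched against
#'   the `Organism ID Interactor` columns, or an organism name matched
#'   case-insensitively against the `Organism Name Interactor` columns when
#'   those are present. `NULL` keeps all rows.
#' @return an [interaction_table()] whose records carry an extra
#'   `self_interaction` logical column.
#' @export
read_biogrid <- function(path, organism_filter = "9606") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read_tsv_raw(path)
  sym_a <- "Official Symbol Interactor A"
  sym_b <- "Official Symbol Interactor B"
  org_a <- "Organism ID Interactor A"
  org_b <- "Organism ID Interactor B"
  absent <- setdiff(c(sym_a, sym_b), names(raw))
  if (length(absent) > 0) {
    stop("not a BioGRID tab3 file (missing column(s): ",
         paste(absent, collapse = ", "), "): ", path)
  }
  n_read <- nrow(raw)
  reasons <- integer()
  keep <- rep(TRUE, n_read)

  a <- trimws(raw[[sym_a]])
  b <- trimws(raw[[sym_b]])
  bad_name <- !nzchar(a) | !nzchar(b) | a == "-" | b == "-"
  if (any(bad_name)) reasons["empty identifier"] <- sum(bad_name)
  keep <- keep & !bad_name

  if (!is.null(organism_filter)) {
    filt <- trimws(as.character(organism_filter))
    if (grepl("^[0-9]+$", filt)) {
      if (!all(c(org_a, org_b) %in% names(raw))) {
        stop("not a BioGRID tab3 file (missing organism id columns): ", path)
      }
      ok <- trimws(raw[[org_a]]) == filt & trimws(raw[[org_b]]) == filt
    } else {
      name_a <- "Organism Name Interactor A"
      name_b <- "Organism Name Interactor B"
      if (!all(c(name_a, name_b) %in% names(raw))) {
        stop("organism name filter requires the 'Organism Name Interactor' ",
             "columns; pass a taxonomy id instead: ", path)
      }
      ok <- tolower(trimws(raw[[name_a]])) == tolower(filt) &
        tolower(trimws(raw[[name_b]])) == tolower(filt)
    }
    off <- keep & !ok
    if (any(off)) reasons["organism filter"] <- sum(off)
    keep <- keep & !off
  }

  rec <- data.frame(
    interaction_id = if ("#BioGRID Interaction ID" %in% names(raw))
      raw[["#BioGRID Interaction ID"]] else rep(NA_character_, n_read),
    nc_name = a, nc_type = rep("protein", n_read),
    target_name = b, target_type = rep("protein", n_read),
    organism = if (org_a %in% names(raw)) raw[[org_a]] else rep(NA_character_, n_read),
    evidence_class = if ("Experimental System" %in% names(raw))
      raw[["Experimental System"]] else rep(NA_character_, n_read),
    source = rep("biogrid", n_read),
    self_interaction = norm_id(a) == norm_id(b),
    stringsAsFactors = FALSE
  )
  kept <- rec[keep, , drop = FALSE]
  rownames(kept) <- NULL
  interaction_table(
    kept, dialect = "biogrid_tab3",
    provenance = list(path = path, read = n_read, kept = nrow(kept),
                      discarded = n_read - nrow(kept), reasons = reasons)
  )
}

#' Read an expression-state file
#'
#' Two tab-separated columns: identifier and state (`expressed` or `down`).
#' Lines starting with `#` are ignored.
#'
#' @param path path to the state file.
#' @return named character vector of states, names are identifiers.
#' @export
read_state_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0) return(stats::setNames(character(), character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- trimws(vapply(parts, `[`, "", 1L))
  states <- trimws(vapply(parts, function(p) if (length(p) >= 2) p[2L] else "", ""))
  bad <- !states %in% c("expressed", "down")
  if (any(bad)) {
    stop("invalid state(s) in ", path, ": ",
         paste(unique(states[bad]), collapse = ", "),
         " (expected 'expressed' or 'down')")
  }
  stats::setNames(states, ids)
}

# relation label for an edge given its endpoint node types; seeds are mRNA
# (or protein) biomarkers, so the exported relation labels use "mRNA"
relation_label <- function(type_a, type_b) {
  lab <- function(t) if (t == "seed") "mRNA" else t
  order3 <- c(mRNA = 1L, miRNA = 2L, lncRNA = 3L)
  ts <- c(lab(type_a), lab(type_b))
  ts <- ts[order(order3[ts])]
  paste(ts, collapse = "-")
}

#' Export a tripartite network as Cytoscape-importable tables
#'
#' Writes three files into `out_dir`: `network.sif` (simple interaction
#' format with relation labels `mRNA-miRNA`, `miRNA-lncRNA`, `mRNA-lncRNA`),
#' `nodes.tsv` (id, node_type, degree, is_seed) and `edges.tsv` (source,
#' target, relation, evidence_count). Re-reading the pair with
#' [read_network()] reconstructs an isomorphic network.
#'
#' @param network a [tripartite_network()].
#' @param out_dir output directory, created if needed.
#' @return invisibly, the character vector of files written.
#' @export
write_network <- function(network, out_dir) {
  stopifnot(inherits(network, "tripartite_network"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- network$nodes
  edges <- network$edges
  type_of <- stats::setNames(nodes$node_type, nodes$id)

  sif_path <- file.path(out_dir, "network.sif")
  if (nrow(edges) > 0) {
    rel <- mapply(relation_label, type_of[edges$from], type_of[edges$to])
    writeLines(paste(edges$from, rel, edges$to, sep = "\t"), sif_path)
  } else {
    writeLines(character(), sif_path)
  }

  deg <- node_degrees(network)
  node_tab <- data.frame(
    id = nodes$id,
    node_type = nodes$node_type,
    degree = unname(deg[nodes$id]),
    is_seed = nodes$node_type == "seed",
    stringsAsFactors = FALSE
  )
  nodes_path <- file.path(out_dir, "nodes.tsv")
  utils::write.table(node_tab, nodes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  edge_tab <- data.frame(
    source = edges$from,
    target = edges$to,
    relation = if (nrow(edges) > 0)
      mapply(relation_label, type_of[edges$from], type_of[edges$to]) else character(),
    evidence_count = edges$evidence_count,
    stringsAsFactors = FALSE
  )
  edges_path <- file.path(out_dir, "edges.tsv")
  utils::write.table(edge_tab, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(c(sif = sif_path, nodes = nodes_path, edges = edges_path))
}

#' Re-import a network written by [write_network()]
#'
#' @param dir directory containing `nodes.tsv` and `edges.tsv`.
#' @return a [tripartite_network()].
#' @export
read_network <- function(dir) {
  nodes <- utils::read.delim(file.path(dir, "nodes.tsv"), sep = "\t",
                             stringsAsFactors = FALSE, colClasses = "character")
  edges <- utils::read.delim(file.path(dir, "edges.tsv"), sep = "\t",
                             stringsAsFactors = FALSE)
  seed_ids <- nodes$id[nodes$node_type == "seed"]
  tripartite_network(
    nodes = data.frame(id = nodes$id, node_type = nodes$node_type,
                       stringsAsFactors = FALSE),
    edges = data.frame(from = as.character(edges$source),
                       to = as.character(edges$target),
                       evidence_count = as.integer(edges$evidence_count),
                       stringsAsFactors = FALSE),
    seed_set = gene_set(seed_ids, role = "seed", label = "reimported")
  )
}
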