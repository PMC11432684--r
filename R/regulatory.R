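#' Detect lncRNA-governed miRNA blocks
#'
#' A miRNA block is a maximal set of "seedless" miRNAs — miRNAs with no edge
#' to any seed node — held together by shared governing lncRNAs. Blocks are
#' computed as connected components of the bipartite subgraph induced on the
#' lncRNA nodes and the seedless miRNA nodes; a component qualifies when it
#' contains at least `min_size` miRNAs. Governors are the component's
#' lncRNAs, ranked by their degree into the block.
#'
#' @param network a [tripartite_network()].
#' @param min_size minimum number of miRNAs for a component to count as a
#'   block.
#' @return list of `mirna_block` objects, largest block first. Each has
#'   elements `mirnas` (character), `governors` (named integer vector of
#'   within-block degrees, decreasing).
#' @export
detect_mirna_blocks <- function(network, min_size = 5L) {
  stopifnot(inherits(network, "tripartite_network"))
  if (!is.numeric(min_size) || min_size < 1) stop("min_size must be >= 1")
  type_of <- stats::setNames(network$nodes$node_type, network$nodes$id)
  e <- network$edges
  if (nrow(e) == 0) return(list())

  seed_adjacent <- unique(c(e$from[type_of[e$to] == "seed"],
                            e$to[type_of[e$from] == "seed"]))
  mirnas <- network$nodes$id[network$nodes$node_type == "miRNA"]
  seedless <- setdiff(mirnas, seed_adjacent)
  lncs <- network$nodes$id[network$nodes$node_type == "lncRNA"]

  keep <- (e$from %in% seedless & e$to %in% lncs) |
          (e$to %in% seedless & e$from %in% lncs)
  sub <- e[keep, , drop = FALSE]
  if (nrow(sub) == 0) return(list())

  g <- igraph::graph_from_data_frame(sub[, c("from", "to")], directed = FALSE,
                                     vertices = unique(c(sub$from, sub$to)))
  comp <- igraph::components(g)
  membership <- comp$membership

  blocks <- list()
  for (cid in seq_len(comp$no)) {
    ids <- names(membership)[membership == cid]
    block_mirnas <- intersect(ids, seedless)
    if (length(block_mirnas) < min_size) next
    block_lncs <- intersect(ids, lncs)
    gov_deg <- vapply(block_lncs, function(l) {
      sum((sub$from == l & sub$to %in% block_mirnas) |
          (sub$to == l & sub$from %in% block_mirnas))
    }, integer(1))
    gov_deg <- sort(gov_deg, decreasing = TRUE)
    blocks[[length(blocks) + 1L]] <- structure(
      list(mirnas = sort(block_mirnas), governors = gov_deg),
      class = "mirna_block"
    )
  }
  blocks[order(vapply(blocks, function(b) length(b$mirnas), integer(1)),
               decreasing = TRUE)]
}

#' @export
print.mirna_block <- function(x, ...) {
  cat(sprintf("<mirna_block> %d miRNAs, governors: %s\n", length(x$mirnas),
              paste(sprintf("%s (%d)", names(x$governors), x$governors),
                    collapse = ", ")))
  invisible(x)
}

#' Reverse query: genes governed through block-linked lncRNAs
#'
#' Finds every lncRNA in the interaction table that interacts with at least
#' `min_links` distinct miRNAs of the block, then returns all mRNA and
#' protein partners of those lncRNAs. This is the search for genes affected
#' by lncRNAs that are themselves governed by multiple block miRNAs.
#'
#' @param table an [interaction_table()].
#' @param block a `mirna_block` (or any list with a `mirnas` element), or a
#'   character vector of miRNA names.
#' @param min_links minimum number of distinct block miRNAs an lncRNA must
#'   bind to qualify.
#' @return a [gene_set()] with role `"governed"`; the qualifying lncRNAs are
#'   attached as attribute `"linking_lncrnas"` (named integer vector of
#'   distinct block-miRNA link counts).
#' @export
governed_genes <- function(table, block, min_links = 2L) {
  stopifnot(inherits(table, "interaction_table"))
  block_mirnas <- if (is.character(block)) block else block$mirnas
  if (!is.numeric(min_links) || min_links < 1) stop("min_links must be >= 1")
  block_keys <- unique(norm_id(block_mirnas))
  rec <- table$records
  if (length(block_keys) == 0 || nrow(rec) == 0) {
    return(gene_set(role = "governed", label = "governed genes"))
  }
  disp <- display_map(c(rec$nc_name, rec$target_name))

  # lncRNA endpoint paired with a block miRNA endpoint (either orientation)
  lnc_a <- rec$nc_type == "lncRNA"
  lnc_b <- rec$target_type == "lncRNA"
  akey <- norm_id(rec$nc_name); bkey <- norm_id(rec$target_name)
  mir_a <- rec$nc_type == "miRNA" & akey %in% block_keys
  mir_b <- rec$target_type == "miRNA" & bkey %in% block_keys

  lnc_mir <- rbind(
    data.frame(lnc = akey[lnc_a & mir_b], mir = bkey[lnc_a & mir_b],
               stringsAsFactors = FALSE),
    data.frame(lnc = bkey[lnc_b & mir_a], mir = akey[lnc_b & mir_a],
               stringsAsFactors = FALSE)
  )
  if (nrow(lnc_mir) == 0) {
    return(gene_set(role = "governed", label = "governed genes"))
  }
  lnc_mir <- unique(lnc_mir)
  link_counts <- table(lnc_mir$lnc)
  qualifying <- names(link_counts)[as.integer(link_counts) >= min_links]
  if (length(qualifying) == 0) {
    return(gene_set(role = "governed", label = "governed genes"))
  }

  gene_a <- rec$nc_type %in% c("mRNA", "protein")
  gene_b <- rec$target_type %in% c("mRNA", "protein")
  partners <- unique(c(rec$target_name[akey %in% qualifying & lnc_a & gene_b],
                       rec$nc_name[bkey %in% qualifying & lnc_b & gene_a]))

  out <- gene_set(partners, role = "governed", label = "governed genes")
  lc <- as.integer(link_counts[qualifying])
  names(lc) <- unname(disp[qualifying])
  attr(out, "linking_lncrnas") <- sort(lc, decreasing = TRUE)
  out
}

#' Propagate binary expression-state hypotheses through the network
#'
#' Encodes competing-endogenous-RNA (sponge) logic: an expressed lncRNA
#' sequesters its neighboring miRNAs, and an unsponged (active) miRNA
#' represses its neighboring seed genes. Starting from a partial assignment
#' of lncRNA states, unassigned lncRNAs default to `"expressed"`; each miRNA
#' becomes `"sponged"` if any neighboring lncRNA is expressed and `"active"`
#' otherwise (a miRNA with no lncRNA neighbor is active); each seed gene
#' becomes `"repressed"` if any neighboring miRNA is active and
#' `"uninhibited"` otherwise. Direct seed-lncRNA edges are not propagated
#' through; they are reported in `unresolved_edges` for manual review. The
#' result does not depend on node iteration order.
#'
#' @param network a [tripartite_network()].
#' @param assigned named character vector: lncRNA node id -> `"expressed"` or
#'   `"down"`.
#' @return object of class `state_map` with elements `lncRNA_states`,
#'   `mirna_states`, `gene_states` (named character vectors) and
#'   `unresolved_edges` (data frame of seed-lncRNA pairs).
#' @export
propagate_states <- function(network, assigned = character()) {
  stopifnot(inherits(network, "tripartite_network"))
  type_of <- stats::setNames(network$nodes$node_type, network$nodes$id)
  lncs <- network$nodes$id[network$nodes$node_type == "lncRNA"]
  mirs <- network$nodes$id[network$nodes$node_type == "miRNA"]
  genes <- network$nodes$id[network$nodes$node_type == "seed"]

  if (length(assigned) > 0) {
    unknown <- setdiff(names(assigned), lncs)
    if (length(unknown) > 0) {
      stop("assigned state for identifier(s) not lncRNA nodes of the network: ",
           paste(unknown, collapse = ", "))
    }
    bad <- !assigned %in% c("expressed", "down")
    if (any(bad)) stop("invalid state(s): ", paste(unique(assigned[bad]), collapse = ", "))
  }
  lnc_states <- stats::setNames(rep("expressed", length(lncs)), lncs)
  lnc_states[names(assigned)] <- assigned

  e <- network$edges
  et_from <- type_of[e$from]; et_to <- type_of[e$to]

  mir_lnc <- rbind(data.frame(mir = e$from[et_from == "miRNA" & et_to == "lncRNA"],
                              lnc = e$to[et_from == "miRNA" & et_to == "lncRNA"],
                              stringsAsFactors = FALSE),
                   data.frame(mir = e$to[et_to == "miRNA" & et_from == "lncRNA"],
                              lnc = e$from[et_to == "miRNA" & et_from == "lncRNA"],
                              stringsAsFactors = FALSE))
  sponged <- unique(mir_lnc$mir[lnc_states[mir_lnc$lnc] == "expressed"])
  mir_states <- stats::setNames(
    ifelse(mirs %in% sponged, "sponged", "active"), mirs)

  gene_mir <- rbind(data.frame(gene = e$from[et_from == "seed" & et_to == "miRNA"],
                               mir = e$to[et_from == "seed" & et_to == "miRNA"],
                               stringsAsFactors = FALSE),
                    data.frame(gene = e$to[et_to == "seed" & et_from == "miRNA"],
                               mir = e$from[et_to == "seed" & et_from == "miRNA"],
                               stringsAsFactors = FALSE))
  repressed <- unique(gene_mir$gene[mir_states[gene_mir$mir] == "active"])
  gene_states <- stats::setNames(
    ifelse(genes %in% repressed, "repressed", "uninhibited"), genes)

  sl <- (et_from == "seed" & et_to == "lncRNA") |
        (et_to == "seed" & et_from == "lncRNA")
  unresolved <- data.frame(
    seed = ifelse(et_from[sl] == "seed", e$from[sl], e$to[sl]),
    lncRNA = ifelse(et_from[sl] == "lncRNA", e$from[sl], e$to[sl]),
    stringsAsFactors = FALSE
  )

  structure(
    list(lncRNA_states = lnc_states, mirna_states = mir_states,
         gene_states = gene_states, unresolved_edges = unresolved),
    class = "state_map"
  )
}

#' @export
print.state_map <- function(x, ...) {
  cat(sprintf("<state_map> %d lncRNA (%d down), %d miRNA (%d active), %d genes (%d repressed); %d unresolved seed-lncRNA edges\n",
              length(x$lncRNA_states), sum(x$lncRNA_states == "down"),
              length(x$mirna_states), sum(x$mirna_states == "active"),
              length(x$gene_states), sum(x$gene_states == "repressed"),
              nrow(x$unresolved_edges)))
  invisible(x)
}
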