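#' Tripartite mRNA-miRNA-lncRNA network container
#'
#' A typed undirected graph over seed-gene, miRNA and lncRNA nodes. Edges are
#' unordered node pairs carrying an `evidence_count` (number of supporting
#' interaction rows). Only the three endpoint-type pairs that make up a
#' regulatory axis are allowed: seed-miRNA, seed-lncRNA and miRNA-lncRNA;
#' seed-seed, miRNA-miRNA and lncRNA-lncRNA edges are rejected.
#'
#' @param nodes data frame with columns `id`, `node_type`
#'   (`seed`/`miRNA`/`lncRNA`).
#' @param edges data frame with columns `from`, `to`, `evidence_count`.
#' @param seed_set the [gene_set()] the network was anchored on.
#' @param threshold_applied the last occurrence threshold applied (0 if none).
#' @return object of class `tripartite_network`.
#' @export
tripartite_network <- function(nodes = data.frame(id = character(),
                                                  node_type = character(),
                                                  stringsAsFactors = FALSE),
                               edges = data.frame(from = character(),
                                                  to = character(),
                                                  evidence_count = integer(),
                                                  stringsAsFactors = FALSE),
                               seed_set = gene_set(),
                               threshold_applied = 0L) {
  stopifnot(all(c("id", "node_type") %in% names(nodes)),
            all(c("from", "to", "evidence_count") %in% names(edges)))
  if (anyDuplicated(nodes$id)) {
    stop("duplicate node ids: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  }
  bad_type <- setdiff(unique(nodes$node_type), c("seed", "miRNA", "lncRNA"))
  if (length(bad_type) > 0) stop("invalid node types: ", paste(bad_type, collapse = ", "))

  if (nrow(edges) > 0) {
    # canonical unordered representation: endpoints sorted lexicographically
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]; edges$to[swap] <- tmp
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL

    missing <- setdiff(c(edges$from, edges$to), nodes$id)
    if (length(missing) > 0) {
      stop("edge endpoints missing from node set: ", paste(missing, collapse = ", "))
    }
    type_of <- stats::setNames(nodes$node_type, nodes$id)
    pair <- paste(pmin(type_of[edges$from], type_of[edges$to]),
                  pmax(type_of[edges$from], type_of[edges$to]), sep = "|")
    allowed <- c("miRNA|seed", "lncRNA|seed", "lncRNA|miRNA")
    if (any(!pair %in% allowed)) {
      stop("disallowed edge type pair(s): ",
           paste(unique(pair[!pair %in% allowed]), collapse = ", "))
    }
    if (any(edges$evidence_count < 1)) stop("evidence_count must be >= 1 on every edge")
    if (anyDuplicated(paste(edges$from, edges$to))) stop("duplicate edges")
  }
  structure(
    list(nodes = nodes, edges = edges, seed_set = seed_set,
         threshold_applied = as.integer(threshold_applied)),
    class = "tripartite_network"
  )
}

#' @export
print.tripartite_network <- function(x, ...) {
  tab <- table(factor(x$nodes$node_type, levels = c("seed", "miRNA", "lncRNA")))
  cat(sprintf("<tripartite_network> %d nodes (%d seed, %d miRNA, %d lncRNA), %d edges\n",
              nrow(x$nodes), tab[["seed"]], tab[["miRNA"]], tab[["lncRNA"]],
              nrow(x$edges)))
  if (x$threshold_applied > 0)
    cat(sprintf("  occurrence threshold applied: %d\n", x$threshold_applied))
  invisible(x)
}

#' Distinct-neighbor degree of every node
#'
#' @param network a [tripartite_network()].
#' @return named integer vector over all node ids (isolated nodes get 0).
#' @export
node_degrees <- function(network) {
  deg <- stats::setNames(integer(nrow(network$nodes)), network$nodes$id)
  if (nrow(network$edges) > 0) {
    cnt <- table(c(network$edges$from, network$edges$to))
    deg[names(cnt)] <- as.integer(cnt)
  }
  deg
}

# adjacency list: id -> character vector of neighbor ids
adjacency_list <- function(network) {
  adj <- stats::setNames(vector("list", nrow(network$nodes)), network$nodes$id)
  for (i in seq_along(adj)) adj[[i]] <- character()
  e <- network$edges
  if (nrow(e) > 0) {
    adj_from <- split(e$to, e$from)
    adj_to <- split(e$from, e$to)
    for (n in names(adj_from)) adj[[n]] <- c(adj[[n]], adj_from[[n]])
    for (n in names(adj_to)) adj[[n]] <- c(adj[[n]], adj_to[[n]])
  }
  adj
}

# occurrence count per node: distinct neighbors or total supporting rows
occurrence_counts <- function(network, mode = c("degree", "rows")) {
  mode <- match.arg(mode)
  if (mode == "degree") return(node_degrees(network))
  occ <- stats::setNames(integer(nrow(network$nodes)), network$nodes$id)
  e <- network$edges
  if (nrow(e) > 0) {
    s <- tapply(c(e$evidence_count, e$evidence_count), c(e$from, e$to), sum)
    occ[names(s)] <- as.integer(s)
  }
  occ
}

# keep a subset of node ids, dropping edges with a removed endpoint
subset_network <- function(network, keep_ids, threshold_applied = NULL) {
  nodes <- network$nodes[network$nodes$id %in% keep_ids, , drop = FALSE]
  e <- network$edges
  e <- e[e$from %in% nodes$id & e$to %in% nodes$id, , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(e) <- NULL
  tripartite_network(
    nodes, e, seed_set = network$seed_set,
    threshold_applied = if (is.null(threshold_applied)) network$threshold_applied
                        else threshold_applied
  )
}

# turn an interaction table into typed endpoint pairs; seeds are matched by
# normalized name on mRNA/protein endpoints (the two are one seed-matchable
# class), miRNA/lncRNA endpoints by their declared type
classify_pairs <- function(table, seeds, primary_nc, secondary_nc) {
  rec <- table$records
  classify <- function(name, type) {
    out <- rep("other", length(name))
    out[type %in% c("mRNA", "protein") & norm_id(name) %in% norm_id(seeds$members)] <- "seed"
    out[type == primary_nc] <- "primary"
    out[type == secondary_nc] <- "secondary"
    out
  }
  data.frame(
    a_name = rec$nc_name, a_class = classify(rec$nc_name, rec$nc_type),
    b_name = rec$target_name, b_class = classify(rec$target_name, rec$target_type),
    stringsAsFactors = FALSE
  )
}

# first-seen display spelling for each normalized key
display_map <- function(names) {
  key <- norm_id(names)
  first <- !duplicated(key)
  stats::setNames(names[first], key[first])
}

#' Build the seed-anchored tripartite network
#'
#' Two-step extraction from an interaction table. Step 1 keeps every
#' primary-type ncRNA (miRNA by default) with at least one interaction to a
#' seed. Step 2 keeps every secondary-type ncRNA (lncRNA by default) with at
#' least one interaction to a seed and at least one to any primary-type
#' molecule. Step 3 extends the primary set with the primary-type neighbors
#' of the retained secondary molecules, which is what lets miRNA blocks with
#' no seed contact enter the network through their governing lncRNAs. Nodes
#' are the seeds with at least one retained edge plus both ncRNA sets; edges
#' are all table rows among retained nodes, collapsed to unique pairs with
#' the supporting row count as `evidence_count`.
#'
#' @param table an [interaction_table()].
#' @param seeds a [gene_set()] of genes/proteins of interest.
#' @param primary_nc,secondary_nc canonical ncRNA types for the two
#'   extraction steps (defaults `"miRNA"` and `"lncRNA"`).
#' @return a [tripartite_network()].
#' @export
build_axis <- function(table, seeds, primary_nc = "miRNA", secondary_nc = "lncRNA") {
  stopifnot(inherits(table, "interaction_table"), inherits(seeds, "gene_set"))
  pairs <- classify_pairs(table, seeds, primary_nc, secondary_nc)
  disp <- display_map(c(pairs$a_name, pairs$b_name))

  akey <- norm_id(pairs$a_name); bkey <- norm_id(pairs$b_name)
  acl <- pairs$a_class; bcl <- pairs$b_class

  seed_hit <- function(cl_self, cl_other) cl_self != "seed" & cl_other == "seed"
  # step 1: primary molecules adjacent to a seed
  m0 <- unique(c(akey[acl == "primary" & bcl == "seed"],
                 bkey[bcl == "primary" & acl == "seed"]))
  # step 2: secondary molecules adjacent to a seed AND to any primary molecule
  sec_seed <- unique(c(akey[acl == "secondary" & bcl == "seed"],
                       bkey[bcl == "secondary" & acl == "seed"]))
  sec_prim <- unique(c(akey[acl == "secondary" & bcl == "primary"],
                       bkey[bcl == "secondary" & acl == "primary"]))
  lset <- intersect(sec_seed, sec_prim)
  # step 3: extend with primary neighbors of retained secondary molecules
  m_ext <- unique(c(akey[acl == "primary" & bcl == "secondary" & bkey %in% lset],
                    bkey[bcl == "primary" & acl == "secondary" & akey %in% lset]))
  mset <- union(m0, m_ext)

  if (length(m0) == 0 && length(sec_seed) == 0) {
    warning("no seed matches any interaction row; unmatched seeds: ",
            paste(seeds$members, collapse = ", "))
    return(tripartite_network(seed_set = seeds))
  }

  node_class <- function(key, cl) {
    ifelse(cl == "seed", "seed",
           ifelse(cl == "primary" & key %in% mset, "miRNA",
                  ifelse(cl == "secondary" & key %in% lset, "lncRNA", NA_character_)))
  }
  a_nt <- node_class(akey, acl)
  b_nt <- node_class(bkey, bcl)
  allowed <- c("seed|miRNA", "seed|lncRNA", "miRNA|lncRNA")
  pair_lab <- paste(pmin(a_nt, b_nt), pmax(a_nt, b_nt), sep = "|")
  pair_lab2 <- paste(pmax(a_nt, b_nt), pmin(a_nt, b_nt), sep = "|")
  row_ok <- !is.na(a_nt) & !is.na(b_nt) &
    (pair_lab %in% allowed | pair_lab2 %in% allowed) & akey != bkey

  ek_from <- pmin(akey[row_ok], bkey[row_ok])
  ek_to <- pmax(akey[row_ok], bkey[row_ok])
  if (length(ek_from) > 0) {
    tab <- table(paste(ek_from, ek_to, sep = "\r"))
    pp <- strsplit(names(tab), "\r", fixed = TRUE)
    edges <- data.frame(
      from = unname(disp[vapply(pp, `[`, "", 1L)]),
      to = unname(disp[vapply(pp, `[`, "", 2L)]),
      evidence_count = as.integer(tab),
      stringsAsFactors = FALSE
    )
  } else {
    edges <- data.frame(from = character(), to = character(),
                        evidence_count = integer(), stringsAsFactors = FALSE)
  }

  # seeds enter only when they carry a retained edge; ncRNA sets enter as-is
  seed_keys <- unique(c(akey[row_ok][a_nt[row_ok] == "seed"],
                        bkey[row_ok][b_nt[row_ok] == "seed"]))
  node_keys <- c(seed_keys, mset, lset)
  node_types <- c(rep("seed", length(seed_keys)),
                  rep("miRNA", length(mset)),
                  rep("lncRNA", length(lset)))
  dup <- duplicated(node_keys)  # name reused across classes: first class wins
  if (any(dup)) {
    warning("identifier(s) retained under two molecule classes, keeping first: ",
            paste(unique(disp[node_keys[dup]]), collapse = ", "))
  }
  nodes <- data.frame(id = unname(disp[node_keys[!dup]]),
                      node_type = node_types[!dup], stringsAsFactors = FALSE)

  net <- tripartite_network(nodes, edges, seed_set = seeds)
  if (length(seed_keys) < length(seeds$members)) {
    unmatched <- seeds$members[!norm_id(seeds$members) %in% seed_keys]
    message(sprintf("build_axis: %d of %d seeds retained (%d without retained edges)",
                    length(seed_keys), length(seeds$members), length(unmatched)))
  }
  net
}

#' Occurrence-threshold filtering
#'
#' Removes, in a single pass, every node in `scope` whose occurrence count is
#' below `k`, along with its edges. Occurrence is the number of distinct
#' neighbors (`mode = "degree"`, the default) or the total number of
#' supporting interaction rows (`mode = "rows"`). At threshold `k`, markers
#' occurring `k` or more times are retained. The scope defaults to the ncRNA
#' layers; seeds then drop out only indirectly, through edge loss and
#' subsequent pruning.
#'
#' @param network a [tripartite_network()].
#' @param k positive integer threshold.
#' @param mode `"degree"` or `"rows"`.
#' @param scope character vector of node types the threshold applies to
#'   (subset of `seed`, `miRNA`, `lncRNA`).
#' @return filtered [tripartite_network()] with `threshold_applied = k`.
#' @export
threshold_filter <- function(network, k, mode = c("degree", "rows"),
                             scope = c("miRNA", "lncRNA")) {
  stopifnot(inherits(network, "tripartite_network"))
  if (!is.numeric(k) || length(k) != 1 || k < 1) stop("threshold k must be >= 1")
  mode <- match.arg(mode)
  scope <- match.arg(scope, c("seed", "miRNA", "lncRNA"), several.ok = TRUE)
  occ <- occurrence_counts(network, mode)
  in_scope <- network$nodes$node_type %in% scope
  expunge <- in_scope & occ[network$nodes$id] < k
  subset_network(network, network$nodes$id[!expunge], threshold_applied = as.integer(k))
}

#' Prune single-interactor nodes
#'
#' Removes nodes in scope that have exactly one distinct neighbor
#' (simultaneously, in one pass), then removes any node left with zero
#' neighbors. With `fixed_point = TRUE` the pass repeats until the network
#' stops changing. The default scope restricts the degree-one predicate to
#' seed nodes, which keeps chain-like ncRNA structures intact.
#'
#' @param network a [tripartite_network()].
#' @param scope `"seeds_only"` (default) or `"all_nodes"`.
#' @param fixed_point repeat until no change?
#' @return pruned [tripartite_network()].
#' @export
prune_single_interactors <- function(network, scope = c("seeds_only", "all_nodes"),
                                     fixed_point = FALSE) {
  stopifnot(inherits(network, "tripartite_network"))
  scope <- match.arg(scope)
  repeat {
    deg <- node_degrees(network)
    in_scope <- if (scope == "seeds_only") network$nodes$node_type == "seed"
                else rep(TRUE, nrow(network$nodes))
    drop1 <- in_scope & deg[network$nodes$id] == 1L
    step1 <- subset_network(network, network$nodes$id[!drop1])
    deg2 <- node_degrees(step1)
    step2 <- subset_network(step1, names(deg2)[deg2 > 0L])
    changed <- nrow(step2$nodes) != nrow(network$nodes)
    network <- step2
    if (!fixed_point || !changed) break
  }
  network
}
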