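# Independent brute-force reference implementations. These enumerate the
# rule definitions directly with explicit loops and deliberately share no
# code with the package.

key <- function(x) tolower(trimws(x))

# --- axis construction ------------------------------------------------------

bf_build_axis <- function(records, seed_names, primary = "miRNA",
                          secondary = "lncRNA") {
  seeds_k <- key(seed_names)
  role <- function(name, type) {
    if (type %in% c("mRNA", "protein") && key(name) %in% seeds_k) return("seed")
    if (type == primary) return("primary")
    if (type == secondary) return("secondary")
    "other"
  }
  n <- nrow(records)
  ra <- character(n); rb <- character(n)
  for (i in seq_len(n)) {
    ra[i] <- role(records$nc_name[i], records$nc_type[i])
    rb[i] <- role(records$target_name[i], records$target_type[i])
  }
  ka <- key(records$nc_name); kb <- key(records$target_name)

  m0 <- character()
  for (i in seq_len(n)) {
    if (ra[i] == "primary" && rb[i] == "seed") m0 <- union(m0, ka[i])
    if (rb[i] == "primary" && ra[i] == "seed") m0 <- union(m0, kb[i])
  }
  all_secondary <- unique(c(ka[ra == "secondary"], kb[rb == "secondary"]))
  lset <- character()
  for (l in all_secondary) {
    has_seed <- FALSE; has_primary <- FALSE
    for (i in seq_len(n)) {
      if (ka[i] == l && ra[i] == "secondary") {
        if (rb[i] == "seed") has_seed <- TRUE
        if (rb[i] == "primary") has_primary <- TRUE
      }
      if (kb[i] == l && rb[i] == "secondary") {
        if (ra[i] == "seed") has_seed <- TRUE
        if (ra[i] == "primary") has_primary <- TRUE
      }
    }
    if (has_seed && has_primary) lset <- c(lset, l)
  }
  mset <- m0
  for (i in seq_len(n)) {
    if (ra[i] == "primary" && rb[i] == "secondary" && kb[i] %in% lset)
      mset <- union(mset, ka[i])
    if (rb[i] == "primary" && ra[i] == "secondary" && ka[i] %in% lset)
      mset <- union(mset, kb[i])
  }

  node_type_of <- function(k, r) {
    if (r == "seed") return("seed")
    if (r == "primary" && k %in% mset) return("miRNA")
    if (r == "secondary" && k %in% lset) return("lncRNA")
    NA_character_
  }
  edge_counts <- list()
  seed_keys <- character()
  for (i in seq_len(n)) {
    ta <- node_type_of(ka[i], ra[i]); tb <- node_type_of(kb[i], rb[i])
    if (is.na(ta) || is.na(tb) || ta == tb || ka[i] == kb[i]) next
    if (ta == "seed") seed_keys <- union(seed_keys, ka[i])
    if (tb == "seed") seed_keys <- union(seed_keys, kb[i])
    pk <- paste(sort(c(ka[i], kb[i])), collapse = "\r")
    edge_counts[[pk]] <- if (is.null(edge_counts[[pk]])) 1L else edge_counts[[pk]] + 1L
  }
  nodes <- data.frame(id = character(), node_type = character(),
                      stringsAsFactors = FALSE)
  for (s in seed_keys) nodes <- rbind(nodes, data.frame(id = s, node_type = "seed"))
  for (m in mset) if (!m %in% nodes$id)
    nodes <- rbind(nodes, data.frame(id = m, node_type = "miRNA"))
  for (l in lset) if (!l %in% nodes$id)
    nodes <- rbind(nodes, data.frame(id = l, node_type = "lncRNA"))
  edges <- data.frame(from = character(), to = character(),
                      evidence_count = integer(), stringsAsFactors = FALSE)
  for (pk in names(edge_counts)) {
    pp <- strsplit(pk, "\r", fixed = TRUE)[[1]]
    edges <- rbind(edges, data.frame(from = pp[1], to = pp[2],
                                     evidence_count = edge_counts[[pk]]))
  }
  list(nodes = nodes, edges = edges)
}

# --- threshold filter -------------------------------------------------------

bf_occurrence <- function(net, node, mode) {
  if (mode == "degree") {
    nb <- character()
    for (i in seq_len(nrow(net$edges))) {
      if (net$edges$from[i] == node) nb <- union(nb, net$edges$to[i])
      if (net$edges$to[i] == node) nb <- union(nb, net$edges$from[i])
    }
    length(nb)
  } else {
    tot <- 0L
    for (i in seq_len(nrow(net$edges))) {
      if (net$edges$from[i] == node || net$edges$to[i] == node)
        tot <- tot + net$edges$evidence_count[i]
    }
    tot
  }
}

bf_threshold <- function(net, k, mode = "degree", scope = c("miRNA", "lncRNA")) {
  keep <- character()
  for (i in seq_len(nrow(net$nodes))) {
    id <- net$nodes$id[i]
    if (!net$nodes$node_type[i] %in% scope || bf_occurrence(net, id, mode) >= k)
      keep <- c(keep, id)
  }
  nodes <- net$nodes[net$nodes$id %in% keep, , drop = FALSE]
  edges <- net$edges[net$edges$from %in% keep & net$edges$to %in% keep, , drop = FALSE]
  list(nodes = nodes, edges = edges)
}

# --- single-interactor pruning ----------------------------------------------

bf_prune <- function(net, scope = "seeds_only", fixed_point = FALSE) {
  repeat {
    n_before <- nrow(net$nodes)
    drop <- character()
    for (i in seq_len(nrow(net$nodes))) {
      id <- net$nodes$id[i]
      in_scope <- scope == "all_nodes" || net$nodes$node_type[i] == "seed"
      if (in_scope && bf_occurrence(net, id, "degree") == 1L) drop <- c(drop, id)
    }
    keep <- setdiff(net$nodes$id, drop)
    nodes <- net$nodes[net$nodes$id %in% keep, , drop = FALSE]
    edges <- net$edges[net$edges$from %in% keep & net$edges$to %in% keep, , drop = FALSE]
    net <- list(nodes = nodes, edges = edges)
    keep2 <- character()
    for (id in net$nodes$id) {
      if (bf_occurrence(net, id, "degree") > 0L) keep2 <- c(keep2, id)
    }
    net <- list(
      nodes = net$nodes[net$nodes$id %in% keep2, , drop = FALSE],
      edges = net$edges
    )
    if (!fixed_point || nrow(net$nodes) == n_before) break
  }
  net
}

# --- miRNA blocks (hand-rolled BFS components) ------------------------------

bf_blocks <- function(net, min_size = 5L) {
  seed_ids <- net$nodes$id[net$nodes$node_type == "seed"]
  mir_ids <- net$nodes$id[net$nodes$node_type == "miRNA"]
  lnc_ids <- net$nodes$id[net$nodes$node_type == "lncRNA"]
  seedless <- character()
  for (m in mir_ids) {
    touches_seed <- FALSE
    for (i in seq_len(nrow(net$edges))) {
      o <- NULL
      if (net$edges$from[i] == m) o <- net$edges$to[i]
      if (net$edges$to[i] == m) o <- net$edges$from[i]
      if (!is.null(o) && o %in% seed_ids) touches_seed <- TRUE
    }
    if (!touches_seed) seedless <- c(seedless, m)
  }
  adj <- list()
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$from[i]; b <- net$edges$to[i]
    ok <- (a %in% seedless && b %in% lnc_ids) || (b %in% seedless && a %in% lnc_ids)
    if (ok) {
      adj[[a]] <- union(adj[[a]], b)
      adj[[b]] <- union(adj[[b]], a)
    }
  }
  unvisited <- names(adj)
  blocks <- list()
  while (length(unvisited) > 0) {
    queue <- unvisited[1]
    comp <- character()
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      queue <- c(queue, setdiff(adj[[v]], comp))
    }
    unvisited <- setdiff(unvisited, comp)
    bm <- sort(intersect(comp, seedless))
    if (length(bm) >= min_size) {
      gov <- character(); deg <- integer()
      for (l in intersect(comp, lnc_ids)) {
        d <- 0L
        for (i in seq_len(nrow(net$edges))) {
          if ((net$edges$from[i] == l && net$edges$to[i] %in% bm) ||
              (net$edges$to[i] == l && net$edges$from[i] %in% bm)) d <- d + 1L
        }
        gov <- c(gov, l); deg <- c(deg, d)
      }
      o <- order(-deg, gov)
      blocks[[length(blocks) + 1]] <- list(mirnas = bm,
                                           governors = setNames(deg[o], gov[o]))
    }
  }
  blocks[order(-vapply(blocks, function(b) length(b$mirnas), integer(1)))]
}

# --- governed genes ---------------------------------------------------------

bf_governed <- function(records, block_mirnas, min_links = 2L) {
  bk <- key(block_mirnas)
  lnc_links <- list()
  n <- nrow(records)
  for (i in seq_len(n)) {
    if (records$nc_type[i] == "lncRNA" && records$target_type[i] == "miRNA" &&
        key(records$target_name[i]) %in% bk) {
      l <- key(records$nc_name[i])
      lnc_links[[l]] <- union(lnc_links[[l]], key(records$target_name[i]))
    }
    if (records$target_type[i] == "lncRNA" && records$nc_type[i] == "miRNA" &&
        key(records$nc_name[i]) %in% bk) {
      l <- key(records$target_name[i])
      lnc_links[[l]] <- union(lnc_links[[l]], key(records$nc_name[i]))
    }
  }
  qual <- names(lnc_links)[vapply(lnc_links, length, integer(1)) >= min_links]
  genes <- character()
  for (i in seq_len(n)) {
    if (key(records$nc_name[i]) %in% qual &&
        records$target_type[i] %in% c("mRNA", "protein"))
      genes <- union(genes, key(records$target_name[i]))
    if (key(records$target_name[i]) %in% qual &&
        records$nc_type[i] %in% c("mRNA", "protein"))
      genes <- union(genes, key(records$nc_name[i]))
  }
  sort(genes)
}

# --- statistics oracles -----------------------------------------------------

# exact upper-tail hypergeometric probability by combinatorial enumeration
bf_hyper_tail <- function(k, K, n, N) {
  if (k <= 0) return(1)
  upper <- min(K, n)
  if (k > upper) return(0)
  tot <- 0
  for (i in k:upper) {
    tot <- tot + choose(K, i) * choose(N - K, n - i)
  }
  tot / choose(N, n)
}

# Holm step-down recurrence: ascending p, adjusted_i = running max of
# min(1, (m - i + 1) * p_(i)), mapped back to input order
bf_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run <- 0
  for (i in seq_len(m)) {
    v <- min(1, (m - i + 1) * p[o[i]])
    run <- max(run, v)
    adj[o[i]] <- run
  }
  adj
}

# --- random instances -------------------------------------------------------

rand_tripartite <- function(seed) {
  set.seed(seed)
  ns <- sample(1:6, 1); nm <- sample(1:8, 1); nl <- sample(1:6, 1)
  nodes <- data.frame(
    id = c(sprintf("s%d", seq_len(ns)), sprintf("m%d", seq_len(nm)),
           sprintf("l%d", seq_len(nl))),
    node_type = c(rep("seed", ns), rep("miRNA", nm), rep("lncRNA", nl)),
    stringsAsFactors = FALSE
  )
  pairs <- rbind(
    expand.grid(a = sprintf("s%d", seq_len(ns)), b = sprintf("m%d", seq_len(nm)),
                stringsAsFactors = FALSE),
    expand.grid(a = sprintf("s%d", seq_len(ns)), b = sprintf("l%d", seq_len(nl)),
                stringsAsFactors = FALSE),
    expand.grid(a = sprintf("m%d", seq_len(nm)), b = sprintf("l%d", seq_len(nl)),
                stringsAsFactors = FALSE)
  )
  hit <- runif(nrow(pairs)) < 0.3
  edges <- data.frame(from = pairs$a[hit], to = pairs$b[hit],
                      evidence_count = sample(1:3, sum(hit), replace = TRUE),
                      stringsAsFactors = FALSE)
  tripartite_network(nodes, edges, seed_set = gene_set(nodes$id[nodes$node_type == "seed"]))
}

rand_records <- function(seed, n_rows = 15) {
  set.seed(seed)
  vocab <- data.frame(
    name = c(sprintf("g%d", 1:5), sprintf("m%d", 1:6), sprintf("l%d", 1:4),
             sprintf("o%d", 1:2)),
    type = c(rep(c("mRNA", "protein"), length.out = 5), rep("miRNA", 6),
             rep("lncRNA", 4), rep("other", 2)),
    stringsAsFactors = FALSE
  )
  i <- sample(nrow(vocab), n_rows, replace = TRUE)
  j <- sample(nrow(vocab), n_rows, replace = TRUE)
  rec <- data.frame(
    interaction_id = sprintf("r%d", seq_len(n_rows)),
    nc_name = vocab$name[i], nc_type = vocab$type[i],
    target_name = vocab$name[j], target_type = vocab$type[j],
    organism = "Homo sapiens", evidence_class = "RNA-RNA", source = "sim",
    stringsAsFactors = FALSE
  )
  seeds <- sample(sprintf("g%d", 1:5), sample(1:4, 1))
  list(records = rec, seeds = seeds)
}

# canonical comparable forms
node_key_set <- function(nodes) sort(paste(key(nodes$id), nodes$node_type))
edge_key_set <- function(edges) {
  if (nrow(edges) == 0) return(character())
  a <- pmin(key(edges$from), key(edges$to))
  b <- pmax(key(edges$from), key(edges$to))
  sort(paste(a, b, edges$evidence_count))
}
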