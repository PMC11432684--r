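test_that("detect_mirna_blocks finds planted seedless components", {
  block_mirs <- sprintf("bm%d", 1:12)
  linked_mirs <- sprintf("sm%d", 1:3)
  edges <- rbind(
    cbind(block_mirs, "H1"),
    cbind(block_mirs[1:9], "H2"),
    cbind("H1", "G1"), cbind("H2", "G2"),
    cbind(linked_mirs, "G1"), cbind(linked_mirs, "H3"), cbind("H3", "G2")
  )
  net <- make_net(seeds = c("G1", "G2"), mirnas = c(block_mirs, linked_mirs),
                  lncs = c("H1", "H2", "H3"), edges = edges)
  blocks <- detect_mirna_blocks(net, min_size = 5)
  expect_length(blocks, 1L)
  expect_setequal(blocks[[1]]$mirnas, block_mirs)
  expect_equal(names(blocks[[1]]$governors), c("H1", "H2"))
  expect_equal(unname(blocks[[1]]$governors), c(12L, 9L))
})

test_that("no seedless miRNA means no blocks", {
  net <- make_net(seeds = "G1", mirnas = c("m1", "m2"), lncs = "l1",
                  edges = rbind(c("G1", "m1"), c("G1", "m2"),
                                c("m1", "l1"), c("m2", "l1")))
  expect_length(detect_mirna_blocks(net, min_size = 1), 0L)
})

test_that("blocks at min_size 1 partition the lncRNA-linked seedless miRNAs", {
  for (s in 1:20) {
    net <- rand_tripartite(s + 300)
    blocks <- detect_mirna_blocks(net, min_size = 1)
    members <- as.character(unlist(lapply(blocks, `[[`, "mirnas")))
    expect_false(anyDuplicated(members) > 0)
    # expected cover: seedless miRNAs with >= 1 lncRNA edge
    type_of <- setNames(net$nodes$node_type, net$nodes$id)
    e <- net$edges
    seed_adj <- unique(c(e$from[type_of[e$to] == "seed"],
                         e$to[type_of[e$from] == "seed"]))
    lnc_adj <- unique(c(e$from[type_of[e$to] == "lncRNA"],
                        e$to[type_of[e$from] == "lncRNA"]))
    expected <- setdiff(intersect(names(type_of)[type_of == "miRNA"], lnc_adj),
                        seed_adj)
    expect_setequal(members, expected)
  }
})

test_that("governed_genes applies the min_links rule over distinct miRNAs", {
  tab <- make_table(
    c("lncA", "lncRNA", "bm1", "miRNA"),
    c("lncA", "lncRNA", "bm2", "miRNA"),
    c("lncA", "lncRNA", "G1", "mRNA"),
    c("lncB", "lncRNA", "bm1", "miRNA"),
    c("lncB", "lncRNA", "G2", "mRNA")
  )
  out <- governed_genes(tab, c("bm1", "bm2"), min_links = 2)
  expect_equal(out$members, "G1")
  expect_equal(attr(out, "linking_lncrnas"), c(lncA = 2L))

  expect_equal(length(governed_genes(tab, character())$members), 0L)

  # raising min_links never enlarges the result
  g1 <- governed_genes(tab, c("bm1", "bm2"), min_links = 1)
  expect_true(all(out$members %in% g1$members))

  # output is a subset of the table's mRNA/protein names
  all_genes <- norm_id(c(tab$records$nc_name[tab$records$nc_type %in% c("mRNA", "protein")],
                         tab$records$target_name[tab$records$target_type %in% c("mRNA", "protein")]))
  expect_true(all(norm_id(g1$members) %in% all_genes))
})

test_that("propagate_states implements sponge logic", {
  # toy chain: down-regulated lnc1 leaves miR1 active, expressed lnc2 sponges miR2
  net <- make_net(seeds = "G1", mirnas = c("miR1", "miR2"),
                  lncs = c("lnc1", "lnc2"),
                  edges = rbind(c("lnc1", "miR1"), c("lnc2", "miR2"),
                                c("miR1", "G1"), c("miR2", "G1")))
  st <- propagate_states(net, c(lnc1 = "down"))
  expect_equal(st$mirna_states[["miR1"]], "active")
  expect_equal(st$mirna_states[["miR2"]], "sponged")
  expect_equal(st$gene_states[["G1"]], "repressed")

  # all lncRNAs expressed: every lncRNA-adjacent miRNA sponged, genes whose
  # only miRNA neighbors are sponged stay uninhibited
  st2 <- propagate_states(net)
  expect_true(all(st2$mirna_states == "sponged"))
  expect_equal(st2$gene_states[["G1"]], "uninhibited")

  # a miRNA with no lncRNA neighbor is active
  net3 <- make_net(seeds = "G1", mirnas = "miR9",
                   edges = rbind(c("miR9", "G1")))
  expect_equal(propagate_states(net3)$mirna_states[["miR9"]], "active")

  expect_error(propagate_states(net, c(nope = "down")), "nope")
  expect_error(propagate_states(net, c(lnc1 = "loud")), "invalid state")
})

test_that("seed-lncRNA edges are surfaced as unresolved, not propagated", {
  net <- make_net(seeds = "G1", mirnas = "m1", lncs = "l1",
                  edges = rbind(c("l1", "m1"), c("l1", "G1"), c("m1", "G1")))
  st <- propagate_states(net, c(l1 = "down"))
  expect_equal(nrow(st$unresolved_edges), 1L)
  expect_equal(st$unresolved_edges$seed, "G1")
  expect_equal(st$unresolved_edges$lncRNA, "l1")
  # the gene state came from the miRNA rule alone
  expect_equal(st$gene_states[["G1"]], "repressed")
})

test_that("propagation is invariant to node and edge order", {
  net <- rand_tripartite(42)
  lncs <- net$nodes$id[net$nodes$node_type == "lncRNA"]
  assigned <- setNames(rep(c("down", "expressed"), length.out = length(lncs)), lncs)
  ref <- propagate_states(net, assigned)
  set.seed(99)
  perm_nodes <- net$nodes[sample(nrow(net$nodes)), , drop = FALSE]
  perm_edges <- net$edges[sample(nrow(net$edges)), , drop = FALSE]
  net2 <- tripartite_network(perm_nodes, perm_edges, seed_set = net$seed_set)
  out <- propagate_states(net2, assigned[sample(length(assigned))])
  for (field in c("lncRNA_states", "mirna_states", "gene_states")) {
    expect_equal(out[[field]][names(ref[[field]])], ref[[field]])
  }
})

test_that("the psoriasis example reproduces the expression hypothesis", {
  ex <- psoriasis_axis_example()
  expect_equal(nrow(ex$network$nodes), 17L)
  st <- propagate_states(ex$network, ex$assigned)
  expect_equal(st$mirna_states[["hsa-miR-485-3p"]], "active")
  expect_equal(st$mirna_states[["hsa-miR-371a-3p"]], "active")
  others <- setdiff(names(st$mirna_states), c("hsa-miR-485-3p", "hsa-miR-371a-3p"))
  expect_true(all(st$mirna_states[others] == "sponged"))
  expect_true(all(st$gene_states[c("TNFAIP3", "SHOC2", "HTR2A")] == "repressed"))
  expect_true(all(st$gene_states[c("MAP3K14", "ERAP1", "SPEN")] == "uninhibited"))
})
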