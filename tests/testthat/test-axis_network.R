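test_that("build_axis applies the two-step extraction rules", {
  tab <- make_table(
    c("hsa-miR-1", "miRNA", "G1", "mRNA"),
    c("lnc1", "lncRNA", "G1", "mRNA"),
    c("hsa-miR-2", "miRNA", "lnc1", "lncRNA"),
    c("hsa-miR-3", "miRNA", "lnc2", "lncRNA")
  )
  seeds <- gene_set("G1")
  net <- build_axis(tab, seeds)
  expect_setequal(net$nodes$id, c("G1", "hsa-miR-1", "lnc1", "hsa-miR-2"))
  # lnc2 has no seed edge, miR-3 only reaches lnc2: both excluded
  expect_false(any(c("lnc2", "hsa-miR-3") %in% net$nodes$id))
  # edges are a subset of input pairs, no edge invented
  in_pairs <- paste(pmin(norm_id(tab$records$nc_name), norm_id(tab$records$target_name)),
                    pmax(norm_id(tab$records$nc_name), norm_id(tab$records$target_name)))
  out_pairs <- paste(pmin(norm_id(net$edges$from), norm_id(net$edges$to)),
                     pmax(norm_id(net$edges$from), norm_id(net$edges$to)))
  expect_true(all(out_pairs %in% in_pairs))
})

test_that("build_axis handles no-match and empty seed inputs", {
  tab <- make_table(c("hsa-miR-1", "miRNA", "G1", "mRNA"))
  expect_warning(net <- build_axis(tab, gene_set("NOPE")), "NOPE")
  expect_equal(nrow(net$nodes), 0L)
  expect_warning(net2 <- build_axis(tab, gene_set()), "no seed")
  expect_equal(nrow(net2$nodes), 0L)
})

test_that("build_axis unifies case-variant miRNA spellings", {
  tab <- make_table(
    c("hsa-miR-1", "miRNA", "G1", "mRNA"),
    c("hsa-mir-1", "miRNA", "G2", "mRNA")
  )
  net <- build_axis(tab, gene_set(c("G1", "G2")))
  expect_equal(sum(net$nodes$node_type == "miRNA"), 1L)
  expect_equal(nrow(net$edges), 2L)
})

test_that("threshold_filter retains markers occurring k or more times", {
  # X has 3 distinct neighbors, Y has 2
  net <- make_net(seeds = c("G1", "G2", "G3"), mirnas = c("X", "Y"),
                  edges = rbind(c("X", "G1"), c("X", "G2"), c("X", "G3"),
                                c("Y", "G1"), c("Y", "G2")))
  out <- threshold_filter(net, 3)
  expect_true("X" %in% out$nodes$id)
  expect_false("Y" %in% out$nodes$id)
  expect_equal(out$threshold_applied, 3L)

  identity <- threshold_filter(net, 1)
  expect_equal(node_key_set(identity$nodes), node_key_set(net$nodes))
  expect_equal(edge_key_set(identity$edges), edge_key_set(net$edges))

  expect_error(threshold_filter(net, 0), "k must be")
})

test_that("rows mode counts supporting rows rather than neighbors", {
  net <- make_net(seeds = "G1", mirnas = c("X", "Y"),
                  edges = rbind(c("X", "G1", 5), c("Y", "G1", 1)))
  out <- threshold_filter(net, 3, mode = "rows")
  expect_true("X" %in% out$nodes$id)
  expect_false("Y" %in% out$nodes$id)
})

test_that("threshold_filter is monotone in k", {
  for (s in 1:25) {
    net <- rand_tripartite(s)
    for (mode in c("degree", "rows")) {
      n2 <- threshold_filter(net, 2, mode = mode)
      n3 <- threshold_filter(net, 3, mode = mode)
      expect_true(all(n3$nodes$id %in% n2$nodes$id))
    }
  }
})

test_that("prune_single_interactors applies the removal predicate", {
  # a seed with two interactors does not match the predicate
  net <- make_net(seeds = "S", mirnas = c("m1", "m2"),
                  edges = rbind(c("S", "m1"), c("S", "m2")))
  out <- prune_single_interactors(net)
  expect_true("S" %in% out$nodes$id)

  # seeds_only: degree-1 seed S removed; miR1/lnc1/T (degree 2) retained
  net2 <- make_net(seeds = c("S", "T"), mirnas = "miR1", lncs = "lnc1",
                   edges = rbind(c("S", "miR1"), c("miR1", "lnc1"),
                                 c("lnc1", "T"), c("miR1", "T")))
  out2 <- prune_single_interactors(net2, scope = "seeds_only")
  expect_setequal(out2$nodes$id, c("T", "miR1", "lnc1"))

  # all_nodes + fixed point collapses a path entirely
  net3 <- make_net(seeds = "A", mirnas = "B", lncs = "C",
                   edges = rbind(c("A", "B"), c("B", "C")))
  out3 <- prune_single_interactors(net3, scope = "all_nodes", fixed_point = TRUE)
  expect_equal(nrow(out3$nodes), 0L)
})

test_that("fixed-point pruning is idempotent", {
  for (s in 1:15) {
    net <- rand_tripartite(s + 100)
    once <- prune_single_interactors(net, scope = "all_nodes", fixed_point = TRUE)
    twice <- prune_single_interactors(once, scope = "all_nodes", fixed_point = TRUE)
    expect_equal(node_key_set(twice$nodes), node_key_set(once$nodes))
    expect_equal(edge_key_set(twice$edges), edge_key_set(once$edges))
  }
})

test_that("the network container rejects malformed graphs", {
  expect_error(make_net(seeds = c("A", "B"), edges = rbind(c("A", "B"))),
               "disallowed edge type")
  expect_error(make_net(seeds = "A", mirnas = "m",
                        edges = rbind(c("A", "zzz"))), "missing from node set")
  expect_error(make_net(seeds = "A", mirnas = "m",
                        edges = rbind(c("A", "m", 0))), "evidence_count")
})
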