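test_that("expand_interactors returns first-degree partners without duplicates", {
  bg <- read_biogrid(write_biogrid_fixture(list(
    c("G1", "P1"), c("G1", "P2"), c("G3", "P4"), c("G1", "G1")
  )))
  out <- expand_interactors(gene_set("G1"), bg)
  expect_setequal(out$members, c("G1", "P1", "P2"))
  expect_setequal(attr(out, "contributions")[["G1"]], c("P1", "P2"))

  expect_equal(length(expand_interactors(gene_set(), bg)$members), 0L)

  only_self <- read_biogrid(write_biogrid_fixture(list(c("G1", "G1"))))
  expect_equal(expand_interactors(gene_set("G1"), only_self)$members, "G1")
})

test_that("load_ontology parses terms, parents and obsolescence", {
  ont <- load_ontology(write_obo_fixture())
  expect_equal(nrow(ont$terms), 6L)
  expect_equal(ont$parents[["GO:A"]], "GO:B")
  expect_equal(ont$parents[["GO:PO"]], "GO:C")  # part_of treated like is_a
  expect_true(ont$terms$obsolete[ont$terms$id == "GO:OBS"])
  anc <- term_ancestors(ont)
  expect_setequal(anc[["GO:A"]], c("GO:A", "GO:B", "GO:C"))
  expect_equal(anc[["GO:LONE"]], "GO:LONE")

  cyc <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: GO:X", "name: x", "is_a: GO:Y", "",
               "[Term]", "id: GO:Y", "name: y", "is_a: GO:X", ""), cyc)
  expect_error(load_ontology(cyc), "cycle")
})

test_that("load_annotations filters evidence and propagates to ancestors", {
  ont <- load_ontology(write_obo_fixture())
  gaf <- write_gaf_fixture(list(
    c("g1", "GO:A", "IDA"),
    c("g2", "GO:B", "IEA"),          # computational: excluded by default
    c("g3", "GO:C", "IMP", "NOT|involved_in"),  # NOT-qualified: skipped
    c("g4", "GO:UNKNOWN", "IDA"),    # unknown term: counted
    c("g5", "GO:OBS", "IDA"),        # obsolete term: counted
    c("g6", "GO:C", "EXP")
  ))
  ann <- load_annotations(gaf, ont)
  # direct annotation propagates along the full is_a chain
  expect_setequal(ann$term_to_genes[["GO:A"]], "g1")
  expect_setequal(ann$term_to_genes[["GO:B"]], "g1")
  expect_setequal(ann$term_to_genes[["GO:C"]], c("g1", "g6"))
  expect_equal(ann$skipped[["evidence filter"]], 1L)
  expect_equal(ann$skipped[["NOT qualifier"]], 1L)
  expect_equal(ann$skipped[["unknown term"]], 1L)
  expect_equal(ann$skipped[["obsolete term"]], 1L)
  expect_setequal(ann$population, c("g1", "g6"))

  # propagation invariant: annotated to t implies annotated to all ancestors
  anc <- term_ancestors(ont)
  for (t in names(ann$term_to_genes)) {
    for (a in anc[[t]]) {
      expect_true(all(ann$term_to_genes[[t]] %in% ann$term_to_genes[[a]]))
    }
  }

  # IEA rows pass when the filter is disabled
  ann_all <- load_annotations(gaf, ont, evidence_codes = NULL)
  expect_true("g2" %in% ann_all$term_to_genes[["GO:B"]])
})

test_that("enrich computes the exact hypergeometric tail", {
  # pop 100 genes, term annotates 10, study of 10 hits 5
  pop <- sprintf("g%03d", 1:100)
  annotated <- pop[1:10]
  study <- c(annotated[1:5], pop[50:54])
  ann <- structure(list(
    term_to_genes = list(`GO:T` = annotated),
    population = pop, evidence_filter = NULL, skipped = integer()
  ), class = "annotation_set")
  res <- enrich(gene_set(study), ann, min_study_count = 1)
  expected <- sum(vapply(5:10, function(i) {
    choose(10, i) * choose(90, 10 - i) / choose(100, 10)
  }, 0))
  expect_equal(res$p_raw[res$term_id == "GO:T"], expected, tolerance = 1e-12)
  expect_equal(res$study_count, 5L)
  expect_equal(res$pop_count, 10L)

  # a term annotating the entire population is never enriched
  ann2 <- structure(list(
    term_to_genes = list(`GO:ALL` = pop),
    population = pop, evidence_filter = NULL, skipped = integer()
  ), class = "annotation_set")
  res2 <- enrich(gene_set(study), ann2, min_study_count = 1)
  expect_equal(res2$p_raw, 1)
  expect_false(res2$significant)
})

test_that("Holm adjustment matches the step-down recurrence", {
  p <- c(0.001, 0.01, 0.04)
  # m=3: 3*.001=.003; max(.003, 2*.01)=.02; max(.02, 1*.04)=.04
  expect_equal(bf_holm(p), c(0.003, 0.02, 0.04))

  pop <- sprintf("g%03d", 1:60)
  set.seed(5)
  t2g <- lapply(1:8, function(i) sample(pop, sample(5:25, 1)))
  names(t2g) <- sprintf("GO:T%d", 1:8)
  ann <- structure(list(term_to_genes = t2g, population = pop,
                        evidence_filter = NULL, skipped = integer()),
                   class = "annotation_set")
  study <- gene_set(sample(pop, 20))
  res <- enrich(study, ann, min_study_count = 1)
  expect_equal(res$p_adjusted, bf_holm(res$p_raw), tolerance = 1e-12)
  # adjusted never below raw, never above plain Bonferroni, and results sorted
  expect_true(all(res$p_adjusted >= res$p_raw))
  expect_true(all(res$p_adjusted <= pmin(1, nrow(res) * res$p_raw) + 1e-15))
  expect_false(is.unsorted(res$p_adjusted))
  # study_count bounded by study and term sizes
  expect_true(all(res$study_count <= pmin(res$study_size, res$pop_count)))
})

test_that("enrich warns and drops study genes outside the population", {
  ann <- structure(list(
    term_to_genes = list(`GO:T` = c("g1", "g2")),
    population = c("g1", "g2", "g3"), evidence_filter = NULL, skipped = integer()
  ), class = "annotation_set")
  expect_warning(res <- enrich(gene_set(c("g1", "g2", "zzz")), ann,
                               min_study_count = 1), "dropped")
  expect_equal(res$study_size, 2L)
  expect_warning(expect_warning(out <- enrich(gene_set("zzz"), ann), "dropped"),
                 "empty study")
  expect_equal(nrow(out), 0L)
})
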