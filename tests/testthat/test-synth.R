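test_that("generation is a pure function of the config", {
  cfg <- fixture_config(rng_seed = 11L)
  d1 <- tempfile(); d2 <- tempfile()
  generate_fixture(cfg, d1)
  generate_fixture(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("generated files round-trip with only the planted decoys discarded", {
  cfg <- fixture_config(rng_seed = 3L, n_decoy_organism_rows = 4L)
  fx <- generate_fixture(cfg, tempfile())
  tab <- read_npinter(fx$files[["npinter"]])
  expect_equal(tab$provenance$discarded, 4L)
  expect_equal(tab$provenance$reasons[["organism filter"]], 4L)
  bg <- read_biogrid(fx$files[["biogrid"]])
  expect_equal(bg$provenance$discarded, 0L)
  seeds <- read_gene_list(fx$files[["seeds"]])
  expect_equal(length(seeds$members), cfg$n_seeds)
  ont <- load_ontology(fx$files[["obo"]])
  ann <- load_annotations(fx$files[["gaf"]], ont)
  expect_equal(length(ann$population), fx$truth$population_size)
  states <- read_state_file(fx$files[["states"]])
  expect_equal(length(states), cfg$n_lncrna)
})

test_that("planted blocks, governors and governed genes are recovered", {
  cfg <- fixture_config(n_mirna = 50L, n_lncrna = 12L,
                        planted_blocks = list(c(12L, 2L), c(7L, 3L)),
                        planted_hub_names = c("NEAT1", "MALAT1"),
                        rng_seed = 21L)
  fx <- generate_fixture(cfg, tempfile())
  tab <- read_npinter(fx$files[["npinter"]])
  seeds <- read_gene_list(fx$files[["seeds"]])
  net <- build_axis(tab, seeds)
  blocks <- detect_mirna_blocks(net, min_size = 5)
  expect_length(blocks, 2L)
  for (i in seq_along(blocks)) {
    expect_equal(blocks[[i]]$mirnas, fx$truth$blocks[[i]]$mirnas)
    expect_setequal(names(blocks[[i]]$governors), fx$truth$blocks[[i]]$governors)
  }
  expect_setequal(names(blocks[[1]]$governors), c("NEAT1", "MALAT1"))
  gg <- governed_genes(tab, blocks[[1]], min_links = 2)
  expect_equal(sort(gg$members), fx$truth$governed_genes[[1]])
})

test_that("inconsistent configs are rejected", {
  expect_error(fixture_config(n_mirna = 5L, planted_blocks = list(c(12L, 2L))),
               "exceed n_mirna")
  expect_error(fixture_config(n_lncrna = 1L, planted_blocks = list(c(3L, 2L))),
               "governor counts")
  expect_error(fixture_config(edge_density = 1.5), "edge_density")
  expect_error(fixture_config(planted_terms = list(list(id = "GO:SIM0001", fold = 8))),
               "non-root")
})

test_that("a YAML fixture config drives the simulate entry point", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("n_seeds: 6", "n_mirna: 15", "n_lncrna: 4",
               "planted_blocks:", "  - [6, 1]", "rng_seed: 5",
               "n_population: 40",
               "planted_terms:", "  - id: 'GO:SIM0020'", "    fold: 8"), yml)
  cfg <- read_fixture_config(yml)
  expect_equal(cfg$n_seeds, 6L)
  expect_equal(cfg$planted_blocks[[1]], c(6L, 1L))
  fx <- generate_fixture(cfg, tempfile())
  expect_length(fx$truth$blocks[[1]]$mirnas, 6L)
})
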