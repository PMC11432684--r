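#' Configuration for the synthetic fixture generator
#'
#' Describes a small, fully synthetic study: a seed biomarker list, an
#' NPInter-style interaction table with planted lncRNA-governed miRNA
#' blocks, a BioGRID tab3 table of first-degree partners, a miniature GO
#' ontology plus GAF annotations with planted over-represented terms, and an
#' expression-state file. All randomness flows from the single `rng_seed`.
#'
#' @param n_seeds,n_mirna,n_lncrna node counts per layer.
#' @param planted_blocks list of `c(block_size, n_governors)` pairs. Block
#'   miRNAs receive edges only to their governor lncRNAs (never to seeds);
#'   each governor also receives a seed edge so it survives axis
#'   construction.
#' @param planted_hub_names optional display names for the first governor
#'   lncRNAs (e.g. `c("NEAT1", "MALAT1")`) for narrative fixtures.
#' @param edge_density probability of each background seed-miRNA,
#'   seed-lncRNA and miRNA-lncRNA edge.
#' @param n_decoy_organism_rows interaction rows planted with a non-target
#'   organism, to exercise the reader's organism filter.
#' @param n_decoy_other_rows interaction rows with an unrecognized ncRNA
#'   type label (kept by the reader as `"other"`, excluded by axis
#'   construction).
#' @param planted_terms list of `list(id = <term id>, fold = <fold
#'   enrichment>)`; each must name a term of the generated ontology
#'   (`GO:SIM0004` ... `GO:SIM00<n_go_terms>`; the first three ids are the
#'   namespace roots).
#' @param n_go_terms number of ontology terms (including the three roots).
#' @param n_population size of the annotation background gene universe.
#' @param baseline_annotation_rate per-gene probability of annotation to a
#'   non-planted term, and to a planted term for non-study genes.
#' @param n_biogrid_partners interactor partners generated per seed.
#' @param rng_seed integer seed controlling all randomness.
#' @return a validated list of class `fixture_config`.
#' @export
fixture_config <- function(n_seeds = 20L, n_mirna = 40L, n_lncrna = 10L,
                           planted_blocks = list(c(12L, 2L)),
                           planted_hub_names = NULL,
                           edge_density = 0.08,
                           n_decoy_organism_rows = 5L,
                           n_decoy_other_rows = 2L,
                           planted_terms = list(list(id = "GO:SIM0020", fold = 8)),
                           n_go_terms = 20L,
                           n_population = 200L,
                           baseline_annotation_rate = 0.05,
                           n_biogrid_partners = 2L,
                           rng_seed = 1L) {
  cfg <- list(n_seeds = as.integer(n_seeds), n_mirna = as.integer(n_mirna),
              n_lncrna = as.integer(n_lncrna), planted_blocks = planted_blocks,
              planted_hub_names = planted_hub_names,
              edge_density = edge_density,
              n_decoy_organism_rows = as.integer(n_decoy_organism_rows),
              n_decoy_other_rows = as.integer(n_decoy_other_rows),
              planted_terms = planted_terms,
              n_go_terms = as.integer(n_go_terms),
              n_population = as.integer(n_population),
              baseline_annotation_rate = baseline_annotation_rate,
              n_biogrid_partners = as.integer(n_biogrid_partners),
              rng_seed = as.integer(rng_seed))
  counts <- c(cfg$n_seeds, cfg$n_mirna, cfg$n_lncrna, cfg$n_decoy_organism_rows,
              cfg$n_decoy_other_rows, cfg$n_go_terms, cfg$n_population,
              cfg$n_biogrid_partners)
  if (any(counts < 0)) stop("fixture_config: counts must be non-negative")
  if (cfg$edge_density < 0 || cfg$edge_density > 1) {
    stop("fixture_config: edge_density must be in [0, 1]")
  }
  block_sizes <- vapply(cfg$planted_blocks, function(b) as.integer(b[1]), integer(1))
  gov_counts <- vapply(cfg$planted_blocks, function(b) as.integer(b[2]), integer(1))
  if (any(block_sizes < 1) || any(gov_counts < 1)) {
    stop("fixture_config: each planted block needs size >= 1 and >= 1 governor")
  }
  if (sum(block_sizes) > cfg$n_mirna) {
    stop("fixture_config: planted block sizes exceed n_mirna")
  }
  if (sum(gov_counts) > cfg$n_lncrna) {
    stop("fixture_config: planted governor counts exceed n_lncrna")
  }
  if (!is.null(cfg$planted_hub_names) &&
      length(cfg$planted_hub_names) > sum(gov_counts)) {
    stop("fixture_config: more hub names than governors")
  }
  if (cfg$n_go_terms < 4) stop("fixture_config: need at least 4 ontology terms")
  if (cfg$n_population < cfg$n_seeds) {
    stop("fixture_config: n_population must cover at least the seeds")
  }
  for (pt in cfg$planted_terms) {
    idx <- as.integer(sub("^GO:SIM", "", pt$id))
    if (is.na(idx) || idx <= 3 || idx > cfg$n_go_terms) {
      stop("fixture_config: planted term ", pt$id,
           " is not a non-root term of the generated ontology")
    }
  }
  structure(cfg, class = "fixture_config")
}

#' Load a fixture configuration from YAML
#'
#' @param path YAML file whose keys are [fixture_config()] arguments.
#' @return a `fixture_config`.
#' @export
read_fixture_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$planted_blocks)) {
    raw$planted_blocks <- lapply(raw$planted_blocks, unlist)
  }
  do.call(fixture_config, raw)
}

# run code under a fixed RNG seed, restoring the caller's RNG state
with_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic fixture directory with known ground truth
#'
#' Writes `npinter.tsv`, `seeds.txt`, `biogrid.tab3.txt`, `ontology.obo`,
#' `annotations.gaf`, `states.tsv` and `truth.json` into `out_dir`.
#' Generation is a pure function of the configuration (including its
#' `rng_seed`): the same config always produces byte-identical files.
#'
#' Planted structure: block miRNAs connect only to their governor lncRNAs,
#' never to seeds, so they form seedless components recoverable by
#' [detect_mirna_blocks()]; every governor carries at least one seed edge so
#' it survives [build_axis()]; background miRNAs always touch a seed, so no
#' background node can leak into a block. Planted GO terms annotate the
#' study genes (seeds plus their BioGRID partners) at `fold` times the
#' baseline rate.
#'
#' @param config a [fixture_config()].
#' @param out_dir output directory, created if needed.
#' @return invisibly, `list(files = <named paths>, truth = <list>)`; `truth`
#'   carries expected block memberships, governors, governed genes and
#'   enriched term ids.
#' @export
generate_fixture <- function(config, out_dir) {
  stopifnot(inherits(config, "fixture_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  with_rng(config$rng_seed, {
    seeds <- sprintf("GENE%04d", seq_len(config$n_seeds))
    mirnas <- sprintf("hsa-miR-sim-%d", seq_len(config$n_mirna))
    lncs <- sprintf("LNC-sim-%d", seq_len(config$n_lncrna))

    block_sizes <- vapply(config$planted_blocks, function(b) as.integer(b[1]), integer(1))
    gov_counts <- vapply(config$planted_blocks, function(b) as.integer(b[2]), integer(1))
    n_block_mir <- sum(block_sizes)
    n_gov <- sum(gov_counts)
    if (!is.null(config$planted_hub_names)) {
      lncs[seq_along(config$planted_hub_names)] <- config$planted_hub_names
    }

    block_mirnas <- split(mirnas[seq_len(n_block_mir)],
                          rep(seq_along(block_sizes), block_sizes))
    governors <- split(lncs[seq_len(n_gov)],
                       rep(seq_along(gov_counts), gov_counts))
    bg_mirnas <- mirnas[setdiff(seq_len(config$n_mirna), seq_len(n_block_mir))]
    bg_lncs <- lncs[setdiff(seq_len(config$n_lncrna), seq_len(n_gov))]

    edge <- function(a, at, b, bt, org = "Homo sapiens") {
      data.frame(nc_name = a, nc_type = at, target_name = b, target_type = bt,
                 organism = org, stringsAsFactors = FALSE)
    }
    rows <- list()

    # planted blocks: every block miRNA binds its first governor (keeps the
    # component connected); extra governors attach to a random miRNA subset
    # but always at least one
    for (bi in seq_along(block_mirnas)) {
      bm <- block_mirnas[[bi]]
      gv <- governors[[bi]]
      rows[[length(rows) + 1L]] <- edge(bm, "miRNA", gv[1L], "lncRNA")
      for (g in gv[-1L]) {
        pick <- bm[stats::runif(length(bm)) < 0.5]
        if (length(pick) == 0) pick <- sample(bm, 1L)
        rows[[length(rows) + 1L]] <- edge(pick, "miRNA", g, "lncRNA")
      }
      # each governor carries a seed edge so step-2 extraction retains it
      for (g in gv) {
        rows[[length(rows) + 1L]] <- edge(g, "lncRNA", sample(seeds, 1L), "mRNA")
      }
    }

    # background layer: every background miRNA touches a seed (so it is never
    # seedless); background lncRNAs get a seed edge and a background-miRNA
    # edge so they survive axis construction
    for (m in bg_mirnas) {
      rows[[length(rows) + 1L]] <- edge(m, "miRNA", sample(seeds, 1L), "mRNA")
    }
    for (l in bg_lncs) {
      rows[[length(rows) + 1L]] <- edge(l, "lncRNA", sample(seeds, 1L), "mRNA")
      if (length(bg_mirnas) > 0) {
        rows[[length(rows) + 1L]] <- edge(sample(bg_mirnas, 1L), "miRNA", l, "lncRNA")
      }
    }
    # random extra edges at the configured density
    if (config$edge_density > 0 && length(bg_mirnas) > 0) {
      for (m in bg_mirnas) {
        hit <- seeds[stats::runif(length(seeds)) < config$edge_density]
        for (s in hit) rows[[length(rows) + 1L]] <- edge(m, "miRNA", s, "mRNA")
        if (length(bg_lncs) > 0) {
          hit <- bg_lncs[stats::runif(length(bg_lncs)) < config$edge_density]
          for (l in hit) rows[[length(rows) + 1L]] <- edge(m, "miRNA", l, "lncRNA")
        }
      }
    }

    # decoys: wrong-organism rows (discarded by the reader's organism
    # filter) and unrecognized-type rows (kept as "other")
    if (config$n_decoy_organism_rows > 0) {
      for (i in seq_len(config$n_decoy_organism_rows)) {
        rows[[length(rows) + 1L]] <- edge(sample(mirnas, 1L), "miRNA",
                                          sample(seeds, 1L), "mRNA",
                                          org = "Mus musculus")
      }
    }
    if (config$n_decoy_other_rows > 0) {
      for (i in seq_len(config$n_decoy_other_rows)) {
        rows[[length(rows) + 1L]] <- edge(sprintf("circSIM-%d", i), "circRNA",
                                          sample(seeds, 1L), "mRNA")
      }
    }

    npinter <- do.call(rbind, rows)
    npinter <- unique(npinter)
    npinter_df <- data.frame(
      interID = sprintf("NPI-SIM-%05d", seq_len(nrow(npinter))),
      ncName = npinter$nc_name, ncType = npinter$nc_type,
      tarName = npinter$target_name, tarType = npinter$target_type,
      organism = npinter$organism, class = "RNA-RNA", datasource = "simulated",
      stringsAsFactors = FALSE, check.names = FALSE
    )

    # BioGRID partners per seed, plus one self-pair to exercise the flag
    partners <- lapply(seeds, function(s) {
      sprintf("%s-BGP%d", s, seq_len(config$n_biogrid_partners))
    })
    bg_rows <- data.frame(
      a = rep(seeds, lengths(partners)), b = unlist(partners),
      stringsAsFactors = FALSE
    )
    if (length(seeds) > 0) {
      bg_rows <- rbind(bg_rows, data.frame(a = seeds[1L], b = seeds[1L],
                                           stringsAsFactors = FALSE))
    }
    biogrid_df <- data.frame(
      `#BioGRID Interaction ID` = sprintf("BG-SIM-%05d", seq_len(nrow(bg_rows))),
      `Official Symbol Interactor A` = bg_rows$a,
      `Official Symbol Interactor B` = bg_rows$b,
      `Organism ID Interactor A` = "9606",
      `Organism ID Interactor B` = "9606",
      `Experimental System` = "Two-hybrid",
      stringsAsFactors = FALSE, check.names = FALSE
    )

    # miniature ontology: three namespace roots, every further term has one
    # parent drawn from earlier terms of the same namespace, plus one
    # obsolete leaf
    ns3 <- c("biological_process", "cellular_component", "molecular_function")
    term_ids <- sprintf("GO:SIM%04d", seq_len(config$n_go_terms))
    term_ns <- c(ns3, ns3[1L + (seq_len(config$n_go_terms - 3L) - 1L) %% 3L])
    parent_of <- rep(NA_character_, config$n_go_terms)
    for (i in 4:config$n_go_terms) {
      cands <- which(term_ns[seq_len(i - 1L)] == term_ns[i])
      parent_of[i] <- term_ids[if (length(cands) == 1L) cands else sample(cands, 1L)]
    }
    obo <- c("format-version: 1.2", "ontology: go-sim", "")
    for (i in seq_len(config$n_go_terms)) {
      obo <- c(obo, "[Term]",
               paste0("id: ", term_ids[i]),
               paste0("name: simulated term ", i),
               paste0("namespace: ", term_ns[i]),
               if (!is.na(parent_of[i]))
                 paste0("is_a: ", parent_of[i], " ! simulated parent"),
               "")
    }
    obo <- c(obo, "[Term]", "id: GO:SIMOBS1", "name: obsolete simulated term",
             paste0("namespace: ", ns3[1]), "is_obsolete: true", "")

    # annotation universe: seeds, their partners, filler genes
    study_genes <- c(seeds, unlist(partners))
    n_filler <- max(0L, config$n_population - length(study_genes))
    population <- c(study_genes, sprintf("GENEPOP%04d", seq_len(n_filler)))
    planted_ids <- vapply(config$planted_terms, function(p) p$id, "")
    annotatable <- setdiff(term_ids[-(1:3)], planted_ids)
    gaf_rows <- list()
    ann <- function(gene, term, evidence = "IDA") {
      aspect <- c(biological_process = "P", cellular_component = "C",
                  molecular_function = "F")[term_ns[match(term, term_ids)]]
      paste("SIM", gene, gene, "involved_in", term, "SIM_REF:0000001",
            evidence, "", aspect, "", "", "protein", "taxon:9606",
            "20260101", "SIM", "", "", sep = "\t")
    }
    for (t in annotatable) {
      hit <- population[stats::runif(length(population)) < config$baseline_annotation_rate]
      for (g in hit) gaf_rows[[length(gaf_rows) + 1L]] <- ann(g, t)
    }
    for (pt in config$planted_terms) {
      p_study <- min(1, pt$fold * config$baseline_annotation_rate)
      hit_study <- study_genes[stats::runif(length(study_genes)) < p_study]
      others <- setdiff(population, study_genes)
      hit_bg <- others[stats::runif(length(others)) < config$baseline_annotation_rate]
      for (g in c(hit_study, hit_bg)) {
        gaf_rows[[length(gaf_rows) + 1L]] <- ann(g, pt$id)
      }
    }
    # evidence-filter decoys: computational annotations that must be excluded
    # under the experimental-evidence default
    iea_genes <- utils::head(population, 2L)
    for (g in iea_genes) {
      gaf_rows[[length(gaf_rows) + 1L]] <- ann(g, term_ids[4L], evidence = "IEA")
    }
    # every population gene is annotated somewhere so the default background
    # equals the intended universe (root-term annotation, IDA)
    for (g in population) gaf_rows[[length(gaf_rows) + 1L]] <- ann(g, term_ids[1L])

    gaf <- c("!gaf-version: 2.2", unlist(gaf_rows))

    states <- paste(lncs, "expressed", sep = "\t")

    # ground truth derived from the realized edge set
    human <- npinter_df[npinter_df$organism == "Homo sapiens", ]
    truth_blocks <- lapply(seq_along(block_mirnas), function(bi) {
      bm <- block_mirnas[[bi]]
      gv <- governors[[bi]]
      gov_deg <- vapply(gv, function(g) {
        sum(human$ncName %in% bm & human$tarName == g |
            human$tarName %in% bm & human$ncName == g)
      }, integer(1))
      list(mirnas = sort(bm), governors = names(sort(gov_deg, decreasing = TRUE)),
           governor_degrees = as.list(sort(gov_deg, decreasing = TRUE)))
    })
    truth_governed <- lapply(seq_along(block_mirnas), function(bi) {
      bm <- block_mirnas[[bi]]
      lnc_rows <- human[human$ncType == "lncRNA" | human$tarType == "lncRNA", ]
      lnc_names <- ifelse(lnc_rows$ncType == "lncRNA", lnc_rows$ncName, lnc_rows$tarName)
      mir_names <- ifelse(lnc_rows$ncType == "lncRNA", lnc_rows$tarName, lnc_rows$ncName)
      is_block_mir <- lnc_rows$tarType == "miRNA" & lnc_rows$tarName %in% bm |
        lnc_rows$ncType == "miRNA" & lnc_rows$ncName %in% bm
      links <- table(lnc_names[is_block_mir & !duplicated(paste(lnc_names, mir_names))])
      qual <- names(links)[as.integer(links) >= 2L]
      gene_rows <- human[(human$ncName %in% qual & human$tarType %in% c("mRNA", "protein")) |
                         (human$tarName %in% qual & human$ncType %in% c("mRNA", "protein")), ]
      sort(unique(c(gene_rows$tarName[gene_rows$ncName %in% qual],
                    gene_rows$ncName[gene_rows$tarName %in% qual])))
    })
    truth <- list(
      seeds = seeds,
      blocks = truth_blocks,
      governed_genes = truth_governed,
      enriched_terms = planted_ids,
      study_genes = sort(study_genes),
      population_size = length(population),
      n_decoy_organism_rows = config$n_decoy_organism_rows
    )

    files <- c(
      npinter = file.path(out_dir, "npinter.tsv"),
      seeds = file.path(out_dir, "seeds.txt"),
      biogrid = file.path(out_dir, "biogrid.tab3.txt"),
      obo = file.path(out_dir, "ontology.obo"),
      gaf = file.path(out_dir, "annotations.gaf"),
      states = file.path(out_dir, "states.tsv"),
      truth = file.path(out_dir, "truth.json")
    )
    utils::write.table(npinter_df, files[["npinter"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeLines(seeds, files[["seeds"]])
    utils::write.table(biogrid_df, files[["biogrid"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeLines(obo, files[["obo"]])
    writeLines(gaf, files[["gaf"]])
    writeLines(states, files[["states"]])
    jsonlite::write_json(truth, files[["truth"]], auto_unbox = TRUE, pretty = TRUE)

    invisible(list(files = files, truth = truth))
  })
}
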