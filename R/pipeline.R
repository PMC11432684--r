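#' Default pipeline configuration
#'
#' @param npinter,seeds,biogrid,obo,gaf,states input file paths (`states`,
#'   `biogrid`, `obo`, `gaf` are optional; stages needing a missing input are
#'   skipped).
#' @param out_dir output directory.
#' @param organism organism label for the interaction-table filter.
#' @param biogrid_organism taxonomy id or organism name for the BioGRID
#'   filter.
#' @param threshold occurrence threshold (default 1, i.e. no removal under
#'   the degree mode).
#' @param occurrence_mode `"degree"` or `"rows"`.
#' @param prune_scope `"seeds_only"` or `"all_nodes"`.
#' @param prune_fixed_point iterate pruning to a fixed point?
#' @param primary_nc,secondary_nc ncRNA types of the two extraction steps.
#' @param min_block_size minimum miRNA count for a reported block.
#' @param min_links distinct block-miRNA links an lncRNA needs in the
#'   governed-genes query.
#' @param alpha,min_study_count enrichment test parameters.
#' @param evidence_codes GO evidence filter.
#' @return named list of configuration values.
#' @export
pipeline_config <- function(npinter, seeds, out_dir,
                            biogrid = NULL, obo = NULL, gaf = NULL,
                            states = NULL,
                            organism = "Homo sapiens",
                            biogrid_organism = "9606",
                            threshold = 1L,
                            occurrence_mode = "degree",
                            prune_scope = "seeds_only",
                            prune_fixed_point = FALSE,
                            primary_nc = "miRNA", secondary_nc = "lncRNA",
                            min_block_size = 5L, min_links = 2L,
                            alpha = 0.05, min_study_count = 2L,
                            evidence_codes = experimental_evidence_codes()) {
  as.list(environment())
}

#' Load a pipeline configuration from YAML
#'
#' Keys are [pipeline_config()] arguments; missing keys fall back to the
#' defaults.
#'
#' @param path YAML file.
#' @return named configuration list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  required <- c("npinter", "seeds", "out_dir")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("pipeline config missing required key(s): ", paste(missing, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}

stage_log <- function(fmt, ...) message(sprintf(paste0("[ncaxis] ", fmt), ...))

#' Run the full workflow
#'
#' Executes read -> axis construction -> threshold filtering -> pruning ->
#' network export -> miRNA-block detection -> governed-genes query ->
#' state propagation (when a states file is given) -> BioGRID interactor
#' expansion -> GO over-representation (when BioGRID/OBO/GAF inputs are
#' given), writing every stage product plus a machine-readable run manifest
#' (`manifest.json`) into `config$out_dir`.
#'
#' @param config list from [pipeline_config()] or [read_pipeline_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    tool = "ncaxis",
    version = as.character(utils::packageVersion("ncaxis")),
    config = config[!vapply(config, is.null, logical(1))],
    inputs = list(), stages = list()
  )
  digest <- function(path) unname(tools::md5sum(path))

  table <- read_npinter(config$npinter, organism_filter = config$organism)
  manifest$inputs$npinter <- list(path = config$npinter, md5 = digest(config$npinter))
  manifest$stages$read_npinter <- table$provenance[c("read", "kept", "discarded")]
  stage_log("read_npinter: %d rows read, %d kept, %d discarded",
            table$provenance$read, table$provenance$kept, table$provenance$discarded)

  seeds <- read_gene_list(config$seeds)
  manifest$inputs$seeds <- list(path = config$seeds, md5 = digest(config$seeds))
  manifest$stages$read_seeds <- list(n = length(seeds$members))
  stage_log("read_gene_list: %d unique seeds", length(seeds$members))

  net <- build_axis(table, seeds, primary_nc = config$primary_nc,
                    secondary_nc = config$secondary_nc)
  manifest$stages$build_axis <- list(nodes = nrow(net$nodes), edges = nrow(net$edges))
  net <- threshold_filter(net, config$threshold, mode = config$occurrence_mode)
  manifest$stages$threshold_filter <- list(k = config$threshold,
                                           nodes = nrow(net$nodes),
                                           edges = nrow(net$edges))
  net <- prune_single_interactors(net, scope = config$prune_scope,
                                  fixed_point = config$prune_fixed_point)
  manifest$stages$prune <- list(nodes = nrow(net$nodes), edges = nrow(net$edges))
  n_seeds_kept <- sum(net$nodes$node_type == "seed")
  stage_log("network: out of %d genes of interest, %d retained (%d nodes, %d edges)",
            length(seeds$members), n_seeds_kept, nrow(net$nodes), nrow(net$edges))
  manifest$stages$seeds_retained <- list(of = length(seeds$members), kept = n_seeds_kept)
  write_network(net, file.path(config$out_dir, "network"))

  blocks <- detect_mirna_blocks(net, min_size = config$min_block_size)
  manifest$stages$blocks <- list(
    n = length(blocks),
    sizes = vapply(blocks, function(b) length(b$mirnas), integer(1))
  )
  stage_log("detect_mirna_blocks: %d block(s) of size >= %d",
            length(blocks), config$min_block_size)
  write_blocks(blocks, file.path(config$out_dir, "mirna_blocks.tsv"))

  governed <- NULL
  if (length(blocks) > 0) {
    governed <- governed_genes(table, blocks[[1L]], min_links = config$min_links)
    manifest$stages$governed_genes <- list(n = length(governed$members))
    stage_log("governed_genes: %d genes via %d qualifying lncRNA(s)",
              length(governed$members),
              length(attr(governed, "linking_lncrnas")))
    writeLines(governed$members, file.path(config$out_dir, "governed_genes.txt"))
  }

  if (!is.null(config$states)) {
    assigned <- read_state_file(config$states)
    assigned <- assigned[names(assigned) %in%
                           net$nodes$id[net$nodes$node_type == "lncRNA"]]
    smap <- propagate_states(net, assigned)
    manifest$stages$propagate_states <- list(
      active_mirnas = sum(smap$mirna_states == "active"),
      repressed_genes = sum(smap$gene_states == "repressed"),
      unresolved_edges = nrow(smap$unresolved_edges)
    )
    write_state_map(smap, file.path(config$out_dir, "states_propagated.tsv"))
  }

  retained <- gene_set(net$nodes$id[net$nodes$node_type == "seed"],
                       role = "seed", label = "retained seeds")
  study <- retained
  if (!is.null(config$biogrid)) {
    biogrid <- read_biogrid(config$biogrid, organism_filter = config$biogrid_organism)
    manifest$inputs$biogrid <- list(path = config$biogrid, md5 = digest(config$biogrid))
    manifest$stages$read_biogrid <- biogrid$provenance[c("read", "kept", "discarded")]
    study <- expand_interactors(retained, biogrid)
    manifest$stages$expand_interactors <- list(before = length(retained$members),
                                               after = length(study$members))
    stage_log("expand_interactors: %d genes -> %d with first-degree partners",
              length(retained$members), length(study$members))
    writeLines(study$members, file.path(config$out_dir, "expanded_genes.txt"))
  }

  if (!is.null(config$obo) && !is.null(config$gaf)) {
    ontology <- load_ontology(config$obo)
    annotations <- load_annotations(config$gaf, ontology,
                                    evidence_codes = config$evidence_codes)
    manifest$inputs$obo <- list(path = config$obo, md5 = digest(config$obo))
    manifest$inputs$gaf <- list(path = config$gaf, md5 = digest(config$gaf))
    res <- enrich(study, annotations, ontology = ontology,
                  alpha = config$alpha, min_study_count = config$min_study_count)
    manifest$stages$enrich <- list(tested = nrow(res),
                                   significant = sum(res$significant))
    stage_log("enrich: %d terms tested, %d significant at alpha %.3g (Holm)",
              nrow(res), sum(res$significant), config$alpha)
    write_enrichment(res, file.path(config$out_dir, "enrichment.tsv"))
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Write a miRNA block report
#'
#' One row per block: block id, size, comma-separated miRNA members,
#' governors with their within-block degrees.
#'
#' @param blocks list from [detect_mirna_blocks()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_blocks <- function(blocks, path) {
  tab <- data.frame(
    block = seq_along(blocks),
    n_mirnas = vapply(blocks, function(b) length(b$mirnas), integer(1)),
    mirnas = vapply(blocks, function(b) paste(b$mirnas, collapse = ","), ""),
    governors = vapply(blocks, function(b) {
      paste(sprintf("%s(%d)", names(b$governors), b$governors), collapse = ",")
    }, ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a propagated state map
#'
#' @param smap a `state_map` from [propagate_states()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_state_map <- function(smap, path) {
  tab <- rbind(
    data.frame(id = names(smap$lncRNA_states), node_type = "lncRNA",
               state = unname(smap$lncRNA_states), stringsAsFactors = FALSE),
    data.frame(id = names(smap$mirna_states), node_type = "miRNA",
               state = unname(smap$mirna_states), stringsAsFactors = FALSE),
    data.frame(id = names(smap$gene_states), node_type = "seed",
               state = unname(smap$gene_states), stringsAsFactors = FALSE)
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an enrichment result table
#'
#' @param res an `enrichment_result` from [enrich()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_enrichment <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
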