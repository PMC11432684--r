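#' Expand a gene set with first-degree BioGRID interactors
#'
#' Returns the union of the input genes and every molecule that shares an
#' interaction row with one of them. Which input gene contributed which
#' partners is recorded in the `"contributions"` attribute.
#'
#' @param genes a [gene_set()].
#' @param biogrid an [interaction_table()] read with [read_biogrid()] (the
#'   organism filter is assumed already applied).
#' @return a [gene_set()] with role `"interactor"`.
#' @export
expand_interactors <- function(genes, biogrid) {
  stopifnot(inherits(genes, "gene_set"), inherits(biogrid, "interaction_table"))
  rec <- biogrid$records
  keys <- norm_id(genes$members)
  akey <- norm_id(rec$nc_name); bkey <- norm_id(rec$target_name)

  contributions <- stats::setNames(vector("list", length(genes$members)),
                                   genes$members)
  partners <- character()
  for (i in seq_along(genes$members)) {
    k <- keys[i]
    p <- c(rec$target_name[akey == k], rec$nc_name[bkey == k])
    p <- p[norm_id(p) != k]  # self-pairs add nothing
    p <- p[!duplicated(norm_id(p))]
    contributions[[i]] <- p
    partners <- c(partners, p)
  }
  out <- gene_set(c(genes$members, partners), role = "interactor",
                  label = paste0(genes$label, " + interactors"))
  attr(out, "contributions") <- contributions
  out
}

#' Load a Gene Ontology graph from an OBO file
#'
#' Minimal OBO 1.2/1.4 reader covering what over-representation analysis
#' needs: term id, name, namespace, obsolescence, and the `is_a` and
#' `relationship: part_of` parent links (other relationship types are
#' ignored). The parent graph must be acyclic.
#'
#' @param obo_path path to an OBO file.
#' @return object of class `ontology`: list with `terms` (data frame: id,
#'   name, namespace, obsolete) and `parents` (named list: term id -> parent
#'   ids).
#' @export
load_ontology <- function(obo_path) {
  if (!file.exists(obo_path)) stop("file not found: ", obo_path)
  lines <- readLines(obo_path, warn = FALSE)

  stanza_starts <- grep("^\\[", lines)
  term_starts <- which(lines == "[Term]")
  if (length(term_starts) == 0) stop("no [Term] stanzas in OBO file: ", obo_path)
  bounds <- c(stanza_starts, length(lines) + 1L)

  ids <- names_ <- ns <- character(length(term_starts))
  obs <- logical(length(term_starts))
  parents <- vector("list", length(term_starts))
  strip_comment <- function(x) trimws(sub("!.*$", "", x))

  for (i in seq_along(term_starts)) {
    s <- term_starts[i]
    e <- min(bounds[bounds > s]) - 1L
    chunk <- lines[(s + 1L):e]
    val <- function(key) {
      hit <- grep(paste0("^", key, ": "), chunk, value = TRUE)
      if (length(hit) == 0) NA_character_
      else strip_comment(sub(paste0("^", key, ": "), "", hit[1L]))
    }
    ids[i] <- val("id")
    names_[i] <- val("name")
    ns[i] <- val("namespace")
    obs[i] <- identical(val("is_obsolete"), "true")
    isa <- strip_comment(sub("^is_a: ", "", grep("^is_a: ", chunk, value = TRUE)))
    po <- grep("^relationship: part_of ", chunk, value = TRUE)
    po <- strip_comment(sub("^relationship: part_of ", "", po))
    parents[[i]] <- unique(c(isa, po))
  }
  names(parents) <- ids

  # obsolete terms keep no links; the parent graph must be a DAG
  parents[obs] <- replicate(sum(obs), character(), simplify = FALSE)
  el <- do.call(rbind, lapply(ids, function(id) {
    ps <- parents[[id]]
    if (length(ps) == 0) NULL else cbind(id, ps)
  }))
  if (!is.null(el) && nrow(el) > 0) {
    g <- igraph::graph_from_edgelist(el, directed = TRUE)
    if (!igraph::is_dag(g)) stop("ontology parent graph contains a cycle")
  }

  structure(
    list(
      terms = data.frame(id = ids, name = names_, namespace = ns,
                         obsolete = obs, stringsAsFactors = FALSE),
      parents = parents
    ),
    class = "ontology"
  )
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d terms (%d obsolete) in namespaces: %s\n",
              nrow(x$terms), sum(x$terms$obsolete),
              paste(sort(unique(stats::na.omit(x$terms$namespace))), collapse = ", ")))
  invisible(x)
}

#' All ancestors of each ontology term (including the term itself)
#'
#' @param ontology an [load_ontology()] result.
#' @return named list: term id -> character vector of the term and all its
#'   ancestors via `is_a`/`part_of`.
#' @export
term_ancestors <- function(ontology) {
  memo <- new.env(parent = emptyenv())
  anc <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    ps <- ontology$parents[[id]]
    ps <- ps[ps %in% names(ontology$parents)]
    out <- unique(c(id, unlist(lapply(ps, anc), use.names = FALSE)))
    memo[[id]] <- out
    out
  }
  stats::setNames(lapply(ontology$terms$id, anc), ontology$terms$id)
}

#' Experimental GO evidence codes
#'
#' The default evidence filter: manually curated experimental and
#' high-throughput experimental codes, excluding computational inference
#' (IEA and friends).
#'
#' @return character vector of evidence codes.
#' @export
experimental_evidence_codes <- function() {
  c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP",
    "HTP", "HDA", "HMP", "HGI", "HEP")
}

#' Load GO annotations from a GAF 2.x file
#'
#' Restricts rows to the accepted evidence codes, skips `NOT`-qualified
#' annotations and annotations to unknown or obsolete terms (counted, never
#' fatal), and propagates every direct annotation to all ancestors of its
#' term. The default population (enrichment background) is the set of all
#' annotated genes.
#'
#' @param gaf_path path to a GAF 2.x file (`!` comment lines ignored).
#' @param ontology an [load_ontology()] result.
#' @param evidence_codes accepted evidence codes; defaults to
#'   [experimental_evidence_codes()]. `NULL` accepts all codes.
#' @return object of class `annotation_set`: list with `term_to_genes`
#'   (named list, ancestor-propagated), `population` (character),
#'   `evidence_filter`, and `skipped` (named integer vector of skip reasons).
#' @export
load_annotations <- function(gaf_path, ontology,
                             evidence_codes = experimental_evidence_codes()) {
  if (!file.exists(gaf_path)) stop("file not found: ", gaf_path)
  stopifnot(inherits(ontology, "ontology"))
  lines <- readLines(gaf_path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  skipped <- c(`evidence filter` = 0L, `NOT qualifier` = 0L,
               `unknown term` = 0L, `obsolete term` = 0L, `malformed row` = 0L)
  if (length(lines) == 0) {
    return(structure(list(term_to_genes = list(), population = character(),
                          evidence_filter = evidence_codes, skipped = skipped),
                     class = "annotation_set"))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok_len <- lengths(parts) >= 7L
  skipped["malformed row"] <- sum(!ok_len)
  parts <- parts[ok_len]
  gene <- vapply(parts, `[`, "", 3L)      # DB object symbol
  qualifier <- vapply(parts, `[`, "", 4L)
  term <- vapply(parts, `[`, "", 5L)
  evidence <- vapply(parts, `[`, "", 7L)

  keep <- rep(TRUE, length(gene))
  is_not <- grepl("(^|\\|)NOT($|\\|)", qualifier)
  skipped["NOT qualifier"] <- sum(is_not)
  keep <- keep & !is_not
  if (!is.null(evidence_codes)) {
    bad_ev <- keep & !evidence %in% evidence_codes
    skipped["evidence filter"] <- sum(bad_ev)
    keep <- keep & !bad_ev
  }
  known <- term %in% ontology$terms$id
  skipped["unknown term"] <- sum(keep & !known)
  keep <- keep & known
  obsolete_ids <- ontology$terms$id[ontology$terms$obsolete]
  is_obs <- term %in% obsolete_ids
  skipped["obsolete term"] <- sum(keep & is_obs)
  keep <- keep & !is_obs

  gene <- gene[keep]; term <- term[keep]
  ancestors <- term_ancestors(ontology)

  # propagate each direct annotation up the graph
  all_terms <- unlist(ancestors[term], use.names = FALSE)
  all_genes <- rep(gene, lengths(ancestors[term]))
  t2g <- lapply(split(all_genes, all_terms), function(g) sort(unique(g)))

  structure(
    list(term_to_genes = t2g, population = sort(unique(gene)),
         evidence_filter = evidence_codes, skipped = skipped),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d terms over %d annotated genes (skipped: %s)\n",
              length(x$term_to_genes), length(x$population),
              paste(sprintf("%s %d", names(x$skipped), x$skipped), collapse = ", ")))
  invisible(x)
}

#' Right-tail hypergeometric over-representation probability
#'
#' Probability of observing at least `study_count` annotated genes when
#' drawing `study_size` genes without replacement from a population of
#' `pop_size` genes of which `pop_count` are annotated.
#'
#' @param study_count,pop_count,study_size,pop_size integers.
#' @return the upper-tail probability `P(X >= study_count)`.
#' @export
hyper_enrich_p <- function(study_count, pop_count, study_size, pop_size) {
  stats::phyper(study_count - 1L, pop_count, pop_size - pop_count, study_size,
                lower.tail = FALSE)
}

#' GO over-representation test
#'
#' Right-tailed hypergeometric test per term with Holm (Bonferroni
#' step-down) correction across the tested terms. For a term annotating
#' `pop_count` of the `pop_size` background genes, with `study_count` of the
#' `study_size` study genes hitting it, the raw p-value is the probability
#' of drawing at least `study_count` annotated genes in `study_size` draws
#' without replacement. Only terms with `study_count >= min_study_count`
#' are tested; a term is significant when its adjusted p-value is below
#' `alpha`.
#'
#' @param study a [gene_set()] (genes outside the annotation population are
#'   dropped with a warning).
#' @param annotations an [load_annotations()] result.
#' @param ontology optional [load_ontology()] result used to attach term
#'   names and namespaces.
#' @param alpha significance level on the adjusted p-value.
#' @param min_study_count minimum study hits for a term to be tested.
#' @return data frame of class `enrichment_result`, sorted by adjusted
#'   p-value: `term_id`, `name`, `namespace`, `study_count`, `study_size`,
#'   `pop_count`, `pop_size`, `p_raw`, `p_adjusted`, `significant`,
#'   `study_genes`.
#' @export
enrich <- function(study, annotations, ontology = NULL, alpha = 0.05,
                   min_study_count = 2L) {
  stopifnot(inherits(study, "gene_set"), inherits(annotations, "annotation_set"))
  pop <- annotations$population
  pop_keys <- norm_id(pop)
  study_keys <- norm_id(study$members)
  in_pop <- study_keys %in% pop_keys
  if (any(!in_pop)) {
    warning(sprintf("%d of %d study genes are not in the annotation population and were dropped",
                    sum(!in_pop), length(study_keys)))
  }
  study_keys <- unique(study_keys[in_pop])
  study_size <- length(study_keys)
  pop_size <- length(pop)

  empty <- data.frame(term_id = character(), name = character(),
                      namespace = character(), study_count = integer(),
                      study_size = integer(), pop_count = integer(),
                      pop_size = integer(), p_raw = numeric(),
                      p_adjusted = numeric(), significant = logical(),
                      study_genes = character(), stringsAsFactors = FALSE)
  if (study_size == 0) {
    warning("empty study set after intersection with the population")
    return(structure(empty, class = c("enrichment_result", "data.frame")))
  }

  rows <- lapply(names(annotations$term_to_genes), function(tid) {
    tg <- annotations$term_to_genes[[tid]]
    tg_keys <- norm_id(tg)
    hits <- tg[tg_keys %in% study_keys]
    k <- length(unique(norm_id(hits)))
    if (k < min_study_count) return(NULL)
    K <- length(unique(tg_keys))
    data.frame(term_id = tid, study_count = k, pop_count = K,
               p_raw = hyper_enrich_p(k, K, study_size, pop_size),
               study_genes = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0) {
    return(structure(empty, class = c("enrichment_result", "data.frame")))
  }

  rows$p_adjusted <- stats::p.adjust(rows$p_raw, method = "holm")
  rows$significant <- rows$p_adjusted < alpha
  rows$study_size <- study_size
  rows$pop_size <- pop_size
  if (!is.null(ontology)) {
    idx <- match(rows$term_id, ontology$terms$id)
    rows$name <- ontology$terms$name[idx]
    rows$namespace <- ontology$terms$namespace[idx]
  } else {
    rows$name <- NA_character_
    rows$namespace <- NA_character_
  }
  rows <- rows[order(rows$p_adjusted, rows$p_raw, rows$term_id),
               c("term_id", "name", "namespace", "study_count", "study_size",
                 "pop_count", "pop_size", "p_raw", "p_adjusted", "significant",
                 "study_genes")]
  rownames(rows) <- NULL
  structure(rows, class = c("enrichment_result", "data.frame"))
}
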