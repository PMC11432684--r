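#' Normalize molecule identifiers for comparison
#'
#' Identifiers from community databases and hand-curated lists differ in
#' surrounding whitespace and letter case (miRNA names in particular appear
#' both as `hsa-miR-...` and `hsa-mir-...`). Comparison is therefore done on
#' a whitespace-stripped, case-folded key, while the first-seen spelling is
#' kept for display.
#'
#' @param x character vector of raw identifiers.
#' @return character vector of normalized comparison keys.
#' @export
norm_id <- function(x) {
  tolower(trimws(as.character(x)))
}

#' Construct a gene set
#'
#' A `gene_set` is a deduplicated collection of molecule identifiers with a
#' role tag. Members are unique under case-folded comparison; the first-seen
#' spelling of each identifier is retained for display.
#'
#' @param members character vector of identifiers (may contain duplicates).
#' @param role one of `"seed"`, `"interactor"`, `"governed"`.
#' @param label free-text dataset name.
#' @return an object of class `gene_set` with elements `members`, `role`,
#'   `label`.
#' @export
gene_set <- function(members = character(), role = c("seed", "interactor", "governed"),
                     label = "") {
  role <- match.arg(role)
  members <- trimws(as.character(members))
  members <- members[nzchar(members)]
  members <- members[!duplicated(norm_id(members))]
  structure(
    list(members = members, role = role, label = label),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d members (role: %s)\n",
              if (nzchar(x$label)) x$label else "unnamed",
              length(x$members), x$role))
  shown <- utils::head(x$members, 8L)
  cat(" ", paste(shown, collapse = ", "),
      if (length(x$members) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$members)

#' Membership test under identifier normalization
#'
#' @param ids character vector of identifiers to test.
#' @param set a `gene_set`.
#' @return logical vector, `TRUE` where the identifier is a member.
#' @export
in_gene_set <- function(ids, set) {
  stopifnot(inherits(set, "gene_set"))
  norm_id(ids) %in% norm_id(set$members)
}
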