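#' Column-mapping dialect for NPInter-style interaction tables
#'
#' NPInter releases have shifted header names between versions, so the reader
#' is driven by a dialect: a mapping from the canonical record fields to the
#' column names present in the file, plus a mapping from raw molecule-type
#' labels to the canonical type vocabulary. The default targets the NPInter
#' V5.0 experimentally validated interaction file.
#'
#' Canonical fields: `interaction_id`, `nc_name`, `nc_type`, `target_name`,
#' `target_type`, `organism`, `evidence_class`, `source`. Of these,
#' `nc_name`, `nc_type`, `target_name`, `target_type` and `organism` must be
#' present in the file; the rest are filled with `NA` when absent.
#'
#' @param columns named list overriding individual column names.
#' @return a list of class `npinter_dialect` with elements `name`, `columns`,
#'   `required`, `nc_type_map`, `target_type_map`.
#' @export
npinter_dialect <- function(columns = list()) {
  cols <- list(
    interaction_id = "interID",
    nc_name        = "ncName",
    nc_type        = "ncType",
    target_name    = "tarName",
    target_type    = "tarType",
    organism       = "organism",
    evidence_class = "class",
    source         = "datasource"
  )
  cols[names(columns)] <- columns
  structure(
    list(
      name = "npinter_v5",
      columns = cols,
      required = c("nc_name", "nc_type", "target_name", "target_type", "organism"),
      # raw labels are matched case-insensitively; anything unrecognized
      # becomes "other" (carried through, excluded later by axis construction)
      nc_type_map = c(mirna = "miRNA", lncrna = "lncRNA"),
      target_type_map = c(mrna = "mRNA", protein = "protein",
                          mirna = "miRNA", lncrna = "lncRNA")
    ),
    class = "npinter_dialect"
  )
}

#' Load an interaction-table dialect from a YAML file
#'
#' The file may define `name` and a `columns` block with any subset of the
#' canonical field names (see [npinter_dialect()]).
#'
#' @param path path to a YAML dialect description.
#' @return an `npinter_dialect` object.
#' @export
read_dialect <- function(path) {
  raw <- yaml::read_yaml(path)
  d <- npinter_dialect(columns = if (is.null(raw$columns)) list() else raw$columns)
  if (!is.null(raw$name)) d$name <- raw$name
  d
}

map_type <- function(raw, map) {
  key <- tolower(trimws(raw))
  out <- unname(map[key])
  out[is.na(out)] <- "other"
  out
}
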