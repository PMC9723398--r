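# Tab-separated input/output in the package dialect, plus a column-mapping
# route for MaxQuant "Phospho (STY)Sites"-style exports.

#' Read a phosphosite quantification table
#'
#' Reads a TSV in the package dialect (columns `site_id`, `protein_id`,
#' `amino_acid`, `position`, `sequence_window`, then
#' `ratio_<condition>_rep<k>`). Other header conventions — e.g. a MaxQuant
#' "Phospho (STY)Sites" export with columns like `Ratio H/L normalized
#' ACKR2_T3_1` — are ingested by supplying `column_map`, a named list
#' mapping dialect names to input header names; ratio columns are mapped
#' with entries like `ratio_T3_rep1 = "Ratio H/L normalized ACKR2_T3_1"`.
#'
#' @param path TSV file path.
#' @param column_map Optional named list (dialect name -> input header).
#' @return A tibble of phosphosite records.
#' @export
read_phosphosites <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop_("phosphosite table not found: %s", path)
  tab <- read.delim(path, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (nm in names(column_map)) {
      src <- column_map[[nm]]
      if (!src %in% names(tab)) {
        stop_("column '%s' (mapped to '%s') not found in %s", src, nm, path)
      }
      tab[[nm]] <- tab[[src]]
    }
    tab <- tab[, names(column_map), drop = FALSE]
  }
  need <- c("site_id", "protein_id")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop_("phosphosite table lacks required column(s): %s",
          paste(miss, collapse = ", "))
  }
  if (length(grep("^ratio_", names(tab))) == 0L) {
    stop_("phosphosite table has no 'ratio_*' columns")
  }
  tibble::as_tibble(tab)
}

#' Read an interaction edge table
#'
#' Reads a TSV with columns `node_a`, `node_b`, optional evidence scores
#' `score_experiments`/`score_databases` and an optional `relation`
#' column. STRING-style exports are ingested via `column_map` (e.g.
#' `list(node_a = "node1", node_b = "node2", score_experiments =
#' "experimentally_determined_interaction", score_databases =
#' "database_annotated")`).
#'
#' @param path TSV file path.
#' @param column_map Optional named list (dialect name -> input header).
#' @return A tibble of interaction edges.
#' @export
read_edges <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop_("edge table not found: %s", path)
  tab <- read.delim(path, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (nm in names(column_map)) {
      src <- column_map[[nm]]
      if (!src %in% names(tab)) {
        stop_("column '%s' (mapped to '%s') not found in %s", src, nm, path)
      }
      tab[[nm]] <- tab[[src]]
    }
    tab <- tab[, names(column_map), drop = FALSE]
  }
  miss <- setdiff(c("node_a", "node_b"), names(tab))
  if (length(miss) > 0L) {
    stop_("edge table lacks required column(s): %s",
          paste(miss, collapse = ", "))
  }
  if (!"relation" %in% names(tab)) tab$relation <- ""
  tab$relation[is.na(tab$relation)] <- ""
  tibble::as_tibble(tab)
}

# deterministic TSV writer: fixed 15-significant-digit formatting so equal
# inputs give byte-identical files
write_tsv_file <- function(tab, path) {
  tab <- as.data.frame(tab)
  for (cl in names(tab)) {
    if (is.numeric(tab[[cl]]) && !is.integer(tab[[cl]])) {
      tab[[cl]] <- formatC(tab[[cl]], digits = 15, format = "g")
      tab[[cl]][tab[[cl]] %in% c("NA", " NA")] <- "NA"
    }
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
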