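ANNOTATION_COLS <- c("gene_symbol", "ensembl_id", "category", "disease")
ANNOTATION_CATEGORIES <- c("protein_coding", "non_protein_coding")

# Disease terms are matched exactly after normalization: trim, collapse
# internal whitespace, fold case. No fuzzy or ontology matching.
normalize_disease <- function(x) {
  tolower(stringr::str_squish(x))
}

#' Import a gene-disease annotation table
#'
#' Reads a CSV of curated (gene, disease) pairings — the annotation relation —
#' with columns `gene_symbol`, `ensembl_id`, `category` and `disease` in any
#' order. Ensembl version suffixes are stripped; duplicate
#' (`ensembl_id`, normalized disease) rows are collapsed to the first
#' occurrence. A gene may legitimately carry both `protein_coding` and
#' `non_protein_coding` records (heterogeneous upstream sources); filters act
#' per record.
#'
#' @param path CSV file (RFC 4180, UTF-8, header required).
#' @return An object of class `gx_annotation`: a list with `records` (tibble),
#'   `n_imported` (rows read) and `n_collapsed` (duplicates dropped).
#' @section Errors:
#' A missing column raises a format error; a category outside
#' `protein_coding` / `non_protein_coding` raises a validation error listing
#' the offending line.
#' @export
import_annotations <- function(path) {
  if (!file.exists(path)) {
    gx_io_error(sprintf("annotation file not found: %s", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(ANNOTATION_COLS, names(raw))
  if (length(missing) > 0L) {
    gx_format_error(sprintf(
      "missing required column%s %s in %s",
      if (length(missing) > 1L) "s" else "",
      paste(sQuote(missing), collapse = ", "), path
    ))
  }
  raw <- raw[ANNOTATION_COLS]

  bad <- which(!raw$category %in% ANNOTATION_CATEGORIES)
  if (length(bad) > 0L) {
    gx_validation_error(sprintf(
      "unknown category %s at line %d of %s (expected %s)",
      sQuote(raw$category[[bad[[1L]]]]), bad[[1L]] + 1L, path,
      paste(sQuote(ANNOTATION_CATEGORIES), collapse = " or ")
    ))
  }

  recs <- tibble::tibble(
    gene_symbol = stringr::str_squish(raw$gene_symbol),
    ensembl_id = strip_ensembl_version(stringr::str_squish(raw$ensembl_id)),
    category = raw$category,
    disease = stringr::str_squish(raw$disease)
  )
  n_imported <- nrow(recs)
  key <- paste(recs$ensembl_id, normalize_disease(recs$disease), sep = "\r")
  recs <- recs[!duplicated(key), ]

  new_gx_annotation(recs, n_imported = n_imported,
                    n_collapsed = n_imported - nrow(recs))
}

new_gx_annotation <- function(records, n_imported = nrow(records),
                              n_collapsed = 0L) {
  structure(
    list(records = records, n_imported = n_imported,
         n_collapsed = n_collapsed),
    class = "gx_annotation"
  )
}

#' @export
print.gx_annotation <- function(x, ...) {
  cat(sprintf(
    "<gx_annotation> %d gene-disease records (%d genes, %d diseases); imported %d, collapsed %d\n",
    nrow(x$records), dplyr::n_distinct(x$records$ensembl_id),
    dplyr::n_distinct(normalize_disease(x$records$disease)),
    x$n_imported, x$n_collapsed
  ))
  invisible(x)
}

# per-record category predicate for the four-valued gene-category filter
category_keep <- function(category, filter) {
  switch(filter,
    coding = category == "protein_coding",
    non_coding = category == "non_protein_coding",
    both = rep(TRUE, length(category)),
    all = rep(TRUE, length(category)),
    gx_validation_error(sprintf("unknown category filter %s", sQuote(filter)))
  )
}

#' Genes annotated to a disease
#'
#' @param store A `gx_annotation`.
#' @param disease Disease term; matched case-insensitively after whitespace
#'   normalization. An unknown term yields an empty result, not an error.
#' @param category One of `"coding"`, `"non_coding"`, `"both"`, `"all"`.
#'   `"both"` and `"all"` impose no per-record category restriction (the
#'   distinction between them only matters when selecting against an
#'   expression dataset; see [build_matrix()]).
#' @return Tibble with columns `gene_symbol` and `ensembl_id`, ordered
#'   alphabetically by symbol, ties broken by Ensembl ID.
#' @export
genes_for_disease <- function(store, disease, category = "all") {
  stopifnot(inherits(store, "gx_annotation"))
  category <- gx_match_arg(category, c("coding", "non_coding", "both", "all"),
                           "category")
  recs <- store$records
  keep <- normalize_disease(recs$disease) == normalize_disease(disease) &
    category_keep(recs$category, category)
  out <- unique(recs[keep, c("gene_symbol", "ensembl_id")])
  out[order(out$gene_symbol, out$ensembl_id, method = "radix"), ]
}

#' Diseases annotated to a gene
#'
#' The gene may be given as an HGNC-style symbol (matched case-insensitively)
#' or as an Ensembl accession (version suffix ignored); both routes return the
#' same set.
#'
#' @param store A `gx_annotation`.
#' @param gene Gene symbol or ENSG accession.
#' @return Sorted character vector of unique disease terms (display form).
#' @export
diseases_for_gene <- function(store, gene) {
  stopifnot(inherits(store, "gx_annotation"))
  recs <- store$records
  g <- stringr::str_squish(gene)
  keep <- tolower(recs$gene_symbol) == tolower(g) |
    recs$ensembl_id == strip_ensembl_version(g)
  sort(unique(recs$disease[keep]), method = "radix")
}

#' Export an annotation store to CSV
#'
#' Import followed by export followed by re-import yields an identical record
#' set.
#'
#' @param store A `gx_annotation`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_annotations <- function(store, path) {
  stopifnot(inherits(store, "gx_annotation"))
  readr::write_csv(store$records, path, progress = FALSE)
  invisible(path)
}
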