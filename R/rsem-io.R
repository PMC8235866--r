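#' @importFrom rlang .data
NULL

RSEM_REQUIRED_COLS <- c("gene_id", "length", "effective_length",
                        "expected_count", "TPM", "FPKM")

RSEM_NUMERIC_COLS <- c("length", "effective_length", "expected_count",
                       "tpm", "fpkm")

#' Strip the version suffix from Ensembl gene accessions
#'
#' `ENSG00000000003.14` becomes `ENSG00000000003`. IDs without a version are
#' returned unchanged. Expression and annotation tables are always joined on
#' unversioned accessions.
#'
#' @param gene_id Character vector of Ensembl gene IDs.
#' @return Character vector of unversioned IDs.
#' @export
#' @examples
#' strip_ensembl_version(c("ENSG00000000003.14", "ENSG00000000005"))
strip_ensembl_version <- function(gene_id) {
  sub("\\.\\d+$", "", gene_id)
}

#' Parse one RSEM `.genes.results` file
#'
#' Reads the tab-separated gene-level quantification table RSEM writes per
#' sample. Required columns are `gene_id`, `length`, `effective_length`,
#' `expected_count`, `TPM` and `FPKM`; column order does not matter and extra
#' columns (such as `transcript_id(s)`) are ignored. Ensembl version suffixes
#' are stripped on ingest.
#'
#' @param path Path to a `.genes.results` file (UTF-8; LF or CRLF line ends).
#' @param sample_id Label to attach to every record.
#' @return A tibble with one row per gene and columns `sample_id`, `gene_id`,
#'   `length`, `effective_length`, `expected_count`, `tpm`, `fpkm`.
#' @section Errors:
#' A missing required column raises a format error naming the column; a
#' non-numeric value in a numeric column raises a parse error with the file
#' line number; a duplicated gene (after version stripping) raises an
#' integrity error.
#' @export
parse_genes_results <- function(path, sample_id) {
  if (!file.exists(path)) {
    gx_io_error(sprintf("RSEM file not found: %s", path))
  }
  stopifnot(is.character(sample_id), length(sample_id) == 1L)

  lines <- readr::read_lines(path)
  if (length(lines) == 0L) {
    gx_format_error(sprintf("empty file (no header line): %s", path))
  }
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  missing <- setdiff(RSEM_REQUIRED_COLS, header)
  if (length(missing) > 0L) {
    gx_format_error(sprintf(
      "missing required column%s %s in %s",
      if (length(missing) > 1L) "s" else "",
      paste(sQuote(missing), collapse = ", "), path
    ))
  }

  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    return(tibble::tibble(
      sample_id = character(), gene_id = character(),
      length = double(), effective_length = double(),
      expected_count = double(), tpm = double(), fpkm = double()
    ))
  }

  fields <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  bad_rows <- which(nfield < length(header))
  if (length(bad_rows) > 0L) {
    gx_parse_error(sprintf(
      "line %d of %s has %d fields, expected %d",
      bad_rows[[1L]] + 1L, path, nfield[[bad_rows[[1L]]]], length(header)
    ))
  }

  col <- function(name) {
    j <- match(name, header)
    vapply(fields, `[[`, character(1L), j)
  }

  out <- tibble::tibble(
    sample_id = sample_id,
    gene_id = strip_ensembl_version(col("gene_id")),
    length = col("length"),
    effective_length = col("effective_length"),
    expected_count = col("expected_count"),
    tpm = col("TPM"),
    fpkm = col("FPKM")
  )

  for (nm in RSEM_NUMERIC_COLS) {
    raw <- out[[nm]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw))
    if (length(bad) > 0L) {
      src <- c(length = "length", effective_length = "effective_length",
               expected_count = "expected_count", tpm = "TPM", fpkm = "FPKM")[[nm]]
      gx_parse_error(sprintf(
        "non-numeric value %s in column %s at line %d of %s",
        sQuote(raw[[bad[[1L]]]]), sQuote(src), bad[[1L]] + 1L, path
      ))
    }
    out[[nm]] <- val
  }

  dup <- out$gene_id[duplicated(out$gene_id)]
  if (length(dup) > 0L) {
    gx_integrity_error(sprintf(
      "duplicate gene_id %s in %s", sQuote(dup[[1L]]), path
    ))
  }
  out
}

#' Load a cohort of RSEM files into an expression dataset
#'
#' @param sample_map Named character vector or named list mapping `sample_id`
#'   to a `.genes.results` path. The mapping's order defines the dataset's
#'   sample order.
#' @param check_tpm_sums If `TRUE` (default) emit a validation warning for any
#'   sample whose TPM column does not sum to 1e6 within relative tolerance
#'   1e-3. Subset files are legal, hence a warning rather than an error.
#' @return An object of class `gx_dataset`: a list with `samples` (ordered
#'   sample IDs), `genes` (union of per-file gene sets, in order of first
#'   appearance) and `records` (the long tibble of quantifications). Missing
#'   (sample, gene) pairs are stored as absent; matrix construction decides
#'   how to materialize them (see [build_matrix()]).
#' @export
load_cohort <- function(sample_map, check_tpm_sums = TRUE) {
  paths <- unlist(sample_map, use.names = TRUE)
  if (length(paths) == 0L) {
    gx_validation_error("sample_map must contain at least one sample")
  }
  ids <- names(paths)
  if (is.null(ids) || any(!nzchar(ids))) {
    gx_validation_error("every entry of sample_map must be named by a sample_id")
  }
  if (anyDuplicated(ids)) {
    gx_integrity_error(sprintf(
      "duplicate sample_id %s in sample_map", sQuote(ids[duplicated(ids)][[1L]])
    ))
  }

  records <- Map(function(sid, p) {
    tryCatch(
      parse_genes_results(p, sid),
      gx_error = function(e) {
        rlang::abort(
          sprintf("sample %s: %s", sQuote(sid), conditionMessage(e)),
          class = grep("^gx_", class(e), value = TRUE),
          parent = e
        )
      }
    )
  }, ids, unname(paths))
  records <- dplyr::bind_rows(records)

  ds <- new_gx_dataset(
    samples = ids,
    genes = unique(records$gene_id),
    records = records
  )
  if (check_tpm_sums) validate_tpm_sums(ds)
  ds
}

new_gx_dataset <- function(samples, genes, records) {
  structure(
    list(samples = samples, genes = genes, records = records),
    class = "gx_dataset"
  )
}

#' @export
print.gx_dataset <- function(x, ...) {
  cat(sprintf(
    "<gx_dataset> %d samples x %d genes (%d records)\n",
    length(x$samples), length(x$genes), nrow(x$records)
  ))
  invisible(x)
}

# Warn (not error) when a complete RSEM file should sum to 1e6 TPM but does
# not; subset files legitimately violate this.
validate_tpm_sums <- function(dataset, rel_tol = 1e-3) {
  sums <- tapply(dataset$records$tpm, dataset$records$sample_id, sum)
  off <- names(sums)[abs(sums - 1e6) > rel_tol * 1e6]
  for (sid in off) {
    gx_warn(sprintf(
      "sample %s: TPM sums to %.1f, not 1e6 (subset file?)",
      sQuote(sid), sums[[sid]]
    ))
  }
  invisible(setdiff(dataset$samples, off))
}

#' Write gene-level records back to RSEM `.genes.results` format
#'
#' The inverse of [parse_genes_results()]. Numeric columns are printed with
#' two decimals, RSEM's own convention, so a write/parse round trip reproduces
#' values at the full written precision.
#'
#' @param records Tibble with the columns produced by [parse_genes_results()]
#'   (the `sample_id` column is ignored; one file holds one sample).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genes_results <- function(records, path) {
  header <- paste(c("gene_id", "transcript_id(s)", "length",
                    "effective_length", "expected_count", "TPM", "FPKM"),
                  collapse = "\t")
  rows <- sprintf(
    "%s\t%s\t%.2f\t%.2f\t%.2f\t%.2f\t%.2f",
    records$gene_id, paste0(records$gene_id, ".t1"),
    records$length, records$effective_length,
    records$expected_count, records$tpm, records$fpkm
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n")
  invisible(path)
}

#' Write every sample of a dataset to RSEM files in a directory
#'
#' @param dataset A `gx_dataset`.
#' @param dir Output directory (created if needed). One
#'   `<sample_id>.genes.results` file per sample.
#' @return Named character vector of written paths.
#' @export
write_dataset_rsem <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(dataset$samples, function(sid) {
    p <- file.path(dir, paste0(sid, ".genes.results"))
    write_genes_results(
      dataset$records[dataset$records$sample_id == sid, ], p
    )
    p
  }, character(1L))
  invisible(paths)
}
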