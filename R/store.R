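# Single-file embedded store with the two-relation layout: gene_expression
# (one row per sample x gene) and gene_disease_annotation (one row per
# gene x disease). Schema creation and loading are idempotent; re-importing
# the same data leaves the store unchanged.

store_connect <- function(path, create = FALSE) {
  if (!create && !file.exists(path)) {
    gx_io_error(sprintf("store not found: %s", path))
  }
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  DBI::dbExecute(con, "
    CREATE TABLE IF NOT EXISTS gene_expression (
      sample_id TEXT NOT NULL,
      gene_id TEXT NOT NULL,
      length REAL, effective_length REAL, expected_count REAL,
      tpm REAL, fpkm REAL,
      PRIMARY KEY (sample_id, gene_id)
    )")
  DBI::dbExecute(con, "
    CREATE TABLE IF NOT EXISTS gene_disease_annotation (
      gene_symbol TEXT NOT NULL,
      ensembl_id TEXT NOT NULL,
      category TEXT NOT NULL,
      disease TEXT NOT NULL,
      PRIMARY KEY (ensembl_id, disease)
    )")
  con
}

#' Write an expression dataset into an embedded store
#'
#' @param dataset A `gx_dataset` from [load_cohort()].
#' @param path SQLite file path (created on first use). Loading is
#'   idempotent: existing (sample, gene) rows are replaced, never duplicated.
#' @return `path`, invisibly.
#' @export
store_write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "gx_dataset"))
  con <- store_connect(path, create = TRUE)
  on.exit(DBI::dbDisconnect(con))
  DBI::dbWithTransaction(con, {
    DBI::dbExecute(
      con,
      "INSERT OR REPLACE INTO gene_expression
       (sample_id, gene_id, length, effective_length, expected_count, tpm, fpkm)
       VALUES (:sample_id, :gene_id, :length, :effective_length,
               :expected_count, :tpm, :fpkm)",
      params = as.list(dataset$records)
    )
  })
  invisible(path)
}

#' Write an annotation store into an embedded store
#'
#' @param store A `gx_annotation` from [import_annotations()].
#' @param path SQLite file path. Idempotent like [store_write_dataset()].
#' @return `path`, invisibly.
#' @export
store_write_annotations <- function(store, path) {
  stopifnot(inherits(store, "gx_annotation"))
  con <- store_connect(path, create = TRUE)
  on.exit(DBI::dbDisconnect(con))
  DBI::dbWithTransaction(con, {
    DBI::dbExecute(
      con,
      "INSERT OR REPLACE INTO gene_disease_annotation
       (gene_symbol, ensembl_id, category, disease)
       VALUES (:gene_symbol, :ensembl_id, :category, :disease)",
      params = as.list(store$records)
    )
  })
  invisible(path)
}

#' Read the expression relation back from an embedded store
#'
#' @param path SQLite file path.
#' @param samples Optional character vector restricting (and ordering) the
#'   samples; default is all samples in first-insertion order.
#' @return A `gx_dataset`.
#' @export
store_read_dataset <- function(path, samples = NULL) {
  con <- store_connect(path)
  on.exit(DBI::dbDisconnect(con))
  recs <- tibble::as_tibble(DBI::dbGetQuery(
    con, "SELECT * FROM gene_expression ORDER BY rowid"
  ))
  if (!is.null(samples)) {
    unknown <- setdiff(samples, recs$sample_id)
    if (length(unknown) > 0L) {
      gx_reference_error(sprintf(
        "sample %s not present in store %s", sQuote(unknown[[1L]]), path
      ))
    }
    recs <- recs[recs$sample_id %in% samples, ]
    sample_order <- samples
  } else {
    sample_order <- unique(recs$sample_id)
  }
  new_gx_dataset(samples = sample_order, genes = unique(recs$gene_id),
                 records = recs)
}

#' Read the annotation relation back from an embedded store
#'
#' @param path SQLite file path.
#' @return A `gx_annotation`.
#' @export
store_read_annotations <- function(path) {
  con <- store_connect(path)
  on.exit(DBI::dbDisconnect(con))
  recs <- tibble::as_tibble(DBI::dbGetQuery(
    con, "SELECT gene_symbol, ensembl_id, category, disease
          FROM gene_disease_annotation ORDER BY rowid"
  ))
  new_gx_annotation(recs)
}

#' Summarize the contents of an embedded store
#'
#' @param path SQLite file path.
#' @return A list with `n_samples`, `n_genes`, `n_expression_rows`,
#'   `n_annotation_rows`.
#' @export
store_summary <- function(path) {
  con <- store_connect(path)
  on.exit(DBI::dbDisconnect(con))
  q1 <- DBI::dbGetQuery(con, "
    SELECT COUNT(DISTINCT sample_id) AS n_samples,
           COUNT(DISTINCT gene_id)  AS n_genes,
           COUNT(*) AS n_rows
    FROM gene_expression")
  q2 <- DBI::dbGetQuery(con,
    "SELECT COUNT(*) AS n FROM gene_disease_annotation")
  list(
    n_samples = q1$n_samples, n_genes = q1$n_genes,
    n_expression_rows = q1$n_rows, n_annotation_rows = q2$n
  )
}
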