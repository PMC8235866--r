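ABUNDANCE_TYPES <- c("tpm", "fpkm", "expected_count", "transcript_length")
CONDITION_MODES <- c("any_sample", "all_samples", "mean_of_samples")
CATEGORY_FILTERS <- c("coding", "non_coding", "both", "all")
FILL_POLICIES <- c("zero_fill", "exclude_missing")

#' Describe an expression analysis
#'
#' A query specification captures the full analysis design: which abundance
#' to analyze, the inclusive `[min_value, max_value]` window, the pruning
#' condition deciding how a gene's profile across the selected samples must
#' relate to that window, the samples (optionally partitioned into labeled
#' cohorts such as control vs diseased), the gene-category filter and an
#' optional disease restriction.
#'
#' @param samples Ordered character vector of sample IDs to analyze.
#' @param abundance `"tpm"` (default), `"fpkm"`, `"expected_count"` or
#'   `"transcript_length"` (the mean expressed transcript length).
#' @param min_value,max_value Inclusive bounds; defaults 0 and `Inf`.
#' @param condition `"any_sample"` (default; at least one selected sample in
#'   range — the convention used for a "cutoff of N TPM for any gene in a
#'   single sample"), `"all_samples"` or `"mean_of_samples"`.
#' @param cohorts Optional named list of sample-ID vectors partitioning
#'   `samples` (labels only group and annotate output columns; no
#'   between-cohort statistic is computed).
#' @param category Gene-category filter: `"coding"`, `"non_coding"`,
#'   `"both"` (any annotated gene) or `"all"` (every dataset gene, annotated
#'   or not; default).
#' @param diseases Character vector of disease terms restricting the
#'   candidate genes; empty (default) means no disease restriction.
#' @param fill_policy How missing (sample, gene) pairs materialize in
#'   matrices: `"zero_fill"` (default; RSEM's own convention of reporting 0
#'   for unexpressed genes) or `"exclude_missing"` (cells become `NA` and are
#'   ignored by threshold predicates).
#' @return An object of class `gx_query_spec`.
#' @export
query_spec <- function(samples,
                       abundance = "tpm",
                       min_value = 0,
                       max_value = Inf,
                       condition = "any_sample",
                       cohorts = NULL,
                       category = "all",
                       diseases = character(),
                       fill_policy = "zero_fill") {
  abundance <- gx_match_arg(abundance, ABUNDANCE_TYPES, "abundance")
  condition <- gx_match_arg(condition, CONDITION_MODES, "condition")
  category <- gx_match_arg(category, CATEGORY_FILTERS, "category")
  fill_policy <- gx_match_arg(fill_policy, FILL_POLICIES, "fill_policy")
  if (length(samples) == 0L) {
    gx_validation_error("samples must be non-empty")
  }
  if (anyDuplicated(samples)) {
    gx_validation_error("samples must not contain duplicates")
  }
  if (!is.numeric(min_value) || length(min_value) != 1L || min_value < 0) {
    gx_validation_error("min_value must be a single non-negative number")
  }
  if (!is.numeric(max_value) || length(max_value) != 1L || max_value <= 0) {
    gx_validation_error("max_value must be a single positive number (or Inf)")
  }
  if (min_value > max_value) {
    gx_validation_error(sprintf(
      "min_value (%g) must not exceed max_value (%g)", min_value, max_value
    ))
  }
  if (!is.null(cohorts)) {
    if (is.null(names(cohorts)) || any(!nzchar(names(cohorts)))) {
      gx_validation_error("cohorts must be a named list of sample vectors")
    }
    flat <- unlist(cohorts, use.names = FALSE)
    if (anyDuplicated(flat) || !setequal(flat, samples)) {
      gx_validation_error("cohort labels must partition the selected samples")
    }
  }
  structure(
    list(samples = as.character(samples), abundance = abundance,
         min_value = min_value, max_value = max_value,
         condition = condition, cohorts = cohorts, category = category,
         diseases = as.character(diseases), fill_policy = fill_policy),
    class = "gx_query_spec"
  )
}

#' @export
print.gx_query_spec <- function(x, ...) {
  cat(sprintf(
    "<gx_query_spec> %s in [%g, %g], %s; %d samples; category=%s; %s\n",
    x$abundance, x$min_value, x$max_value, x$condition, length(x$samples),
    x$category,
    if (length(x$diseases) == 0L) "no disease restriction"
    else paste0("diseases: ", paste(x$diseases, collapse = ", "))
  ))
  invisible(x)
}

abundance_field <- function(abundance) {
  switch(abundance,
    tpm = "tpm", fpkm = "fpkm", expected_count = "expected_count",
    transcript_length = "length"
  )
}

new_gx_matrix <- function(values, gene_symbols, fill_policy, abundance) {
  structure(
    list(values = values, gene_symbols = gene_symbols,
         fill_policy = fill_policy, abundance = abundance),
    class = "gx_matrix"
  )
}

#' @export
print.gx_matrix <- function(x, ...) {
  cat(sprintf("<gx_matrix> %s: %d genes x %d samples (%s)\n",
              x$abundance, nrow(x$values), ncol(x$values), x$fill_policy))
  invisible(x)
}

# Candidate gene selection: category/disease filters resolved against the
# annotation store, then intersected with the dataset's gene universe in
# dataset order.
candidate_genes <- function(dataset, spec, annotations) {
  if (spec$category == "all" && length(spec$diseases) == 0L) {
    return(dataset$genes)
  }
  if (is.null(annotations)) {
    gx_validation_error(
      "an annotation store is required for category or disease selection"
    )
  }
  recs <- annotations$records
  keep <- category_keep(recs$category, spec$category)
  if (length(spec$diseases) > 0L) {
    keep <- keep &
      normalize_disease(recs$disease) %in% normalize_disease(spec$diseases)
  }
  selected <- unique(recs$ensembl_id[keep])
  dataset$genes[dataset$genes %in% selected]
}

#' Build an abundance matrix for a query
#'
#' Selects candidate genes via the category/disease filters, then assembles
#' the chosen abundance as a genes x samples matrix. Under `zero_fill`,
#' missing (sample, gene) pairs become 0; under `exclude_missing` they become
#' `NA` and are skipped by threshold predicates.
#'
#' @param dataset A `gx_dataset`.
#' @param spec A `gx_query_spec`.
#' @param annotations A `gx_annotation`; required unless `category = "all"`
#'   with no disease restriction.
#' @return A `gx_matrix` with `values` (dimnames: gene IDs x sample IDs),
#'   `gene_symbols`, `fill_policy` and `abundance`. An empty candidate set
#'   yields a 0-row matrix, not an error.
#' @export
build_matrix <- function(dataset, spec, annotations = NULL) {
  stopifnot(inherits(dataset, "gx_dataset"), inherits(spec, "gx_query_spec"))
  unknown <- setdiff(spec$samples, dataset$samples)
  if (length(unknown) > 0L) {
    gx_reference_error(sprintf(
      "unknown sample_id %s in query", sQuote(unknown[[1L]])
    ))
  }
  genes <- candidate_genes(dataset, spec, annotations)
  fill <- if (spec$fill_policy == "zero_fill") 0 else NA_real_
  m <- matrix(fill, nrow = length(genes), ncol = length(spec$samples),
              dimnames = list(genes, spec$samples))
  recs <- dataset$records
  recs <- recs[recs$gene_id %in% genes & recs$sample_id %in% spec$samples, ]
  if (nrow(recs) > 0L) {
    m[cbind(match(recs$gene_id, genes), match(recs$sample_id, spec$samples))] <-
      recs[[abundance_field(spec$abundance)]]
  }
  new_gx_matrix(m, gene_symbols = gene_symbols_for(genes, annotations),
                fill_policy = spec$fill_policy, abundance = spec$abundance)
}

# Display symbol per gene: alphabetically first annotated symbol, else the
# Ensembl ID itself for unannotated genes.
gene_symbols_for <- function(genes, annotations) {
  syms <- stats::setNames(genes, genes)
  if (!is.null(annotations) && nrow(annotations$records) > 0L) {
    recs <- annotations$records[order(annotations$records$gene_symbol,
                                      method = "radix"), ]
    first <- recs[!duplicated(recs$ensembl_id), ]
    hit <- match(genes, first$ensembl_id)
    syms[!is.na(hit)] <- first$gene_symbol[hit[!is.na(hit)]]
  }
  syms
}

#' Filter matrix rows by an abundance window and pruning condition
#'
#' Retains exactly the gene rows whose profile over the matrix's samples
#' satisfies the condition against the inclusive window
#' `[min_value, max_value]`:
#' * `any_sample` — at least one sample value in range;
#' * `all_samples` — every sample value in range;
#' * `mean_of_samples` — the row mean in range.
#'
#' `NA` cells (fill policy `exclude_missing`) are ignored; a gene observed in
#' no selected sample is dropped. The column set is unchanged.
#'
#' @param matrix A `gx_matrix`.
#' @param min_value,max_value Inclusive bounds (`min_value <= max_value`).
#' @param condition One of the three pruning modes.
#' @return A `gx_matrix` with the retained rows.
#' @export
apply_threshold <- function(matrix, min_value, max_value = Inf,
                            condition = "any_sample") {
  stopifnot(inherits(matrix, "gx_matrix"))
  condition <- gx_match_arg(condition, CONDITION_MODES, "condition")
  if (min_value > max_value) {
    gx_validation_error(sprintf(
      "min_value (%g) must not exceed max_value (%g)", min_value, max_value
    ))
  }
  v <- matrix$values
  if (nrow(v) == 0L) return(matrix)
  in_range <- v >= min_value & v <= max_value
  keep <- switch(condition,
    any_sample = apply(in_range, 1L, function(r) any(r, na.rm = TRUE)),
    all_samples = apply(in_range, 1L, function(r) {
      if (all(is.na(r))) FALSE else all(r, na.rm = TRUE)
    }),
    mean_of_samples = {
      mu <- rowMeans(v, na.rm = TRUE)
      !is.nan(mu) & mu >= min_value & mu <= max_value
    }
  )
  new_gx_matrix(v[keep, , drop = FALSE],
                gene_symbols = matrix$gene_symbols[rownames(v)[keep]],
                fill_policy = matrix$fill_policy,
                abundance = matrix$abundance)
}

#' Join a filtered matrix with disease annotation
#'
#' Produces the exportable result table: one row per retained gene with its
#' symbol, Ensembl ID, per-sample abundances, mean expressed transcript
#' length (averaged over the matrix's samples from the dataset records) and
#' the sorted list of annotated diseases. Genes with no annotation are
#' retained with an empty disease list. Rows are ordered by descending mean
#' abundance, ties broken alphabetically by gene symbol.
#'
#' @param matrix A (typically threshold-filtered) `gx_matrix`.
#' @param store A `gx_annotation` (may be empty).
#' @param dataset The `gx_dataset` the matrix was built from (source of
#'   transcript lengths).
#' @return An `gx_result` tibble: `gene_symbol`, `ensembl_id`, one numeric
#'   column per sample, `mean_transcript_length`, `diseases` (list column of
#'   sorted character vectors).
#' @export
annotate_result <- function(matrix, store, dataset) {
  stopifnot(inherits(matrix, "gx_matrix"), inherits(store, "gx_annotation"),
            inherits(dataset, "gx_dataset"))
  v <- matrix$values
  genes <- rownames(v) %||% character(0)
  samples <- colnames(v) %||% character(0)

  lens <- dataset$records[
    dataset$records$gene_id %in% genes &
      dataset$records$sample_id %in% samples,
    c("gene_id", "length")
  ]
  mean_len <- if (nrow(lens) == 0L) stats::setNames(numeric(0), character(0))
              else tapply(lens$length, lens$gene_id, mean)

  symbols <- gene_symbols_for(genes, store)
  diseases <- lapply(genes, function(g) diseases_for_gene(store, g))

  out <- tibble::tibble(
    gene_symbol = unname(symbols),
    ensembl_id = genes,
    mean_transcript_length = as.numeric(mean_len[genes]),
    diseases = diseases
  )
  out <- dplyr::bind_cols(
    out[, c("gene_symbol", "ensembl_id")],
    tibble::as_tibble(v, .name_repair = "minimal"),
    out[, c("mean_transcript_length", "diseases")]
  )

  mu <- rowMeans(v, na.rm = TRUE)
  mu[is.nan(mu)] <- -Inf
  ord <- order(-mu, out$gene_symbol, out$ensembl_id, method = "radix")
  out <- out[ord, ]
  structure(out, class = c("gx_result", class(out)),
            samples = samples, abundance = matrix$abundance)
}

#' Count distinct genes per disease in a result table
#'
#' Genes carrying no annotation are counted under the reserved
#' `"(unannotated)"` key. A gene annotated to several diseases counts toward
#' each of them, so the sum over real diseases equals the number of
#' (gene, disease) pairs in the table.
#'
#' @param table A `gx_result` from [annotate_result()].
#' @return A tibble with columns `disease` and `n_genes`, sorted by disease
#'   term.
#' @export
summarize_by_disease <- function(table) {
  if (nrow(table) == 0L) {
    return(tibble::tibble(disease = character(), n_genes = integer()))
  }
  terms <- lapply(table$diseases, function(d) {
    if (length(d) == 0L) "(unannotated)" else d
  })
  long <- tibble::tibble(
    ensembl_id = rep(table$ensembl_id, lengths(terms)),
    disease = unlist(terms)
  )
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$disease),
    n_genes = dplyr::n_distinct(.data$ensembl_id), .groups = "drop"
  )
  dplyr::arrange(out, .data$disease)
}

#' Scale a TPM matrix by library size
#'
#' Transforms within-sample relative abundances to count-scale values by
#' multiplying each sample's gene-level TPMs with its total library size in
#' millions. Gene-level TPM is taken directly from the gene results (RSEM has
#' already summed transcript TPMs within genes). With a library of exactly
#' one million reads the transform is the identity; for a complete
#' quantification each scaled column sums to the sample's library size.
#'
#' @param dataset A `gx_dataset`.
#' @param library_sizes Named numeric vector, total mapped reads per sample;
#'   names must cover the samples to scale (a subset of the dataset's
#'   samples). Non-positive sizes are a validation error.
#' @return A `gx_matrix` of scaled TPMs (abundance `"scaled_tpm"`) over all
#'   dataset genes x the named samples.
#' @export
scaled_tpm_matrix <- function(dataset, library_sizes) {
  stopifnot(inherits(dataset, "gx_dataset"))
  if (is.null(names(library_sizes)) || any(!nzchar(names(library_sizes)))) {
    gx_validation_error("library_sizes must be named by sample_id")
  }
  unknown <- setdiff(names(library_sizes), dataset$samples)
  if (length(unknown) > 0L) {
    gx_reference_error(sprintf(
      "unknown sample_id %s in library_sizes", sQuote(unknown[[1L]])
    ))
  }
  if (any(!is.finite(library_sizes)) || any(library_sizes <= 0)) {
    gx_validation_error("every library size must be a positive finite number")
  }
  spec <- query_spec(samples = names(library_sizes), abundance = "tpm")
  m <- build_matrix(dataset, spec)
  m$values <- sweep(m$values, 2L, library_sizes[colnames(m$values)] / 1e6, `*`)
  m$abundance <- "scaled_tpm"
  m
}
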