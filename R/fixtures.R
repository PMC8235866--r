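# Synthetic-cohort generator. Emits standard RSEM `.genes.results` files, a
# gene-disease annotation CSV and a machine-readable truth table with planted
# expression structure: per-disease gene panels whose "expressed" members
# exceed the TPM cutoff in at least one sample while every background gene
# stays below it in all samples. This makes the whole
# parse -> annotate -> filter -> summarize pipeline testable without any
# external data.

DEFAULT_PANELS <- tibble::tibble(
  term = c("Alzheimer's disease", "arthritis", "asthma", "diabetes mellitus",
           "obesity", "osteoporosis", "heart failure", "hypertension",
           "cancer"),
  panel_size = c(34L, 51L, 32L, 43L, 5L, 9L, 2L, 20L, 184L),
  expressed_fraction = c(1, 1, 1, 1, 0, 1, 1, 1, 1)
)

DECOY_DISEASES <- c("migraine", "psoriasis", "gout", "anemia", "epilepsy",
                    "glaucoma")

#' Configure a synthetic cohort
#'
#' The defaults emulate the package's reference study design: 31 RNA-seq
#' samples, nine disjoint disease panels analyzed at a 100 TPM cutoff, with
#' one panel planting zero expressed genes and one planting two (the
#' degenerate cases a summary must handle).
#'
#' @param n_samples Number of samples (default 31).
#' @param n_genes Total genes per sample (default 500).
#' @param diseases Tibble with columns `term`, `panel_size`,
#'   `expressed_fraction` (fraction of panel genes planted above the cutoff).
#'   Panels are disjoint gene sets.
#' @param cutoff TPM threshold used for planting (default 100).
#' @param background_tpm_max Upper bound for background TPMs; must be below
#'   `cutoff` (default 50).
#' @param n_housekeeping Number of unannotated high-abundance filler genes
#'   per sample that absorb the remaining TPM mass so each sample sums to
#'   exactly 1e6 (default 8).
#' @param seed Integer seed; generation is fully deterministic given the
#'   seed.
#' @return An object of class `gx_fixture_config`.
#' @export
fixture_config <- function(n_samples = 31L, n_genes = 500L,
                           diseases = DEFAULT_PANELS, cutoff = 100,
                           background_tpm_max = 50, n_housekeeping = 8L,
                           seed = 1L) {
  diseases <- tibble::as_tibble(diseases)
  need <- c("term", "panel_size", "expressed_fraction")
  if (!all(need %in% names(diseases))) {
    gx_validation_error(
      "diseases must have columns term, panel_size, expressed_fraction"
    )
  }
  if (n_samples < 1L || n_genes < 1L) {
    gx_validation_error("n_samples and n_genes must be positive")
  }
  if (anyDuplicated(normalize_disease(diseases$term))) {
    gx_validation_error("disease terms must be unique")
  }
  if (sum(diseases$panel_size) + n_housekeeping > n_genes) {
    gx_validation_error(sprintf(
      "panel sizes (%d) plus housekeeping genes (%d) exceed n_genes (%d)",
      sum(diseases$panel_size), n_housekeeping, n_genes
    ))
  }
  if (background_tpm_max >= cutoff) {
    gx_validation_error("background_tpm_max must be below cutoff")
  }
  if (any(diseases$expressed_fraction < 0 | diseases$expressed_fraction > 1)) {
    gx_validation_error("expressed_fraction must lie in [0, 1]")
  }
  structure(
    list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
         diseases = diseases, cutoff = cutoff,
         background_tpm_max = background_tpm_max,
         n_housekeeping = as.integer(n_housekeeping),
         seed = as.integer(seed)),
    class = "gx_fixture_config"
  )
}

with_preserved_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic RSEM cohort with planted gene-disease structure
#'
#' Writes one `.genes.results` file per sample, an annotation CSV and a truth
#' JSON into `dir`. Per sample, panel genes planted as "expressed" draw a TPM
#' uniform in `[cutoff, 10 * cutoff]` in at least one randomly chosen sample;
#' all other TPMs are background draws in `[0, background_tpm_max]`. A small
#' set of unannotated housekeeping genes absorbs exactly the remaining mass
#' so every sample's TPMs sum to 1e6 (RSEM's defining property) without
#' disturbing any gene's above/below-cutoff status. Expected counts are
#' derived from TPM, effective length and a drawn library size; FPKM follows
#' from the counts. Numeric columns are written at two decimals (RSEM's
#' convention) and the truth table stores the written values, so file and
#' truth agree exactly.
#'
#' @param config A `gx_fixture_config`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list: `files` (named vector of per-sample paths),
#'   `annotation_path`, `truth_path`, and `truth` — a list with `expression`
#'   (the long records tibble), `panels` (per-disease tibbles of panel genes
#'   with their `expressed` status), `expressed_sets` (per-disease character
#'   vectors of Ensembl IDs above the cutoff), `library_sizes`, `symbols`
#'   and `annotation` (the annotation tibble).
#' @export
generate_cohort <- function(config, dir) {
  stopifnot(inherits(config, "gx_fixture_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_preserved_rng(config$seed, generate_cohort_impl(config, dir))
}

generate_cohort_impl <- function(config, dir) {
  ng <- config$n_genes
  ns <- config$n_samples
  panels <- config$diseases
  cutoff <- config$cutoff

  gene_ids <- sprintf("ENSG%011d", sample.int(99999999L, ng))
  symbols <- sprintf("GX%s", formatC(sample.int(9999L, ng), width = 4L,
                                     flag = "0"))
  lengths <- round(stats::runif(ng, 500, 5000), 2)
  eff_lengths <- pmax(round(lengths - 180, 2), 1)

  # disjoint panel assignment + housekeeping fillers
  pool <- sample.int(ng)
  take <- function(n) {
    idx <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    idx
  }
  panel_idx <- lapply(panels$panel_size, take)
  hk_idx <- take(config$n_housekeeping)
  background_idx <- pool

  expressed_idx <- lapply(seq_len(nrow(panels)), function(i) {
    n_expr <- round(panels$panel_size[[i]] * panels$expressed_fraction[[i]])
    if (n_expr == 0L) integer(0)
    else sort(sample(panel_idx[[i]], n_expr))
  })

  # TPM draws: background everywhere, then overwrite expressed genes in a
  # random non-empty subset of samples with values in [cutoff, 10 * cutoff]
  tpm <- matrix(stats::runif(ng * ns, 0, config$background_tpm_max),
                nrow = ng, ncol = ns)
  for (g in unlist(expressed_idx)) {
    n_high <- 1L + stats::rbinom(1L, ns - 1L, 0.25)
    cols <- sample.int(ns, n_high)
    tpm[g, cols] <- stats::runif(n_high, cutoff, 10 * cutoff)
  }

  # housekeeping fillers absorb the remainder so each column sums to 1e6
  tpm[hk_idx, ] <- 0
  remainder <- 1e6 - colSums(tpm)
  if (any(remainder <= config$n_housekeeping * cutoff)) {
    gx_validation_error(
      "infeasible config: planted TPM mass leaves no room for housekeeping fillers"
    )
  }
  for (s in seq_len(ns)) {
    w <- stats::runif(config$n_housekeeping, 0.5, 1.5)
    tpm[hk_idx, s] <- remainder[[s]] * w / sum(w)
  }
  tpm <- round(tpm, 2)

  library_sizes <- stats::setNames(
    round(stats::runif(ns, 15e6, 40e6)),
    sprintf("S%02d", seq_len(ns))
  )
  sample_ids <- names(library_sizes)

  # expected_count from TPM, effective length and library size; FPKM from
  # counts (RSEM's own relationships)
  denom <- colSums(tpm * eff_lengths)
  counts <- round(sweep(tpm * eff_lengths, 2L, library_sizes / denom, `*`), 2)
  fpkm <- round(sweep(counts / eff_lengths, 2L, 1e9 / library_sizes, `*`), 2)

  records <- tibble::tibble(
    sample_id = rep(sample_ids, each = ng),
    gene_id = rep(gene_ids, ns),
    length = rep(lengths, ns),
    effective_length = rep(eff_lengths, ns),
    expected_count = as.vector(counts),
    tpm = as.vector(tpm),
    fpkm = as.vector(fpkm)
  )

  files <- stats::setNames(
    file.path(dir, paste0(sample_ids, ".genes.results")), sample_ids
  )
  for (s in seq_len(ns)) {
    write_genes_results(records[records$sample_id == sample_ids[[s]], ],
                        files[[s]])
  }

  # annotation: every panel gene annotated to its disease; roughly half the
  # background genes carry decoy annotations (one or two decoy diseases)
  ann <- purrr::map2_dfr(panels$term, panel_idx, function(term, idx) {
    tibble::tibble(
      gene_symbol = symbols[idx],
      ensembl_id = gene_ids[idx],
      category = sample(ANNOTATION_CATEGORIES, length(idx), replace = TRUE,
                        prob = c(0.7, 0.3)),
      disease = term
    )
  })
  decoy_pick <- background_idx[stats::runif(length(background_idx)) < 0.5]
  if (length(decoy_pick) > 0L) {
    decoys <- purrr::map_dfr(decoy_pick, function(g) {
      k <- 1L + stats::rbinom(1L, 1L, 0.3)
      tibble::tibble(
        gene_symbol = symbols[[g]],
        ensembl_id = gene_ids[[g]],
        category = sample(ANNOTATION_CATEGORIES, k, replace = TRUE),
        disease = sample(DECOY_DISEASES, k)
      )
    })
    ann <- dplyr::bind_rows(ann, decoys)
  }
  annotation_path <- file.path(dir, "annotations.csv")
  readr::write_csv(ann, annotation_path, progress = FALSE)

  truth <- list(
    expression = records,
    panels = stats::setNames(lapply(seq_len(nrow(panels)), function(i) {
      idx <- panel_idx[[i]]
      tibble::tibble(
        gene_symbol = symbols[idx],
        ensembl_id = gene_ids[idx],
        expressed = idx %in% expressed_idx[[i]]
      )
    }), panels$term),
    expressed_sets = stats::setNames(
      lapply(expressed_idx, function(idx) sort(gene_ids[idx])),
      panels$term
    ),
    library_sizes = library_sizes,
    symbols = stats::setNames(symbols, gene_ids),
    housekeeping = sort(gene_ids[hk_idx]),
    annotation = ann,
    cutoff = cutoff
  )
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(
      expressed_sets = truth$expressed_sets,
      library_sizes = as.list(truth$library_sizes),
      housekeeping = truth$housekeeping,
      cutoff = cutoff,
      n_samples = ns, n_genes = ng,
      n_annotation_rows = nrow(ann)
    ),
    truth_path, auto_unbox = TRUE, digits = NA
  )

  invisible(list(files = files, annotation_path = annotation_path,
                 truth_path = truth_path, truth = truth))
}

#' Generate a random annotation table with a known record count
#'
#' A standalone generator for exercising the annotation importer: `n_genes`
#' genes each annotated to a random number of diseases (at least one,
#' averaging `mean_diseases`) drawn from a fixed vocabulary.
#'
#' @param n_genes Number of genes (default 200).
#' @param mean_diseases Mean diseases per gene (default 3.4).
#' @param seed Integer seed.
#' @return A list with `table` (tibble of annotation rows) and `n_records`.
#' @export
generate_annotation_table <- function(n_genes = 200L, mean_diseases = 3.4,
                                      seed = 11L) {
  stopifnot(mean_diseases >= 1)
  vocab <- c(DEFAULT_PANELS$term, DECOY_DISEASES,
             paste("synthetic disorder", LETTERS))
  with_preserved_rng(seed, {
    gene_ids <- sprintf("ENSG%011d", sample.int(99999999L, n_genes))
    symbols <- sprintf("GX%s", formatC(sample.int(9999L, n_genes),
                                       width = 4L, flag = "0"))
    n_dis <- 1L + stats::rpois(n_genes, mean_diseases - 1)
    n_dis <- pmin(n_dis, length(vocab))
    rows <- purrr::map_dfr(seq_len(n_genes), function(g) {
      tibble::tibble(
        gene_symbol = symbols[[g]],
        ensembl_id = gene_ids[[g]],
        category = sample(ANNOTATION_CATEGORIES, n_dis[[g]], replace = TRUE),
        disease = sample(vocab, n_dis[[g]])
      )
    })
    list(table = rows, n_records = nrow(rows))
  })
}

MALFORMED_KINDS <- c("missing_column", "non_numeric", "duplicate_gene",
                     "bad_category", "missing_annotation_column")

#' Write a deliberately malformed fixture
#'
#' Exercises every declared parse/validation error path: an RSEM file with a
#' required column missing, a non-numeric value in a numeric column, a
#' duplicated gene, an annotation CSV with an unknown category token, and an
#' annotation CSV with a missing column.
#'
#' @param dir Output directory.
#' @param kind One of `"missing_column"`, `"non_numeric"`,
#'   `"duplicate_gene"`, `"bad_category"`, `"missing_annotation_column"`.
#' @return A list with `path`, the `error_class` the file must trigger, and
#'   `line` (the offending line, where applicable).
#' @export
generate_malformed_fixture <- function(dir, kind) {
  kind <- gx_match_arg(kind, MALFORMED_KINDS, "kind")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  good_header <- "gene_id\ttranscript_id(s)\tlength\teffective_length\texpected_count\tTPM\tFPKM"
  row <- function(id, tpm = "50.00") {
    sprintf("%s\t%s.t1\t3000.00\t2820.00\t150.00\t%s\t40.00", id, id, tpm)
  }
  switch(kind,
    missing_column = {
      p <- file.path(dir, "missing_column.genes.results")
      writeLines(c(
        "gene_id\ttranscript_id(s)\tlength\teffective_length\texpected_count\tFPKM",
        "ENSG00000000003\tENSG00000000003.t1\t3000.00\t2820.00\t150.00\t40.00"
      ), p)
      list(path = p, error_class = "gx_format_error", line = 1L)
    },
    non_numeric = {
      p <- file.path(dir, "non_numeric.genes.results")
      writeLines(c(good_header, row("ENSG00000000003"),
                   row("ENSG00000000005", tpm = "not_a_number")), p)
      list(path = p, error_class = "gx_parse_error", line = 3L)
    },
    duplicate_gene = {
      p <- file.path(dir, "duplicate_gene.genes.results")
      writeLines(c(good_header, row("ENSG00000000003.14"),
                   row("ENSG00000000003.9")), p)
      list(path = p, error_class = "gx_integrity_error", line = 3L)
    },
    bad_category = {
      p <- file.path(dir, "bad_category.csv")
      writeLines(c(
        "gene_symbol,ensembl_id,category,disease",
        "GX0001,ENSG00000000003,protein_coding,asthma",
        "GX0002,ENSG00000000005,weird_category,asthma"
      ), p)
      list(path = p, error_class = "gx_validation_error", line = 3L)
    },
    missing_annotation_column = {
      p <- file.path(dir, "missing_annotation_column.csv")
      writeLines(c(
        "gene_symbol,ensembl_id,disease",
        "GX0001,ENSG00000000003,asthma"
      ), p)
      list(path = p, error_class = "gx_format_error", line = 1L)
    }
  )
}
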