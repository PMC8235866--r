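# Shared in-code fixtures: a tiny hand-built dataset/annotation pair with
# known values, plus writers for small RSEM files.

tiny_rsem_lines <- function(rows) {
  header <- paste(c("gene_id", "transcript_id(s)", "length",
                    "effective_length", "expected_count", "TPM", "FPKM"),
                  collapse = "\t")
  c(header, rows)
}

write_tiny_rsem <- function(rows, path = withr::local_tempfile(
                              fileext = ".genes.results",
                              .local_envir = parent.frame())) {
  writeLines(tiny_rsem_lines(rows), path)
  path
}

rsem_row <- function(gene, tpm, fpkm = tpm * 0.8, count = tpm * 3,
                     len = 3000, efflen = len - 180) {
  sprintf("%s\t%s.t1\t%.2f\t%.2f\t%.2f\t%.2f\t%.2f", gene, gene, len, efflen,
          count, tpm, fpkm)
}

# dataset built directly in memory: 3 genes x 2 samples with simple values
tiny_dataset <- function() {
  recs <- tibble::tibble(
    sample_id = rep(c("A", "B"), each = 3L),
    gene_id = rep(c("ENSG00000000001", "ENSG00000000002",
                    "ENSG00000000003"), 2L),
    length = rep(c(1000, 2000, 3000), 2L),
    effective_length = rep(c(820, 1820, 2820), 2L),
    expected_count = c(10, 20, 30, 40, 50, 60),
    tpm = c(120, 50, 100, 5, 60, 0),
    fpkm = c(96, 40, 80, 4, 48, 0)
  )
  gexmap:::new_gx_dataset(samples = c("A", "B"),
                          genes = unique(recs$gene_id), records = recs)
}

tiny_annotation_csv <- function(path = withr::local_tempfile(
                                  fileext = ".csv",
                                  .local_envir = parent.frame())) {
  writeLines(c(
    "gene_symbol,ensembl_id,category,disease",
    "CTSB,ENSG00000000001,protein_coding,Alzheimer's disease",
    "CTSB,ENSG00000000001,protein_coding,arthritis",
    "LNC1,ENSG00000000002,non_protein_coding,arthritis"
  ), path)
  path
}

tiny_annotation <- function() import_annotations(tiny_annotation_csv())

# R returns NULL rownames for zero-row matrices; normalize for comparisons
rownames0 <- function(m) {
  rn <- rownames(m)
  if (is.null(rn)) character(0) else rn
}

# brute-force oracle: per-gene predicate evaluation by explicit loops
oracle_threshold <- function(values, min_value, max_value, condition) {
  keep <- logical(nrow(values))
  for (i in seq_len(nrow(values))) {
    v <- values[i, ]
    v_ok <- v[!is.na(v)]
    keep[[i]] <- switch(condition,
      any_sample = {
        hit <- FALSE
        for (x in v_ok) if (x >= min_value && x <= max_value) hit <- TRUE
        hit
      },
      all_samples = {
        if (length(v_ok) == 0L) FALSE
        else {
          ok <- TRUE
          for (x in v_ok) if (x < min_value || x > max_value) ok <- FALSE
          ok
        }
      },
      mean_of_samples = {
        if (length(v_ok) == 0L) FALSE
        else {
          mu <- sum(v_ok) / length(v_ok)
          mu >= min_value && mu <= max_value
        }
      }
    )
  }
  keep
}

# random gx_matrix for property tests
random_matrix <- function(n_genes, n_samples, na_frac = 0) {
  v <- matrix(round(stats::runif(n_genes * n_samples, 0, 200), 2),
              nrow = n_genes,
              dimnames = list(sprintf("ENSG%011d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  if (na_frac > 0) {
    v[stats::runif(length(v)) < na_frac] <- NA_real_
  }
  gexmap:::new_gx_matrix(
    v, gene_symbols = stats::setNames(rownames(v), rownames(v)),
    fill_policy = if (na_frac > 0) "exclude_missing" else "zero_fill",
    abundance = "tpm"
  )
}
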