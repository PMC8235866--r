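test_that("query_spec validates its fields", {
  expect_error(query_spec(samples = character(0)),
               class = "gx_validation_error")
  expect_error(query_spec(samples = "A", min_value = 10, max_value = 5),
               class = "gx_validation_error")
  expect_error(query_spec(samples = "A", abundance = "rpkm"),
               class = "gx_validation_error")
  expect_error(query_spec(samples = c("A", "B"),
                          cohorts = list(control = "A")),
               class = "gx_validation_error")
  spec <- query_spec(samples = c("A", "B"),
                     cohorts = list(control = "A", case = "B"))
  expect_s3_class(spec, "gx_query_spec")
})

test_that("build_matrix selects all genes when unrestricted", {
  ds <- tiny_dataset()
  m <- build_matrix(ds, query_spec(samples = c("A", "B")))
  expect_equal(dim(m$values), c(3L, 2L))
  expect_equal(m$values["ENSG00000000001", "A"], 120)
  expect_equal(m$values["ENSG00000000003", "B"], 0)
  expect_error(build_matrix(ds, query_spec(samples = "Z")),
               class = "gx_reference_error")
})

test_that("disease and category restrictions shrink the candidate set", {
  ds <- tiny_dataset()
  ann <- tiny_annotation()
  m1 <- build_matrix(ds, query_spec(samples = c("A", "B"),
                                    diseases = "Alzheimer's disease"), ann)
  expect_equal(rownames(m1$values), "ENSG00000000001")

  m2 <- build_matrix(ds, query_spec(samples = c("A", "B"),
                                    category = "non_coding"), ann)
  expect_equal(rownames(m2$values), "ENSG00000000002")

  m3 <- build_matrix(ds, query_spec(samples = c("A", "B"), category = "both"),
                     ann)
  expect_equal(nrow(m3$values), 2L)  # only annotated genes

  m4 <- build_matrix(ds, query_spec(samples = c("A", "B"),
                                    diseases = "no such disease"), ann)
  expect_equal(nrow(m4$values), 0L)
  expect_error(build_matrix(ds, query_spec(samples = "A",
                                           category = "coding")),
               class = "gx_validation_error")
})

test_that("random matrices equal brute-force per-cell lookup", {
  withr::local_seed(17)
  for (rep in 1:5) {
    ns <- sample(2:5, 1L)
    ng <- sample(3:20, 1L)
    recs <- tidyr::expand_grid(
      sample_id = sprintf("S%02d", seq_len(ns)),
      gene_id = sprintf("ENSG%011d", seq_len(ng))
    )
    recs <- recs[stats::runif(nrow(recs)) < 0.8, ]  # drop some pairs
    n <- nrow(recs)
    recs <- dplyr::mutate(recs,
      length = round(stats::runif(n, 500, 5000), 2),
      effective_length = pmax(length - 180, 1),
      expected_count = round(stats::runif(n, 0, 1000), 2),
      tpm = round(stats::runif(n, 0, 500), 2),
      fpkm = round(stats::runif(n, 0, 400), 2)
    )
    ds <- gexmap:::new_gx_dataset(
      samples = sprintf("S%02d", seq_len(ns)),
      genes = sprintf("ENSG%011d", seq_len(ng)),
      records = recs
    )
    ab <- sample(c("tpm", "fpkm", "expected_count", "transcript_length"), 1L)
    fld <- if (ab == "transcript_length") "length" else ab
    m <- build_matrix(ds, query_spec(samples = ds$samples, abundance = ab))
    for (g in ds$genes) {
      for (s in ds$samples) {
        row <- recs[recs$gene_id == g & recs$sample_id == s, ]
        expected <- if (nrow(row) == 0L) 0 else row[[fld]]
        expect_identical(unname(m$values[g, s]), expected)
      }
    }
  }
})

test_that("threshold conditions match their stated semantics", {
  v <- rbind(G1 = c(120, 5), G2 = c(50, 60))
  rownames(v) <- c("ENSG00000000001", "ENSG00000000002")
  colnames(v) <- c("A", "B")
  m <- gexmap:::new_gx_matrix(v, stats::setNames(rownames(v), rownames(v)),
                              "zero_fill", "tpm")

  any_hit <- apply_threshold(m, 100, Inf, "any_sample")
  expect_equal(rownames(any_hit$values), "ENSG00000000001")

  # vacuous filter keeps everything
  expect_equal(apply_threshold(m, 0, Inf, "any_sample")$values, v)
  expect_equal(apply_threshold(m, 0, Inf, "all_samples")$values, v)

  # inclusive boundary: a value exactly at min passes
  vb <- rbind(ENSG00000000009 = c(100, 0))
  colnames(vb) <- c("A", "B")
  mb <- gexmap:::new_gx_matrix(vb, c(ENSG00000000009 = "ENSG00000000009"),
                               "zero_fill", "tpm")
  expect_equal(nrow(apply_threshold(mb, 100, Inf, "any_sample")$values), 1L)
  expect_equal(nrow(apply_threshold(mb, 50, 100, "mean_of_samples")$values),
               1L)  # mean 50 at lower bound

  expect_error(apply_threshold(m, 10, 5), class = "gx_validation_error")
})

test_that("threshold filtering equals the exhaustive oracle on random instances", {
  withr::local_seed(23)
  for (rep in 1:40) {
    m <- random_matrix(sample(1:50, 1L), sample(1:10, 1L),
                       na_frac = sample(c(0, 0.2), 1L))
    bounds <- sort(round(stats::runif(2L, 0, 220), 1))
    cond <- sample(c("any_sample", "all_samples", "mean_of_samples"), 1L)
    got <- apply_threshold(m, bounds[[1L]], bounds[[2L]], cond)
    want <- oracle_threshold(m$values, bounds[[1L]], bounds[[2L]], cond)
    expect_identical(rownames0(got$values), rownames(m$values)[want])
  }
})

test_that("filtering is monotone in the threshold window", {
  withr::local_seed(29)
  for (rep in 1:10) {
    m <- random_matrix(30L, 6L)
    cond <- sample(c("any_sample", "all_samples", "mean_of_samples"), 1L)
    lo <- stats::runif(1L, 0, 100)
    hi <- stats::runif(1L, 100, 250)
    base <- rownames(apply_threshold(m, lo, hi, cond)$values)
    narrower <- rownames(apply_threshold(m, lo + 20, hi, cond)$values)
    wider <- rownames(apply_threshold(m, lo - 20, hi + 50, cond)$values)
    expect_true(all(narrower %in% base))
    expect_true(all(base %in% wider))
    # all_samples result is always a subset of any_sample
    expect_true(all(
      rownames(apply_threshold(m, lo, hi, "all_samples")$values) %in%
        rownames(apply_threshold(m, lo, hi, "any_sample")$values)
    ))
  }
})

test_that("annotate_result joins diseases, keeps unannotated genes and orders rows", {
  ds <- tiny_dataset()
  ann <- tiny_annotation()
  m <- build_matrix(ds, query_spec(samples = c("A", "B")))
  tab <- annotate_result(m, ann, ds)

  expect_s3_class(tab, "gx_result")
  expect_named(tab, c("gene_symbol", "ensembl_id", "A", "B",
                      "mean_transcript_length", "diseases"))
  # ordering: G1 mean 62.5 > G2 mean 55 > G3 mean 50
  expect_equal(tab$ensembl_id, c("ENSG00000000001", "ENSG00000000002",
                                 "ENSG00000000003"))
  expect_equal(tab$diseases[[1L]], c("Alzheimer's disease", "arthritis"))
  expect_equal(tab$diseases[[3L]], character(0))  # unannotated, retained
  expect_equal(tab$gene_symbol, c("CTSB", "LNC1", "ENSG00000000003"))
  expect_equal(tab$mean_transcript_length, c(1000, 2000, 3000))
})

test_that("summarize_by_disease counts distinct genes and the unannotated bucket", {
  ds <- tiny_dataset()
  ann <- tiny_annotation()
  m <- build_matrix(ds, query_spec(samples = c("A", "B")))
  s <- summarize_by_disease(annotate_result(m, ann, ds))
  expect_equal(s$n_genes[s$disease == "arthritis"], 2L)
  expect_equal(s$n_genes[s$disease == "Alzheimer's disease"], 1L)
  expect_equal(s$n_genes[s$disease == "(unannotated)"], 1L)
  # totals over real diseases equal the number of (gene, disease) pairs
  tab <- annotate_result(m, ann, ds)
  expect_equal(sum(s$n_genes[s$disease != "(unannotated)"]),
               sum(lengths(tab$diseases)))

  empty <- annotate_result(apply_threshold(m, 1e9), ann, ds)
  expect_equal(nrow(summarize_by_disease(empty)), 0L)
})

test_that("scaled TPM is the identity at one million reads and scales linearly", {
  ds <- tiny_dataset()
  m1 <- scaled_tpm_matrix(ds, c(A = 1e6, B = 1e6))
  tpm <- build_matrix(ds, query_spec(samples = c("A", "B")))$values
  expect_equal(m1$values, tpm)

  m2 <- scaled_tpm_matrix(ds, c(A = 2e7, B = 5e6))
  expect_equal(m2$values[, "A"], tpm[, "A"] * 20)
  expect_equal(m2$values[, "B"], tpm[, "B"] * 5)
  expect_equal(unname(m2$values["ENSG00000000002", "A"]), 50 * 20)

  expect_error(scaled_tpm_matrix(ds, c(A = 0, B = 1e6)),
               class = "gx_validation_error")
  expect_error(scaled_tpm_matrix(ds, c(Z = 1e6)),
               class = "gx_reference_error")
})

test_that("scaled TPM column totals equal library sizes on complete cohorts", {
  dir <- withr::local_tempdir()
  cfg <- fixture_config(n_samples = 4L, n_genes = 80L,
                        diseases = tibble::tibble(
                          term = "asthma", panel_size = 6L,
                          expressed_fraction = 1
                        ), seed = 9L)
  res <- generate_cohort(cfg, dir)
  ds <- load_cohort(res$files)
  sm <- scaled_tpm_matrix(ds, res$truth$library_sizes)
  totals <- colSums(sm$values)
  expect_equal(totals, res$truth$library_sizes[names(totals)],
               tolerance = 1e-3)
})
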