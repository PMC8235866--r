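Package: gexmap
Title: Gene-Disease Annotation and Expression Analysis of RSEM Quantifications
    with Customizable Heat Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A scriptable toolkit for RNA-seq-driven gene-disease annotation
    and expression analysis. Reads RSEM per-gene quantification files for a
    sample cohort, joins them against a curated gene-disease annotation table,
    filters genes by abundance thresholds under configurable pruning
    conditions (any sample, all samples, or cohort mean), and exports
    disease-wise results as customizable heat maps (PNG/TIFF) and CSV tables.
    Includes an embedded SQLite store mirroring the two-relation design
    (gene expression and gene-disease annotation), a scaled-TPM transform for
    count-scale downstream analysis, a synthetic-cohort generator with planted
    gene-disease expression structure for fully reproducible testing, and a
    command-line interface covering the whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    DBI,
    RSQLite,
    dplyr,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
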