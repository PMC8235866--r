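---
title: "Methods: gene-disease expression analysis with gexmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-disease expression analysis with gexmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gexmap)
```

## The two-relation model

`gexmap` treats a cohort analysis as a join between two relations.

The **gene expression** relation holds one row per (sample, gene) with the
fields RSEM reports at gene level: mean expressed transcript length,
effective length, expected count, TPM and FPKM. TPM is the primary
abundance: it is a within-sample relative measure that sums to $10^6$ over
a complete quantification, which makes thresholds comparable across
samples. Ensembl version suffixes are stripped on ingest so that
expression and annotation always join on unversioned ENSG accessions.
Missing (sample, gene) pairs can occur with subset files; by default they
materialize as 0 in matrices (matching RSEM's own convention of reporting
0 for unexpressed genes), with an `exclude_missing` fill policy that
instead treats them as absent and makes threshold predicates skip them.

The **gene–disease annotation** relation holds curated
(symbol, ENSG, category, disease) rows. Disease terms are matched exactly
after normalization (trim, collapse internal whitespace, case-fold); no
fuzzy or ontology matching is attempted, because the analysis treats
disease as a selectable categorical label. A gene may carry both a
`protein_coding` and a `non_protein_coding` record — heterogeneous
upstream sources do disagree — and filters deliberately operate per
record rather than per gene, so no precedence rule has to be invented.
Duplicate (ENSG, disease) rows are collapsed on import, keeping the first
occurrence.

Both relations can be persisted in a single-file SQLite store with
`INSERT OR REPLACE` loading, so re-importing the same data is idempotent.

## Query semantics

A query is: an abundance type, an inclusive window
$[v_{\min}, v_{\max}]$, a pruning condition, an ordered sample selection
(optionally partitioned into labeled cohorts), a gene-category filter and
an optional disease restriction.

The three pruning conditions are `any_sample` (some selected sample in
range), `all_samples` (every selected sample in range) and
`mean_of_samples` (row mean in range). `any_sample` is the default
because it corresponds to the common screening question — "which genes
exceed 100 TPM in at least one patient" — and the other two are its
obvious universal and average counterparts; no further modes are offered.
Comparisons are **inclusive** at both bounds: a gene at exactly 100 TPM
passes a min-100 filter. This is the conventional reading of "cutoff",
and it is pinned by tests so the convention cannot drift.

Two structural properties follow and are tested as invariants: the
retained set under `all_samples` is always a subset of the set under
`any_sample`, and filtering is monotone (raising `min_value` never adds a
gene; widening the window never removes one).

Cohort labels (e.g. control vs diseased) group and annotate output
columns only. No between-cohort statistic is computed — differential
expression is explicitly out of scope for this package — so labels never
influence which genes are retained.

Result rows are ordered by descending mean abundance, ties broken
alphabetically by gene symbol then Ensembl ID. Some deterministic order
is required for reproducible exports; mean abundance puts the strongest
signals at the top of tables and heat maps. Genes with no annotation are
retained with an empty disease list and are counted under a reserved
`"(unannotated)"` key by `summarize_by_disease()`; a gene annotated to
several diseases counts toward each, so per-disease counts sum to the
number of (gene, disease) pairs.

### Scaled TPM

`scaled_tpm_matrix()` multiplies each sample's gene-level TPM by
$L_s/10^6$ (library size in millions), yielding count-scale values that
carry sequencing-depth information into any downstream count-based
method. Gene-level TPM is taken directly from the `.genes.results` file —
RSEM has already summed transcript TPMs within genes — so no isoform
parsing is needed. Two checks pin the semantics: a library of exactly
$10^6$ reads is the identity, and on complete quantifications each scaled
column sums to its library size (to within the 2-decimal file precision).

## Heat-map rendering

The renderer is deliberately device-free: the raster is composed directly
as a pixel array and written with fixed PNG compression settings or as
uncompressed TIFF, and titles/labels are drawn with an embedded 5×7
bitmap font. This makes output byte-identical across runs and platforms —
a property the test suite asserts — and makes cell colors exactly
recoverable from the file (the center pixel of cell $(i,j)$ equals the
grid color, which tests verify by read-back).

Color mapping: $t = \mathrm{clamp}((v - v_{\min})/(v_{\max} -
v_{\min}), 0, 1)$, followed by piecewise-linear interpolation between the
two bracketing anchors of the gradient (anchors are 2–5 RGB triples at
evenly spaced positions). Channels are rounded **half-up**; this fixed
tie-break is what makes the grayscale midpoint exactly (128, 128, 128)
and renders reproducible. The registry ships 30 named gradients — the
identities are a design choice, the count and extensibility are the
feature — and `register_gradient()` accepts user palettes.

Transforms: `linear` (default) or `log10_plus1`
($\log_{10}(v + 1)$), offered because TPM spans orders of magnitude and a
log-like scale is usually more legible. Which scale the analyst plots is
a presentation choice; the transform provably never changes the retained
gene set or row order, only colors. With auto-ranging on a constant
matrix ($v_{\min} = v_{\max}$) the range degenerates; it is widened to
$[v, v+1]$ so every cell takes the first anchor color rather than
erroring. Missing cells under `exclude_missing` render in a fixed
`na_color` (default light gray). An empty result renders as a small
"NO GENES RETAINED" canvas rather than failing, so batch pipelines never
crash on an empty disease.

CSV export writes
`gene_symbol,ensembl_id,<samples>,mean_transcript_length,diseases` with
RFC 4180 quoting and diseases joined by `"; "`; `read_result_csv()`
inverts it at full written precision.

## The synthetic-cohort generator

`generate_cohort()` emulates the study conditions the package is designed
for: a default of **31 samples**, **500 genes**, **nine disjoint disease
panels** analyzed at a **100 TPM cutoff**. The default panels plant 34,
51, 32, 43, 0, 9, 2, 20 and 184 expressed genes for Alzheimer's disease,
arthritis, asthma, diabetes mellitus, obesity, osteoporosis, heart
failure, hypertension and cancer respectively — a size distribution
spanning two edge cases a per-disease summary must handle (an empty panel
and a two-gene panel) and a large multi-disease panel. Background TPMs
are uniform on $[0, 50]$, safely below the cutoff; each expressed panel
gene draws TPMs uniform on $[100, 1000]$ in at least one (on average
about a quarter) of the samples, giving the patient-to-patient
variability the analysis is meant to surface.

Per-sample TPMs must sum to $10^6$ — RSEM's defining property — without
disturbing any gene's above/below-cutoff status. Rather than rescaling
all values (which can push planted genes across the cutoff and would need
retry logic), the generator includes eight unannotated high-abundance
*housekeeping filler* genes per cohort whose values absorb exactly the
remaining mass in each sample, split by random weights. This is
renormalization with a factor of exactly 1: sums are exact, planting
invariants hold deterministically, and the fillers surface in results
only under `"(unannotated)"`. Biologically it mimics the handful of
housekeeping/mitochondrial genes that dominate real libraries. The
generator validates that the remainder leaves each filler above the
cutoff, and rejects infeasible panel configurations up front.

Expected counts derive from RSEM's relationship
$c_g \propto \mathrm{TPM}_g \cdot \tilde{\ell}_g$ scaled to a drawn
library size (uniform 15–40 million reads), and FPKM from
$c_g \cdot 10^9 / (\tilde{\ell}_g L)$, so the three abundance measures in
every generated file are mutually consistent. Transcript lengths are
uniform on 500–5000 bases with effective length $\ell - 180$. All numeric
columns are written at two decimals (RSEM's own convention) and the truth
table stores the written values, so file-vs-truth comparisons are exact.
Generation is a pure function of the config seed and leaves the caller's
RNG stream untouched.

What the generator does **not** emulate: gene–gene correlation,
dispersion structure, batch effects, isoform-level signal, or any
realistic disease biology — panels are random gene sets. Passing the
recovery tests therefore demonstrates that the *pipeline machinery*
(parsing, joining, thresholding, counting, export) is exact, not that the
package makes biological discoveries; on real data the interesting
variation comes from the data, while the mechanics are what this package
guarantees.

A companion malformed-fixture generator produces files exercising every
declared error path: missing required columns, non-numeric cells,
duplicated genes, unknown category tokens. Errors are classed conditions
(`gx_format_error`, `gx_parse_error`, `gx_integrity_error`,
`gx_validation_error`, ...) so callers and the CLI can separate bad input
(exit 1) from internal faults (exit 2).

## Numerical and testing choices

Problem sizes in the test suite are chosen to keep the default run fast
while covering the reference design: the oracle-equivalence suite checks
210 random instances up to 50 genes × 10 samples across all three
pruning conditions against a loop-written exhaustive oracle, and the
end-to-end recovery suite runs 20 seeds of the full 31-sample / 9-panel
design, asserting the recovered per-disease gene *sets* (not just counts)
equal the planted truth exactly. The acceptance script repeats the
pipeline computation from scratch at whatever seed it is given.

Known limitations: the annotation store is held in memory (fine for the
hundreds of thousands of pairs a curated database holds, not for
arbitrary scale); disease matching is exact-after-normalization by
design; the bitmap font covers ASCII letters, digits and common
punctuation, rendering other characters as a placeholder box; and no
statistical testing of any kind is performed — the package ends where
differential analysis begins.
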