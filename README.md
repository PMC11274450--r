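# regulink

Integrative prediction of transcription factor (TF)–target gene
interactions in R.

## The problem

Deciding whether a TF regulates a gene from any single evidence source is
unreliable: ChIP-seq peaks show binding without regulatory consequence,
knockdown experiments show consequence without directness, curated
literature is sparse, and promoter motif matches are noisy. regulink is
for computational biologists who want the consensus strategy — treat each
resource as a vote and keep the pairs that several independent channels
agree on — as a scriptable, offline-testable library rather than a web
form. It targets workflows built around public TF–target compendia
(ChIP-derived, knockdown-derived, curated and motif-based evidence
tables) and expression cohorts with tumor/normal annotation.

## What it computes

* **Evidence harmonization** — heterogeneous tab-separated TF–target
  tables become one canonical edge model `(tf, target, source,
  attributes)` with symbol normalization and per-source deduplication.
* **Motif channel** — JASPAR position frequency matrices are scanned over
  TSS-upstream promoter windows with log-odds scores
  `s(w) = Σ_j log2(p_{w_j,j} / π_{w_j})` and *exact* p-values
  `P(S ≥ s)` under the background model, computed by dynamic-programming
  convolution of the per-position score distribution (exact over distinct
  score sums for tractable motifs, fine-grid fallback otherwise). Default
  threshold `p < 1e-4`.
* **Correlation engine** — Pearson (or Spearman) `r` per annotated
  cohort with the two-sided p-value from `t = r√((n−2)/(1−r²))`;
  correlation-derived gene sets (default threshold `|r| ≥ 0.3`) join the
  evidence sets, and pan-tissue analysis flags cohorts at
  `|r| ≥ 0.3, p < 0.05`.
* **Bidirectional prediction** — targets of a TF or regulators of a gene
  by strict intersection (optionally k-of-n support) of the selected
  sets, with knockdown `|log2FC| ≥ 0.5` filtering, down-only mode, and
  Venn-region accounting whose region counts partition the union.
* **Network construction** — from a user differential-expression table
  (`|log2FC| ≥ 1`, `p < 0.05` defaults): extract the differentially
  expressed TFs known to the chosen sources, keep their
  multi-source-supported targets that are themselves DEGs, and export the
  directed graph as sorted edge-list TSV or GraphML.
* **Seeded fixtures** — a generator that plants edges, correlations,
  motif sites and DEGs with recorded ground truth, so the entire pipeline
  runs and is verified without any database download.

## Worked example

Plant 50 targets of `TF01` in five synthetic evidence sources (plus 500
decoy edges per source) and a ρ = 0.6 expression correlation for each,
then predict:

```r
library(regulink)

spec <- fixture_spec(
  seed = 42, n_tfs = 50, n_genes = 2000, n_cohorts = 1,
  n_samples_per_cohort = 500,
  planted_edges = data.frame(
    tf = "TF01", target = sprintf("G%04d", 1:50),
    sources = "htftarget,chip_atlas,knocktf,trrust,encode"),
  decoy_rate = 0.25,
  planted_correlations = data.frame(
    tf = "TF01", gene = sprintf("G%04d", 1:50),
    cohort = "COHORT1", rho = 0.6)
)
evidence <- make_evidence(spec)
expr     <- make_expression(spec)
cor_set  <- correlated_gene_set(expr, "TF01", "COHORT1", r_threshold = 0.3)
res <- predict_targets("TF01", evidence$tables,
                       knocktf_lfc_threshold = 0.5,
                       correlation_sets = list(cor_fixture = cor_set))
res
#> <prediction_result> 6 set(s), intersecting over 6
#>   htftarget             55 gene(s)  [intersected]
#>   chip_atlas            60 gene(s)  [intersected]
#>   knocktf               62 gene(s)  [intersected]
#>   trrust                57 gene(s)  [intersected]
#>   encode                61 gene(s)  [intersected]
#>   cor_fixture           50 gene(s)  [intersected]
#>   intersection: 50 gene(s)
```

Each source returns its planted 50 targets plus a handful of decoys
(55–62 genes); the strict six-way intersection removes every decoy and
returns exactly the 50 planted targets. The pan-tissue view of one pair:

```r
pan_tissue_correlation(expr, "TF01", "G0001")
#>     tf  gene  cohort         r       pvalue   n  method significant
#> 1 TF01 G0001 COHORT1 0.5948364 3.576345e-49 500 pearson        TRUE
```

The estimated `r` of 0.595 recovers the planted ρ = 0.6 and clears both
default thresholds, so the cohort is flagged significant.

The same operations are available from a shell via the thin wrapper in
`inst/cli/` (subcommands `fixtures`, `scan-motifs`, `correlate`,
`pan-correlate`, `predict-targets`, `predict-regulators`, `network`), each
writing result files plus a JSON run manifest.

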