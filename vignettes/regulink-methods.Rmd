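---
title: "Methods: integrative TF-target prediction with regulink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative TF-target prediction with regulink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulink)
```

## The problem

A transcription factor (TF) binds regulatory DNA and modulates the
transcription of its target genes. No single evidence type settles whether
a TF-target relationship is real: ChIP-seq maps physical binding but not
regulatory consequence, TF knockdown experiments show consequence but not
directness, literature curation is accurate but sparse, and motif matches
in promoters are cheap but noisy. The pragmatic strategy, used by a family
of integrative web tools, is to treat each resource as a vote and call a
pair credible when several independent evidence channels agree —
optionally requiring, in addition, that the TF and the candidate target
are co-expressed across tissues.

regulink implements that strategy as a library: evidence harmonization, a
motif channel built from first principles, an expression-correlation
filter, bidirectional prediction by set intersection, and regulatory
network construction from user differential-expression results. Every
stage is driven by plain-text files, and a seeded fixture generator
produces schema-identical synthetic inputs so the full pipeline is
testable offline.

## Evidence model

Each source contributes edges $(\mathrm{tf}, \mathrm{target})$ with
class-specific attributes: knockdown sources carry a log2 fold-change of
the target after TF perturbation, curated sources an
activation/repression mode, ChIP and motif sources a score and p-value.
Harmonization uppercases symbols, strips whitespace and collapses
duplicate pairs; for knockdown sources the row with the largest
$|\log_2 \mathrm{FC}|$ wins (the most informative perturbation), elsewhere
the first row wins. We deliberately do no alias mapping: the upstream
resources this emulates already publish plain HGNC-style symbols, and
silent alias rewriting causes more cross-source mismatches than it cures.
Duplicate genes in a differential-expression table keep the smallest
p-value. P-values of exactly zero are clamped to the smallest positive
double with a warning, so downstream $\log$ transforms stay finite.

## The motif channel

Promoters are modelled as the 2,000 bp immediately upstream of the
transcription start site (the window length is a parameter; the FASTA
input is already the window, so no genome coordinates are involved). A
motif is a position frequency matrix with counts $c_{b,j}$ for base $b$ at
column $j$, a background distribution $\pi$ (uniform by default,
overridable), and a total pseudocount $\alpha = 0.1$ distributed
proportionally to the background. The score of base $b$ at column $j$ is
the log-odds

$$ s_{b,j} = \log_2 \frac{(c_{b,j} + \alpha \pi_b) / (C_j + \alpha)}{\pi_b}, $$

with $C_j$ the raw column total, and a window's score is the sum over
columns. Both strands are scanned at every offset; minus-strand scores use
the reverse complement, and reported offsets are always forward-strand
0-based starts, so scanning the reverse complement of a promoter swaps
strand labels and maps offsets by $o' = W - L - o$ without changing the
hit multiset.

A hit's p-value is exact: the probability that a random $L$-mer drawn
i.i.d. from the background scores at least as high. The null distribution
is built by position-wise convolution. Numerically we convolve over the
*exact* attainable score sums while their count stays below a cap
(100,000 states); only for long motifs, where distinct sums proliferate,
do we fall back to a discretized grid of 10,000 bins spanning the
attainable score range, reading p-values conservatively from the bin
containing the query score. The exact path matters: adjacent word scores
of a random PWM are closer together than any practical grid resolution,
so a pure grid DP cannot agree with exhaustive enumeration to $10^{-6}$,
while exact convolution agrees to floating-point precision (the test
suite checks all $4^L$ words for $L \le 6$).

The scan threshold defaults to $p < 10^{-4}$, the documented default of
the FIMO scanner this channel emulates. No per-promoter multiple-testing
correction is applied (also the emulated default): a TF-gene edge exists
as soon as one sub-threshold hit exists. Note the granularity consequence:
a motif of length $L$ under a uniform background cannot report a p-value
below $4^{-L}$, so very short motifs cannot pass very strict thresholds
at all — the fixture generator's default motifs are 10 bp long for
exactly this reason ($4^{-10} \approx 9.5 \times 10^{-7}$).

The scanner reconciles one long-standing ambiguity by construction: where
upstream tools run two motif pipelines side by side without stating how
their outputs combine, regulink exposes a single, well-tested scanner as
one motif evidence source. Motif names are kept verbatim (dimeric motifs
included) and can be remapped to gene symbols via configuration.

## The correlation engine

Expression input is a genes × samples matrix of log-scale values with
per-sample cohort, tissue and tumor/normal annotations; values are used
as provided, with no re-normalization. For a pair of vectors the engine
reports Pearson's product-moment $r$ (or Spearman's $\rho$, i.e. Pearson
on average ranks) with the two-sided p-value from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom, computed via
`stats::cor.test(exact = FALSE)`. Missing values are removed pairwise and
$n$ is reported per pair; fewer than 3 complete pairs or a zero-variance
vector is an error, and $|r| = 1$ reports the clamp floor
(`.Machine$double.xmin`) instead of $p = 0$.

Two uses follow. `correlated_gene_set()` returns all genes whose
correlation with a TF in one cohort clears a threshold (default 0.3, the
convention of the emulated tools); the result participates in prediction
as an ordinary named set. The threshold is interpreted on $|r|$ by
default, with `signed = "positive"`/`"negative"` overrides — repressive
TF-target pairs are negatively correlated, so an absolute rule is the
safer default where the emulated tools leave the sign convention
unstated. `pan_tissue_correlation()` correlates one TF-target pair within
every cohort (optionally tumor samples only) and flags cohorts with
$|r| \ge 0.3$ and $p < 0.05$ by default; all cohorts are reported, pass
or fail. Raw p-values are used for flagging, matching the plain-threshold
convention, with an optional Benjamini-Hochberg flag across cohorts.

## Prediction by intersection

A prediction query names a symbol and a direction — targets of a TF, or
regulators of a gene — plus the sources to consult. Knockdown sources are
filtered by $|\log_2 \mathrm{FC}| \ge 0.5$ by default (the customary
slider value), and regulator queries can additionally demand
downregulation only, i.e. targets that *fall* when the TF is removed,
which is the activation-consistent reading of a knockdown experiment.
Correlation-derived sets join the per-source sets verbatim.

The intersection is strict over the selected sets; a k-of-n minimum
support mode is available but off by default. Venn-region accounting
assigns every gene in the union to exactly one region (the exact subset
of selected sets containing it), so region counts always sum to the union
size; up to 5 sets render as a Venn table/diagram, 6-7 sets as a petal
(flower) summary of per-set sizes around the common core. Support counts
over *all* sets are reported alongside, and sources contributing an empty
set are flagged so users can drop sparse sources and re-intersect — the
practical remedy when a strict core comes back empty. All output sets are
sorted for determinism.

## Network construction from user DE results

Given a user differential-expression table, DEGs are selected by
$|\log_2 \mathrm{FC}| \ge 1$ and $p < 0.05$ (the customary defaults; both
configurable). The DE-TFs are the DEGs that appear as regulators in at
least one selected source. For each DE-TF, candidate targets must be
supported by `required_support` sources — "all" by default, mirroring the
strict-intersection convention, with k-of-n exposed because dropping to
lower support is the documented way to densify a sparse network — and
must themselves be DEGs. Nodes carry role (tf/target/both) and their DE
statistics; self-loops are kept and flagged; TFs left without targets are
dropped from the graph but listed in the report. Exports are a sorted,
byte-deterministic edge-list TSV and attribute-preserving GraphML (via
igraph); a force-directed drawing is provided for inspection, but the
exported graph is the artifact.

## The fixture generator

`fixture_spec()` declares universes (50 TFs, 2,000 genes, 5 cohorts × 200
samples by default — large enough for stable correlation estimates,
small enough for seconds-scale runs) and planted ground truth:

* **Evidence**: each planted edge appears in exactly its listed sources;
  decoys are drawn uniformly per source (`round(decoy_rate * n_genes)`
  of them, 500 per source at the defaults) and never collide with planted
  pairs. Planted knockdown edges get negative log2 fold-changes of
  magnitude 0.8-2.5, i.e. clear, activation-consistent knockdown
  responses that survive the default 0.5 filter; decoys get
  Uniform(−2, 2).
* **Expression**: per-gene baselines Uniform(2, 10) with unit residual
  SD on the log scale; planted pairs are bivariate-normal with the
  requested $\rho$ within their cohort (optionally only its tumor or its
  normal samples), everything else independent.
* **Promoters**: i.i.d. background sequence with motif consensus (or its
  reverse complement) written at each planted offset; motifs are strong
  10-bp PWMs (97-vs-1 counts) so planted sites are unambiguous.
* **DEGs**: exactly the declared rows plus filler kept below any
  customary threshold ($|\log_2 \mathrm{FC}| < 0.5$, $p > 0.2$).

One integer seed drives one named pseudo-random stream per output, so
adding an output never perturbs the others and generation is
byte-reproducible. A manifest records all planted truth.

What passing tests on these fixtures shows — and what it does not: the
generator exercises schemas, planted-signal recovery and the set algebra
exactly, but its decoys are uniform and its expression is homoscedastic
bivariate normal. Real ChIP peak distributions, correlated decoy
structure, batch effects and the covariance of real tumor compendia are
deliberately out of scope, so perfect precision/recall on fixtures
validates the machinery, not biological accuracy on live databases.

## Parameters that matter

| Parameter | Default | Unit / meaning |
|---|---|---|
| `knocktf_lfc_threshold` | 0.5 | min $|\log_2 \mathrm{FC}|$ for knockdown edges |
| `knocktf_down_only` | off | keep only negative-log2FC knockdown edges |
| `r_threshold` | 0.3 | correlation-coefficient threshold |
| `p_threshold` (correlation) | 0.05 | per-cohort significance flag |
| `p_threshold` (motif scan) | 1e-4 | exact hit p-value ceiling |
| pseudocount | 0.1 | total per PWM column, split by background |
| DEG thresholds | 1.0 / 0.05 | $|\log_2 \mathrm{FC}|$ / p-value |
| `required_support` | all | sources that must support a network edge |
| promoter window | 2000 | bp upstream of the TSS |

## Numerical choices and degenerate inputs

* Exact convolution merges score sums within $10^{-9}$ (absolute) to
  absorb floating-point noise; tail queries use the same tolerance.
* Grid-mode p-values are read conservatively (never smaller than the
  exact value beyond the stated bin tolerance).
* Zero p-values are clamped to `.Machine$double.xmin`; perfect
  correlations report that floor rather than 0.
* Windows containing `N` are skipped and counted; characters outside
  `ACGTN` abort the scan naming the offending record.
* Ties in PWM consensus resolve to the first base in A, C, G, T order;
  all output gene sets and edge lists are sorted lexicographically.
* Cohorts with fewer than 3 usable samples are omitted from pan-tissue
  results rather than reported with meaningless statistics.

## Problem sizes used by the test suite

The suite verifies exactness at enumerable scale (all $4^L$ words for
$L \le 6$; brute-force set arithmetic over 100 random instances of up to
6 sets × 1,000 genes) and end-to-end recovery at the default fixture
scale (50 planted targets across 5 sources with 500 decoys each, plus a
correlation channel at $\rho = 0.6$, $n = 500$; an 8-TF/40-edge planted
network). These sizes give stable statistics with seconds-scale runs; the
same generators scale up by changing `fixture_spec()` arguments.

## Known limitations

* Human-style plain symbol matching only; no orthology or alias service.
* One motif scanner channel; no group-enrichment statistics over
  promoter sets.
* Correlation is marginal Pearson/Spearman per cohort — no partial
  correlations, confounder adjustment or isoform resolution.
* Activator/repressor calls come only from curated `mode` labels; the
  network module does not infer sign.
* The live public databases the evidence schemas emulate are not
  downloaded; predictions are only as good as the evidence tables the
  user supplies.
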