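---
title: "Methods: from count tables to co-expression and regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from count tables to co-expression and regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnanet)
```

`rnanet` implements the downstream half of an RNA-Seq analysis: it consumes
count matrices and differential-expression (DE) tables produced upstream and
turns them into normalized expression, weighted co-expression networks, GO
enrichment results, graph statistics and bipartite regulatory networks. This
vignette explains the models and procedures, the parameters that matter, the
numerical choices, and what the synthetic-data generator does and does not
emulate.

## Inputs and experimental design

The pipeline is configured by a single file (YAML or flat `key=value`)
naming the design matrix, the comparison matrix (DGECM), a significance
level, and stage-specific inputs. The design matrix has one row per sample
(`sample_id`, `sample_path`, plus covariates such as genotype, condition,
time, replicate). Each DGECM row names one comparison as two
semicolon-separated sample groups (`reference`, `treatment`); group
membership is the union of the listed identifiers, groups must be disjoint
and resolve against the design matrix. DE testing itself is out of scope:
effect sizes (log-fold-changes or beta coefficients), p- and q-values are
read from the upstream tool's tables in either the `edger`
(`logFC`/`PValue`/`FDR`) or `sleuth` (`b`/`pval`/`qval`) column dialect.

## Normalization

Counts per million are `10^6 x_gs / N_s` with `N_s` the column sum, and
log-CPM is `log2(cpm + c)`. The prior count `c` (default 0.5) only matters
for genes near zero: it bounds the log transform below by `log2(c)` and
shrinks fold-change estimates of barely expressed genes. Filtering keeps
genes with CPM ≥ `min_cpm` (default 1) in at least `min_samples` (default 2)
samples; thresholds are exposed because no universal value exists — deeper
libraries justify lower CPM cutoffs.

TMM factors correct for composition bias between samples. For each sample
against a reference (the sample whose 75th-percentile count/library-size is
closest to the mean of those percentiles), gene-wise M-values
`log2((x_g/N)/(r_g/N_r))` are trimmed 30% on each side, A-values 5% on each
side, and the factor is `2^mean(trimmed M)`, rescaled so factors have
geometric mean 1. Genes with a zero count in either sample drop out of the
pair's mean. One deliberate choice: the trimmed mean is **unweighted** by
default. Precision weights (inverse asymptotic variances of the M-values)
are available via `do_weighting = TRUE`, but they depend on absolute counts,
so a pure sequencing-depth change — which leaves every relative abundance,
M-value and trim rank untouched — would still move the weighted factors by
around a percent. We consider exact depth invariance the more valuable
property for a scaling factor whose whole purpose is to be independent of
depth; the weighted variant is retained for comparability with the common
default of DE tools.

## Co-expression networks

The similarity between genes `i` and `j` is the absolute correlation of
their expression profiles across all samples; in factorial time-series
designs the profile spans time points, treatments and genotypes, so
"co-expression" here means co-variation over the whole design. Pearson
correlation is the default; biweight midcorrelation (`bicor`) is available
where outliers are a concern. `bicor` standardizes by median and 9× the
(unscaled) median absolute deviation and applies Tukey biweights
`(1-u^2)^2 · 1[|u|<1]`; when the MAD is zero the pair falls back to Pearson
and is flagged, since the biweight standardization is undefined.

The network is *soft*: adjacency is `a_ij = s_ij^β` rather than a hard
threshold. β is chosen by the scale-free topology criterion: for each
candidate power, connectivities `k_i = Σ_{j≠i} a_ij` are binned into
`degree_bins` (default 10) equal-width bins, and `log10(frequency)` is
regressed on `log10(mean k)`; the fit R² (requiring a negative slope) is
the scale-free index. The smallest candidate with R² ≥ 0.85 wins; if none
qualifies the best-fitting candidate is returned and flagged
(`reached_cutoff = FALSE`). Empty bins are excluded from the regression;
a similarity whose connectivities are all identical is rejected as
degenerate rather than fitted.

Topological overlap replaces raw adjacency as the clustering metric because
two genes of one module should be considered close even when their direct
correlation is middling, provided they share neighbors:
`ω_ij = (ℓ_ij + a_ij)/(min(k_i,k_j) + 1 − a_ij)` with
`ℓ_ij = Σ_{u≠i,j} a_iu a_uj`. Genes are clustered by average-linkage
hierarchical clustering of `d_ij = 1 − ω_ij`.

**Tree cutting.** Branch-based ("dynamic") tree cutting has several
published variants with free parameters; we implement the deterministic
static-height variant: the tree is cut at the `tree_cut_height_quantile`
(default 0.99) quantile of the merge heights, clusters smaller than
`min_module_size` (default 30) become unassigned (label 0), and surviving
modules are labeled 1, 2, … by decreasing size. The 0.99 default reflects
that between-module merges are the last few, highest merges of the tree;
the quantile is exposed for designs with many small modules. The adaptive
hybrid variant is a possible extension, but the static cut is fully
reproducible across platforms and is what the recovery tests certify.
`hclust` resolves merge-height ties deterministically by element order, so
module detection is invariant to gene input order up to label permutation
(verified by a shuffling test).

**Eigengenes and merging.** A module's eigengene is the first right
singular vector (over samples) of its per-gene z-scored submatrix — the
profile a module summarizes to — with sign fixed so it correlates
non-negatively with the module's mean profile, and variance explained equal
to the leading singular value's share. Modules whose eigengenes cluster
below `merge_cut_height` (default 0.25, i.e. eigengene correlation above
0.75) are merged iteratively until stable. Size-1 modules get their own
z-scored profile as eigengene, variance explained 1, and a flag.

## GO enrichment

The ontology is read from OBO 1.2 (`is_a` and `part_of` edges, obsolete
terms skipped, `alt_id` aliases resolved, acyclicity enforced), and gene
annotations are propagated to all ancestors (true-path rule) before
testing. Each term with at least `min_annotated` (default 10) genes is
tested by a one-sided two-sample Kolmogorov–Smirnov test: term genes'
scores against all other genes' scores, alternative "term scores
stochastically smaller", matching score conventions where smaller is more
significant (DE p-values). p-values come from `stats::ks.test`, which uses
the exact conditional distribution when sample-size products permit and the
asymptotic bound otherwise. Raw p-values are reported deliberately — the
nested DAG makes term tests strongly dependent, so an FDR column over terms
would suggest more control than it delivers; a Benjamini–Hochberg column is
appended for convenience only. Decorrelation schemes that re-score parents
after removing significant children's genes (elim/weight-style) are out of
scope. "Most significant enrichment genes" are the union of the gene sets
of the top `k_terms` terms (ties at the cutoff all included).

## Network analytics

Reference networks arrive as source–target edge lists and are reduced to
simple undirected graphs: reversed duplicates collapse, self-loops are
dropped by default (they distort centralities; a keep flag exists), and
malformed rows land in a rejects report. DEG overlap induces the subgraph
on differentially expressed nodes, averaging isoform-level effects per gene
and flagging sign conflicts between isoforms. Metrics are classical:
unweighted betweenness, closeness as the reciprocal summed distance to
reachable vertices, eigenvector centrality, diameter per connected
component, mean local clustering with low-degree nodes counted as zero.
Hubs are the `top_k` nodes by centrality (eigenvector by default) within
each module's induced subgraph; ties break by descending centrality then
ascending gene id, so results are reproducible. All graphs export to
GraphML with their attributes and round-trip through igraph.

## Regulatory networks

Predicted regulation connects a transcription factor to a significant gene
when their |bicor| clears a user threshold τ (applied globally; edges carry
the signed correlation as an activation/repression hint). The TF side and
gene side are kept disjoint — a TF that is itself significant stays on the
TF side — so every constructed network is bipartite by invariant, checked
at construction. Path tables from time-series regulatory inference (one
file per path, regulators from an in-table column or a sidecar file)
convert to the same bipartite form through a TF-by-gene incidence matrix;
incidence and graph forms are mutually inverse. Networks from the two
provenances merge by union with per-edge provenance preserved. For the
time-series input files consumed by the external path-inference tool, the
count matrix is rearranged into one file per (genotype, condition,
replicate) with columns in design time order; replicates are kept separate
by default (averaging is an option) because replicate-level variation is
exactly what the downstream tool models as noise.

## The synthetic-data generator

`simulate_counts()` emulates a factorial time-series design: per-module
latent profiles over samples, gene log-means
`baseline + amplitude·(√ρ·latent + √(1−ρ)·noise)` so that ρ (default 0.8)
is the within-module correlation of log-means, and negative-binomial counts
(dispersion 0.1, baseline log-mean log 300 with SD 0.7, amplitude 1.5 —
values typical of moderately deep RNA-Seq of a stressed plant time course).
Planted DEGs receive a log2 fold-change shift in treatment samples; planted
TF–target groups share an extra driver component nested inside the residual
signal so TF–target correlations exceed the within-module background
without disturbing module membership. The annotation generator plants one
GO leaf term enriched in DEGs among uniform decoys; the reference-network
generator uses preferential attachment for a heavy-tailed degree
distribution; and a separate Chung–Lu-style construction provides a
similarity matrix whose soft-thresholded connectivities follow a clean
truncated power law, giving soft-threshold selection a known good answer.

What the generator does **not** emulate: GC/length biases, batch effects,
outlier samples, zero inflation, correlated noise between modules,
annotation incompleteness, or isoform-level structure beyond a trivial
one-transcript-per-gene map. Passing recovery tests therefore certify the
algorithms' correctness on well-specified signals, not robustness to every
artifact of real libraries.

## Problem sizes and determinism

The test suite exercises module recovery on 500 genes × 24 samples over
five seeds (adjusted Rand index ≥ 0.9 against planted labels), KS
calibration on 1000 simulated null terms (type-I error within the exact
binomial 99% CI at α = 0.05), oracle equivalence of the TOM and of
betweenness/closeness on twenty random 30-node instances each, planted-term
ranking across ten seeds, and a complete command-line run on a 500-gene
bundle — sizes chosen so the full suite runs in well under a minute while
leaving each statistical check enough replicates to be meaningful. Every
stochastic step derives from an explicit seed; the pipeline itself is
deterministic given its inputs, which the stage-isolation and re-run tests
verify at file level.

## Known limitations

- Blockwise/approximate TOM is not implemented; dense similarity and TOM
  matrices limit practical use to ~10⁴ genes on typical memory.
- Module–trait correlation (relating eigengenes to phenotypes) is not
  included; eigengenes are exported so it can be done downstream.
- Enrichment offers the classic KS scoring only — no Fisher's exact
  variant, no parent–child decorrelation.
- The co-expression entry point accepts either all filtered genes or a
  DEG-restricted matrix; the choice is the caller's, and results differ —
  DEG-only networks emphasize treatment-responsive structure at the cost
  of background topology.
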