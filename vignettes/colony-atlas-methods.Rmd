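---
title: "Methods: downstream statistics for colony-part cell atlases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: downstream statistics for colony-part cell atlases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonykit)
```

## Scope

Colonial hydrozoans grow as a network of polymorphic polyps (feeding and
sexual zooids) connected by stolons. When a single-cell atlas of such a
colony is sampled per body part, the questions that follow clustering are
largely independent of how the atlas itself was built: which cell types
are enriched in which part, how stable the cell-type partition is, which
co-expression modules underlie the types, where transcription factors
(TFs) sit in the module graph, which glycine-rich secreted proteins mark
part-specific types, and whether a cell type can be recognised in a
second species. colonykit implements these downstream analyses as
separate, individually testable modules, together with seeded generators
that produce synthetic inputs carrying the statistical structure each
analysis assumes. Atlas construction (normalization of a real matrix,
batch integration, graph clustering, marker finding) is out of scope.

## Synthetic data: what it emulates, and what it does not

`simulate_atlas()` draws, for every colony part, a fixed number of cells
from a multinomial over cell clusters. Part-specific composition is
induced by multiplying baseline cluster proportions by configurable
factors and renormalizing within the part, so each part remains a proper
multinomial — which also means that planting an enrichment necessarily
dilutes every other cluster in that part; this is a real compositional
effect, not an artefact, and the enrichment statistics see it. Counts
follow a gamma–Poisson (negative binomial) mixture, the standard
scRNA-seq noise model, with dedicated marker genes up-shifted in their
own cluster by a configurable natural-log fold change. The default
baseline gene means are log-normal with most genes well below one count
per cell, emulating shallow combinatorial-barcoding libraries. The
generator does **not** simulate reads, UMIs, barcodes, doublets, ambient
RNA or batch effects, so passing tests demonstrate correctness of the
statistics under the assumed model, not robustness to those artefacts.

`simulate_module_expression()` uses a latent-factor construction: genes
of a module share a standard-normal factor with loading `sqrt(r)`, giving
exact expected pairwise correlation `r` within a module and zero between
modules. `simulate_proteins()` plants X G^n X repeats (X from I/L/V/Y,
n = 1..4) at disjoint positions; filler residues immediately adjacent to
a planted flank are never glycine, so planted spans can never be silently
extended and the truth table is exact, while the rest of the filler uses
the full 20-letter alphabet and may form additional chance repeats — a
scanner must therefore recover *at least* the planted spans.

`simulate_species_pair()` composes these pieces into a cross-species
scenario: a target atlas plus a source-species marker table and a
one-to-one ortholog map in which only the homologous cluster's markers
map onto genes that truly carry signal.

All generators take an integer seed and are bit-reproducible.

## Pseudobulk and the CV filter

`aggregate_counts()` sums raw counts over the cells of each cluster.
`normalize_pseudobulk()` then applies the median-of-ratios estimator:
reference genes are those nonzero in every profile; each profile's size
factor is the median ratio of its counts to the per-gene geometric means,
rescaled so the factors have geometric mean 1. We implement the estimator
directly rather than delegating to a differential-expression package, and
cross-check it against an independent implementation in the test suite.
Two consequences of the geometric-mean-1 convention are worth noting:
single-profile input gets factor 1, and rescaling one library is absorbed
by its factor only up to one common constant shared by all profiles.
When no gene is common to all profiles the function falls back to
total-count scaling with a warning. An optional `per_million` flag
rescales each normalized profile to a counts-per-million scale; it is off
by default because the per-million step would override the size-factor
ratios.

The variability filter `cv_filter()` keeps genes whose coefficient of
variation across clusters is strictly greater than the threshold
(default 1). We use the sample (n − 1) standard deviation — the default
statistical convention; the choice matters only marginally at tens of
clusters — and exclude genes with zero mean from the ranking rather than
assigning them CV 0.

## Compositional enrichment

For a focal cluster and two parts, the 2×2 table is cluster-vs-rest
crossed with part-vs-part. The odds ratio is reported as

log2 OR = log2[ (a + ε)(d + ε) / ((b + ε)(c + ε)) ]

with a Haldane–Anscombe pseudocount ε = 0.5 by default; ε protects
against empty cells and is exposed as a parameter since only "small
positive values" are conventional. The p-value is the exact two-sided
Fisher probability on the **raw** integer counts — pseudocounts never
touch the test, which conditions on the margins and is exact as is. The
implementation sums hypergeometric probabilities over the support with
the customary 1 + 1e-7 relative tolerance for floating-point ties, and is
validated against both a from-scratch enumeration over binomial
coefficients and `stats::fisher.test`. Benjamini–Hochberg correction is
applied across clusters *within* one pairwise comparison (each comparison
is reported as its own panel), and significance tiers are assigned at
q ≤ 0.05 (*), 0.005 (**) and 0.0005 (***). Tiers are non-directional;
the sign of the log2 odds ratio carries the direction, and enrichment
calls toward a given part should combine the tier with a positive ratio
toward that part.

## Ensemble co-occurrence trees

Cluster stability is assessed by perturbed re-clustering of the
pseudobulk profiles. Highly variable genes are those whose top cluster
value exceeds the mean of the remaining clusters by more than a
fold-change threshold (default 1.5); genes expressed in exactly one
cluster are kept (infinite fold change). Each of `n_iterations` (default
1000) iterations samples 85% of the HVGs without replacement, correlates
cell types on the sampled genes (Pearson by default, on `log1p` of the
normalized profiles for variance stabilization — set `log1p = FALSE` for
already-transformed input), clusters on distance 1 − correlation with
average linkage, and cuts the dendrogram at a height drawn uniformly from
the configured interval (default 0.65–0.95). Drawing the cut height
randomly, rather than applying two fixed cuts, is our reading of a height
*interval*: the random cuts are what make the ensemble informative at
multiple resolutions, and the choice is surfaced in the configuration
rather than asserted as the only possible semantics. The co-occurrence
matrix is the fraction of iterations in which two cell types share a cut
cluster; the consensus tree hierarchically clusters 1 − co-occurrence
with the same linkage and can be exported as Newick.

## Weighted co-expression network

Adjacency is `|cor|^β` (unsigned, the default — a `signed` flag is
provided) with soft power β = 14, a value typical after a scale-free
topology fit on pseudobulk data; the fit scan itself is not
reimplemented. The topological overlap matrix is

TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)

with connectivity k excluding the diagonal, TOM_ii = 1, and is verified
against a triple-loop oracle.

Modules are detected by average-linkage clustering on 1 − TOM with a
static height scan: the tree is cut at the height that maximizes the
number of clusters of at least `min_module_size` genes (default 75), and
among tied heights the highest is taken so that peripheral genes join
their module instead of being stranded; clusters below the minimum size
become `"unassigned"`. This deliberately replaces the dynamic tree-cut
algorithm, which is a separate method in its own right; for the
well-separated block structures the package targets, both approaches
recover the planted partition, and the simplification keeps the cutter
fully transparent.

Module eigengenes are first principal components of the standardized
module expression, sign-aligned to correlate positively with their genes
on average. TF–eigengene connectivity counts, per TF class, the TF genes
with Spearman correlation ≥ 0.01 to each eigengene.

The module graph keeps edges with TOM > 0.01. Component membership is
compared to module membership with the adjusted Rand index (implemented
from the contingency-table formula; the degenerate single-cluster case
is defined as 1, and an external implementation serves as a test
oracle). Closeness of a TF is computed within its connected component on
the **unweighted** graph, (n_c − 1)/Σd, with isolated nodes at 0: the
common weighted-closeness convention treats weights as distances, which
would invert TOM semantics, so we avoid it. Cross-module weights follow
the neighbour-count normalization: a gene's neighbour count in each
module is divided by the size of the gene's own module and summed per
module pair; the reported weight is the upper-triangle entry of the
aggregated matrix.

## TF catalog

TF evidence rows (gene, source, class) from five sources — three domain
scans, reciprocal best hits against curated TFs, and orthogroup
co-membership with model-organism TFs — are pooled; a gene is kept with
at least two distinct sources. Its class is the majority vote over
sources; ties break by source priority (domain scans over RBH over
orthogroup), and an unresolvable tie yields `"ambiguous"`. Class
prominence in a cluster is the class's summed expression divided by the
number of class genes expressed there ("expressed" meaning value > 0, as
no threshold is established), optionally row-normalized to [0, 1] for
display. Class variability statistics reuse the CV convention of the
pseudobulk module.

## Repeat scanner

The scanner reports every *maximal* glycine run of length 1–4 whose
immediate neighbours on both sides are in {I, L, V, Y}. Runs of five or
more glycines match nothing — the length bound reads as a property of
the run, and decomposing a long run would double-count. Adjacent repeats
may share a flank residue (as in `IGLGGY`): the two repeats are
chemically distinct units sharing a residue, and the brute-force
substring oracle in the tests enforces the same rule, so the convention
is itself under test. Both flanks must match; ambiguity codes never
match. Coordinates are 0-based half-open everywhere, including the BED
export; the signal-region reader converts from 1-based inclusive
predictor output. Architecture summaries report per-class counts, the
majority class (ties resolved to the lexicographically first name),
union coverage, and an optional N/H/C signal-peptide overlay consumed
from a predictor table — signal-peptide prediction itself is out of
scope.

## Cross-species marker scores

Marker transfer keeps source markers with fold change ≥ 1 (on whatever
scale the source atlas reports), maps them through a strictly one-to-one
ortholog table, and deduplicates. Scoring uses the binned-control
gene-set score on `log1p`-normalized per-cell expression: genes with
nonzero total expression are ranked by dataset-wide mean and divided
into 25 bins; each set gene contributes up to 50 control genes sampled
from its bin (excluding the set); the score is the per-cell mean over
the set minus the mean over the pooled controls. Excluding all-zero
genes from the binning universe makes scores invariant to padding the
matrix with unexpressed genes. If the control pool is empty the
dataset-wide mean serves as reference. Bin and control counts follow the
scoring routine's widely used defaults and are exposed as parameters.

## Numerical conventions and degenerate inputs

* Exact test ties: probabilities equal up to a 1 + 1e-7 relative factor
  count as ties, matching the classical implementations.
* `cv_filter()` and `class_cv_stats()` error below two profiles, where a
  CV is undefined; all-zero TF classes are flagged rather than dropped.
* `ensemble_cooccurrence()` refuses constant cell-type profiles, naming
  the offender; co-occurrence matrices are symmetric with unit diagonal
  by construction.
* `detect_modules()` with fewer genes than the minimum size returns all
  `"unassigned"` with a warning; one-gene modules get their standardized
  profile as eigengene.
* Every stochastic routine takes an explicit integer seed and restores
  the caller's RNG state (`withr::with_seed`), so identical
  configurations are bit-identical and independent of call order.

## Problem sizes

The test-suite and acceptance-script simulations use 20 clusters × 3
parts × 5,000 cells per part for compositional properties (20 planted
and 50 null replicates), eight cell types over 300 genes at 200 ensemble
iterations for co-occurrence, four 100-gene modules over 500 samples for
network recovery, 1,000 random glycine-enriched sequences for the
scanner oracle, and 50 replicates of the species-pair transfer. These
sizes are chosen so each statistical property is measured with
comfortable margins while a full run stays interactive.

## Known limitations

* The compositional model treats cells as independent draws; replicate
  (library-level) variation and the negative correlation induced by
  jointly modelling all proportions are not handled — a Bayesian
  compositional model is the appropriate tool there and is intentionally
  not reimplemented.
* The static module cutter assumes well-separated modules; on real data
  with nested or overlapping co-expression structure a dynamic cutter
  will split more finely, so module counts are not comparable between
  the two.
* The fold-change definition behind HVG selection (top cluster over mean
  of the rest) and the uniform sampling of ensemble cut heights are
  documented conventions where the field uses several variants; both are
  configurable.
* Scores and correlations operate on dense matrices; the package targets
  pseudobulk-scale and desk-scale single-cell inputs, not
  atlas-of-millions sparse pipelines.
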