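---
title: "Time-aware chromatin co-accessibility networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-aware chromatin co-accessibility networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronet)
```

## The problem

Cis-regulatory elements (CRE) — enhancers and promoters — drive
spatiotemporal gene expression. Longitudinal chromatin profiling
(ATAC-seq accessibility, or histone marks such as H3K27ac by ChIP-seq)
measures the activity of tens of thousands of such regions across a time
course. Regions that are co-modulated over time plausibly belong to the
same regulatory program. `chronet` finds these groups by embedding the
regions into an undirected weighted network — nodes are regions, edges are
the Spearman rank correlation of their signal across samples — and
partitioning it into communities.

The choice of Spearman correlation is deliberate: it captures any
monotone relationship, is robust to outliers and non-normal signal
distributions, and admits a closed-form significance test. The cost is
that only statistical similarity is captured — no directionality, no
distinction between direct and indirect coupling.

## The procedure

### 1. Preprocessing

Raw counts over regions are transformed to log2 counts per million
(`log_cpm()`), with formula

$$\log_2\!\Big(\frac{x_{ij} + c}{N_j + 2c} \times 10^6\Big),$$

where $N_j$ is the library size of sample $j$ and $c$ (default 0.5) a
pseudo-count. This is a self-contained member of the log-CPM family; it
does not rescale the prior by library size as some implementations do, so
numerical parity with those is not a goal (the downstream rank
correlation is invariant to any monotone within-sample transform, which
is what makes this a safe simplification). Optional steps follow the
standard recipe for longitudinal epigenomic matrices: additive batch
correction by per-feature batch-mean equalization
(`remove_batch_effect()`; the sample-size-weighted centering preserves
each feature's grand mean exactly and is idempotent), exclusion of sex
chromosomes by exact chromosome-name match, a row-variance filter
(`filter_regions()`, default cutoff 0.1 on the log scale, sample variance
with denominator $m-1$ throughout the package), optional quantile
trimming of extremely low/high mean signals, and replicate averaging
within time points (`average_replicates()`).

The variance cutoff is exposed as a parameter because the appropriate
value depends on the assay: 0.1 suits deeply sampled designs, while
noisier cohorts warrant 1.0. The $m-1$ denominator is fixed once and
tested, since the cutoff's meaning depends on it.

### 2. Network construction

Each row is converted to tie-averaged ranks, centered, and scaled by its
population standard deviation (`rank_standardize()`), so that for two
rows the dot product divided by $m$ is exactly the Pearson correlation of
ranks — the Spearman correlation. All pairs are evaluated block-wise
(`batch_plan()`): `chunk_size` rows per chunk, and at most `step_size`
(default $10^5$) pairwise correlations materialized at once, which bounds
memory independently of $n$. The schedule provably never changes the
result: edges are re-sorted within each bin before writing, and the
acceptance suite asserts byte-identical stores across plans.

Significance thresholding converts a two-sided p-value into a minimum
correlation through the Student $t$ distribution with $df = m - 2$:

$$t_{crit} = t_{1 - p/2,\,df}, \qquad
  r_{min} = \frac{t_{crit}}{\sqrt{t_{crit}^2 + df}}.$$

No multiple-testing correction is applied at this stage; the threshold is
a graph-sparsification device, not an inferential claim about single
edges. Surviving edges are persisted into a columnar store partitioned by
0.1-wide correlation bins (`[0.5, 0.6)`, ..., top bin closed at 1.0),
Parquet by default with a CSV fallback of identical schema. Binning uses
the magnitude rounded to 12 decimals so bin membership is reproducible
across platforms; pairs are oriented source < target in C-locale
(bytewise) order so stores are collation-independent.

By default only positive correlations are kept (co-accessibility, the
biological reading of the communities); `edge_sign = "absolute"` admits
anti-correlated edges binned by magnitude with the sign preserved, for
users who want antagonistic programs in one graph.

### 3. Threshold selection

For each bin boundary $\tau$ the package computes edge count, density,
global transitivity, the largest connected component (LCC) and the
relative LCC over the thresholded graph (`build_series()`). Every region
of the input matrix remains a node even when isolated — so density and
rLCC use the total node count as denominator, a convention pinned by a
dedicated test (reported densities under the connected-nodes convention
would differ, which matters when comparing with other tools).
`select_threshold()` picks the $\tau$ with maximal rLCC; ties go to the
*largest* $\tau$, which discards weak edges that do not change the
reachable topology. Transitivity of a triangle-free graph is defined as 0
rather than NaN so series are always comparable.

### 4. Community detection

The thresholded weighted graph is partitioned with the Leiden algorithm
(RB-configuration modularity objective) at each resolution $\gamma$ in a
grid, default 0.5–1.5 in steps of 0.1 (`detect_communities()`). For
cross-grid comparability, the quality of each resulting partition is then
re-evaluated as standard modularity at $\gamma = 1$:

$$Q = \frac{1}{2W} \sum_{ij} \Big[w_{ij} -
  \frac{s_i s_j}{2W}\Big]\,\delta(c_i, c_j),$$

and `select_resolution()` returns the $\gamma$ maximizing this $Q$, ties
to the smaller $\gamma$ (the coarser partition, guarding against
over-fragmentation). Running Leiden on the weighted graph is the default;
`weighted = FALSE` binarizes. The seed is fixed (default 42) and set
before every Leiden call, making label vectors byte-reproducible.
Community ids are reassigned by decreasing size so community 1 is always
the largest; isolated nodes can either stay unlabeled or form one
trailing "disconnected" community (id = max + 1) that participates in the
annotation stage — useful when the isolated fraction itself is of
interest. `partition_stability()` reports the Adjusted Rand Index between
partitions across the grid so fragmentation at high resolutions is
visible before committing to a $\gamma$.

### 5. Characterization

* **Temporal trends** (`community_trends()`): per-region z-scores
  (sample sd), summarized per community and time point by median and
  quartiles — the numbers behind trend box plots.
* **Target genes** (`regulatory_domains()`, `assign_targets()`): a
  basal-plus-extension rule with the GREAT defaults — basal window 5 kb
  upstream / 1 kb downstream of the TSS, extension up to 1 Mb from the
  TSS, stopping at the nearest neighboring basal domain. One canonical
  TSS per gene. When basal domains overlap, the extension collapses to
  zero but the basal window is always kept. Assignment is by ≥ 1 bp
  overlap (midpoint containment available), verified against a per-base
  oracle.
* **Gene-set enrichment** (`enrich_genesets()`): one-sided
  hypergeometric over-representation with the *network nodes' target
  genes* as background — using a whole-genome background would inflate
  every term; BH correction across the collection, default report cutoff
  q < 0.05 (a raw-p cutoff is available for small cohorts).
* **Genomic classes** (`annotate_classes()`): each region takes the class
  (e.g. SCREEN's PLS/pELS/dELS) of its maximal-overlap annotation
  interval, ties to the first interval in file order, no overlap =
  "unclassified"; fractions per community sum to 1.
* **Upstream TFs** (`score_tf_experiments()`, `aggregate_tf()`): for each
  TF ChIP-seq experiment, a 2×2 overlap table of community vs rest of the
  network is scored by a one-sided Fisher exact test and the sample odds
  ratio (+0.5 Haldane–Anscombe correction when a cell is zero; p floored
  at 1e-300), combined as $-\log_{10}(p)\cdot\log_2(OR)$ — the GIGGLE
  score — then averaged per TF across experiments and ranked, top 10 kept.
  This is a local, self-contained scorer over user-supplied BED files; it
  follows the same scoring formula as interval-database web services but
  runs on whatever experiment compendium the user provides, so absolute
  scores are comparable only within one compendium.
* **Liftover**: `lift_regions()` is a pass-through hook that refuses
  chain files — coordinates must arrive pre-lifted.

## The synthetic generator

`planted_design()` / `simulate_signal()` emulate the temporal structure
the method targets: K communities (default 5) of regions following
distinct archetypes on the time rank — monotone up, monotone down, early
peak, transient dip, bimodal — each scaled to unit range on the log2
scale, on a baseline of $2^8 = 256$ expected counts (typical coverage for
accessible regions; deep enough that Poisson noise does not dominate the
planted signal). Observations get i.i.d. Gaussian log-scale noise
(default sd 0.2), optional per-batch offsets, and are Poisson-sampled to
raw counts. Decoy noise-only regions are placed on chrX so the chromosome
filter is exercised end to end. Defaults: 200 regions per community,
8 time points × 2 replicates.

`simulate_annotations()` plants one gene per community region (up to 20
per community) so that each community's gene set is its expected top
enrichment, and one TF per community overlapping 100% of its community's
regions vs 5% of the rest, making it the expected top GIGGLE rank.

What the generator does *not* emulate: fragment-level read structure,
Tn5 insertion bias, peak-calling artifacts, correlated (batch-structured)
noise between regions, heavy-tailed count dispersion (a negative-binomial
extension is the obvious next step), and the spatial autocorrelation of
real chromatin domains. Passing the planted-recovery tests therefore
demonstrates the correctness of the pipeline's logic under its own model
assumptions, not performance on real data.

## Numerical choices

* Sample variance ($m-1$) everywhere except rank standardization, which
  uses the population scaling so the dot-product identity for Spearman is
  exact.
* Correlations are binned after rounding to 12 decimals; threshold
  comparisons use the same rounding, so an edge exactly on a boundary is
  treated identically everywhere.
* Degenerate inputs fail loudly: constant rows must be filtered before
  ranking; z-scoring a zero-variance row, an edgeless graph's modularity,
  and an all-filtered matrix are errors, not silent NaNs.
* `pvalue_to_min_correlation(1, m)` returns exactly 0; p = 0 is rejected.
* ARI of two identical trivial partitions is defined as 1.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline on the
default planted design (1 000 regions + 50 decoys, 16 samples, ~500 000
candidate pairs), 50 × 200-region oracle comparisons, and 12 batch-plan
combinations — sizes chosen so the whole suite completes in well under a
minute on one core while still exceeding the regime where chunking and
binning logic can hide errors. The engine itself is bounded by
`step_size` memory-wise and scales to the $10^4$–$10^5$-node networks
typical of genome-wide CRE sets.

## Known limitations

Correlation networks capture similarity, not causation or direction;
small or noisy cohorts yield unstable edges (the p-value threshold guards
the false-positive rate per edge but the network is not a joint
inferential object); communities depend on the resolution grid supplied,
and the automatic selector optimizes a single scalar (modularity at
$\gamma = 1$) that can be flat across neighboring resolutions — inspect
`partition_stability()` before interpreting fine splits. The local TF
scorer ranks only the experiments provided and inherits their biases.
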