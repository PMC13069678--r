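# chronet — time-aware chromatin co-accessibility networks

Longitudinal epigenomic profiling (ATAC-seq, histone ChIP-seq) measures
the activity of tens of thousands of cis-regulatory elements (CRE) across
a time course. `chronet` groups CRE into *communities with coherent
temporal behavior* by building a co-accessibility network — nodes are
genomic regions, edges the Spearman rank correlation ρ of their
log-normalized signal across samples — and partitioning it with the
Leiden algorithm. It is aimed at anyone with a regions × samples count
matrix from a time course (cell-line stimulation, organ development,
disease progression cohorts) who wants interpretable groups of
co-modulated regions plus their likely target genes, pathways and
upstream transcription factors.

## Method at a glance

1. **Preprocess**: log2-CPM normalization, optional batch-mean
   correction, sex-chromosome and low-variance filters, replicate
   averaging.
2. **Network**: all-pairs Spearman correlations via standardized ranks
   (ρ = Zₐ·Z_b / m), computed in memory-bounded chunks and persisted to a
   correlation-binned Parquet edge store. A p-value threshold is
   converted to a minimum correlation through the Student t distribution:
   t = t₁₋ₚ/₂,df with df = m − 2 and r_min = t / √(t² + df).
3. **Threshold selection**: per-threshold topology metrics (edges,
   density, transitivity, LCC); the threshold τ maximizing the relative
   largest connected component (rLCC = LCC / all nodes, isolated nodes
   included) is selected, ties to the more stringent τ.
4. **Communities**: Leiden over a resolution grid (default γ = 0.5–1.5,
   step 0.1) on the weighted graph; the γ maximizing modularity
   Q = (1/2W) Σᵢⱼ [wᵢⱼ − sᵢsⱼ/2W] δ(cᵢ,cⱼ) is selected automatically.
5. **Characterization**: temporal trend summaries, GREAT-style
   basal-plus-extension target-gene assignment, hypergeometric gene-set
   enrichment against the network background (BH-corrected), genomic
   class fractions (e.g. SCREEN PLS/pELS/dELS), and GIGGLE-score
   (−log₁₀ p × log₂ OR) TF ranking from user-supplied ChIP-seq BED files.

A synthetic generator with planted temporal communities
(`simulate_signal()`, `simulate_annotations()`) makes the whole pipeline
testable without downloads.

## Worked example

```r
library(chronet)

# a planted design: 5 communities x 200 regions, 8 time points x 2
# replicates, log-scale noise sd 0.2, plus 50 decoy regions on chrX
sim <- simulate_signal(planted_design(seed = 7))

sm <- log_cpm(sim$sm)                                   # raw counts -> log2 CPM
sm <- filter_regions(sm, drop_chroms = c("chrX", "chrY"),
                     min_variance = 0.1)                # drops decoys + flat rows
sm <- average_replicates(sm)                            # one column per time point

fit <- chronet(sm, threshold = 0.1)                     # p-value threshold
print(fit)
#> Time-aware chromatin co-accessibility network
#>   nodes: 822 (822 connected)   edges at tau: 45551
#>   selected tau (rLCC): 0.8000   rLCC: 0.5365   density: 0.135
#>   selected resolution (modularity): 0.50   Q: 0.6981
#>   communities: 5   sizes: 201, 198, 183, 144, 96

ok <- intersect(names(sim$truth), names(fit$labels))
adjusted_rand_index(sim$truth[ok], fit$labels[ok])
#> [1] 0.9730259
```

Reading the output: 822 of the 1 050 simulated regions survive the
chromosome and variance filters; the automatic scan selects a correlation
threshold of 0.8 (the rLCC optimum) and a Leiden resolution of 0.5 (the
modularity optimum), recovering the five planted communities almost
exactly (ARI 0.97; 1.0 would be a perfect match). `summary(fit)` prints
the full threshold series and resolution scan, `plot(fit)` draws them,
and `labels(fit)` returns the community label of every region.

Downstream characterization on the same objects:

```r
ann     <- simulate_annotations(sim)                    # genes, sets, classes, TF beds
domains <- regulatory_domains(ann$genes, ann$chrom_sizes)
targets <- assign_targets(sm$regions, domains)
enrich_genesets(sort(unique(unlist(targets[names(fit$labels)[fit$labels == 1]]))),
                sort(unique(unlist(targets))), ann$gene_sets)
trends  <- community_trends(sm, labels(fit))
```

A shell entry point wrapping the same functions ships in
`inst/scripts/chronet`
(`chronet simulate | preprocess | build | series | communities | annotate | run-all`),
with a YAML config for `run-all` (see `?read_run_config`).

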