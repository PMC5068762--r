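# broaddomain

Downstream analysis of **broad H3K4me3 domains** from ChIP-seq peak
calls. H3K4me3 usually marks active promoters as sharp ~1 kb peaks, but
in sorted neurons a small subset of peaks stretches over 4–12 kb, and
these broadest domains concentrate at cell-identity genes: they are far
more likely to be cell-type specific, sit almost always within ±4 kb of
a transcription start site, are partially conserved across species, and
their genes occupy central positions in gene-regulatory networks.
`broaddomain` packages that entire workflow — everything downstream of
the peak caller — for epigenomics analysts working with per-cell-type
BED interval sets.

## The statistics at the core

* **Breadth selection.** With peak lengths `L(1) <= ... <= L(n)`, the
  top-`f` set is `{i : L_i > L(ceil((1-f) n))}` — nearest-rank percentile
  with a strict threshold, so ties are excluded and the realized fraction
  is at most `f`.
* **Specificity enrichment.** For `a` specific among `b` broadest peaks
  and `c` specific among `d` total peaks: fold `= (a/b)/(c/d)`, with a
  two-sided Fisher exact test on `[[a, b-a], [c, d-c]]`.
* **Shuffle null.** Peaks are re-placed uniformly within chromosome
  bounds (lengths and per-chromosome counts preserved); association is
  scored as `fold = observed / E[null overlap]` with the add-one
  empirical p-value `(1 + #{null >= obs}) / (1 + n_perm)`, never zero.
* **Network centrality.** For a connected undirected graph, one
  Brandes-style BFS pass per source yields degree, stress
  `sum_{s!=v!=t} sigma_st(v)`, normalized betweenness
  `sum sigma_st(v)/sigma_st / [(n-1)(n-2)/2]`, eccentricity and mean
  shortest-path length; groups are compared by Wilcoxon rank-sum.
* **Paired expression.** Wilcoxon matched-pairs signed-rank test over
  genes of gray- vs white-matter mean FPKM, plus Spearman sample QC.

A synthetic-data generator (`synthetic_config()`, `simulate_all()`)
plants every one of these effects at known values — length mixture,
enrichment ratio, TSS proximity, cohort sharing, cross-species
conservation, network hubs, expression effect — so the full pipeline is
testable offline.

## Worked example

Simulate a study (two neuronal cohorts, two other cell types, genes,
networks, expression), then run the core question — are the broadest
peaks cell-type specific? — on cohort 1:

```r
library(broaddomain)

cfg <- synthetic_config(seed = 1)          # planted enrichment rho = 2
sim <- simulate_all(cfg, "sim")
c1     <- read_bed(sim$universe$paths$cohort1, cell_type = "NeuN+", cohort = "cohort1")
others <- list(read_bed(sim$universe$paths[["NeuN-"]], cell_type = "NeuN-"),
               read_bed(sim$universe$paths$blood,      cell_type = "blood"))

sel <- select_broadest(c1, fraction = 0.05)
sel$summary
#> <breadth_summary> n=1000 mean=5772.4 median=5417.5 range=[4006, 12347] threshold=4004

spec <- call_cell_type_specific(c1, others)
a <- intersect_count(sel$peaks, spec)
specificity_enrichment(a, nrow(sel$peaks), nrow(spec), nrow(c1))
#> <enrichment_result> 540/1000 vs 5400/20000: fold = 2, OR = 3.174, Fisher p = 1.59e-68
```

The broadest 5% (1000 of 20,000 peaks, mean 5.8 kb vs 1.5 kb overall)
are 2.0-fold enriched for cell-type specificity — exactly the planted
ratio. The two cohorts' broad specific peaks overlap far more than
shuffled placement allows, and the broadest peaks concentrate at TSSs:

```r
layout <- read_chrom_sizes(sim$universe$paths$chrom_sizes)
bs1 <- read_bed(sim$universe$paths$broad_specific1)
bs2 <- read_bed(sim$universe$paths$broad_specific2)
permutation_overlap_test(bs1, bs2, layout, n_perm = 1000, seed = 7)
#> <permutation_result> observed = 378, expected = 67.69 +/- 7.78, fold = 5.584, empirical p = 0.000999 (1000 shuffles)

genes <- read_gene_models(sim$universe$paths$genes)
round(tss_window_fraction(sel$peaks, genes), 3)
#> within_1000 within_2000 within_3000 within_4000
#>       0.236       0.446       0.682       0.850
```

85% of the broadest peaks lie within ±4 kb of a TSS (planted: 0.85).
`run_pipeline(out_dir, seed)` chains every stage — breadth, specificity,
reproducibility + shuffle test, annotation, cross-species conservation,
network centrality group comparison, paired gray/white expression — and
writes a JSON report with planted values alongside recovered ones.

A thin command-line wrapper over the same functions ships in
`inst/cli/broaddomain.R`
(`Rscript inst/cli/broaddomain.R broadest --bed peaks.bed --out top.bed ...`,
subcommands `broadest`, `specificity`, `shuffle-test`, `annotate`,
`conserve`, `netstats`, `expression`, `qc-correlation`, `simulate`,
`all`).

## Layout

```
R/                  breadth, specificity, shuffle, annotation, conservation,
                    network, expression, io, synthetic generator, pipeline, cli
src/node_stats.cpp  Brandes pass for the five node statistics
tests/testthat/     unit + property + acceptance suites (oracle-checked)
vignettes/          methods vignette: models, parameters, design choices
scripts/acceptance.R
```
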