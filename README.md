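# mirlag

Time-lagged miRNA–mRNA inverse-expression network integration for early
retinal degeneration in the rd10 mouse model of retinitis pigmentosa.

## The problem

In rd10 mice, photoreceptor apoptosis starts abruptly around postnatal day
16 (P16). miRNAs dysregulated *before* onset (at P13/P15) are candidate
drivers of degeneration; miRNAs shifting only *after* onset (P17) more
plausibly mark compensatory responses. `mirlag` is for researchers who
want to run, scrutinize or benchmark this style of integration analysis:

* **Differential expression** — per-feature Welch t-tests on log2 signals
  against age-matched wild-type (WT) and against the rd10 P13 pre-onset
  baseline, Benjamini–Hochberg adjustment within each comparison, and
  signed fold changes (ratio *r* reported as *r* when *r* ≥ 1 and as
  −1/*r* otherwise), with the study cutoffs |FC| ≥ 1.5 (miRNA) / 1.3
  (mRNA), adjusted *P* < 0.05, plus near-background and high-CV
  exclusions.
* **Temporal grouping** — group A (pre-onset: significant at P15 against
  both references, or at P13 vs WT) vs group B (post-onset-only:
  significant at P17 against both references with no earlier hit).
* **Inverse-expression networks** — bipartite miRNA→target networks
  (`A15`, `A17`, `B17`) from a consensus target-prediction table (≥ 2
  supporting algorithms), requiring the gene to be retina-expressed, DE at
  the network's timepoint, and opposite in sign to its regulator. `A17`
  captures the time-delayed regulator→target interaction (miRNA shifted
  at P15, target responding at P17).
* **Enrichment** — hypergeometric over-representation of the inversely
  expressed gene set against GMT annotation, with the detected-gene
  universe.
* **qPCR validation** — reference-assay selection by Ct stability,
  ΔΔCt relative quantification (ratio 2^−ΔΔCt) against the mean of the
  chosen references, and per-direction confirmation percentages.
* **Synthetic data** — a seeded generator reproducing the full study
  design (2 genotypes × P13/P15/P17 × triplicates, planted group-A/B
  signatures, delayed inverse target responses, prediction tables with
  spurious edges, Ct tables) so every stage is testable against ground
  truth.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` methods for result objects, and `autoplot()` / `plot_*()`
figures.

## Worked example

```r
library(mirlag)

cfg <- pipeline_config(sim = sim_config(
  n_mirna = 200, n_mrna = 400, frac_groupA = 0.12, frac_groupB = 0.12,
  targets_per_mirna = 4, false_prediction_rate = 0.01,
  noise_sd = 0.15, seed = 1
))
report <- run_pipeline(cfg)
report
```

```
<mirlag_report> seed 1
# A tibble: 5 × 2
  stage          n_mirna
  <chr>            <int>
1 raw                200
2 detected           185
3 de_filtered         45
4 quality_passed      45
5 grouped             30
groups: A = 10  B = 20
<interaction_network A15> 0 miRNAs, 0 genes, 0 edges
<interaction_network A17> 10 miRNAs, 20 genes, 20 edges
<interaction_network B17> 16 miRNAs, 25 genes, 25 edges
<validation_summary>
# A tibble: 3 × 4
  direction tested confirmed pct_confirmed
  <chr>      <int>     <int>         <dbl>
1 down          14        14         100
2 up            16        15          93.8
3 overall       30        29          96.7
```

Reading the output: of 200 simulated miRNAs, 185 pass the detection
filter, 45 pass the fold-change/significance filters in at least one
comparison, and 30 classify into a temporal group (10 pre-onset, 20
post-onset). Network `A15` is empty while `A17` holds 20 edges — the
planted target responses are delayed to P17, so pre-onset regulators pair
with their targets only in the lagged network, the signature the analysis
is designed to expose. ΔΔCt validation confirms 29/30 candidates (96.7%).

Each piece is inspectable:

```r
generics::glance(report$networks$A17)
#> # A tibble: 1 × 4
#>   network n_mirnas n_genes n_edges
#> 1 A17           10      20      20

head(report$enrichment[, c("term_id", "k", "K", "n", "p_adj")], 3)
#> 1 planted_05    11    18    45 0.0000249   <- planted term recovered
#> 2 random_025     5    17    45 0.693
#> 3 random_038     5    17    45 0.693
```

With `outdir` set, every intermediate table is written as TSV and the
networks additionally as SIF and GraphML for Cytoscape-style viewers. A
thin command-line wrapper lives in `inst/scripts/mirlag-pipeline.R`.

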