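---
title: "Methods: time-lagged miRNA-mRNA integration in early retinal degeneration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-lagged miRNA-mRNA integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirlag)
library(dplyr)
```

## The scientific problem

In the rd10 mouse, a point mutation in *Pde6b* triggers rod photoreceptor
apoptosis beginning around postnatal day 16 (P16). miRNAs whose expression
shifts *before* that onset are candidate drivers of degeneration; miRNAs
shifting only *after* onset more plausibly reflect compensatory responses or
consequences of cell death. `mirlag` implements the full integration
analysis around that idea: differential miRNA expression between rd10 and
wild-type (WT) retinas at P13, P15 and P17; classification of candidates by
temporal onset; linkage of each candidate to predicted target mRNAs whose
expression moves in the opposite direction, allowing for a time lag between
regulator and target; over-representation analysis of the inversely
expressed gene set; and validation by multi-reference delta-delta-Ct (ddCt)
qPCR.

Because no raw data are distributed with the original arrays, a seeded
synthetic-data generator reproduces the study design with planted ground
truth, so every stage of the pipeline can be verified quantitatively.

## Models and procedures

### Differential expression

Signals are analyzed on the log2 scale. For a comparison (case group vs
control group, three replicates each by default) each feature gets a Welch
two-sample t-test on log2 signals, Benjamini-Hochberg (BH) adjustment
across all tested features within the comparison, and a signed fold change
from linear group means: a ratio $r \ge 1$ is reported as $r$, and $r < 1$
as $-1/r$, so down-regulation appears as a negative magnitude $\ge 1$.
Candidates must satisfy $|\mathrm{FC}| \ge 1.5$ (miRNA) or $\ge 1.3$
(mRNA) with adjusted $P < 0.05$. Additional quality exclusions drop
features whose median signal sits within `background_margin` (default 1.2)
times the estimated background level (median signal of features absent in
every array) or whose within-group linear coefficient of variation exceeds
`cv_max` (default 0.5).

The Welch test was chosen as the standard robust choice for n = 3 arrays
with possibly unequal variances; moderated-variance (empirical Bayes)
testing is deliberately out of scope. BH was chosen as the adjustment
because only "adjusted P" is specified by the study design this package
models; both choices are configurable nowhere — they are the package's
definition of the DE contract.

### Temporal grouping

Five comparisons define each miRNA's temporal profile: rd10 vs age-matched
WT at P13, P15 and P17, and rd10 at P15/P17 vs the rd10 P13 baseline
(pre-onset reference). Group A (pre-onset) is assigned when a feature is
significant at P15 against *both* references, or at P13 against WT (the
baseline comparison is undefined at P13). Group B (post-onset-only)
requires significance at P17 against both references *and* no
filtered-significant result at any earlier stage; A and B are mutually
exclusive by construction.

The group-A rule has a genuine ambiguity: the definition can be read as
requiring significance at *both* P13 and P15, or at *either*. The package
defaults to the disjunctive reading (`group_a_rule = "disjunctive"`),
because demanding P13 significance would conflate group A with the
strictly-earlier-onset subset; the conjunctive reading is selectable.

### Inverse-expression networks

Predicted miRNA-target pairs (a consensus table with per-pair supporting
algorithms, e.g. miRWalk/miRanda/TargetScan/RNA22) are first filtered to
pairs supported by at least two algorithms. Three bipartite networks are
then built: group A miRNAs against DE mRNAs at P15 (`A15`) and at P17
(`A17`), and group B against DE mRNAs at P17 (`B17`). An edge requires the
pair to be predicted, the miRNA to be in the group, the gene to pass the
mRNA DE filter at the network's timepoint, the gene to be detected in at
least one array (retina-expressed), and the two signed fold changes to
have opposite signs. `A17` is the time-delayed network: a regulator
dysregulated at P15 paired with targets responding two days later, the
lag the study design expects between a miRNA shift and measurable mRNA
decay.

Design choices made here: mRNA DE membership is required, not merely an
opposite sign, because the networks are defined against *DE* mRNAs; the
miRNA fold change anchoring the sign comparison is its FC vs age-matched
WT at the group's defining timepoint (P15 for group A, P17 for group B),
since that comparison defines candidacy; no extra magnitude threshold is
imposed on the mRNA side beyond the 1.3 cutoff.

### Over-representation analysis

The inversely expressed gene set (union of gene nodes over the three
networks) is tested against annotation terms with the hypergeometric upper
tail $P(X \ge k)$, BH-adjusted across terms. The universe is the set of
detected mRNA features — the expressed-in-retina background — rather than
the whole annotation, to avoid expression-bias inflation. Terms smaller
than `min_term_size = 3` (after intersection with the universe) are
skipped.

### ddCt validation

Threshold-cycle (Ct) values are normalized per biological sample to the
arithmetic mean of reference-assay Cts (equivalent to the geometric mean
of linear reference quantities). References are selected by ranking
candidate assays by the SD of their mean Ct across biological samples and
taking the most stable pair, with all pairwise $r^2$ values reported as a
coherence check. $\Delta\Delta Ct$ is the case-group mean minus the
control-group mean of per-sample $\Delta Ct$; the linear ratio is
$2^{-\Delta\Delta Ct}$ (amplification efficiency fixed at 2, as no
standard-curve correction is modeled), reported as a signed FC. A
candidate is *confirmed* when its qPCR FC has the same sign as its array
FC and its qPCR P (Welch t on per-sample $\Delta Ct$) is below 0.05; the
direction-only criterion is available via `alpha = 1`. Confirmation
percentages are reported separately for up- and down-regulated candidates.

## The synthetic-data generator

`sim_config()` fixes the simulated study conditions: two genotypes
(rd10, WT) x three timepoints (P13, P15, P17) x 3 replicates; 1900 miRNA
and 5000 mRNA features by default. Log2 baseline levels for expressed
features are uniform over background + 3 to background + 8; a
`frac_background = 0.2` fraction of features carries pure background
signal ($N(4, 0.5^2)$ log2) and is called absent when below the background
0.95 quantile — so background features are present in ~5% of arrays by
construction. Replicate noise is additive $N(0, 0.25^2)$ on log2 signals;
data are exported linear. Default DE fractions are 2% group A and 4%
group B, in line with the order of magnitude of DE calls in studies of
this design; planted effects are $\pm 1.5$ log2 for miRNAs and $\mp 0.6$
log2 for their true targets, which respond at P17 (delayed) regardless of
the regulator's group. Group A's optional smaller P13 effect is off by
default. Each DE miRNA gets 5 disjoint true targets; every true pair
enters the prediction table with $\ge 2$ supporting algorithms, while
spurious pairs appear at `false_prediction_rate` with a support
distribution skewed toward single-algorithm calls (60% singletons). The
qPCR generator models $Ct = 35 - \log_2(\text{expression}) + N(0,
\sigma_{ct}^2)$ with triplicate technical replicates and
genotype/timepoint-invariant reference assays.

What the generator does *not* emulate: probe-level effects, spatial
retinal structure, sample-wide intensity distortions (so quantile
normalization is an identity in expectation on simulated data),
correlated noise across features, and the pooled-retina structure (pooling
only shrinks the effective noise, which is absorbed into `noise_sd`).
Passing tests therefore demonstrate correctness of the computations and
calibration under idealized array noise, not robustness to real-array
artifacts.

## Numerical choices

* Quantile normalization uses the mean-of-sorted-vectors reference with
  ties receiving the mean of the quantile values they span (the dense
  variant); after normalization all sample sorted-value vectors agree to
  machine tolerance.
* The hypergeometric tail is computed in log space for stability and is
  exact against exhaustive enumeration for all parameter combinations with
  $N \le 12$.
* Degenerate DE inputs: a feature with zero variance in both groups gets
  $P = 1$ when the means agree and $P = 0$ otherwise; group means must be
  strictly positive for fold changes.
* Background estimation falls back to 0 when no feature is absent
  everywhere (nothing can then sit "near background").

## Verification scale and measured operating characteristics

The test suite and the acceptance script verify the pipeline on scaled
problem sizes chosen for desk runtimes: classification benchmarks use 200
seeded 25-feature validation panels (7 group A, 8 group B, 10 null —
mirroring a candidate panel rather than a whole array) with the planted
effect 1.5 log2, noise 0.25 and n = 3; network benchmarks use 100 seeded
runs of 60 miRNAs x 300 genes at noise 0.15, a regime chosen by the power
oracle so the mRNA differential-expression stage retains adjusted power
(~0.5) and the recall and precision checks are informative rather than
vacuous; the end-to-end pipeline demonstration uses 200 x 600 features. The classification benchmark runs differential
expression directly on the generator's output: the generator emits
distribution-matched samples, and quantile normalization — which assumes
most features are invariant — would be statistically invalid on a
25-feature panel where 60% of features are DE; the normalization contract
is verified separately.

One operating characteristic deserves emphasis. With n = 3 per side the
Welch statistic has roughly 4 degrees of freedom, so even a strong planted
effect (1.5 log2, noncentrality ~7.3) yields raw $P$ values with a heavy
right tail: the raw-test power at $\alpha = 0.05$ is ~0.999, but
$P(p < 0.01)$ is ~0.94 and the BH step-up pushes the effective per-feature
threshold well below 0.01 whenever true effects are sparse. Group-A
assignment requires *two* adjusted-significant comparisons at P15, and its
recovery rate consequently plateaus around 0.7 on the 25-feature panels
(and far lower at whole-array scale with 2-6% planted effects); group-B
recovery, whose P17 comparisons share signal from both classes and face a
lighter BH penalty, reaches ~0.95. This is an inherent property of
unmoderated three-replicate designs with multiplicity control, not an
implementation artifact; the package reports both rates as measured.

## Known limitations

* The enrichment module is a documented stand-in for interactive
  DAVID/ClueGO analyses; it implements a standard hypergeometric ORA, not
  those tools' exact statistics or backgrounds.
* No moderated-variance testing; with triplicate arrays this leaves
  adjusted-significance power low when true effects are sparse (see
  above).
* Amplification efficiency in ddCt is fixed at 2.0; no standard-curve or
  melt-curve modeling.
* The extended P19/P22 timecourse is reported descriptively in the source
  study design and is out of classification scope here.

## A compact worked run

```{r, eval = FALSE}
cfg <- pipeline_config(sim = sim_config(
  n_mirna = 200, n_mrna = 400, frac_groupA = 0.12, frac_groupB = 0.12,
  targets_per_mirna = 4, false_prediction_rate = 0.01,
  noise_sd = 0.15, seed = 1
))
report <- run_pipeline(cfg)
report$counts
glance(report$networks$A17)
head(report$enrichment)
report$validation$summary
```

The report carries every intermediate table (DE results per comparison,
temporal profiles, group labels, the three networks, enrichment results,
reference-stability ranking and the validation summary) plus a
seed-and-version manifest; with `outdir` set, all of them are written as
TSV/SIF/GraphML for external viewers.
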