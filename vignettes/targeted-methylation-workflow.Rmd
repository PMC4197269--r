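---
title: "Targeted bisulfite methylation analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted bisulfite methylation analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylpanel)
```

## The analysis in one paragraph

`methylpanel` analyses a targeted (capture-based) bisulfite sequencing panel
measured across a small leukemia cohort with one pooled healthy CD34+
control. Per-CpG methylated/unmethylated read counts are assembled into a
filtered CpG × sample ratio matrix; samples are clustered by correlation
distance with Ward linkage and bootstrap support; regions whose average
methylation separates one molecular subgroup from everyone else are
extracted and classified as hypo- or hypermethylated; regions are assigned
to genes through strand-aware promoter windows around each TSS and screened
for strong Spearman anti-correlation between methylation and expression;
and candidate genes are carried into cohort statistics — expression
categorization against healthy donors, Fisher's exact and Mann–Whitney
tests, Kaplan–Meier/log-rank survival and cumulative incidence of relapse
with death as a competing risk. Because cohorts of this design are rarely
deposited, the package ships a synthetic cohort generator that plants every
signal the analysis is meant to find, so each stage can be validated
against ground truth.

## Methylation matrix model

A CpG's methylation ratio is `n_meth / (n_meth + n_unmeth)`, undefined (not
zero) at zero coverage. The matrix filter keeps exactly the autosomal
positions with coverage ≥ `min_coverage` (default 10) in *every* sample.
The completeness requirement is what makes correlation distance
well-defined downstream without imputation, and the autosome restriction
avoids sex-chromosome dosage artifacts in a mixed-sex cohort. Input files
use the Bismark coverage dialect (1-based inclusive positions); internal
coordinates are uniformly 0-based half-open, and conversion happens only at
the I/O boundary. Duplicate positions within one file are summed with a
warning; the percent column is cross-checked against the counts (tolerance
0.1) but the counts are always authoritative. Strand collapsing is not
applied: input rows are taken as given.

Region-level methylation is the unweighted mean of defined CpG ratios
inside the region — the amplicon average that targeted designs validate
against — with an explicit missing value when no CpG is defined.

## Clustering and bootstrap support

Sample distance is `1 − Pearson r` across complete features; linkage is
Ward under the Ward.D2 convention (Lance–Williams update on squared
dissimilarities), which is deterministic with ties resolved to the lowest
node pair. Cluster confidence is the ordinary bootstrap probability:
features are resampled with replacement (default 1000 replicates; the
analysis scripts use 200, which is ample for a 15-sample tree), the tree is
rebuilt, and a node's support is the fraction of bootstrap trees containing
its exact leaf set. Multiscale bootstrap (AU p-values, as in Pvclust) is
deliberately **not** implemented: it changes the calibration of support
values but not the qualitative question asked here — whether the designated
subgroup pair is a confidently supported sibling — and ordinary bootstrap
probabilities are directly interpretable and exactly testable. This is a
documented divergence from the software the original analysis used.

Expression matrices pass through a detection filter (gene kept when its
detection p-value is ≤ α, default 0.05, in **all** samples — the threshold
is inclusive) and quantile normalization (cross-column rank means, ties
averaged; `limma::normalizeQuantiles` provides the implementation).
Microarray background subtraction is out of scope.

## The uniqueness criterion for subgroup DMRs

The published analysis reports regions "uniquely differentially methylated"
in the fusion-positive subgroup without stating a numeric criterion. The
package operationalizes it as a two-sided threshold rule on region means:

* every subgroup sample differs from the control by ≥ `delta_subgroup_min`
  (default 0.2) **with a common sign**;
* every other patient differs by < `delta_others_max` (default 0.1);
* the region has ≥ `min_cpgs_per_region` (default 3) defined CpGs.

Direction is the sign of the subgroup shift (hypo below control). The
defaults reflect the scale of methylation differences that targeted
validation assays can confirm (Δβ ≈ 0.2) and a tolerance for the others
well inside sampling noise at ≥10× coverage; both are configurable
precisely because they are reconstructions, not published values. The rule
is deliberately simple enough to brute-force, which is how the test suite
checks it. There is no per-region significance test: with two subgroup
samples no such test is meaningful, and none was published.

## Promoter-window integration

Each gene contributes a window from `upstream_bp` (default 5000) upstream
to `downstream_bp` (default 1000) downstream of its TSS, mirrored on the
minus strand and clipped at zero; a region is assigned to every gene whose
window it overlaps by ≥1 bp (half-open intervals; `GenomicRanges` does the
overlap). An assigned pair becomes a hit when:

* Spearman rho (methylation vs expression across samples, control included
  so 15 profiles enter by default — the published text does not say whether
  the control was included, so a flag exposes both choices) ≤ `rho_max`
  (default −0.7);
* methylation changes ≥ `fold_min` (default 2)-fold between control and at
  least one patient, computed as a ratio of ratios in either direction with
  pseudocount ε = 0.01 stabilising folds near zero (how the published
  2-fold rule handled a zero ratio is unstated; ε is configurable);
* some sample, control included, reaches methylation ratio ≥ `ratio_min`
  (default 0.3).

No p-value filter or multiplicity correction is applied — at this sample
size rank-correlation p-values are uninformative, and the published screen
explicitly declined them. Expression enters as provided; a log transform
would not change ranks and is therefore not applied.

## Cohort statistics

Expression categories against healthy donors apply the published two-clause
rule conjunctively: a patient is "up" when expression exceeds the healthy
mean by more than both the 2-fold and the order-of-magnitude cut (so
10-fold is the effective threshold), "down" symmetrically. The conjunctive
reading is a choice — the clauses could be read against the healthy range
rather than its mean — and both cuts are configurable.

Fisher's exact test uses the standard two-sided hypergeometric summation.
The Mann–Whitney test computes U with average ranks and takes its two-sided
p from exact enumeration of all `choose(n+m, n)` rank assignments when
`min(n, m) ≤ 8` (valid under ties), otherwise from the tie-corrected normal
approximation without continuity correction; the enumeration cutoff
balances fidelity against runtime at cohort-scale group sizes.
Kaplan–Meier, the log-rank test and the Aalen–Johansen cumulative incidence
(death without relapse as the competing risk) delegate to the `survival`
package. The published relapse comparison does not state its method; the
package reports the log-rank test on relapse with death censored alongside
the competing-risks incidence curve, and documents that mismatch rather
than guessing. Gray's test and Cox regression are out of scope.

## What the synthetic cohort emulates

`sim_config()` defaults encode the emulated study design:

| parameter | default | meaning |
|---|---|---|
| `n_case_groups` × `samples_per_group` | 7 × 2 | 14 patients across molecular subgroups; group 1 ("inv16") carries the signature |
| `n_controls` | 1 | pooled CD34+ healthy control |
| `n_regions`, `cpgs_per_region` | 500, 5–15 | targeted panel on chr1–chr22 + chrX |
| `coverage_mean`, `coverage_dispersion` | 83, 10 | negative-binomial per-CpG coverage; the emulated study reports mean 83× (per-sample range 46–131) but not the per-CpG distribution, so the NB is a stand-in with configurable dispersion |
| `baseline_beta_params` | Beta(1,9) / Beta(3,3) / Beta(9,1) | island / shore / open-sea baselines mimicking the panel's CpG-context mix |
| `n_planted_dmrs`, `dmr_effect` | 50, 0.4 | subgroup-unique planted shifts; 69% hypomethylated (`hypo_fraction`), matching the reported tendency |
| `n_planted_pairs`, `coupling_strength`, `coupling_slope` | 30, 0.9, 2 | genes whose log10 expression drops with region methylation |
| `expression_noise_sd` | 0.2 | log10-scale biological + technical scatter |
| `level_jitter_sd` | 0.02 | per-sample wobble of region methylation around its baseline |

Two structural choices matter. First, a region's baseline methylation is
drawn **once** and shared by all samples, so that between-sample variation
at unplanted regions comes only from sampling noise — this is what makes a
"unique to the subgroup" criterion meaningful. Second, planted
anti-correlated pair regions are the exception: their levels vary per
sample (Beta(2,2)), because a rank correlation across samples needs
cross-sample methylation spread to exist at all. Planted signals are placed
on autosomes only, since the analysis is autosome-restricted; chrX regions
act as filter-exercising nulls. Planted hypomethylated shifts re-draw their
baseline (bounded retries) until the shift is representable inside [0, 1],
so the realized effect is never silently clamped away.

Per component (layout, methylation, expression, survival) the generator
uses an RNG stream derived from the master seed by a fixed offset, so
adding one component never perturbs another; identical seeds give
byte-identical output files.

The generator does **not** emulate: read-level artifacts (incomplete
bisulfite conversion, M-bias, mapping error), strand structure, spatial
correlation of methylation along a region, copy-number or mutation effects
on either data type, or realistic expression distributions beyond
log-normal scatter. Passing recovery tests therefore demonstrate that the
pipeline's logic is correct under its own statistical assumptions — not
that those assumptions capture everything in patient data.

Survival simulation is exponential: relapse hazard log(2)/500 per day
(multiplied by `relapse_rate_ratio` in the "up" category), death-without-
relapse hazard log(2)/1500, administrative censoring at 5 years. These are
plausible AML relapse/mortality scales chosen once for the artifact; the
null (`relapse_rate_ratio = 1`) and a planted ratio of 3 are the two
settings the tests exercise.

## Numerical choices and degenerate inputs

* Missing is a first-class state everywhere; a ratio is never silently 0.
* `spearman_rho` returns an explicit `NA` for a constant vector; the
  integration filter skips and counts such pairs.
* An empty DMR list has an undefined (`NA`) hypomethylation fraction, not
  0%; zero retained matrix sites yield a valid empty matrix, not an error.
* Correlation distances are floored at 0 to absorb `1 - r` rounding
  slightly below zero; a zero-variance sample is an error naming the
  sample.
* Exact Mann–Whitney tail sums use a 1e-9 tolerance when comparing tied U
  values so floating-point rank sums do not drop boundary tables.
* Degenerate bootstrap resamples (a sample with zero variance across the
  resampled features) are skipped and the support denominator adjusted.
* Deterministic TSV output formats doubles at 8 significant digits, which
  is what makes the pipeline byte-reproducible across runs.

## Problem sizes used in validation

The recovery analyses run on the default 500-region, 15-sample cohort
(~5000 CpGs), with 200 bootstrap replicates for cluster support; null
calibration of the group tests uses 2000 replicates of direct null draws
(binomial 2×2 tables at n = 23 per arm, Gaussian samples of 7 per arm,
equal-hazard exponential survival at 20 per arm) — the same null structures
the generator produces, sampled directly at a fraction of the cost of 2000
full cohorts. These sizes give stable pass/fail behaviour for the planted
effect sizes while keeping a full validation run in the low minutes.

## Known limitations

* The uniqueness-DMR thresholds are reconstructions; the published region
  count (182) is therefore not a quantity this package can reproduce, and
  only the direction *fraction* given a DMR set is checked against the
  published 125/182 ≈ 69%.
* Bootstrap supports are BP, not AU; they are typically conservative for
  small true clusters.
* The relapse-incidence comparison reports log-rank on cause-specific
  relapse, which tests a different null than Gray's test on the CIF.
* With a single pooled control, "control value" is one draw, not an
  estimate with error; multi-control designs are supported by averaging.
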