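# methylpanel

Analysis pipeline for targeted bisulfite sequencing of small leukemia
cohorts, built around the question that motivates such panels: *which
genomic regions are uniquely differentially methylated in one molecular
subgroup, and which of those changes are coupled to gene expression and to
outcome?*

The package covers the full path from per-CpG methylation counts to cohort
statistics:

* **Methylation matrices** — Bismark-style coverage files in, filtered
  CpG × sample ratio matrices out (autosomes only, coverage ≥ 10 in every
  sample by default), plus region-level methylation averages
  (`read_coverage_file`, `build_matrix`, `region_sample_means`).
* **Clustering** — correlation distance (`d = 1 − r`) with Ward.D2 linkage
  and feature-bootstrap cluster support
  (`correlation_distance`, `ward_cluster`, `bootstrap_support`).
* **Subgroup-unique DMRs** — regions where every subgroup sample shifts
  ≥ 0.2 from the healthy control with a common sign while every other
  patient stays within 0.1, classified hypo/hyper
  (`call_unique_dmrs`, `hypomethylation_fraction`).
* **Methylation–expression integration** — strand-aware TSS windows (5 kb
  upstream to 1 kb downstream), ≥ 1 bp overlap assignment, and a screen for
  Spearman rho ≤ −0.7 with a ≥ 2-fold methylation change reaching ratio
  ≥ 0.3 (`tss_window`, `assign_regions`, `integration_filter`).
* **Cohort statistics** — expression up/down categorization against healthy
  donors (2-fold *and* order-of-magnitude, conjunctive), Fisher's exact,
  Mann–Whitney (exact enumeration for small groups), Kaplan–Meier,
  log-rank, and Aalen–Johansen cumulative incidence of relapse with death
  as a competing risk (`classify_expression`, `fisher_exact`,
  `mann_whitney`, `kaplan_meier`, `logrank_test`, `relapse_incidence`).
* **A synthetic cohort generator** (`sim_config`, `generate_cohort`,
  `generate_survival`) that emulates the target study design — 14 patients
  in 7 molecular groups plus a pooled CD34+ control, ~500-region panel at
  mean coverage 83× — and plants subgroup-unique DMRs (69% hypomethylated)
  and methylation-coupled genes, with machine-readable ground truth for
  recovery testing.

The methods, parameter defaults and generator assumptions are documented in
`vignettes/targeted-methylation-workflow.Rmd`.

## Worked example

The `analysis/` directory is a numbered end-to-end run over the default
synthetic cohort (`Rscript analysis/01_simulate.R`, then `02`…`06`).
Output from a run:

```
== analysis/01_simulate.R
samples:       15
regions:       500
panel CpGs:    4955
planted DMRs:  50  (60% hypomethylated)
planted pairs: 30
mean coverage: 83.0x
== analysis/02_build_matrix.R
retained sites: 4748 of 4955
== analysis/03_cluster.R
inv(16) samples: AML_1 AML_2
sibling-pair bootstrap support: 1.000
== analysis/04_dmr.R
unique DMRs called: 48
hypomethylated: 28 of 48 (58%)
sensitivity vs planted truth: 0.96  (false positives: 0)
== analysis/05_integrate.R
candidate (region, gene) pairs: 500
anti-correlated hits: 28 assigned to 28 unique genes
planted-pair recovery: 0.93  (extra hits: 0)
== analysis/06_cohort_stats.R
focus gene: G0269  region: R0269  (rho = -0.96)
methylation up vs normal: median 0.16 vs 0.58, U = 0.0, p = 0.00155
overexpression 0/6 (0%) vs 26/46 (57%): Fisher p = 0.02
OS log-rank p = 0.483 (no planted OS effect)
relapse log-rank p = 3.537e-05 (planted hazard ratio 3)
```

Reading this: the filters keep 4748 of 4955 panel CpGs (chrX and
low-coverage sites drop out); the planted two-patient subgroup is a
perfectly supported sibling pair in the methylation dendrogram; the DMR
caller recovers 48 of the 50 planted regions with no false calls (the
planted direction split for this seed is 60% hypo); the integration screen
recovers 28 of 30 planted methylation–expression pairs with no extras; and
for the strongest hit, patients with up-regulated expression show markedly
lower promoter-region methylation (median 0.16 vs 0.58) — the
anti-correlation pattern the screen is designed to find — while the
simulated validation cohort shows the planted relapse excess (log-rank
p ≈ 4e-05) without an overall-survival effect.

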