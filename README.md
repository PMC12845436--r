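# microstab

Longitudinal gut microbiota stability analysis in R.

Repeatedly sampled gut microbial communities differ not just in *what*
they contain but in *how much they change* between visits — and that
temporal variability is itself a subject-level trait linked to host
physiology. `microstab` turns an ASV count table plus longitudinal
metadata (subject × timepoint) into that trait and everything built on
it:

* **Instability score** per subject: the mean intra-individual
  Bray–Curtis dissimilarity over all timepoint pairs,
  `instability_i = mean{ BC(x_it, x_is) : t < s }`, on rarefied counts.
* **LS/HS stratification**: a two-component Gaussian mixture (or KDE
  valley) finds the data-driven threshold in a bimodal score
  distribution; subjects above it are low-stability (LS), below
  high-stability (HS). Unimodal score sets are refused, not forced.
* **Temporal coefficient of variation** (SD/mean over timepoints) for
  alpha-diversity indices and each taxon — the dispersion features that
  drive the classifier.
* **Repeated-measures correlation** (ANCOVA with per-subject
  intercepts and common slope; r from within-subject-centered data,
  df = N − k − 1) for diet/phenotype–taxon associations and for
  all-pairs co-abundance networks, with Louvain modules and Zi–Pi node
  roles (peripherals / connectors / module hubs / network hubs).
* **Sloan neutral community model**: occurrence frequency vs mean
  relative abundance, `f(p) = 1 − BetaCDF(1/depth; Nm·p, Nm·(1−p))`,
  fitted by least squares over log(Nm); R² = 1 − SSE/SST may be
  negative (niche-dominated assembly), and taxa are classified against
  a 95% Wilson band.
* **Subject-stratified PERMANOVA**: distance-based pseudo-F with
  permutations restricted within each subject's samples.
* **Mixed-model differential testing** (random intercept per subject,
  BH adjustment, dual rule p < 0.05 & q < 0.15).
* **Nested random-forest classification** of stability class:
  stratified 5-fold outer CV, recursive feature elimination scored by
  leave-one-out AUROC inside each fold, Gini importances, consensus
  features, and a cross-dataset integration step.
* A **synthetic longitudinal cohort generator** with planted ground
  truth (bimodal instability, driver taxa, LS-only diet coupling,
  lipid shifts) that makes every stage testable end to end.

## Worked example

```r
library(microstab)

sim  <- simulate_cohort(cohort_scenario(n_subjects = 24, n_taxa = 80,
                                        depth_mean = 8000), seed = 7)
rare <- rarefy_cohort(filter_low_abundance(sim$cohort), 5000, seed = 1)

prof <- stability_profile(rare, seed = 1)
prof
#> stability_profile: 24 subjects
#>   instability range: 0.42 - 0.952
#> stability_strata (gmm2): threshold = 0.6513
#>   LS (unstable): 9   HS (stable): 15

fit_ncm(rare)
#> Sloan neutral community model: Nm = 95.3, R2 = -0.979
#>   m = 0.01906, detection limit = 0.0002, 95 samples
#>
#>  above  below within
#>      6     42     17
```

The profile says: per-subject instability spans 0.42–0.95, the mixture
threshold lands at 0.651, and 9 of 24 subjects fall in the unstable
group. The NCM fit's strongly negative R² says occurrence frequencies
of this AR-driven synthetic community deviate from neutral-assembly
expectations — most taxa sit below the neutral band.

A repeated-measures correlation on longitudinal pairs:

```r
subj <- rep(paste0("s", 1:6), each = 4)
x <- rep(1:4, 6) + rnorm(24, 0, 0.2)
y <- 0.8 * rep(1:4, 6) + rep(rnorm(6, 0, 3), each = 4) + rnorm(24, 0, 0.5)
rmcorr_test(x, y, subj)
#> rmcorr: r = 0.9309, df = 17, p = 7.459e-09 (24 obs, 6 subjects)
```

Subject-level intercepts differ by several units, yet the common
within-subject slope is recovered with r = 0.93 on 17 degrees of
freedom.

The whole workflow — filter, rarefy, diversity, stability, CoV,
differential tests, rmcorr associations, PERMANOVA, NCM per group,
networks per group, three classifiers — runs as one call:

```r
res <- run_full(sim$cohort, sim$covariates,
                pipeline_config(seed = 1), outdir = "out/")
```

Every table under `out/` carries a config-hash/seed header; rerunning
with the same inputs and seed reproduces each file byte for byte.

A thin CLI wraps the same functions
(`inst/scripts/microstab simulate|stability|ncm|network|permanova|classify|run`).

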