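---
title: "Quantifying longitudinal gut microbiota stability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying longitudinal gut microbiota stability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Gut microbial communities sampled repeatedly from the same person change
over time, and the *amount* of change differs strongly between people.
This package treats that temporal variability as the quantity of
interest. Given an ASV (amplicon sequence variant) count table over a
longitudinal cohort — subjects sampled at a handful of timepoints — it
asks: how unstable is each subject's community, do subjects split into
distinct low-stability (LS) and high-stability (HS) groups, which taxa
drive the instability, is the community assembled neutrally or shaped by
selection, how does the co-abundance structure differ between groups,
and can stability class be predicted from baseline measurements alone?

## The instability statistic and LS/HS stratification

The per-subject **instability score** is the unweighted mean Bray–Curtis
dissimilarity over all C(T, 2) pairs of that subject's samples; with
four timepoints this is an average of six pairwise dissimilarities. We
deliberately average over *all* pairs rather than consecutive pairs
(`instability_score(..., consecutive_only = TRUE)` gives the variant):
the all-pairs mean is invariant to uneven visit spacing and uses all
information in a short series. Bray–Curtis requires equal sequencing
depth, so counts are rarefied first (single draw without replacement,
seeded); relative abundances are also accepted.

Stratification assumes the scores are bimodal. The default method
(`gmm2`) fits a two-component univariate Gaussian mixture and places
the threshold at the equal-posterior crossing between the component
means; subjects above the threshold are LS, below are HS. A kernel
density valley finder (`kde_valley`) is the cross-check. If the fitted
components are separated by less than `min_separation` pooled SDs
(default 1) the fit refuses to assign classes rather than manufacture a
grouping — bimodality is an empirical claim, not an assumption to force.
The package never hard-codes a threshold value: the split is
distribution-driven per cohort.

Feature-level dispersion uses the **temporal coefficient of variation**
(sample SD / mean over a subject's timepoints, n−1 denominator — with
four observations the unbiased variance matters). CoV applies to
non-negative inputs (rarefied abundances, alpha indices), never to CLR
values, whose zero crossings make SD/mean meaningless. An all-zero
series (taxon absent in a subject) has CoV 0 with an absence flag, and
the classifier feature matrix exposes those flags as separate indicator
columns so "absent" is not conflated with "constant".

## Compositional and diversity conventions

* **CLR**: counts + pseudocount (default 0.5) are closed to relative
  abundances and log-ratio centered per sample. The pseudocount is
  deliberately on the count scale before closure, so its influence
  shrinks with depth.
* **Alpha diversity**: Shannon in nats, Simpson as 1 − Σp², observed
  richness, Pielou = H / ln(richness) (0 for one-taxon samples). Nats
  make Pielou's normalisation exact.
* **PCoA**: eigendecomposition of the Gower-centered −D²/2 matrix.
  Bray–Curtis is non-Euclidean, so negative eigenvalues occur; they are
  reported, never clipped, and explained fractions are taken over the
  positive spectrum only.

## Repeated-measures correlation and differential testing

Associations between longitudinally measured variables are estimated
with the repeated-measures correlation: an ANCOVA with one intercept
per subject and a common slope. Algebraically the estimate equals the
Pearson correlation of the within-subject-centered variables, with
error degrees of freedom N − k − 1 (N complete pairs, k subjects); the
package computes it in that centered form, which also makes the
all-pairs taxon–taxon correlation matrix a single cross-product — the
co-abundance network over hundreds of taxa costs one matrix multiply.
The unit tests verify the centered form against an explicit
normal-equations ANCOVA solver to 1e-10.

Group differences in features over time use a per-feature linear mixed
model with a random intercept per subject and fixed adjustments (sex,
age) where supplied, Satterthwaite p-values for the group coefficient,
BH adjustment across features, and the dual significance rule
p < 0.05 AND q < 0.15. Continuous phenotypes are signed-cube-root
transformed before modelling. BH families are declared explicitly: one
family per analysis block (e.g., all taxa against one phenotype within
one group), never a global pool across unrelated analyses.

## Subject-stratified PERMANOVA

The contribution of a covariate to community variation is tested with a
distance-based pseudo-F from the Gower decomposition. Because repeated
samples of one subject are exchangeable only with each other, the
permutation null shuffles covariate values *within* each subject's
samples; free permutation remains available for between-subject
factors. For a single predictor the permuted statistics reduce to
quadratic forms x'Gx/x'x, evaluated as one matrix product over all
permutations — this is what makes 999 permutations × hundreds of
replicates affordable in the calibration tests. p = (#{F* ≥ F} + 1) /
(B + 1). The acceptance suite verifies the type-I error of this scheme
lies in [0.03, 0.07] at nominal 0.05 under a global null.

## The Sloan neutral community model

Neutral assembly predicts a taxon's occurrence frequency from its mean
relative abundance: with detection limit d = 1/depth and parameter Nm
(metacommunity size × immigration), f(p) = 1 − BetaCDF(d; Nm·p,
Nm·(1−p)). Nm is fitted by least squares on a log(Nm) grid via 1-D
bounded optimisation (a single parameter; log scale avoids the
many-orders-of-magnitude search problem), and fit quality is R² = 1 −
SSE/SST — *not* a squared correlation, so a community that fits worse
than a flat line yields a negative R², which is a meaningful statement
(niche-dominated assembly), not an error. The 95% band is a Wilson
binomial interval on the predicted frequency at the observed sample
count; taxa are classified above/within/below the band.

The companion generator draws per-sample abundances from the same beta
law and quantises reads at the detection limit (`floor(depth * p)`), so
a taxon is observed exactly when its abundance exceeds 1/depth. A
binomial read-sampling step would smear detection around the limit and
bias Nm recovery upward by ~20% at Nm = 500; quantised reads keep the
generator faithful to the contract the estimator assumes, and parameter
recovery stays within ±15% at Nm ∈ {50, 100, 500} (300 samples × 150
taxa).

## Co-abundance networks and node roles

Edges are taxon pairs with repeated-measures |r| > 0.5 and BH q < 0.05
(BH across all pairs within the group being analysed — the families
question is settled per subgroup). Modules come from Louvain modularity
maximisation on |r| weights; the sign stays on the edge as an
attribute, because co-abundance clusters legitimately mix positive and
negative couplings. Node roles use within-module degree z-score (Zi)
and participation coefficient (Pi = 1 − Σ(k_is/k_i)²) with the
conventional cutoffs Zi ≥ 2.5 and Pi > 0.62 splitting peripherals,
connectors, module hubs and network hubs. A module whose members all
have equal within-degree has SD 0 and Zi is defined 0 there.

## The nested classification protocol

Stability class is predicted with random forests (500 trees, default
split heuristic) under a fully nested protocol: stratified 5-fold outer
cross-validation; inside each outer training set, features are ranked
by mean-decrease-Gini importance and a recursive feature elimination
over sizes {2, 4, ..., 64, p} is scored by leave-one-out AUROC; the
selected set trains the fold's final model, evaluated once on the
held-out fold. AUROC is rank-based (Mann–Whitney identity, midranks for
ties). Averaged metrics, fold-averaged importances and the consensus
feature set (intersection over folds) are reported. Ties in the inner
AUROC go to the *larger* feature set: correlated informative features
produce indistinguishable inner scores, and discarding them would make
the consensus set arbitrary. One 5-fold pass is the default reading of
"repeated five times via external 5-fold cross-validation"; a repeated
variant can be run by re-seeding. A leakage unit test perturbs held-out
subjects' features and asserts the fold's selection is unchanged.

Dataset integration takes each source dataset's top-5
importance-ranked features, namespaces them by dataset, and re-runs the
identical nested protocol on the pooled matrix.

## What the synthetic cohort emulates

`simulate_cohort()` generates the study-shaped data every stage is
validated on: 51 subjects × 4 timepoints (T0 < T9 < T14 < T52) × 200
taxa by default, with covariates at the three non-T9 visits. Each
subject has a persistent personal profile (`mu_s ~ N(mu_taxa, 1)`), and
the realised latent log-abundances follow a *stationary* AR(1) (ρ =
0.5) around it whose stationary SD is the subject's instability knob,
drawn from a two-component mixture (means 1.4 / 2.1, SD 0.08, mixing
0.5). Counts are multinomial at log-normal depth (mean 25000, sdlog
0.25), so rarefaction is genuinely exercised. The mixture means were
fixed once so that the realised instability distribution is bimodal
over roughly 0.45–0.9 with the unstable group ~40% higher — the scale
the field reports for school-age cohorts — and were not revisited.

Planted structure with recorded ground truth:

* **Driver taxa** (10, drawn from upper-middle abundance ranks) get
  their stationary SD doubled in LS subjects. They sit below the
  community dominants on purpose: amplifying a dominant taxon drags
  every other taxon's relative abundance along through compositional
  closure and smears the instability signal across the whole community.
  The boost (2×) was chosen for test power; a larger boost saturates
  the 4-point CoV near its ceiling (√T) and paradoxically *reduces*
  driver detectability.
* **Diet coupling**: in LS subjects a fraction (default 0.5) of each
  driver's latent variance *is* the subject's standardized intake of an
  assigned diet variable (fiber or an amino acid, round-robin) at the
  nearest covariate visit — a variance split, so the planted
  correlation is interpretable (r ≈ √0.5 on the latent scale) without
  changing the driver's marginal dynamics.
* **Lipid phenotypes** (LDL-C, TC, TC/HDL-C, ApoB) are shifted up by
  0.8 SD in LS subjects; fasting glucose and triglycerides carry no
  planted effect and act as negative controls.

What the generator does **not** emulate: phylogenetic correlation,
strain dynamics, compositional overdispersion beyond multinomial,
seasonal trends, and measurement error in diet records. Passing tests
therefore demonstrate that the *methods* recover the structure they
claim to recover under a faithful longitudinal sampling design — not
that real cohorts contain such structure.

## Problem sizes and numerical choices

The validation suite runs the full pipeline at the default 51-subject
scale, stratification recovery on 200-subject cohorts over 20 seeds,
PERMANOVA calibration with 400 null replicates × 999 permutations, and
neutral-model recovery at 300 samples × 150 taxa over 20 seeds — sizes
chosen so each property is measured with useful precision while the
whole suite stays comfortably re-runnable on a laptop.

Numerical conventions worth knowing: the abundance filter removes taxa
with mean per-sample relative abundance strictly below 0.1% (mean of
per-sample proportions, not pooled counts, so deep samples do not
dominate); rarefaction is a single seeded draw; distance-based stages
declare rarefied input and model-based stages declare CLR input; all
stochastic stages take explicit seeds derived from one pipeline seed,
and a rerun with identical inputs and config is byte-identical. The
stratification recovery guarantee (≥95%) presumes realised instability
components separated by ≥3 within-class SDs; cohorts below that
separation can still be stratified, but recovery degrades gracefully
with the overlap, as it must.

## Known limitations

Bimodality is assessed in one dimension only (the instability score);
the mixed-model differential stage assumes a common within-group
covariance; the neutral fit pools all samples per group rather than
fitting per timepoint (one fit per subgroup mirrors how such results
are usually reported); and with four timepoints the per-taxon CoV is an
intrinsically noisy statistic — its classifier works because many taxa
vote, not because any single CoV is precise.
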