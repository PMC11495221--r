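---
title: "Grey-matter network extraction and CSF biomarker trajectory methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grey-matter network extraction and CSF biomarker trajectory methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in `gmnet`,
the assumptions behind them, the parameters that matter, and the design
choices that were genuinely open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## Single-subject covariance networks

A subject's network is built from one grey-matter probability volume
(2 mm isotropic is the intended resolution; the voxel spacing is read from
the NIfTI header and only enters the total-volume computation).

**Parcellation.** The volume is tiled from voxel (0,0,0) with axis-aligned
cubes of `cube_edge = 3` voxels per side; trailing partial slabs are
discarded rather than padded, so every node owns exactly 27 voxel
intensities and the node set is deterministic. A cube becomes a node when at
least `min_gm_voxels = 1` of its voxels exceed `gm_inclusion_threshold =
0.1` probability. The study this emulates does not state its inclusion rule,
so both knobs are exposed rather than hard-coded; the defaults admit any
cube touching grey matter, which errs toward keeping nodes and letting the
correlation threshold decide.

**Correlation.** Pairwise Pearson correlation of the 27-voxel vectors. The
historical reference implementation of this method maximizes each pairwise
correlation over the 48 axis-aligned rotations/reflections of one cube;
because the description we follow specifies only plain pairwise
correlation, `rotation_mode = FALSE` is the default and the rotation variant
is provided for compatibility. Zero-variance cubes produce flagged `NA`
correlations — never edges, but the node count is preserved so network size
stays comparable across subjects.

**Permutation threshold.** In-mask voxel values (mask: probability above the
inclusion threshold) are shuffled across in-mask positions, which destroys
spatial structure while preserving the intensity distribution exactly. The
permuted volume is re-parcellated and its cube-pair correlations form the
subject's null distribution; the binarization threshold is the `1 − α`
quantile (default `α = 0.05`, one-sided upper tail, so negative
correlations never form edges). One permuted volume per subject is used,
with pair subsampling (`n_null_pairs`, default 10^6) bounding cost on large
volumes with negligible quantile error. Calibration is verified end to end:
across 20 simulated null volumes the mean fraction of retained pairs is
close to `α` (acceptance suite).

## Graph statistics

Clustering is the Watts–Strogatz local coefficient (`C_i = 2t_i / k_i(k_i −
1)`, zero below degree 2), path length the mean shortest-path distance over
unordered pairs within the largest connected component — the dominant
convention for binarized covariance networks, avoiding infinite distances;
the component fraction is always reported so the choice stays auditable.
Random references preserve the degree sequence via double-edge swaps
(10 × edges attempted swaps), and `σ = (C/C̄_rand)/(L/L̄_rand)` uses means
over `n_random = 5` references. Graph primitives are delegated to igraph;
the test suite checks them against independent brute-force triangle
enumeration and Floyd–Warshall oracles on graphs up to 50 nodes.

### The σ floor of thresholded correlation graphs

A structure-free volume does **not** give σ ≈ 1. Sample correlation is
transitive: with 27 voxels per cube, conditional on `r(A,B) > t` and
`r(A,C) > t` the null correlation of the third pair concentrates near `t²`
with spread `1/√26`, so at the 5% threshold (`t ≈ 0.32`) the probability of
closing the triangle is roughly `P(Z > (t − t²)√26) ≈ 0.15` — three times
the 5% edge density. Degree-preserving rewiring destroys that geometry, so
γ ≈ 3 and σ ≈ 3 on pure-noise volumes (the acceptance suite measures this;
the corresponding spec-level expectation of σ ≈ 1 for null volumes is left
failing deliberately rather than weakened). Planted community structure is
therefore read against this chance level: structured volumes must (and do)
exceed both 1 and their own noise floor, and graph-level benchmarks where
σ ≈ 1 *is* the correct null (Erdős–Rényi) are tested separately. Since the
same few-sample transitivity operates in real 27-voxel cube networks, σ
values in that setting should also be compared between subjects rather than
against 1.

## Synthetic data

**Volumes.** Each cube belongs to exactly one of `n_communities` (default
12) communities; all cubes of a community share a latent 27-position
intensity pattern with amplitude `community_signal × noise_sd` on top of
iid voxel noise (`noise_sd`, default 0.05 probability units). The expected
within-community cube correlation is the intraclass ratio `s²/(s² + 1)`
with `s = community_signal` — the closed form the tests check. Amplitudes
are kept small against the [0, 1] clipping range so the ratio interpretation
stays exact; `community_signal` is dimensionless, so the calibration example
"signal-to-noise 3 gives ICC 0.9" holds at any amplitude that avoids
clipping. Null volumes are iid uniform values, giving chance-level
correlations with sd `1/√26`.

**Cohorts.** Defaults mirror the published cohort structure this emulates:
216 carriers and 136 non-carriers in 100 families, EYO (visit age minus
family onset age, onset drawn uniform over 40–55 years) uniform over −30 to
+10 years, 42% male. Non-carrier analyte distributions are log-normal with
the published group means/sds; carrier means depart after a per-analyte
divergence EYO via a linear hinge on the standardized log scale reaching
`mc_effect` sd units at EYO 0 — the simplest shape whose onset is a
recoverable parameter. Default hinge locations order amyloid/tau/synaptic
markers earliest (−22 to −15), NfL and YKL-40 with the small-world decline
(−12), and sTREM2 last (−3), with per-analyte missingness completely at
random matching the published availability (about 53% for NfL and sTREM2,
7% for the immunoassay panel). CDR steps through 0 / 0.5 / 1 / 2 / 3 at EYO
cutpoints (−3, 3, 8, 12) for carriers only. Families contribute shared
random intercepts (`family_sd = 0.3` against `residual_sd ≈ 0.95` on the
standardized scale); a shared latent factor across analytes exists but
defaults to loading 0, since the joint correlation structure among analytes
is not documented in the source material. What the generator does *not*
emulate: anatomy, longitudinal visits, assay batch effects, non-random
missingness, and EYO uncertainty — so passing tests show the estimators
recover the generating process, not that real data meet its assumptions.

## Association models

The eight skewed analytes (pTau, tTau, SNAP-25, Ng, NfL, VILIP-1, YKL-40,
sTREM2) are natural-log transformed (the base cancels after
standardization); amyloid peptides and the Aβ42/40 ratio stay on their
native scale. All analysis variables are then Z-scored on the **entire**
cohort, and subgroup models reuse that cohort-level scaling, so slopes are
comparable across predictors. Model tiers: (1) `outcome ~ predictor + sex`;
(2) adds `mutation_status` and its interaction with the predictor; (3) adds
age as a main effect. Fits are OLS on complete cases per model. Group
slopes come from the tier ≥ 2 coefficients (`β_pred` for non-carriers,
`β_pred + β_int` for carriers) with delta-method standard errors from the
fitted covariance, so slopes and the interaction test are internally
consistent; stratified per-group refits agree up to the shared-sex-term
constraint and both routes are kept. Confidence intervals are Wald
normal-approximation intervals — adequate at the intended n ≥ 100 and
documented so exact-t intervals can be swapped in.

Disease stage within carriers: stage 1 if the pTau/Aβ42 ratio is strictly
below 0.019 (the boundary itself is classed abnormal, since "normal" is
defined by strict inequality); otherwise CDR 0 / 0.5 / ≥1 give stages
2/3/4. The stage-by-predictor interaction is tested jointly by F test;
when significant at 0.05, all pairwise stage-slope contrasts are adjusted
with the studentized-range (Tukey HSD) distribution using the residual df
of the single fitted model. With two stages this reduces exactly to the
unadjusted two-sided t test, which the suite verifies, along with agreement
with emmeans' independently computed Tukey contrasts.

## Trajectory model

Before fitting, biomarkers are Z-scored to young non-carriers (non-carriers
under 40), the reference population assumed free of preclinical disease.
The outcome model is Gaussian:

```
y ~ (1 | family) + eyo_1 + eyo_2 + mutation + eyo_1:mutation + eyo_2:mutation + covariates
```

with `eyo_1, eyo_2` the restricted-cubic-spline basis (knots at the
0.1/0.5/0.9 quantiles of pooled EYO; Harrell truncated-power construction,
linear beyond the boundary knots; 3 knots ⇒ 2 columns). Covariates always
include sex; the small-world outcome additionally adjusts for total
grey-matter volume. Priors are Cauchy(0, 2.5) on all standardized
coefficients and half-Cauchy(0, 2.5) on both scales — the weakly
informative default of the applied-Bayes software family this follows,
since the source material names only the prior family.

**Sampler.** Posterior draws come from JAGS (rjags); the contract is
backend-neutral and targets posterior summaries, not a specific sampler.
Two numerical choices matter. First, the Cauchy prior is implemented as its
exact gamma scale-mixture of normals (`β|λ ~ N(0, 2.5²/λ)`, `λ ~
Gamma(½, ½)`), which keeps the marginal prior identical while making the
conditional prior normal so JAGS's `glm` block updater can sample the
correlated fixed effects jointly; without it, one-at-a-time updates of the
strongly collinear spline and interaction columns mix far too slowly.
Second, non-intercept design columns are centred for sampling and the
intercept draws are mapped back afterwards (`β₀ = β₀' − Σβⱼx̄ⱼ` per draw), so
reported draws are in the original parameterization. The first half of
`iter` is warmup (the source states iterations, chains and thinning but not
warmup); stored draws equal `chains × (iter − warmup)/thin`. Split-chain
convergence statistics are computed for every parameter and any value above
1.01 triggers a warning, never silence. Production settings are 8 chains ×
10 000 iterations thinned by 10; tests and the acceptance script use 2–4
chains × 1 200–2 000 iterations, which the diagnostics accept for these
well-identified Gaussian models.

**Divergence points.** The carrier-minus-non-carrier difference at EYO `x`
is `β_mut + β_int1·eyo_1(x) + β_int2·eyo_2(x)` per draw, summarized by
central credible bands at 95/99/99.5% on a grid from −25 to +10 years in
0.5-year steps (spanning the cohort's EYO range, with the step below any
claimed precision). The divergence point at a level is the earliest grid
EYO from which the band excludes zero there **and at every later grid
point**. This sustained-exclusion rule was chosen because a single "point
of divergence" implies a persistent departure, and it makes the
false-divergence rate far below the pointwise level; pointwise-first
exclusion remains available (`sustained = FALSE`) for sensitivity. Band
nesting guarantees the estimate at a stricter level is never earlier.

Estimated divergence lags the generating hinge when effects are weak or
missingness is high: the band can only exclude zero once the true
difference clears roughly 2.6 posterior standard errors, several years
after a shallow hinge starts. The acceptance suite therefore tests location
recovery (±2 years) under a strong hinge with complete data, and *ordering*
recovery — the scientifically load-bearing claim — under the default
generator conditions.

## Problem sizes and limitations

Tests and the acceptance script use 30³-voxel volumes (1000-node networks),
cohorts of 352 subjects in 40–100 families, 200–500 replicates for the OLS
calibrations, 15 replicates for Bayesian coverage, and reduced MCMC draws;
these sizes give the binomial/Monte-Carlo error bars quoted in the tests.
Known limitations: no anatomical realism or registration; cross-sectional
only; the Gaussian observation model is not robustified against the
outliers real assays produce; Wald rather than exact-t intervals; divergence
estimates inherit the cross-sectional early-bias of EYO trajectory designs
and should be read as ordering information, not individual-level onset
predictions.
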