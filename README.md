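# gmnet

Grey-matter structural covariance networks decline toward random organization
in Alzheimer's disease, and that decline is summarized by the small-world
coefficient. `gmnet` implements, as a tested R pipeline, an analysis of how
cerebrospinal-fluid (CSF) biomarkers relate to single-subject grey-matter
network organization in autosomal dominant Alzheimer's disease (ADAD)
families: mutation carriers and their non-carrier relatives share an
estimated-years-to-onset (EYO) timeline, so biomarker and network changes can
be ordered relative to expected symptom onset. The real cohort data this kind
of study uses are access-restricted, so the package ships synthetic volume
and cohort generators with known ground truth; every stage is exercised and
calibrated on them.

The pipeline has four stages:

1. **Network extraction** — a grey-matter probability volume is parcellated
   into 3×3×3-voxel cubes (nodes); Pearson correlations between the 27-voxel
   intensity vectors of every cube pair are thresholded at the upper
   `1 − α` quantile (α = 0.05) of a subject-specific permutation null built
   by shuffling in-mask voxels, and binarized into an undirected graph.
2. **Graph statistics** — Watts–Strogatz clustering `C`, characteristic path
   length `L` (largest connected component), and the small-world coefficient
   `σ = (C/C_rand)/(L/L_rand)` with `C_rand`, `L_rand` averaged over 5
   degree-preserving randomized references.
3. **Association models** — after natural-log transform of the skewed
   analytes and cohort-wide Z-scoring, three nested OLS tiers per biomarker:
   `small_world ~ biomarker + sex`, `… ~ biomarker * mutation_status + sex`,
   and the same plus age; per-group marginal slopes with delta-method CIs,
   disease-stage (pTau/Aβ42 ratio < 0.019 and CDR) interactions within
   carriers with Tukey-HSD post hocs, and pairwise-complete Spearman
   correlations.
4. **Trajectories** — Bayesian linear mixed model per biomarker:
   restricted-cubic-spline EYO terms (knots at the 0.1/0.5/0.9 quantiles),
   mutation status, their interactions, a family random intercept, Cauchy
   priors, after Z-scoring to young (<40) non-carriers. The divergence point
   is the earliest EYO from which the credible band (95/99/99.5%) of the
   carrier-minus-non-carrier difference excludes zero through the end of the
   grid.

## Worked example

```r
library(gmnet)

vol <- simulate_volume(volume_sim_spec(shape = c(30, 30, 30), seed = 7))
net <- extract_network(vol, analysis_config(seed = 7))
small_world(net, seed = 7)
#> network_metrics: 1000 nodes, 61442 edges, <k> = 122.88
#>   C = 0.8080  L = 2.5687  gamma = 5.540  lambda = 1.368  sigma = 4.048
#>   (5 random references, 100% of nodes in largest component)
```

The community covariance planted in the volume survives permutation
thresholding: the network is far more clustered (γ ≈ 5.5) than its
degree-matched random references while path length stays comparable
(λ ≈ 1.4), giving σ ≈ 4. A structure-free volume processed identically
yields σ ≈ 3.2 — not 1, because thresholded correlation graphs are
transitive by construction (see the methods vignette) — so planted structure
is read against that chance level, not against σ = 1.

```r
coh <- simulate_cohort(cohort_sim_spec(seed = 3))   # 216 carriers, 136 non-carriers
pp  <- preprocess_cohort(coh)
gs  <- group_slopes(fit_association(pp, "nfl", tier = 2))
gs
#>         group        slope         se   ci_lower   ci_upper
#> 1 non-carrier  0.004016901 0.14575333 -0.2816544  0.2896882
#> 2     carrier -0.703361098 0.06991789 -0.8403976 -0.5663246
```

Higher neurofilament light (NfL, axonal damage) relates to lower small-world
values in carriers (standardized slope ≈ −0.70) but not in these simulated
non-carriers, mirroring the carrier-specific associations the models are
built to detect.

The numbered drivers under `analysis/` run the full workflow and write
tables beneath `results/`:

```sh
Rscript analysis/01_simulate_data.R  --seed 1   # volumes + cohort + ground truth
Rscript analysis/02_extract_networks.R --seed 1 # networks + small-world metrics
Rscript analysis/03_associations.R              # tiered models, stages, Spearman
Rscript analysis/04_trajectories.R --seed 1     # spline fits + divergence table
```

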