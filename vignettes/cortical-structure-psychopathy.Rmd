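---
title: "Cortical morphometry, structural-covariance gradients, and psychopathy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cortical morphometry, structural-covariance gradients, and psychopathy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# What this package models

`cortigrad` implements a complete analysis chain for asking how cortical
structure relates to trait empathy and psychopathy in a forensic cohort.
The measurements it works with are:

- **Cortical thickness (CT)**, in mm, and **cortical surface area (SA)**,
  in mm², per region of a 360-parcel HCP-MMP1.0-style parcellation (180
  parcels per hemisphere);
- **IRI-PT** and **IRI-EC**, the Perspective Taking and Empathic Concern
  subscales of the Interpersonal Reactivity Index (7 items each, 0–4 per
  item, subscale range 0–28);
- the **PCL-R**, 20 items scored 0/1/2, with an interpersonal/affective
  factor F1 (range 0–16 under the default 8-item map), a
  lifestyle/antisocial factor F2 (0–20, 10 items), and a total score
  (0–40). High psychopathy is a total ≥ 30, low ≤ 20;
- covariates: age (years), full-scale IQ, and total intracranial volume
  (TIV, mm³; used for SA only because head size scales area, not
  thickness), plus optional extras such as the surface Euler number.

Because subject-level MRI and psychometric data of this kind are not
publicly depositable, the package ships a **synthetic-cohort generator**
whose planted structure makes every downstream stage testable: each
statistical claim the pipeline produces can be checked against what the
generator actually planted.

# The synthetic cohort

## Atlas

`make_parcellation()` places 180 parcels per hemisphere on a unit sphere
with a deterministic Fibonacci spiral (mirrored across the midline) and
assigns Mesulam laminar classes (paralimbic 12%, heteromodal 40%,
unimodal 36%, idiotypic 12%) and Yeo-7 networks in contiguous bands along
an anterior–posterior (AP) coordinate `ap_axis` in [−1, 1]. Spin tests
only need plausible spherical geometry and a complete labelling, so no
real surface meshes are involved.

## Covariance model and gradient compression

`make_covariance_model()` builds the parcel correlation model

$$K_{ij} = 0.22\,\exp\!\big[-(g\,|ap_i - ap_j|/1.5)^2\big],\qquad K_{ii}=1,$$

with `gradient_strength` $g$ (default 1). Two choices here are deliberate
and were fixed once, during design:

- **Amplitude 0.22.** Empirical structural-covariance matrices have
  moderate inter-regional correlations (mostly |r| ≲ 0.3), not
  correlations near 1. Keeping the amplitude moderate also means sample
  correlation matrices at realistic cohort sizes (a few hundred subjects)
  carry visible estimation noise — which is exactly the regime in which
  group differences in covariance structure express themselves in
  gradient space.
- **Squared-exponential shape, length 1.5.** A smooth kernel concentrates
  variance in the leading component (the observed scaled eigenvalue of
  the first gradient is ≈ 0.5), so the first gradient is a stable object
  rather than one of several near-degenerate components.

Group-level **gradient compression** is planted by convex blending toward
uniformity: `compress_covariance()` returns $(1-c)K + c\bar K$, where
$\bar K$ is the constant matrix at $K$'s mean off-diagonal value. Both
terms are positive semi-definite, so no jitter is needed. One parameter
$c \in [0,1)$ therefore controls how much the high-psychopathy group's
covariance loses its AP differentiation; the defaults are $c = 0.3$ for
CT and $c = 0$ for SA, reproducing the qualitative study finding
(compressed CT gradient, unchanged SA gradient).

## Morphometry and behavior

`simulate_morphometry()` draws subject rows from a multivariate normal
with the group-specific covariance, on top of realistic baselines
(CT 2.5 ± 0.15 mm; SA 500 ± 50 mm²), adds standardized covariate slopes
(age, IQ, and TIV for SA), and a per-parcel high-group shift in SD units.
The default SA group effect is +0.3 SD in paralimbic and somatomotor
parcels — the territories where the study's group effects concentrate —
and zero elsewhere. Positivity is guaranteed by the baselines, with a
uniform global shift as a guard (it preserves all covariance and contrast
structure).

`simulate_behavior()` generates latent F1/F2 factors with Spearman
correlation ≈ 0.5 (Gaussian copula, Pearson 0.52), thresholds latent item
variables into the instruments' integer scales, and couples the IRI to
the factors with two signed coefficients: F1 → IRI-EC and F2 → IRI-PT
(both −0.4 by default). This yields the study's signature pattern of
*unique* relationships. The cohort builder hits requested group sizes
(289 low / 337 moderate / 178 high by default) exactly, by rejection
sampling from latent distributions shifted per group; one global seed is
expanded into per-stage child seeds by fixed offsets.

## What the generator does *not* emulate

- Spatial autocorrelation beyond the AP axis (no folding, no lobar
  structure), and no item-level reverse scoring for the IRI;
- the empirical dissociation in which empathy scores show *no* cortical
  signal: because IRI-EC is coupled to F1, a cortical F1 signal leaks
  weakly into IRI-EC predictions;
- measurement artifacts (scanner drift, site effects, surface
  reconstruction errors) beyond a generic Euler-number covariate.

Passing tests therefore demonstrate that the estimators recover planted
structure of the stated kind and size — not that the pipeline is robust
to every pathology of real MRI data.

# Statistical methods

## Robust brain-behavior mapping

`robust_fit()` is iteratively reweighted least squares with Tukey
bisquare weights (tuning constant 4.685) and scale re-estimated each
iteration as MAD/0.6745 of the residuals; convergence is declared when
the largest coefficient change falls below `tol` (1e−8, max 50
iterations). Standardized betas ($\beta_Z$) are obtained by rescaling
each slope by $sd(x_j)/sd(y)$, which for an M-estimator is *exactly*
equivalent to refitting on z-scored data (bisquare weights are invariant
to affine rescaling of the response and of individual columns); the test
suite asserts this equivalence against a literal z-scored refit, and
checks the estimator against an independent implementation. Two-sided
p-values use asymptotic normal theory on the robust sandwich covariance.
Degenerate inputs are handled explicitly: a constant response returns
zero slopes, an exact fit short-circuits, rank-deficient designs raise an
error.

`map_association()` fits one such regression per parcel (predictor plus
age and IQ for CT; plus TIV for SA), then applies Benjamini–Hochberg FDR
across the 360 parcels of that one map (not pooled across maps), at
q < 0.05. `fdr_bh()` implements the step-up cumulative-minimum
definition directly, and the suite requires *exact* equality with a
literal reimplementation.

Partition contrasts (`compare_by_partition()`) compare the per-parcel
$\beta_Z$ distributions between Mesulam classes (6 pairwise tests) or Yeo
networks (21 tests) with rank-sum tests, Bonferroni-multiplied by the
number of pairs and capped at 1. Parcels are treated as exchangeable
units; this ignores residual spatial autocorrelation between parcels, a
known caveat of the procedure it reproduces (the spin test below is the
spatially aware alternative for map-level questions).

## Out-of-sample prediction

`run_prediction()` composes:

1. `split_train_test()` — a simple random split with
   `n_test = round(n × fraction)` (no stratification);
2. `residualize_covariates()` — OLS residualization of every parcel
   column on the covariates, *separately* within the training and test
   sets, so no training statistic touches a test row;
3. training-set standardization of the residualized features (training
   SDs applied to both sets), so the penalty grid acts on a common scale;
4. `ridge_cv()` — 10-fold cross-validation of MSE over a 25-point
   log-spaced grid λ ∈ [1e−3, 1e5], selection of the minimizer, refit on
   the full training set. The solver is the exact SVD closed form of
   $(X^\top X + \lambda I)^{-1}X^\top y$ (verified against the normal
   equations), with fold SVDs precomputed once — which is what makes the
   permutation null affordable;
5. `evaluate_oos()` — out-of-sample $R^2 = 1 - SS_{res}/SS_{tot}$ with
   $SS_{tot}$ around the test-set mean (training-mean variant available),
   and a normalized MSE (MSE divided by the target's maximum possible
   score: 16 for F1, 20 for F2, 28 for IRI subscales);
6. `permute_null_mse()` — the stricter permutation scheme: the
   *training* target is shuffled and the entire selection-plus-refit
   pipeline re-run per permutation, so the null retains the selection's
   optimism; $p = (1 + \#\{\text{null MSE} \le \text{observed}\})/(1+N)$.

The package default is 10,000 permutations; the analysis drivers and the
acceptance script use 1,000, and the calibration suite uses 200 per
split with 100 outer replicates — sizes chosen so a full desk-scale pass
of every stage stays comfortable on one core.

## Structural-covariance gradients

`structural_covariance()` is the parcel-pair Pearson correlation of the
residualized morphometry (group gradients use group-wise
residualization, matching sample-specific covariance construction).
`build_affinity()` keeps, per row, the top (1 − sparsity) fraction of
entries, zeroes the rest and all negatives, and converts retained row
profiles to normalized-angle similarity $1 - \arccos(\cos\theta)/\pi$.
`diffusion_embedding()` density-normalizes by degree$^{\alpha}$
(α = 0.5), forms the diffusion transition operator, eigendecomposes via
the conjugate symmetric matrix (dense, exact at p = 360), drops the
trivial constant eigenvector, and returns eigenvalue-scaled eigenvectors
as loadings, with variance explained reported as normalized eigenvalue
magnitudes. Signs are fixed deterministically, and `orient_gradients()`
orients template components to correlate positively with the AP axis.

**Default sparsity is 0.75, not the 0.9 common for dense
functional-connectivity matrices.** With 360 parcels, 90% sparsification
keeps only 36 neighbours per row; the normalized-angle profile then
carries almost no information about correlation *magnitude*, and the
embedding becomes nearly invariant to exactly the covariance blending
that group compression consists of (at c = 0.3 the population-level
loading range shrinks by ~1%). Keeping the top quarter restores
magnitude sensitivity while still suppressing noise; sparsity remains a
user-facing argument for sensitivity analyses.

`procrustes_align()` solves the orthogonal Procrustes problem by SVD of
the cross-product of column-centered loadings — rotation/reflection only,
no scaling — so group gradients traverse the template's axes.
`compression_stats()` then runs a two-sample Kolmogorov–Smirnov test on
the aligned first-component loadings (360 per group) and reports loading
ranges and their high/low ratio; `partition_compression()` adds
class/network-level signed-rank tests (Bonferroni factors 4 and 7) and a
compression-orientation flag: the label median of the high group lying
strictly closer to that group's center (the median across label medians)
than the low group's label median does to its own. Labels with fewer
than 5 parcels are excluded as unstable. As with the partition
contrasts, parcels enter the KS test as exchangeable observations.

## Spin permutation

`spin_permutation_corr()` builds a spatial null for map-to-map
correlations: a uniformly random rotation (QR of a Gaussian matrix with
sign correction; determinant fixed to +1 by negating the whole matrix,
which preserves the Haar measure in odd dimension) is applied to the
left-hemisphere centroids and its x-mirrored counterpart to the right,
and each parcel takes the value of the nearest rotated centroid within
its hemisphere (with replacement — the simplest standard variant;
one-to-one assignment is a possible extension). The two-sided p-value
counts null |r| at or above the observed. The mean rotation angle of the
generator matches the closed-form uniform-SO(3) expectation
$\pi/2 + 2/\pi$ (≈ 126.5°).

# Scoring and group definitions

`score_iri()` sums 7 items per subscale and refuses missing items (no
IRI prorating). `prorate_pclr()` rescales each scale's observed item sum
to its full item count (`sum × n_items / n_scored`, decimals retained —
equivalent to mean-imputing omissions), with caps of 5 omitted items for
the total and 2 per factor, the scoring-manual convention; both the caps
and the item-factor map are arguments because the instrument's exact
published item assignment is licensed content (the default maps items
1–8 to F1 and 9–18 to F2). `assign_group()` applies the ≥30 / ≤20
cutoffs. `spearman_matrix()` uses average-rank Spearman correlations
with t-approximation p-values and Bonferroni flags across a configurable
family size (28 for the 8-variable behavioral matrix).

# Design choices in brief

| Choice | Value | Why |
|---|---|---|
| bisquare constant / scale | 4.685, MAD/0.6745 | the common default when a robust fit is otherwise unspecified; configurable |
| FDR scope | per map (360 parcels) | mirrors per-map reporting of grayed-out parcels |
| ridge folds / grid | 10 folds, 25 λ in [1e−3, 1e5] | unspecified upstream; standard choices, exposed as arguments |
| permutation unit | training target, full re-selection | the stricter reading; preserves selection optimism in the null |
| $R^2_{oos}$ centering | test-set mean | the standard coefficient of determination; training-mean variant exposed |
| embedding | α = 0.5, diffusion time 0, sparsity 0.75 | toolbox-style kernel chain; sparsity lowered for magnitude sensitivity (see above) |
| alignment | orthogonal Procrustes, no scaling | scaling would absorb the compression signal being measured |
| group covariance | group-wise residualization | sample-specific covariance matrices |
| spin variant | mirrored rotations, nearest-centroid with replacement | standard practice preserving hemisphere correspondence |

# Problem sizes used in the shipped analyses

The drivers under `analysis/` and `scripts/acceptance.R` run the full
cohort at the study's scale (N = 804; 289/337/178 by group; 360 parcels)
with 1,000 prediction permutations and 500 spin rotations. The test
suite uses the sizes its properties prescribe: gradient recovery at
n = 400, compression detection at n = 300 per group over 20 replicates,
prediction null calibration over 100 replicates at 200 permutations, and
signal recovery at n = 800 over 20 replicates. These are the package's
chosen desk-scale conditions; all counts are arguments, so larger runs
only cost time.

# Known limitations

- The generator's geometry is a sphere pair with banded labels; spin
  tests on it are exchangeable by construction, which real cortical
  geometry only approximates.
- Parcel-level rank-sum/KS/signed-rank procedures treat parcels as
  independent observations, as in the analyses they reproduce.
- The IRI–cortex null result of the empirical study is not reproduced
  (see above); conclusions about empathy-specific cortical signals
  should not be read off the synthetic cohort.
- PCL-R item-factor assignment and prorating caps are conventions, not
  the licensed instrument's exact tables; both are configurable.
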