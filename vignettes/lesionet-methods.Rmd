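---
title: "Lesion-symptom and lesion-network mapping on a synthetic phantom: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion-symptom and lesion-network mapping on a synthetic phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own methods: the statistical
models, what each tunable parameter means and why its default was chosen,
what the synthetic phantom does and does not emulate, and the design
choices made where the methodology was genuinely open. Nothing here states
an empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. Setting

A cohort of stroke patients with unilateral thalamic lesions is assessed
with the Aphasia Check List (ACL): a total score from 0 to 148 (lower =
worse; aphasia is diagnosed strictly below 135) and eight subdomain
ordinals from 0 to 3 (3 = no disorder; 0–2 are labelled impaired). The
reading, writing and repeating subdomains each merge three task items by
their median. Lesions are binary masks on a shared voxel grid; a normative
resting-state connectome (healthy-subject BOLD time series) stands in for
patient fMRI, which is unavailable in acute stroke.

Two questions drive the pipeline. *Where* does damage track the score?
(lesion-symptom mapping, LSM). *What is the damaged tissue connected to*,
and does that connectivity profile track the score? (lesion network
mapping, LNM).

## 2. Multivariate LSM by a sparse canonical component

With X the n × p matrix of binary lesions over the analysis mask
(columns standardized) and y the behaviour score residualized on nuisance
covariates, the component solves

u* = argmax cor(Xu, y)  subject to a sparseness budget on u, ‖u‖₂ = 1.

For a single behavioural variable the penalised solution has a closed
form: soft-threshold the voxel–behaviour covariance X′y at a quantile of
its absolute values and renormalise. The solver iterates a projected power
step until the weights stabilise and is tested against that closed form at
1e-6 (after sign alignment).

**The sparseness parameter.** s ∈ [−1, 1]; |s| is the fraction of mask
voxels allowed a nonzero weight, implemented as thresholding at the
(1 − |s|)-quantile of |X′y| (at |s| = 1 the threshold is zero and the dense
solution u ∝ X′y is returned). The sign convention follows the sparse-CCA
tradition in lesion mapping: s < 0 permits signed weights; s ≥ 0 restricts
the component to its dominant sign. The exact numeric scale of the
sparseness parameter in existing lesion-mapping software is not documented
publicly; our support-fraction definition is a stated approximation with
the same sign semantics. Support is monotone: shrinking |s| never adds
voxels.

**Cross-validated selection.** The default grid is −0.9 … 0.9 in steps of
0.1 (0 excluded as degenerate). For each grid value a seeded 4-fold
cross-validation builds the component on 75 % of the sample and predicts
the held-out 25 %; pooled out-of-fold predictions are correlated with the
observed scores, and the grid value with the highest CV correlation wins
(ties toward the sparser model). Fold assignment is seeded, so selection
is deterministic.

**Why the reported correlation is nested.** Reporting the maximised grid
CV correlation would inherit a winner's-curse: under a true null, the
maximum of ~18 correlated CV correlations is systematically positive, and
its t-based p-value rejects far too often. The package therefore reports a
*nested* cross-validation correlation — the sparseness is re-selected
inside each outer training fold and only the untouched outer fold is
predicted — whose null distribution is centred (the test suite checks
that permuted-score cohorts yield p > 0.05 in ≥ 90 % of replicates). The
selected sparseness itself is still reported from the full-sample grid
search. The p-value uses the one-sided t transform r√(n−2)/√(1−r²); the
hypothesis is directional (lesion patterns predict worse scores).

**Other LSM choices.**

- Coverage filter: voxels lesioned in at least `max(1, ceiling(0.10·n))`
  patients. `ceiling` implements a strict "at least 10 %" reading; the
  floor of one lesion keeps the rule meaningful for tiny cohorts. The mask
  is recomputed per analysis (per score column), since patients with
  missing scores drop out.
- Covariates: lesion volume is regressed out of the behaviour vector only,
  not out of the lesion matrix — simpler, testable, and sufficient to
  remove the "bigger lesions are simply worse" confound.
- The weight map is |u| scaled so its maximum is 1 (unselected voxels are
  exactly 0), matching the convention of a unitless 0–1 relevance scale.
- Zero-variance lesion columns are excluded with a warning at the user
  level; inside cross-validation folds they are expected (a voxel can be
  constant within a fold) and silently receive zero weight.

## 3. Lesion network mapping

**Connectivity profiles.** Per connectome subject, the lesion's mean BOLD
series is correlated with every voxel's series; r is clipped to ±0.999999,
Fisher-z transformed (atanh), and the per-subject z-maps are averaged.
Fisher-z before averaging is the convention of the lead-mapper tools;
the alternative order (average r, then transform) is not variance-
stabilised. Within-lesion voxels keep their (clipped) z values — no lesion
exclusion mask is applied. Subjects whose seed series is constant are
skipped with a warning.

**Correlation maps.** Voxel-wise Pearson correlation between profiles and
the inverted score (148 − ACL, higher = worse), two-sided p from the t
transform with n−2 df, Benjamini–Hochberg FDR at α = 0.05 across the
analysis mask. Two-sided testing is consistent with reporting symmetric
positive/negative significance thresholds (the smallest |r| declared
significant in each direction). Constant profile voxels get r = 0, p = 1.

**Similarity prediction.** A held-out patient's predicted severity is the
spatial Pearson correlation of their profile with the training cohort's
*unthresholded* r-map (thresholding would discard graded information and
make the prediction depend on the FDR level). Leave-one-out rebuilds the
r-map from the other n−1 patients; the split validation draws a seeded
random `floor(0.7·n)` training set (for n = 76: 53 train / 23 test,
`floor` chosen to match that arithmetic) and predicts the untouched test
set. Validation p-values are one-sided (directional prediction
hypothesis); the two-sided value is also stored. Leave-one-out similarity
prediction carries a known mild negative coupling between the held-out
score and the leave-one-out map; at the cohort sizes used here the test
suite checks it is negligible (null cohorts stay within |r| < 0.3 in
≥ 90 % of replicates).

## 4. Permutation inference

The voxel-wise GLM uses an explicit intercept plus the inverted score and
the nuisance covariates (presence of aphasia, age, lesion volume);
dropping the aphasia flag is a pure configuration change (the sensitivity
variant), not new code. t-statistics are OLS with
t = c′β̂ / √(c′(X′X)⁻¹c·σ̂²), df = n − q.

**Freedman–Lane.** The data are regressed on the nuisance columns; the
reduced-model residuals are row-permuted, the nuisance fit is added back,
and the full-model t-map is recomputed. This is the default scheme of the
standard neuroimaging permutation tools and is asymptotically exact with
covariates. An explicit permutation matrix can be supplied, which the test
suite uses to check exactness against exhaustive enumeration on a
6-sample two-group design.

**TFCE.** TFCE(v) = Σ_h e_v(h)^E · h^H · dh over thresholds h = dh, 2dh,
…, with E = 0.5, H = 2, 26-neighbour connectivity and dh = (map max)/100 —
the standard volumetric defaults. Each contrast is enhanced on its
positive side. The kernel (C++, incremental union-find over descending
thresholds) is verified at 1e-10 against a brute-force per-threshold
connected-component oracle and against the analytic plateau value
e^0.5·h³/3.

**FWE.** The max TFCE statistic over the volume per permutation forms the
null; corrected p(v) = (1 + #{max_perm ≥ TFCE_obs(v)}) / (1 + n_perm),
reported as a 1−P map thresholded strictly (> 0.95, and > 0.98 for the
strongest connections). The +1 convention makes the smallest achievable p
equal 1/(n_perm+1) and the estimator valid at any permutation count; at
the phantom scale we run 200 permutations (5000 remains the configurable
full-scale setting), which makes the test slightly conservative — the
calibration check accepts a family-wise rate in [0.01, 0.10] at nominal
0.05 and the measured rate sits at the conservative end.

## 5. The synthetic phantom

The phantom exists so that every stage has a ground truth. Geometry: a
24³ grid of 2 mm voxels (small enough that the full pipeline including
permutation inference runs in minutes), centred so negative x is "left".
Regions (disjoint box primitives): a 3³ **critical nucleus** inside a left
thalamic placement shell, a mirrored right thalamus, and two left frontal
patches (**broca**, **frontal_left**) forming the planted remote network.

**Connectome.** Each voxel's series is Σ_k λ(region,k)·s_k(t) + ε with
i.i.d. standard-normal latents and N(0, σ²) noise, so two voxels sharing a
latent have expected correlation λ₁λ₂/√((λ₁²+σ²)(λ₂²+σ²)) — checked
empirically at T = 2000 within ±0.03. Defaults: 8 subjects × 100
timepoints, σ = 1, loadings 0.9/0.9/0.7 linking the critical nucleus to
the two cortical patches and 0.8 on a separate right-thalamic latent.
Eight subjects stand in for the 1000-subject normative database: profile
averaging behaves identically, only with more sampling noise, which the
recovery margins absorb.

**Cohort.** Spherical lesions (radius 1.5–3 voxels) centred uniformly in
the placement regions; 70 % left-sided. Scores follow
`round(clamp(148·(1 − β·overlap) + N(0, σ_score²), 0, 148))` with
round-half-to-even (ACL scores are integers), `overlap` the fractional
coverage of the critical nucleus, zero effect for right-sided lesions
(mirroring left-lateralised language). Defaults β = 0.25, σ_score = 4:
a full-coverage lesion costs ≈ 37 ACL points, placing severe patients
well below the 135 diagnostic cut-off while zero-overlap patients stay
unimpaired — a realistic spread for mild-to-moderate thalamic aphasia.
Subdomain ordinals bin a noisy copy of the overlap (σ = 0.15) into
{3,2,1,0}; age is uniform 35–90. β = 0 produces exact null cohorts used
by the calibration tests.

**What the phantom does not emulate** — and hence what passing tests do
not show about real data: spatial autocorrelation of BOLD noise and
hemodynamics, vascular-territory lesion shapes, registration and
segmentation error, score floor effects from multi-domain damage, and the
scale of a real connectome. Results on the phantom validate the
*machinery* (estimators, calibration, recovery under a known model), not
clinical effect sizes.

## 6. Numerical and degenerate-input choices

- Coverage threshold: `ceiling`, floor of 1; mismatched geometries are
  hard errors (normalisation is upstream and out of scope).
- Voxel sets are ordered by sorted linear (column-major) index — a
  deterministic ordering used for tie-free reproducibility.
- Peak extraction breaks ties toward the lexicographically smallest
  (i, j, k); centre of mass uses map values as weights (uniform for
  binary ROIs).
- Missing ACL items: a subdomain's median uses the available items (lower
  median for even counts — conservative toward impairment); the subdomain
  is missing only when every item is missing. Patients without a total
  score stay in the table but leave score-based analyses (the coverage
  mask is recomputed on the reduced cohort).
- Correlation clipping at ±0.999999 keeps Fisher-z finite for
  self-correlated seed voxels.
- The sparse component returns the zero vector (not an error) when no
  voxel survives the budget or the behaviour is orthogonal to every
  column; a CV fold with constant predictions contributes r = 0.
- All simulated-score rounding is round-half-to-even (R's `round`).
- One global study seed fans out to fixed per-stage offsets, so any stage
  can be rerun in isolation and reproduce the full run bit-for-bit.

## 7. Validation problem sizes

The test suite validates at these scales, chosen as the package's own
study conditions: LSM recovery on an 80-patient cohort (β = 0.25,
σ_score = 4) with 50 permuted-score null replicates; LNM recovery and
50 null cohorts at n = 76 (the split arithmetic size); family-wise error
calibration on 100 null cohorts of n = 40 at 200 permutations against one
fixed connectome (a study has one normative connectome; only cohorts
resample); sparse-CCA and TFCE oracles on 50 and 20 random problems;
exhaustive permutation enumeration at n = 6. The acceptance script runs
the full 76-patient phantom study at 200 permutations.

## 8. Known limitations

- Single-component CCA only: one behavioural variable at a time (the
  subdomain analyses loop over columns); no multi-behaviour components.
- The sparseness scale is package-specific; absolute values are not
  comparable with other implementations, only the sign semantics.
- Permutation inference assumes exchangeable rows (no exchangeability
  blocks, no variance smoothing, no sign-flipping one-sample mode).
- The connectome container is dense in memory (subjects × timepoints ×
  voxels); at real MNI resolution a file-backed representation would be
  needed.
- No image registration, resampling or smoothing: all inputs must share
  one geometry, and atlas overlap runs at native resolution.
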