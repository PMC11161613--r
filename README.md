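# lesionet

Lesion-symptom and lesion-network mapping for focal stroke cohorts, with
nonparametric voxel-wise inference — packaged as a tested, reproducible R
pipeline and exercised end to end on a synthetic phantom cohort.

## The problem

Focal lesions (here: unilateral ischemic thalamic stroke) can impair
language both through the damaged tissue itself and through remote,
functionally connected cortex. Two complementary analyses address this:

- **Multivariate lesion-symptom mapping (LSM)** asks *where* damage is
  associated with a behavioural score. Binary lesion masks over a common
  voxel grid form an n × p matrix X; a sparse canonical component finds a
  unit voxel-weight vector **u** maximising cor(X**u**, y) under a
  sparseness budget s ∈ [−1, 1] (|s| = fraction of voxels allowed nonzero,
  realised by soft-thresholding X′y at the matching quantile; s < 0 permits
  signed weights). The sparseness is selected by seeded 4-fold
  cross-validation over a grid; the reported CV correlation comes from a
  nested cross-validation so the grid search cannot inflate it. Only voxels
  lesioned in ≥ 10 % of cases enter the analysis, and lesion volume is
  regressed out of the score as a nuisance covariate. The output is a 0–1
  voxel weight map.

- **Lesion network mapping (LNM)** asks *what the damaged site is connected
  to*. Each lesion acts as a seed in a normative resting-state connectome:
  per connectome subject, the mean BOLD series over the lesion is
  correlated with every voxel, Fisher-z transformed (atanh, with r clipped
  to ±0.999999), and averaged over subjects, giving one connectivity
  profile per patient. Profiles are related to the (inverted, higher =
  worse) behaviour score by voxel-wise Pearson maps with Benjamini–Hochberg
  FDR control, leave-one-out and 70/30 split-half similarity prediction,
  and a voxel-wise GLM tested by Freedman–Lane permutation with
  threshold-free cluster enhancement (TFCE, E = 0.5, H = 2, 26-neighbour)
  and max-statistic family-wise error correction, reported as 1−P maps
  thresholded at 1−P > 0.95 (and 0.98).

Behaviour is an Aphasia Check List (ACL) total score, 0–148 (lower =
worse, diagnosis strictly below 135), plus eight subdomain ordinals 0–3
(impaired ≤ 2); the clinical module implements the scoring rules (median
merge of reading/writing/repeating items, inversion 148 − score).

Because real patient cohorts and 1000-subject connectomes cannot be
shipped, the package includes a first-class synthetic module: a phantom
label atlas (24³ grid, 2 mm voxels) with a "critical nucleus" and remote
cortical network patches, a latent-factor connectome with analytically
known correlations, and lesion cohorts whose scores follow
`round(clamp(148·(1 − β·overlap), 0, 148) + noise)` where `overlap` is the
lesion's fractional coverage of the critical nucleus (left-sided lesions
only). Every stage of the pipeline is validated against this phantom.

## Worked example

```r
library(lesionet)

atlas <- make_phantom_atlas(default_phantom_spec())
conn  <- simulate_connectome(atlas, connectome_spec(seed = 102))
sim   <- simulate_lesion_cohort(atlas, cohort_spec(n_patients = 76, seed = 212))

lsm <- run_sccan_lsm(sim$masks, sim$records, config = sccan_config(seed = 308))
lsm
#> <lsm_result> n=76, optimal sparseness -0.100, CV r = 0.843 (one-sided p = 7.18e-22), 43 voxels selected

prof <- cohort_profiles(sim$masks, conn)
yinv <- invert_score(sim$records$aphasia_score)
loocv_predict(prof, yinv)
#> <validation_result> loocv: r = 0.788, one-sided p = 1.44e-17
split_validate(prof, yinv, train_frac = 0.7, seed = 402)
#> <validation_result> split: r = 0.823, one-sided p = 7.24e-07
```

The LSM result is a 0–1 weight map whose support overlaps the planted
critical nucleus (Dice 0.70 in this run); the LOOCV/split correlations
measure how well a held-out patient's connectivity profile predicts
severity by spatial similarity to the cohort's correlation map. The split
uses `floor(0.7·76) = 53` training and 23 test patients.
`atlas_overlap()`, `peak_and_center()` and `decode_map()` relate any
resulting map to a label atlas or a map library;
`permutation_fwe()`/`threshold_significant()` provide the nonparametric
FWE-corrected 1−P maps. `run_study()` chains all stages under one seed and
writes a JSON report; `inst/cli/lesionet.R` is a thin command-line wrapper
(`simulate`, `run`).

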