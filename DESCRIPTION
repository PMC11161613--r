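Package: lesionet
Title: Lesion-Symptom and Lesion-Network Mapping with Permutation Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multivariate lesion-symptom mapping by sparse canonical
    correlation with cross-validated sparseness, lesion network mapping
    against a normative resting-state connectome (seed-averaged BOLD
    connectivity profiles, Fisher-z transformed, voxel-wise correlation
    maps with Benjamini-Hochberg FDR control, leave-one-out and split-half
    similarity prediction), and nonparametric voxel-wise GLM inference
    (Freedman-Lane permutation, threshold-free cluster enhancement,
    max-statistic family-wise error correction). Ships a synthetic phantom
    generator (label atlas, multi-subject time series with planted latent
    networks, lesion cohorts with planted lesion-behaviour effects) so the
    full pipeline is testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
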