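test_that("phantom atlas is deterministic with analytic region sizes", {
  spec <- default_phantom_spec()
  a1 <- make_phantom_atlas(spec)
  a2 <- make_phantom_atlas(spec)
  expect_identical(a1$labels, a2$labels)
  expect_length(atlas_region_indices(a1, "vlpv_left"), 27)       # 3^3 box
  expect_length(atlas_region_indices(a1, "thalamus_right"), 125) # 5^3 box
  expect_length(atlas_region_indices(a1, "thalamus_left"), 75)   # 5x3x5 box

  bad <- spec
  bad$regions$clash <- list(shape = "box", center = c(8, 12, 11), size = 3)
  bad$network_regions <- spec$network_regions
  expect_error(make_phantom_atlas(bad), "overlap")
  outside <- spec
  outside$regions$far <- list(shape = "box", center = c(24, 24, 24), size = 3)
  expect_error(make_phantom_atlas(outside), "outside")
})

test_that("connectome correlations follow the latent-factor expectation", {
  atlas <- fixture_atlas()
  # noiseless limit: unit loading on a shared latent gives r = 1
  conn0 <- simulate_connectome(atlas, connectome_spec(
    n_subjects = 1, n_timepoints = 50,
    latent_loadings = list(f = c(vlpv_left = 1, broca = 1)),
    noise_sd = 1e-8, seed = 5))
  v1 <- atlas_region_indices(atlas, "vlpv_left")[1]
  v2 <- atlas_region_indices(atlas, "broca")[1]
  ts <- conn0$subjects[[1]]
  expect_equal(cor(ts[, v1], ts[, v2]), 1, tolerance = 1e-6)

  # l1 = l2 = 1, sigma = 1: expected r = 1 / sqrt(4) = 0.5 at T = 500
  conn1 <- simulate_connectome(atlas, connectome_spec(
    n_subjects = 1, n_timepoints = 500,
    latent_loadings = list(f = c(vlpv_left = 1, broca = 1)),
    noise_sd = 1, seed = 6))
  r <- cor(conn1$subjects[[1]][, v1], conn1$subjects[[1]][, v2])
  ci <- tanh(atanh(0.5) + c(-1, 1) * 1.96 / sqrt(500 - 3))
  expect_gt(r, ci[1]); expect_lt(r, ci[2])

  # empirical correlations converge to the analytic value at T = 2000
  conn2 <- simulate_connectome(atlas, connectome_spec(
    n_subjects = 1, n_timepoints = 2000,
    latent_loadings = list(f = c(vlpv_left = 0.9, broca = 0.7)),
    noise_sd = 1, seed = 7))
  expected <- 0.9 * 0.7 / sqrt((0.9^2 + 1) * (0.7^2 + 1))
  r2 <- cor(conn2$subjects[[1]][, v1], conn2$subjects[[1]][, v2])
  expect_lt(abs(r2 - expected), 0.03)

  # background voxels are pure noise: near-zero correlation to the latent
  bg <- which(atlas$labels == 0L)[1]
  expect_lt(abs(cor(conn2$subjects[[1]][, bg], conn2$subjects[[1]][, v1])), 0.08)

  # seeding: different seeds give different series, same seed identical
  ca <- simulate_connectome(atlas, connectome_spec(n_subjects = 1,
                                                   n_timepoints = 20, seed = 1))
  cb <- simulate_connectome(atlas, connectome_spec(n_subjects = 1,
                                                   n_timepoints = 20, seed = 2))
  cc <- simulate_connectome(atlas, connectome_spec(n_subjects = 1,
                                                   n_timepoints = 20, seed = 1))
  expect_false(identical(ca$subjects[[1]], cb$subjects[[1]]))
  expect_identical(ca$subjects[[1]], cc$subjects[[1]])

  expect_error(simulate_connectome(atlas, connectome_spec(
    latent_loadings = list(f = c(nowhere = 1)))), "unknown region")
})

test_that("simulated scores follow the planted overlap model exactly", {
  atlas <- fixture_atlas()
  # noiseless, full critical-nucleus coverage: round(148 * 0.8) = 118
  full <- simulate_lesion_cohort(atlas, cohort_spec(
    n_patients = 6, radius_range = c(4, 4), placement_left = "vlpv_left",
    effect_beta = 0.2, noise_sd_score = 0, left_fraction = 1, seed = 9))
  expect_true(all(full$overlap == 1))
  expect_true(all(full$records$aphasia_score == 118L))

  # right-sided lesions carry no effect: score stays 148 without noise
  right <- simulate_lesion_cohort(atlas, cohort_spec(
    n_patients = 5, effect_beta = 0.5, noise_sd_score = 0,
    left_fraction = 0, seed = 10))
  expect_true(all(right$records$aphasia_score == 148L))
  expect_true(all(right$records$side == "right"))

  # generic run: score = round(clamp(148(1 - beta * overlap))) given outputs
  sim <- simulate_lesion_cohort(atlas, cohort_spec(
    n_patients = 30, effect_beta = 0.4, noise_sd_score = 0, seed = 11))
  crit <- atlas_region_indices(atlas, "vlpv_left")
  ov <- vapply(sim$masks, function(m) sum(m$voxels[crit]) / length(crit),
               numeric(1))
  ov[vapply(sim$masks, `[[`, character(1), "side") == "right"] <- 0
  expect_equal(sim$overlap, ov)
  expect_equal(sim$records$aphasia_score,
               as.integer(round(pmin(pmax(148 * (1 - 0.4 * ov), 0), 148))))
})

test_that("cohort generation is reproducible and sized as requested", {
  atlas <- fixture_atlas()
  s1 <- simulate_lesion_cohort(atlas, cohort_spec(n_patients = 76, seed = 3))
  s2 <- simulate_lesion_cohort(atlas, cohort_spec(n_patients = 76, seed = 3))
  expect_length(s1$masks, 76)
  expect_equal(nrow(s1$records), 76)
  expect_identical(s1$records, s2$records)
  expect_identical(which(s1$masks[[40]]$voxels), which(s2$masks[[40]]$voxels))
  # lesion volumes on the record match the masks
  expect_equal(s1$records$lesion_volume,
               vapply(s1$masks, lesion_volume_cm3, numeric(1)))
  expect_true(all(s1$records$age >= 35 & s1$records$age <= 90))
})

test_that("a phantom study writes the pipeline's on-disk formats", {
  dir <- withr::local_tempdir()
  paths <- write_phantom_study(dir,
                               connectome = connectome_spec(n_subjects = 2,
                                                            n_timepoints = 20),
                               cohort = cohort_spec(n_patients = 6))
  expect_true(file.exists(paths$atlas))
  expect_true(file.exists(paths$clinical))
  masks <- read_cohort(paths$manifest)
  expect_length(masks, 6)
  conn <- read_connectome(paths$connectome_dir)
  expect_length(conn$subjects, 2)
  expect_equal(conn$n_timepoints, 20)
  atlas <- read_atlas(paths$atlas, paths$labels)
  expect_identical(atlas$labels, fixture_atlas()$labels)
})
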