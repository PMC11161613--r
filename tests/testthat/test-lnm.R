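make_tiny_connectome <- function(geom, n_subjects = 1, Tn = 30, seed = 1) {
  set.seed(seed)
  V <- prod(geom$shape)
  subjects <- lapply(seq_len(n_subjects), function(s)
    matrix(rnorm(Tn * V), Tn, V))
  structure(list(subjects = subjects, geometry = geom, n_timepoints = Tn),
            class = "connectome")
}

test_that("a single-voxel seed reproduces that voxel's correlation map", {
  geom <- small_geometry(c(5L, 5L, 5L))
  conn <- make_tiny_connectome(geom, seed = 2)
  v <- array(FALSE, geom$shape); v[2, 3, 4] <- TRUE
  prof <- lesion_connectivity_profile(lesion_mask(v, geom, "P1"), conn)
  ts <- conn$subjects[[1]]
  seed_series <- ts[, which(v)]
  expected <- atanh(pmin(pmax(cor(seed_series, ts), -0.999999), 0.999999))
  expect_equal(as.numeric(prof$zmap$values), as.numeric(expected),
               tolerance = 1e-12)
  # the seed voxel itself is perfectly correlated, hence clipped
  expect_equal(prof$zmap$values[2, 3, 4], atanh(0.999999))
})

test_that("profiles average per-subject Fisher-z maps", {
  geom <- small_geometry(c(5L, 5L, 5L))
  conn2 <- make_tiny_connectome(geom, n_subjects = 2, seed = 3)
  v <- array(FALSE, geom$shape); v[1:2, 1, 1] <- TRUE
  m <- lesion_mask(v, geom, "P1")
  both <- lesion_connectivity_profile(m, conn2)
  one <- lapply(1:2, function(s) {
    c1 <- conn2; c1$subjects <- conn2$subjects[s]
    lesion_connectivity_profile(m, c1)$zmap$values
  })
  expect_equal(both$zmap$values, (one[[1]] + one[[2]]) / 2, tolerance = 1e-12)

  # duplicating a subject leaves the profile unchanged (linearity)
  cdup <- conn2; cdup$subjects <- conn2$subjects[c(1, 1)]
  dup <- lesion_connectivity_profile(m, cdup)
  expect_equal(dup$zmap$values, one[[1]], tolerance = 1e-12)
})

test_that("batched cohort profiles equal the per-patient computation", {
  geom <- small_geometry(c(6L, 6L, 6L))
  conn <- make_tiny_connectome(geom, n_subjects = 3, seed = 4)
  set.seed(5)
  masks <- lapply(1:7, function(i) random_mask(geom, n_vox = 4))
  batch <- cohort_profiles(masks, conn)
  for (i in c(1, 4, 7)) {
    single <- lesion_connectivity_profile(masks[[i]], conn)
    expect_equal(batch[[i]]$zmap$values, single$zmap$values, tolerance = 1e-12)
  }
})

test_that("correlation maps recover exact linear relations and report thresholds", {
  geom <- small_geometry(c(5L, 5L, 5L))
  n <- 12
  scores <- seq(10, 120, length.out = n)
  set.seed(6)
  profiles <- lapply(seq_len(n), function(i) {
    vals <- array(rnorm(prod(geom$shape), sd = 3), geom$shape)
    vals[3, 3, 3] <- 1 + 0.02 * scores[i]         # exact positive relation
    vals[1, 1, 1] <- 2 - 0.05 * scores[i]         # exact negative relation
    structure(list(patient_id = paste0("P", i),
                   zmap = scalar_map(vals, geom, "z"),
                   n_connectome_subjects = 1L),
              class = "connectivity_profile")
  })
  cm <- correlation_map(profiles, scores)
  expect_equal(cm$rmap$values[3, 3, 3], 1, tolerance = 1e-10)
  expect_equal(cm$rmap$values[1, 1, 1], -1, tolerance = 1e-10)
  lin <- function(i, j, k) i + (j - 1) * 5 + (k - 1) * 25
  expect_true(lin(3, 3, 3) %in% cm$significant_pos$indices)
  expect_true(lin(1, 1, 1) %in% cm$significant_neg$indices)
  expect_true(cm$threshold_neg <= 0 && cm$threshold_pos >= 0)
  expect_error(correlation_map(profiles, rep(1, n)), "constant")
})

test_that("correlation maps are shift-invariant and sign-equivariant in the scores", {
  geom <- small_geometry(c(4L, 4L, 4L))
  set.seed(7)
  profiles <- lapply(1:8, function(i)
    structure(list(patient_id = paste0("P", i),
                   zmap = scalar_map(array(rnorm(64), geom$shape), geom, "z"),
                   n_connectome_subjects = 1L),
              class = "connectivity_profile"))
  y <- rnorm(8)
  a <- correlation_map(profiles, y)
  b <- correlation_map(profiles, y + 100)
  d <- correlation_map(profiles, -y)
  expect_equal(a$rmap$values, b$rmap$values, tolerance = 1e-12)
  expect_equal(a$rmap$values, -d$rmap$values, tolerance = 1e-12)
})

test_that("BH selection equals a brute-force step-up on the same p-values", {
  geom <- small_geometry(c(6L, 6L, 6L))
  n <- 20
  set.seed(8)
  scores <- rnorm(n)
  profiles <- lapply(seq_len(n), function(i)
    structure(list(patient_id = paste0("P", i),
                   zmap = scalar_map(
                     array(rnorm(216) + scores[i] * rep(c(1, 0), c(30, 186)),
                           geom$shape), geom, "z"),
                   n_connectome_subjects = 1L),
              class = "connectivity_profile"))
  cm <- correlation_map(profiles, scores, fdr_alpha = 0.05)
  p <- as.numeric(cm$pmap$values)
  sig_oracle <- which(bh_oracle(p) <= 0.05)
  got <- sort(c(cm$significant_pos$indices, cm$significant_neg$indices))
  expect_identical(got, sig_oracle)
})

test_that("spatial similarity behaves like a Pearson correlation", {
  geom <- small_geometry(c(4L, 4L, 4L))
  set.seed(9)
  a <- scalar_map(array(rnorm(64), geom$shape), geom, "z")
  neg <- scalar_map(-a$values, geom, "z")
  expect_equal(spatial_similarity(a, a), 1)
  expect_equal(spatial_similarity(a, neg), -1)
  const <- scalar_map(array(1, geom$shape), geom, "z")
  expect_error(spatial_similarity(a, const), "constant")
})

test_that("leave-one-out similarities match an incremental-sums oracle", {
  geom <- small_geometry(c(5L, 5L, 5L))
  n <- 10
  set.seed(10)
  P <- matrix(rnorm(n * 125), n, 125)
  y <- rnorm(n)
  profiles <- lapply(seq_len(n), function(i)
    structure(list(patient_id = paste0("P", i),
                   zmap = scalar_map(array(P[i, ], geom$shape), geom, "z"),
                   n_connectome_subjects = 1L),
              class = "connectivity_profile"))
  res <- loocv_predict(profiles, y)
  # incremental oracle: leave-one-out r-maps from downdated sufficient sums
  Sx <- colSums(P); Sxx <- colSums(P^2); Sxy <- drop(crossprod(P, y))
  Sy <- sum(y); Syy <- sum(y^2)
  sim_oracle <- vapply(seq_len(n), function(i) {
    m <- n - 1
    sx <- Sx - P[i, ]; sxx <- Sxx - P[i, ]^2; sxy <- Sxy - P[i, ] * y[i]
    sy <- Sy - y[i]; syy <- Syy - y[i]^2
    num <- sxy - sx * sy / m
    den <- sqrt((sxx - sx^2 / m) * (syy - sy^2 / m))
    cor(P[i, ], num / den)
  }, numeric(1))
  expect_equal(res$pairs$predicted, sim_oracle, tolerance = 1e-10)
  expect_equal(res$r, cor(sim_oracle, y), tolerance = 1e-10)
  expect_error(loocv_predict(profiles[1:2], y[1:2]), "at least 5")
})

test_that("split validation uses floor(train_frac * n) and is seed-stable", {
  sim <- fixture_cohort(n = 76)
  prof <- cohort_profiles(sim$masks, fixture_connectome())
  yinv <- invert_score(sim$records$aphasia_score)
  sp1 <- split_validate(prof, yinv, 0.7, seed = 123)
  sp2 <- split_validate(prof, yinv, 0.7, seed = 123)
  expect_length(sp1$train_ids, 53)
  expect_length(sp1$test_ids, 23)
  expect_identical(sp1$train_ids, sp2$train_ids)
  expect_equal(sp1$r, sp2$r)
  expect_length(intersect(sp1$train_ids, sp1$test_ids), 0)
  expect_error(split_validate(prof[1:8], yinv[1:8], 0.7, seed = 1),
               "at least 10")
})
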