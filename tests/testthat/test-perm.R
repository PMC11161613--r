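test_that("GLM t-statistics reduce to the bivariate t transform", {
  set.seed(1)
  n <- 25
  x <- rnorm(n)
  Y <- matrix(rnorm(n * 40), n, 40)
  X <- cbind(intercept = 1, x = x)
  g <- glm_tstat(Y, X, c(0, 1))
  r <- drop(cor(x, Y))
  t_oracle <- r * sqrt(n - 2) / sqrt(1 - r^2)
  expect_equal(g$t, t_oracle, tolerance = 1e-10)
  expect_equal(g$df, n - 2)
})

test_that("degenerate designs and contrasts are rejected", {
  set.seed(2)
  Y <- matrix(rnorm(30), 10, 3)
  x <- rnorm(10)
  expect_error(glm_tstat(Y, cbind(1, x, x), c(0, 0, 1)), "rank deficient")
  expect_error(glm_tstat(Y, cbind(1, x), c(0, 0, 1)), "length")
  expect_error(glm_tstat(Y, cbind(1, x), c(0, 0)), "nonzero")
  geom <- small_geometry(c(2L, 2L, 2L))
  expect_error(permutation_fwe(matrix(rnorm(80), 10, 8),
                               cbind(intercept = 1, x = x),
                               c(1, 0), geom, n_perm = 5),
               "non-intercept")
})

test_that("TFCE matches the brute-force per-threshold oracle", {
  set.seed(3)
  for (rep in 1:5) {
    arr <- array(rnorm(8^3), c(8, 8, 8))
    expect_equal(tfce_enhance(arr), tfce_oracle(arr), tolerance = 1e-10)
  }
  # 6-connectivity variant
  arr <- array(rnorm(6^3), c(6, 6, 6))
  expect_equal(tfce_enhance(arr, tfce_params(connectivity = 6)),
               tfce_oracle(arr, conn = 6), tolerance = 1e-10)
  expect_true(all(tfce_enhance(array(0, c(4, 4, 4))) == 0))
  expect_true(all(tfce_enhance(array(-1, c(4, 4, 4))) == 0))
})

test_that("a plateau integrates to the analytic e^0.5 h^3 / 3 value", {
  arr <- array(0, c(12, 12, 12))
  arr[4:8, 4:8, 6] <- 2                       # extent 25, height 2
  out <- tfce_enhance(arr)
  analytic <- sqrt(25) * 2^3 / 3
  expect_lt(abs(out[6, 6, 6] - analytic) / analytic, 0.05)
})

test_that("TFCE is monotone for pointwise-dominating maps with a shared maximum", {
  set.seed(4)
  a <- array(abs(rnorm(6^3)), c(6, 6, 6))
  mx <- max(a)
  b <- pmin(a + 0.3 * abs(rnorm(6^3)), mx)    # b >= a, same maximum
  b <- array(pmax(a, b), dim(a))
  expect_true(all(tfce_enhance(b) - tfce_enhance(a) >= -1e-12))
})

test_that("permutation p-values equal exhaustive enumeration on a 6-sample design", {
  geom <- small_geometry(c(3L, 3L, 2L))
  V <- prod(geom$shape)
  n <- 6
  group <- c(1, 1, 1, 0, 0, 0)
  set.seed(5)
  Y <- matrix(rnorm(n * V), n, V)
  Y[group == 1, 1:4] <- Y[group == 1, 1:4] + 1.5
  X <- cbind(intercept = 1, group = group)

  # exact null: every distinct relabelling (choose(6,3) = 20) of the rows
  combs <- combn(6, 3)
  tfce_of <- function(perm) {
    Yp <- Y[perm, , drop = FALSE]
    g <- glm_tstat(Yp, X, c(0, 1))
    max(tfce_enhance(array(g$t, geom$shape)))
  }
  perm_of_comb <- function(cols) c(cols, setdiff(1:6, cols))
  all_max <- apply(combs, 2, function(cols) tfce_of(perm_of_comb(cols)))
  obs_tfce <- tfce_enhance(array(glm_tstat(Y, X, c(0, 1))$t, geom$shape))
  p_exact <- vapply(as.numeric(obs_tfce),
                    function(v) mean(all_max >= v), numeric(1))

  # implementation: the 19 non-identity relabellings as explicit permutations
  id_col <- which(apply(combs, 2, function(cl) all(cl == 1:3)))
  perms <- t(apply(combs[, -id_col], 2, perm_of_comb))
  pr <- permutation_fwe(Y, X, c(0, 1), geom, perms = perms)
  p_impl <- 1 - as.numeric(pr$one_minus_p$values)
  expect_equal(p_impl, p_exact, tolerance = 1e-12)
  expect_true(all(as.numeric(pr$one_minus_p$values) <=
                    pr$n_perm / (pr$n_perm + 1)))
})

test_that("Freedman-Lane leaves nuisance structure in place", {
  # with a strong nuisance covariate, permutation under the reduced model
  # must not destroy its fit: observed t for the tested column stays extreme
  # relative to the null only when a true effect exists
  geom <- small_geometry(c(4L, 4L, 2L))
  V <- prod(geom$shape)
  n <- 24
  set.seed(6)
  age <- rnorm(n)
  score <- rnorm(n)
  Y <- outer(age, rep(2, V)) + matrix(rnorm(n * V, sd = 0.5), n, V)
  Y[, 1:3] <- Y[, 1:3] + outer(score, rep(1.5, 3))
  X <- cbind(intercept = 1, score = score, age = age)
  pr <- permutation_fwe(Y, X, c(0, 1, 0), geom, n_perm = 99, seed = 9)
  sig <- threshold_significant(pr$one_minus_p, 0.95)
  expect_true(all(1:3 %in% sig$indices))
  expect_lt(length(sig), 6)
})

test_that("1-P thresholding is strict and checks the map kind", {
  geom <- small_geometry(c(2L, 2L, 2L))
  vals <- array(c(0.96, 0.95, 0.951, 0, 0.99, 0.98, 0.97, 0.1), geom$shape)
  m <- scalar_map(vals, geom, "one_minus_p")
  kept <- threshold_significant(m, 0.95)$indices
  expect_true(1 %in% kept)        # 0.96 > 0.95
  expect_false(2 %in% kept)       # 0.95 excluded, strict
  expect_true(3 %in% kept)
  expect_identical(threshold_significant(scalar_map(array(0, geom$shape),
                                                    geom, "one_minus_p"),
                                         0.95)$indices, integer(0))
  expect_error(threshold_significant(scalar_map(vals, geom, "weight"), 0.95),
               "one_minus_p")
})

test_that("dropping the aphasia-flag covariate is a pure design change", {
  sim <- fixture_cohort(n = 20, seed = 55)
  rec <- sim$records
  rec$inverted_score <- invert_score(rec$aphasia_score)
  X_full <- design_matrix(rec, c("inverted_score", "aphasia_flag", "age",
                                 "lesion_volume"))
  X_sens <- design_matrix(rec, c("inverted_score", "age", "lesion_volume"))
  expect_identical(colnames(X_sens),
                   setdiff(colnames(X_full), "aphasia_flag"))
  Y <- matrix(rnorm(20 * 6), 20, 6)
  t1 <- glm_tstat(Y, X_full, as.numeric(colnames(X_full) == "inverted_score"))
  t2 <- glm_tstat(Y, X_sens, as.numeric(colnames(X_sens) == "inverted_score"))
  expect_equal(t1$df, 20 - 5)
  expect_equal(t2$df, 20 - 4)
})
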