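# Nonparametric voxel-wise GLM inference: OLS t-statistics, threshold-free
# cluster enhancement, Freedman-Lane permutation with max-statistic
# family-wise error correction, and significance thresholding.

#' @useDynLib lesionet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Design matrix for voxel-wise GLM inference
#'
#' Builds an n x q numeric design with named columns from a clinical table,
#' prepending an intercept by default, and checks full column rank.
#'
#' @param records Data.frame of per-patient covariates.
#' @param columns Column names entering the design (in order). Logical
#'   columns are coerced to 0/1.
#' @param intercept Include an intercept column (default TRUE).
#' @return Numeric matrix with named columns.
#' @export
design_matrix <- function(records, columns, intercept = TRUE) {
  miss <- setdiff(columns, names(records))
  if (length(miss)) stop("missing design columns: ", paste(miss, collapse = ", "))
  X <- vapply(columns, function(cl) as.numeric(records[[cl]]),
              numeric(nrow(records)))
  X <- matrix(X, nrow = nrow(records),
              dimnames = list(NULL, columns))
  if (intercept) X <- cbind(intercept = 1, X)
  if (any(!is.finite(X))) stop("non-finite values in the design")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  X
}

#' Voxel-wise GLM t-statistics
#'
#' Per-voxel OLS fit of Y on X; the t-statistic for the contrast c is
#' \code{t = c'beta / sqrt(c'(X'X)^-1 c * sigma2)} with \code{n - q}
#' degrees of freedom.
#'
#' @param Y n x p matrix (rows = patients, columns = voxels).
#' @param X n x q design matrix of full column rank, n > q.
#' @param contrast Length-q contrast vector (nonzero).
#' @return List with \code{t} (length-p vector), \code{df}.
#' @export
glm_tstat <- function(Y, X, contrast) {
  n <- nrow(X); q <- ncol(X)
  if (nrow(Y) != n) stop("Y and X row mismatch")
  if (length(contrast) != q) stop("contrast length must match design columns")
  if (all(contrast == 0)) stop("contrast must be nonzero")
  if (n <= q) stop("need more observations than design columns")
  qrx <- qr(X)
  if (qrx$rank < q) stop("design matrix is rank deficient")
  beta <- qr.coef(qrx, Y)
  res <- Y - X %*% beta
  sigma2 <- colSums(res^2) / (n - q)
  xtxinv <- chol2inv(qr.R(qrx))
  cvar <- drop(t(contrast) %*% xtxinv %*% contrast)
  eff <- drop(crossprod(contrast, beta))
  se <- sqrt(cvar * sigma2)
  t <- ifelse(se > 0, eff / se, 0)
  list(t = t, df = n - q)
}

#' TFCE parameters
#'
#' Standard volumetric defaults: extent exponent E = 0.5, height exponent
#' H = 2, 26-neighbour connectivity, and a step of 1/100 of the map maximum.
#'
#' @param E,H Extent and height exponents (> 0).
#' @param n_steps Number of integration steps (dh = max / n_steps).
#' @param connectivity 6, 18 or 26.
#' @return An object of class \code{tfce_params}.
#' @export
tfce_params <- function(E = 0.5, H = 2, n_steps = 100L, connectivity = 26L) {
  stopifnot(E > 0, H > 0, n_steps >= 1, connectivity %in% c(6L, 18L, 26L))
  structure(list(E = E, H = H, n_steps = as.integer(n_steps),
                 connectivity = as.integer(connectivity)),
            class = "tfce_params")
}

#' Threshold-free cluster enhancement
#'
#' Integrates connected-component extent^E x height^H over suprathreshold
#' levels h = dh, 2dh, ..., max, boosting spatially coherent signal without
#' a fixed cluster-forming threshold. Negative values are ignored (each
#' contrast is enhanced on its positive side); an all-nonpositive map
#' returns all zeros.
#'
#' @param stat 3D numeric array (or \code{scalar_map}) of statistics.
#' @param params A \code{tfce_params}.
#' @return Enhanced values, same container type as the input.
#' @export
tfce_enhance <- function(stat, params = tfce_params()) {
  is_map <- inherits(stat, "scalar_map")
  arr <- if (is_map) stat$values else stat
  if (length(dim(arr)) != 3L) stop("TFCE needs a 3D array")
  if (any(!is.finite(arr))) stop("non-finite values in the statistic map")
  pos <- pmax(arr, 0)
  mx <- max(pos)
  out <- if (mx <= 0) array(0, dim(arr)) else {
    dh <- mx / params$n_steps
    array(.tfce_cpp(as.numeric(pos), as.integer(dim(arr)), params$E,
                    params$H, dh, params$connectivity, params$n_steps),
          dim(arr))
  }
  if (is_map) scalar_map(out, stat$geometry, "tfce", stat$analysis_mask)
  else out
}

#' Freedman-Lane permutation inference with TFCE and max-statistic FWE
#'
#' Tests one contrast of a voxel-wise GLM nonparametrically. The data are
#' regressed on the nuisance columns (those with zero contrast weight);
#' the reduced-model residuals are row-permuted, the nuisance fit added
#' back, and the full-model t-map and its TFCE enhancement recomputed for
#' each permutation. The maximum TFCE value over the volume forms the null
#' distribution, giving FWE-corrected p-values
#' \code{p(v) = (1 + #\{max_perm >= TFCE_obs(v)\}) / (1 + n_perm)},
#' reported as a 1-P map.
#'
#' @param Y n x V matrix over the full voxel grid (column-major order).
#' @param X Design matrix (see \code{\link{design_matrix}}).
#' @param contrast Length-q contrast; it must not touch only the intercept.
#' @param geometry The grid's \code{volume_geometry} (V = prod(shape)).
#' @param params A \code{tfce_params}.
#' @param n_perm Number of permutations (default 5000; phantom-scale runs
#'   use fewer).
#' @param seed Seed for the permutation draws.
#' @param perms Optional n_perm x n matrix of explicit row permutations
#'   (e.g. an exhaustive enumeration, excluding the identity); overrides
#'   random generation.
#' @return An object of class \code{permutation_result}: \code{tmap},
#'   \code{tfce_map}, \code{one_minus_p} (scalar_maps), \code{null_max}
#'   (length n_perm), \code{n_perm}, \code{df}, \code{seed}.
#' @export
permutation_fwe <- function(Y, X, contrast, geometry,
                            params = tfce_params(), n_perm = 5000L,
                            seed = 1L, perms = NULL) {
  V <- prod(geometry$shape)
  if (ncol(Y) != V) stop("Y columns must cover the full voxel grid")
  n <- nrow(Y)
  cn <- colnames(X)
  if (!is.null(cn) && all(which(contrast != 0) %in% which(cn == "intercept")))
    stop("contrast must involve a non-intercept column")
  if (!is.null(perms)) {
    perms <- as.matrix(perms)
    if (ncol(perms) != n) stop("perms must have n columns")
    n_perm <- nrow(perms)
  }
  if (n_perm < 1L) stop("n_perm must be >= 1")

  # precomputed pieces of the per-permutation t-statistic:
  # t = a'Y / sqrt(cvar * sigma2), sigma2 from the projection residual
  q <- ncol(X)
  qrx <- qr(X)
  if (qrx$rank < q) stop("design matrix is rank deficient")
  if (n <= q) stop("need more observations than design columns")
  if (all(contrast == 0)) stop("contrast must be nonzero")
  xtxinv <- chol2inv(qr.R(qrx))
  cvar <- drop(t(contrast) %*% xtxinv %*% contrast)
  a <- drop(X %*% xtxinv %*% contrast)
  Qx <- qr.Q(qrx)
  fast_t <- function(Ym) {
    s2 <- (colSums(Ym^2) - colSums(crossprod(Qx, Ym)^2)) / (n - q)
    se <- sqrt(cvar * s2)
    tt <- drop(crossprod(a, Ym)) / se
    tt[!is.finite(tt)] <- 0
    tt
  }
  obs <- list(t = fast_t(Y), df = n - q)
  tfce_obs <- tfce_enhance(array(obs$t, geometry$shape), params)

  nuis <- which(contrast == 0)
  if (length(nuis)) {
    Z <- X[, nuis, drop = FALSE]
    qz <- qr(Z)
    fit <- Z %*% qr.coef(qz, Y)
    R <- Y - fit
  } else {
    fit <- matrix(0, n, V)
    R <- Y
  }

  set.seed(seed)
  null_max <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    pi_b <- if (is.null(perms)) sample.int(n) else perms[b, ]
    Yb <- fit + R[pi_b, , drop = FALSE]
    null_max[b] <- max(tfce_enhance(array(fast_t(Yb), geometry$shape), params))
  }
  srt <- sort(null_max)
  cnt <- n_perm - findInterval(as.numeric(tfce_obs), srt, left.open = TRUE)
  one_minus_p <- 1 - (1 + cnt) / (1 + n_perm)

  structure(list(
    tmap = scalar_map(array(obs$t, geometry$shape), geometry, "t"),
    tfce_map = scalar_map(tfce_obs, geometry, "tfce"),
    one_minus_p = scalar_map(array(one_minus_p, geometry$shape), geometry,
                             "one_minus_p"),
    null_max = null_max, n_perm = n_perm, df = obs$df, seed = seed),
    class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %d permutations, max 1-P = %.4f\n",
              x$n_perm, max(x$one_minus_p$values)))
  invisible(x)
}

#' Threshold an FWE-corrected 1-P map
#'
#' Keeps voxels with 1-P strictly greater than the level (0.95 for
#' pFWE < 0.05; 0.98 extracts the strongest connections).
#'
#' @param map A \code{scalar_map} of kind \code{one_minus_p}.
#' @param level Significance level in (0, 1).
#' @return A \code{voxel_set} of significant voxels.
#' @export
threshold_significant <- function(map, level = 0.95) {
  if (!inherits(map, "scalar_map") || map$kind != "one_minus_p")
    stop("expected a scalar_map of kind 'one_minus_p'")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  voxel_set(which(map$values > level), map$geometry)
}
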