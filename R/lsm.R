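# Multivariate lesion-symptom mapping by sparse canonical correlation
# (single behavioural variable) with cross-validated sparseness selection.
#
# The sparseness parameter s in [-1, 1] follows the SCCAN sign convention:
# |s| is the fraction of analysis-mask voxels allowed a nonzero weight
# (realised as soft-thresholding the voxel-behaviour covariance at the
# corresponding quantile of its absolute values); s < 0 permits signed
# weights, s >= 0 restricts the component to its dominant sign.

#' Configuration for sparse-CCA lesion-symptom mapping
#'
#' @param sparseness_grid Candidate sparseness values in [-1, 1] (0 is
#'   degenerate and excluded by default).
#' @param n_folds Cross-validation folds (default 4, i.e. models built on
#'   75\% of the sample and evaluated on the held-out 25\%).
#' @param min_coverage Minimum lesion fraction for the analysis mask.
#' @param covariates Clinical columns regressed out of the behaviour score
#'   before fitting (default lesion volume).
#' @param max_iter,tol Iteration cap and convergence tolerance of the
#'   component solver.
#' @param seed Seed for the fold assignment.
#' @return An object of class \code{sccan_config}.
#' @export
sccan_config <- function(sparseness_grid = setdiff(seq(-0.9, 0.9, by = 0.1), 0),
                         n_folds = 4L, min_coverage = 0.10,
                         covariates = "lesion_volume",
                         max_iter = 50L, tol = 1e-8, seed = 1L) {
  stopifnot(length(sparseness_grid) >= 1L, n_folds >= 2L,
            all(abs(sparseness_grid) <= 1))
  structure(list(sparseness_grid = sparseness_grid,
                 n_folds = as.integer(n_folds), min_coverage = min_coverage,
                 covariates = covariates, max_iter = as.integer(max_iter),
                 tol = tol, seed = as.integer(seed)),
            class = "sccan_config")
}

.soft_threshold <- function(v, tau) sign(v) * pmax(abs(v) - tau, 0)

.sparse_project <- function(cv, s) {
  a <- abs(cv)
  tau <- if (abs(s) >= 1) 0 else stats::quantile(a, 1 - abs(s), names = FALSE)
  u <- .soft_threshold(cv, tau)
  if (s >= 0 && any(u != 0)) {
    # keep only the dominant sign
    pos <- sum(u[u > 0]^2)
    neg <- sum(u[u < 0]^2)
    u[if (pos >= neg) u < 0 else u > 0] <- 0
  }
  n2 <- sqrt(sum(u^2))
  if (n2 > 0) u / n2 else u
}

#' Sparse canonical component for one behavioural variable
#'
#' Finds the unit voxel-weight vector u maximising the correlation of the
#' lesion-pattern score X u with the behaviour y under the sparseness
#' budget, by iterating a projected power step (covariance step followed by
#' quantile soft-thresholding and renormalisation) until the weights
#' stabilise. Zero-variance columns get zero weight with a warning; if no
#' voxel survives the budget the zero vector is returned.
#'
#' @param X n x p lesion matrix with standardized columns.
#' @param y Length-n behaviour vector.
#' @param s Sparseness in [-1, 1] (see module header for the convention).
#' @param max_iter,tol Iteration control.
#' @return Unit-norm (or zero) weight vector of length p.
#' @export
sparse_cca_component <- function(X, y, s, max_iter = 50L, tol = 1e-8) {
  stopifnot(nrow(X) == length(y), nrow(X) >= 4L, ncol(X) >= 1L)
  yc <- y - mean(y)
  ss <- sqrt(sum(yc^2))
  if (ss == 0) return(numeric(ncol(X)))
  yn <- yc / ss
  sds <- sqrt(colSums(scale(X, scale = FALSE)^2))
  dead <- sds == 0
  if (any(dead)) warning(sum(dead), " zero-variance columns excluded")
  cv <- drop(crossprod(X, yn))
  cv[dead] <- 0
  if (all(cv == 0)) return(numeric(ncol(X)))
  u <- .sparse_project(cv, s)
  for (it in seq_len(max_iter)) {
    # power step against the rank-one cross-covariance X' yn yn' X
    g <- cv * drop(crossprod(cv, u))
    g[dead] <- 0
    u_new <- .sparse_project(g, s)
    if (sqrt(sum((u_new - u)^2)) < tol) { u <- u_new; break }
    u <- u_new
  }
  u
}

#' Cross-validated sparseness selection
#'
#' For each candidate sparseness, a component is fitted on the training
#' folds and used to predict the held-out behaviour scores; predictions are
#' pooled over folds and correlated with the observed scores. The
#' sparseness with the highest cross-validation correlation wins, ties
#' broken toward the sparser (smaller |s|) model. Fold assignment is
#' seeded, so the selection is deterministic.
#'
#' @param X n x p standardized lesion matrix.
#' @param y Behaviour vector (already residualized on covariates).
#' @param config An \code{sccan_config}.
#' @return List with \code{optimal_sparseness}, \code{cv_r} (at the
#'   optimum) and \code{table} (per-grid sparseness and CV r).
#' @export
optimize_sparseness <- function(X, y, config = sccan_config()) {
  n <- nrow(X)
  k <- config$n_folds
  if (n < 2L * k) stop("need at least 2 observations per fold")
  set.seed(config$seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  grid <- config$sparseness_grid
  cv_r <- vapply(grid, function(s)
    .cv_corr(X, y, s, fold, config$max_iter, config$tol), numeric(1))
  best <- order(-cv_r, abs(grid), grid)[1]
  list(optimal_sparseness = grid[best], cv_r = cv_r[best],
       table = data.frame(sparseness = grid, cv_r = cv_r))
}

# pooled out-of-fold prediction correlation for one sparseness value;
# fold-level constant columns are expected and silently given zero weight
.cv_corr <- function(X, y, s, fold, max_iter, tol) {
  pred <- numeric(length(y))
  for (f in unique(fold)) {
    tr <- fold != f
    u <- suppressWarnings(
      sparse_cca_component(X[tr, , drop = FALSE], y[tr], s, max_iter, tol))
    pred[!tr] <- X[!tr, , drop = FALSE] %*% u
  }
  if (stats::sd(pred) == 0) 0 else stats::cor(pred, y)
}

#' Run sparse-CCA lesion-symptom mapping on a cohort
#'
#' Pipeline: coverage filter on the lesion masks, standardized lesion
#' matrix, behaviour residualized on the nuisance covariates (lesion volume
#' by default), cross-validated sparseness selection, final component fit on
#' the full sample, and a 0-1 voxel weight map (absolute weights scaled so
#' the maximum is 1). The reported cross-validation correlation comes from
#' a nested cross-validation (sparseness re-selected within each outer
#' training fold), so the grid search cannot inflate it, and carries a
#' one-sided p-value from the t transform \code{r*sqrt(n-2)/sqrt(1-r^2)}.
#'
#' @param masks List of \code{lesion_mask} objects.
#' @param records An \code{aphasia_records} data.frame aligned with
#'   \code{masks} by patient_id.
#' @param score_column Behaviour column (default "aphasia_score"; any of the
#'   eight subdomain ordinals may be used).
#' @param config An \code{sccan_config}.
#' @return An object of class \code{lsm_result}: \code{weight_map}
#'   (scalar_map, kind "weight"), \code{optimal_sparseness},
#'   \code{cv_correlation}, \code{p_value}, \code{cv_table},
#'   \code{analysis_mask}, \code{n}, \code{peak}.
#' @export
run_sccan_lsm <- function(masks, records, score_column = "aphasia_score",
                          config = sccan_config()) {
  ids <- vapply(masks, function(m) m$patient_id, character(1))
  records <- records[match(ids, records$patient_id), , drop = FALSE]
  ok <- !is.na(records[[score_column]])
  if (sum(ok) < 10L) stop("need at least 10 patients with the score present")
  masks <- masks[ok]
  records <- records[ok, , drop = FALSE]
  n <- length(masks)

  vs <- coverage_filter(masks, config$min_coverage)
  if (length(vs) == 0L) stop("empty analysis mask after coverage filtering")
  geom <- masks[[1]]$geometry
  Xraw <- t(vapply(masks, function(m) as.numeric(m$voxels[vs$indices]),
                   numeric(length(vs))))
  keep <- apply(Xraw, 2, stats::sd) > 0
  if (!any(keep)) stop("no variable voxels in the analysis mask")
  X <- scale(Xraw[, keep, drop = FALSE])

  y <- as.numeric(records[[score_column]])
  covs <- intersect(config$covariates, names(records))
  if (length(covs)) {
    y <- stats::resid(stats::lm(y ~ ., data = records[, covs, drop = FALSE]))
  }

  opt <- optimize_sparseness(X, y, config)
  # the reported effect size comes from a nested cross-validation: the
  # sparseness is re-selected inside each outer training fold and the
  # untouched outer fold is predicted, so the grid search's winner's-curse
  # cannot inflate the correlation (or its p-value)
  set.seed(config$seed + 1L)
  fold_outer <- sample(rep(seq_len(config$n_folds), length.out = n))
  pred <- numeric(n)
  for (f in seq_len(config$n_folds)) {
    tr <- fold_outer != f
    cfg_in <- config
    cfg_in$seed <- config$seed + 10L + f
    opt_in <- suppressWarnings(
      optimize_sparseness(X[tr, , drop = FALSE], y[tr], cfg_in))
    u_in <- suppressWarnings(
      sparse_cca_component(X[tr, , drop = FALSE], y[tr],
                           opt_in$optimal_sparseness,
                           config$max_iter, config$tol))
    pred[!tr] <- X[!tr, , drop = FALSE] %*% u_in
  }
  cv_r_eval <- if (stats::sd(pred) == 0) 0 else stats::cor(pred, y)
  u <- sparse_cca_component(X, y, opt$optimal_sparseness,
                            config$max_iter, config$tol)
  w_kept <- abs(u)
  if (max(w_kept) > 0) w_kept <- w_kept / max(w_kept)
  w_full <- array(0, geom$shape)
  w_full[vs$indices[keep]] <- w_kept
  wmap <- scalar_map(w_full, geom, "weight", analysis_mask = vs)

  r <- cv_r_eval
  tstat <- r * sqrt(n - 2) / sqrt(max(1 - r^2, .Machine$double.eps))
  p <- stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  support <- voxel_set(vs$indices[keep][w_kept > 0], geom)
  peak <- if (length(support)) peak_and_center(wmap, support) else NULL

  structure(list(weight_map = wmap, optimal_sparseness = opt$optimal_sparseness,
                 cv_correlation = r, p_value = p, cv_table = opt$table,
                 analysis_mask = vs, support = support, n = n, peak = peak),
            class = "lsm_result")
}

#' @export
print.lsm_result <- function(x, ...) {
  cat(sprintf(paste0("<lsm_result> n=%d, optimal sparseness %.3f, ",
                     "CV r = %.3f (one-sided p = %.3g), %d voxels selected\n"),
              x$n, x$optimal_sparseness, x$cv_correlation, x$p_value,
              length(x$support)))
  invisible(x)
}

#' Dice coefficient between two voxel sets
#' @param a,b \code{voxel_set}s (or logical arrays) on the same grid.
#' @return 2|A n B| / (|A| + |B|).
#' @export
dice_coefficient <- function(a, b) {
  ia <- if (inherits(a, "voxel_set")) a$indices else which(a)
  ib <- if (inherits(b, "voxel_set")) b$indices else which(b)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}
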