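# Lesion network mapping: connectivity profiles from lesion seeds against a
# normative connectome, voxel-wise correlation maps with BH-FDR control, and
# similarity-based score prediction (leave-one-out and split-half).

Z_CLIP <- 0.999999

#' Connectivity profile of a lesion against a normative connectome
#'
#' Per connectome subject, the mean BOLD-like series over the lesion voxels
#' is correlated with every voxel's series; correlations are clipped to
#' +/- 0.999999, Fisher-z transformed (atanh) per subject, and averaged
#' across subjects. Subjects with a zero-variance seed series are skipped
#' with a warning (an error if none remain). Voxels whose own series is
#' constant get z = 0.
#'
#' @param mask A \code{lesion_mask}.
#' @param connectome A \code{connectome} sharing the mask's geometry.
#' @return An object of class \code{connectivity_profile}: \code{patient_id},
#'   \code{zmap} (scalar_map, kind "z"), \code{n_connectome_subjects}.
#' @export
lesion_connectivity_profile <- function(mask, connectome) {
  .check_geometry(mask$geometry, connectome$geometry, mask$patient_id)
  idx <- which(mask$voxels)
  zsum <- 0
  used <- 0L
  for (ts in connectome$subjects) {
    seed <- rowMeans(ts[, idx, drop = FALSE])
    if (stats::sd(seed) == 0) {
      warning("zero-variance seed series for ", mask$patient_id,
              "; connectome subject skipped")
      next
    }
    sc <- seed - mean(seed)
    num <- drop(crossprod(ts, sc))
    den <- sqrt(colSums(ts^2) - nrow(ts) * colMeans(ts)^2) * sqrt(sum(sc^2))
    r <- ifelse(den > 0, num / den, 0)
    zsum <- zsum + atanh(pmin(pmax(r, -Z_CLIP), Z_CLIP))
    used <- used + 1L
  }
  if (used == 0L) stop("all connectome subjects skipped for ", mask$patient_id)
  structure(list(patient_id = mask$patient_id,
                 zmap = scalar_map(zsum / used, mask$geometry, "z"),
                 n_connectome_subjects = used),
            class = "connectivity_profile")
}

#' Connectivity profiles for a whole cohort
#'
#' Equivalent to mapping \code{\link{lesion_connectivity_profile}} over the
#' masks, but computed one connectome subject at a time with all seeds
#' batched, which avoids recomputing per-voxel moments per patient.
#'
#' @param masks List of \code{lesion_mask}s.
#' @param connectome A \code{connectome}.
#' @return List of \code{connectivity_profile}s.
#' @export
cohort_profiles <- function(masks, connectome) {
  geom <- connectome$geometry
  for (m in masks) .check_geometry(m$geometry, geom, m$patient_id)
  n <- length(masks)
  V <- ncol(connectome$subjects[[1]])
  zsum <- matrix(0, V, n)
  used <- integer(n)
  for (ts in connectome$subjects) {
    Tn <- nrow(ts)
    den_v <- sqrt(colSums(ts^2) - Tn * colMeans(ts)^2)
    seeds <- vapply(masks,
                    function(m) rowMeans(ts[, which(m$voxels), drop = FALSE]),
                    numeric(Tn))
    sc <- sweep(seeds, 2, colMeans(seeds))
    sn <- sqrt(colSums(sc^2))
    ok <- sn > 0
    if (!all(ok))
      warning("zero-variance seed series; connectome subject skipped for ",
              sum(!ok), " patient(s)")
    if (!any(ok)) next
    num <- crossprod(ts, sc[, ok, drop = FALSE])
    r <- num / outer(den_v, sn[ok])
    r[!is.finite(r)] <- 0
    zsum[, ok] <- zsum[, ok] + atanh(pmin(pmax(r, -Z_CLIP), Z_CLIP))
    used[ok] <- used[ok] + 1L
  }
  if (any(used == 0L)) stop("all connectome subjects skipped for some patients")
  lapply(seq_len(n), function(i) {
    structure(list(patient_id = masks[[i]]$patient_id,
                   zmap = scalar_map(zsum[, i] / used[i], geom, "z"),
                   n_connectome_subjects = used[i]),
              class = "connectivity_profile")
  })
}

.profile_matrix <- function(profiles, idx = NULL) {
  v <- if (is.null(idx)) length(profiles[[1]]$zmap$values) else length(idx)
  t(vapply(profiles, function(p) {
    x <- p$zmap$values
    if (is.null(idx)) as.numeric(x) else x[idx]
  }, numeric(v)))
}

# Voxel-wise Pearson correlation of the columns of P (n x V) with y.
# Constant columns get r = 0.
.vox_cor <- function(P, y) {
  n <- nrow(P)
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2))
  Pc <- sweep(P, 2, colMeans(P))
  sx <- sqrt(colSums(Pc^2))
  r <- drop(crossprod(Pc, yc)) / (sx * sy)
  r[sx == 0] <- 0
  pmin(pmax(r, -1), 1)
}

.cor_pvalue <- function(r, n, two_sided = TRUE) {
  t <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  if (two_sided) 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE)
  else stats::pt(t, n - 2, lower.tail = FALSE)
}

#' Voxel-wise correlation map of connectivity profiles against behaviour
#'
#' Pearson correlation per voxel between the cohort's connectivity profiles
#' and the (inverted, higher = worse) behaviour scores, with two-sided
#' p-values from the t transform and Benjamini-Hochberg FDR control across
#' the analysis mask. The signed thresholds are the smallest |r| declared
#' significant in each direction.
#'
#' @param profiles List of \code{connectivity_profile}s.
#' @param scores_inverted Inverted behaviour scores, aligned with profiles.
#' @param fdr_alpha FDR level (default 0.05).
#' @param analysis_mask Optional \code{voxel_set}; default whole grid.
#' @return An object of class \code{correlation_map_result}: \code{rmap},
#'   \code{pmap}, \code{fdr_alpha}, \code{threshold_neg},
#'   \code{threshold_pos}, \code{significant_pos}, \code{significant_neg}.
#' @export
correlation_map <- function(profiles, scores_inverted, fdr_alpha = 0.05,
                            analysis_mask = NULL) {
  n <- length(profiles)
  if (n < 4L) stop("need at least 4 patients")
  if (length(scores_inverted) != n) stop("scores misaligned with profiles")
  if (stats::sd(scores_inverted) == 0) stop("constant behaviour scores")
  geom <- profiles[[1]]$zmap$geometry
  idx <- if (is.null(analysis_mask)) seq_len(prod(geom$shape))
         else analysis_mask$indices
  P <- .profile_matrix(profiles, idx)
  r <- .vox_cor(P, scores_inverted)
  p <- .cor_pvalue(r, n)
  p[r == 0 & apply(P, 2, stats::sd) == 0] <- 1
  padj <- stats::p.adjust(p, method = "BH")
  sig <- padj <= fdr_alpha
  rfull <- array(0, geom$shape); rfull[idx] <- r
  pfull <- array(1, geom$shape); pfull[idx] <- p
  thr_pos <- if (any(sig & r > 0)) min(r[sig & r > 0]) else NA_real_
  thr_neg <- if (any(sig & r < 0)) max(r[sig & r < 0]) else NA_real_
  structure(list(
    rmap = scalar_map(rfull, geom, "r"),
    pmap = scalar_map(pfull, geom, "p"),
    fdr_alpha = fdr_alpha,
    threshold_pos = thr_pos, threshold_neg = thr_neg,
    significant_pos = voxel_set(idx[sig & r > 0], geom),
    significant_neg = voxel_set(idx[sig & r < 0], geom),
    n = n), class = "correlation_map_result")
}

#' Spatial similarity of two maps
#'
#' Pearson correlation over the voxels of the analysis mask; the standard
#' similarity used both for score prediction and for map decoding.
#'
#' @param a,b \code{scalar_map}s (or plain arrays) on the same grid.
#' @param mask Optional \code{voxel_set} (>= 3 voxels).
#' @return Pearson r.
#' @export
spatial_similarity <- function(a, b, mask = NULL) {
  va <- if (inherits(a, "scalar_map")) a$values else a
  vb <- if (inherits(b, "scalar_map")) b$values else b
  idx <- if (!is.null(mask)) mask$indices else seq_along(va)
  if (length(idx) < 3L) stop("need at least 3 voxels")
  x <- va[idx]; y <- vb[idx]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant map on the analysis mask")
  stats::cor(x, y)
}

#' Leave-one-out similarity prediction of behaviour
#'
#' For each patient, the unthresholded voxel-wise correlation map is rebuilt
#' from the other n-1 patients and the held-out profile's spatial similarity
#' to that map is the predicted severity. The result correlates predictions
#' with the observed (inverted) scores; the p-value is one-sided (the
#' directional hypothesis that similarity predicts severity), with the
#' two-sided value also reported.
#'
#' @inheritParams correlation_map
#' @return An object of class \code{validation_result} with \code{mode =
#'   "loocv"}, \code{r}, \code{p}, \code{p_two_sided} and the per-patient
#'   \code{pairs} (predicted similarity, observed score).
#' @export
loocv_predict <- function(profiles, scores_inverted, analysis_mask = NULL) {
  n <- length(profiles)
  if (n < 5L) stop("need at least 5 patients for leave-one-out")
  geom <- profiles[[1]]$zmap$geometry
  idx <- if (is.null(analysis_mask)) seq_len(prod(geom$shape))
         else analysis_mask$indices
  P <- .profile_matrix(profiles, idx)
  sim <- vapply(seq_len(n), function(i) {
    rmap <- .vox_cor(P[-i, , drop = FALSE], scores_inverted[-i])
    if (stats::sd(rmap) == 0 || stats::sd(P[i, ]) == 0) return(0)
    stats::cor(P[i, ], rmap)
  }, numeric(1))
  r <- stats::cor(sim, scores_inverted)
  structure(list(mode = "loocv", train_ids = NULL, test_ids = NULL,
                 r = r, p = .cor_pvalue(r, n, two_sided = FALSE),
                 p_two_sided = .cor_pvalue(r, n),
                 pairs = data.frame(
                   patient_id = vapply(profiles, `[[`, character(1), "patient_id"),
                   predicted = sim, observed = scores_inverted)),
            class = "validation_result")
}

#' Split-half similarity validation
#'
#' The cohort is split at random (seeded) into a training fraction (size
#' \code{floor(train_frac * n)}) and a held-out test set. The training
#' cohort's correlation map (with its own leave-one-out report) predicts
#' each test patient's severity by spatial similarity; the result
#' correlates those predictions with the observed test scores.
#'
#' @inheritParams correlation_map
#' @param train_frac Training fraction in (0, 1), default 0.7.
#' @param seed Seed for the random split.
#' @return A \code{validation_result} with \code{mode = "split"},
#'   \code{train_ids}, \code{test_ids}, \code{r}, \code{p},
#'   \code{train_loocv} (the training cohort's LOOCV result) and
#'   \code{pairs}.
#' @export
split_validate <- function(profiles, scores_inverted, train_frac = 0.7,
                           seed = 1L, analysis_mask = NULL) {
  n <- length(profiles)
  if (n < 10L) stop("need at least 10 patients for a split validation")
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)")
  set.seed(seed)
  n_train <- floor(train_frac * n)
  tr <- sort(sample.int(n, n_train))
  te <- setdiff(seq_len(n), tr)
  if (length(tr) < 3L || length(te) < 3L) stop("degenerate split sizes")
  geom <- profiles[[1]]$zmap$geometry
  idx <- if (is.null(analysis_mask)) seq_len(prod(geom$shape))
         else analysis_mask$indices
  P <- .profile_matrix(profiles, idx)
  train_map <- .vox_cor(P[tr, , drop = FALSE], scores_inverted[tr])
  train_loocv <- loocv_predict(profiles[tr], scores_inverted[tr], analysis_mask)
  pred <- vapply(te, function(i) stats::cor(P[i, ], train_map), numeric(1))
  r <- stats::cor(pred, scores_inverted[te])
  ids <- vapply(profiles, `[[`, character(1), "patient_id")
  structure(list(mode = "split", train_ids = ids[tr], test_ids = ids[te],
                 r = r, p = .cor_pvalue(r, length(te), two_sided = FALSE),
                 p_two_sided = .cor_pvalue(r, length(te)),
                 train_loocv = train_loocv,
                 pairs = data.frame(patient_id = ids[te], predicted = pred,
                                    observed = scores_inverted[te])),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("<validation_result> %s: r = %.3f, one-sided p = %.3g\n",
              x$mode, x$r, x$p))
  invisible(x)
}
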