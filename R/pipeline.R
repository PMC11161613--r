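# Study orchestration: simulate (or load) inputs, then run LSM, the LNM
# correlation/validation stages, and permutation inference as one seeded,
# reproducible pipeline with a machine-readable report.

#' Study configuration
#'
#' One global seed is fanned out to named per-stage substreams (fixed
#' offsets), so any stage can be rerun in isolation and reproduce the full
#' run's result bit-for-bit.
#'
#' @param seed Global integer seed.
#' @param stages Character vector of enabled stages, a subset of
#'   \code{c("lsm", "corrmap", "loocv", "split", "permute", "report")}.
#' @param paths Optional named list of input paths (\code{manifest},
#'   \code{clinical}, \code{connectome}, \code{atlas}, \code{atlas_labels});
#'   when NULL the phantom study is simulated in memory.
#' @param phantom,connectome,cohort Synthetic specs used when no paths are
#'   given.
#' @param lsm An \code{sccan_config}.
#' @param score_column Behaviour column for LSM.
#' @param fdr_alpha FDR level for the correlation map.
#' @param train_frac Split-validation training fraction.
#' @param permute_covariates Covariate columns of the permutation design
#'   (default presence of aphasia, age, lesion size; dropping
#'   \code{"aphasia_flag"} here is the sensitivity variant).
#' @param n_perm Permutations for the FWE stage.
#' @param tfce A \code{tfce_params}.
#' @param sig_levels 1-P thresholds reported by the permutation stage.
#' @param out Optional output directory; when given, stage outputs (NIfTI
#'   maps, TSVs, report JSON) are written there.
#' @return An object of class \code{study_config}.
#' @export
study_config <- function(seed = 1L,
                         stages = c("lsm", "corrmap", "loocv", "split",
                                    "permute", "report"),
                         paths = NULL,
                         phantom = default_phantom_spec(),
                         connectome = connectome_spec(),
                         cohort = cohort_spec(),
                         lsm = sccan_config(),
                         score_column = "aphasia_score",
                         fdr_alpha = 0.05, train_frac = 0.7,
                         permute_covariates = c("aphasia_flag", "age",
                                                "lesion_volume"),
                         n_perm = 200L, tfce = tfce_params(),
                         sig_levels = c(0.95, 0.98), out = NULL) {
  structure(list(seed = as.integer(seed), stages = stages, paths = paths,
                 phantom = phantom, connectome = connectome, cohort = cohort,
                 lsm = lsm, score_column = score_column,
                 fdr_alpha = fdr_alpha, train_frac = train_frac,
                 permute_covariates = permute_covariates,
                 n_perm = as.integer(n_perm), tfce = tfce,
                 sig_levels = sig_levels, out = out),
            class = "study_config")
}

# fixed per-stage substream offsets off the global seed
.stage_seed <- function(seed, stage) {
  off <- c(phantom = 0L, connectome = 101L, cohort = 211L, lsm = 307L,
           split = 401L, permute = 503L)
  (seed + off[[stage]]) %% .Machine$integer.max
}

.load_inputs <- function(config) {
  p <- config$paths
  if (is.null(p)) {
    config$phantom$seed <- .stage_seed(config$seed, "phantom")
    config$connectome$seed <- .stage_seed(config$seed, "connectome")
    config$cohort$seed <- .stage_seed(config$seed, "cohort")
    atlas <- make_phantom_atlas(config$phantom)
    conn <- simulate_connectome(atlas, config$connectome)
    sim <- simulate_lesion_cohort(atlas, config$cohort)
    list(atlas = atlas, connectome = conn, masks = sim$masks,
         records = sim$records,
         planted = voxel_set(atlas_region_indices(atlas,
                                                  config$phantom$critical_label),
                             atlas$geometry))
  } else {
    for (nm in c("manifest", "clinical", "connectome")) {
      if (is.null(p[[nm]]) || !file.exists(p[[nm]]))
        stop(sprintf("missing input '%s': %s", nm,
                     if (is.null(p[[nm]])) "(not set)" else p[[nm]]))
    }
    masks <- read_cohort(p$manifest)
    geom <- masks[[1]]$geometry
    atlas <- if (!is.null(p$atlas))
      read_atlas(p$atlas, p$atlas_labels, geom) else NULL
    list(atlas = atlas, connectome = read_connectome(p$connectome, geom),
         masks = masks, records = read_clinical(p$clinical), planted = NULL)
  }
}

#' Run a configured study end to end
#'
#' Executes the enabled stages in order (LSM, correlation map, LOOCV, split
#' validation, permutation FWE) and returns a report; identical config and
#' seed give an identical report. Patients without an aphasia score are
#' excluded from score-based stages.
#'
#' @param config A \code{study_config}.
#' @return A list of class \code{study_report} with one element per stage
#'   plus \code{inputs} (cohort bookkeeping). If \code{config$out} is set,
#'   maps and a \code{report.json} are written there.
#' @export
run_study <- function(config = study_config()) {
  inp <- .load_inputs(config)
  masks <- inp$masks
  records <- inp$records
  report <- list(seed = config$seed,
                 inputs = list(n_patients = length(masks),
                               n_scored = sum(!is.na(records$aphasia_score)),
                               n_connectome = length(inp$connectome$subjects)))
  out <- config$out
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)

  scored <- !is.na(records$aphasia_score)
  masks_s <- masks[scored]
  rec_s <- records[scored, , drop = FALSE]
  y_inv <- invert_score(rec_s$aphasia_score)

  lsm_res <- NULL
  if ("lsm" %in% config$stages) {
    cfg <- config$lsm
    cfg$seed <- .stage_seed(config$seed, "lsm")
    lsm_res <- run_sccan_lsm(masks, records, config$score_column, cfg)
    report$lsm <- list(optimal_sparseness = lsm_res$optimal_sparseness,
                       cv_r = lsm_res$cv_correlation, p = lsm_res$p_value,
                       n = lsm_res$n, n_selected = length(lsm_res$support),
                       peak_world = unname(lsm_res$peak$peak_world))
    if (!is.null(inp$planted))
      report$lsm$dice_vs_planted <- dice_coefficient(lsm_res$support,
                                                     inp$planted)
    if (!is.null(inp$atlas)) {
      ovl <- atlas_overlap(lsm_res$weight_map, inp$atlas)
      report$lsm$top_label <- ovl$label[1]
    }
    if (!is.null(out)) write_volume(lsm_res$weight_map,
                                    file.path(out, "lsm_weight_map.nii.gz"))
  }

  profiles <- NULL
  need_profiles <- any(c("corrmap", "loocv", "split", "permute") %in%
                         config$stages)
  if (need_profiles) profiles <- cohort_profiles(masks_s, inp$connectome)

  if ("corrmap" %in% config$stages) {
    cm <- correlation_map(profiles, y_inv, config$fdr_alpha)
    report$corrmap <- list(
      r_range = range(cm$rmap$values),
      threshold_neg = cm$threshold_neg, threshold_pos = cm$threshold_pos,
      n_sig_pos = length(cm$significant_pos),
      n_sig_neg = length(cm$significant_neg))
    if (!is.null(out)) write_volume(cm$rmap, file.path(out, "corr_rmap.nii.gz"))
  }

  if ("loocv" %in% config$stages) {
    lo <- loocv_predict(profiles, y_inv)
    report$loocv <- list(r = lo$r, p = lo$p)
  }

  if ("split" %in% config$stages) {
    sp <- split_validate(profiles, y_inv, config$train_frac,
                         seed = .stage_seed(config$seed, "split"))
    report$split <- list(n_train = length(sp$train_ids),
                         n_test = length(sp$test_ids), r = sp$r, p = sp$p,
                         train_loocv_r = sp$train_loocv$r)
  }

  if ("permute" %in% config$stages) {
    geom <- masks[[1]]$geometry
    P <- .profile_matrix(profiles)
    covs <- intersect(config$permute_covariates, names(rec_s))
    const <- vapply(covs, function(cl)
      stats::var(as.numeric(rec_s[[cl]])) == 0, logical(1))
    if (any(const)) {
      warning("dropping constant covariate(s) from the permutation design: ",
              paste(covs[const], collapse = ", "))
      covs <- covs[!const]
    }
    rec_s$inverted_score <- y_inv
    X <- design_matrix(rec_s, c("inverted_score", covs))
    cvec <- as.numeric(colnames(X) == "inverted_score")
    pr <- permutation_fwe(P, X, cvec, geom, config$tfce, config$n_perm,
                          seed = .stage_seed(config$seed, "permute"))
    sig <- lapply(config$sig_levels, function(l)
      length(threshold_significant(pr$one_minus_p, l)))
    report$permute <- list(
      n_perm = pr$n_perm, covariates = covs,
      max_one_minus_p = max(pr$one_minus_p$values),
      n_significant = stats::setNames(sig, paste0("level_",
                                                  config$sig_levels)))
    if (!is.null(out)) {
      write_volume(pr$one_minus_p, file.path(out, "perm_one_minus_p.nii.gz"))
      write_volume(pr$tmap, file.path(out, "perm_tmap.nii.gz"))
    }
  }

  if (!is.null(out)) {
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(report, class = "study_report")
}

#' Read a study configuration from JSON
#'
#' Only the scalar fields of \code{\link{study_config}} plus the synthetic
#' spec fields can be set from JSON; unspecified fields keep their defaults.
#'
#' @param path JSON path.
#' @return A \code{study_config}.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- study_config()
  for (nm in intersect(names(j), c("seed", "stages", "score_column",
                                   "fdr_alpha", "train_frac",
                                   "permute_covariates", "n_perm",
                                   "sig_levels", "out"))) {
    cfg[[nm]] <- j[[nm]]
  }
  if (!is.null(j$paths)) cfg$paths <- as.list(j$paths)
  for (blk in c("cohort", "connectome")) {
    if (!is.null(j[[blk]]))
      for (nm in intersect(names(j[[blk]]), names(cfg[[blk]])))
        cfg[[blk]][[nm]] <- j[[blk]][[nm]]
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_perm <- as.integer(cfg$n_perm)
  cfg
}
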