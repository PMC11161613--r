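# Synthetic phantom study: a label atlas standing in for thalamic-nuclei /
# cortical anatomy, a toy normative connectome with planted latent networks,
# and a lesion cohort with a planted lesion-behaviour effect. Everything is
# seeded and bit-reproducible so every downstream stage is testable without
# patient data.

#' Phantom atlas specification
#'
#' Defines a small MNI-like grid and a set of disjoint labelled regions from
#' box/sphere primitives. One region plays the "critical nucleus" whose
#' lesion load drives the simulated aphasia score (a VLpv-like target); one
#' or more cortical patches play the remote language network (Broca-like).
#'
#' @param shape Grid dimensions (default 24^3 at 2 mm isotropic).
#' @param voxel_mm Isotropic voxel size in mm.
#' @param regions Named list; each element is
#'   \code{list(shape = "box"|"sphere", center = c(i,j,k), size = <scalar>)},
#'   with one-based voxel centers. For boxes \code{size} is the (odd) edge
#'   length in voxels; for spheres the radius in voxels.
#' @param critical_label Name of the critical nucleus region.
#' @param network_regions Names of the planted network's cortical regions.
#' @param seed Integer seed recorded on the spec.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape = c(24L, 24L, 24L), voxel_mm = 2,
                         regions, critical_label, network_regions,
                         seed = 1L) {
  stopifnot(length(shape) == 3L, voxel_mm > 0, length(regions) >= 1L)
  if (is.null(names(regions)) || any(names(regions) == ""))
    stop("regions must be a named list")
  if (!critical_label %in% names(regions))
    stop("critical_label not among regions")
  if (!all(network_regions %in% names(regions)))
    stop("network_regions not among regions")
  structure(list(shape = as.integer(shape), voxel_mm = voxel_mm,
                 regions = regions, critical_label = critical_label,
                 network_regions = network_regions, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default phantom: left thalamus with a critical nucleus and a remote
#' frontal language network
#'
#' The critical nucleus \code{vlpv_left} (3^3 box) sits inside a larger left
#' "thalamic" placement shell; \code{thalamus_right} mirrors it. Two left
#' cortical patches (\code{broca}, \code{frontal_left}) form the planted
#' network coupled to the critical nucleus in the synthetic connectome.
#'
#' @param seed Seed recorded on the spec.
#' @return A \code{phantom_spec}.
#' @export
default_phantom_spec <- function(seed = 1L) {
  phantom_spec(
    shape = c(24L, 24L, 24L), voxel_mm = 2,
    regions = list(
      vlpv_left      = list(shape = "box", center = c(8, 12, 11), size = 3),
      thalamus_left  = list(shape = "box", center = c(8, 15, 11), size = c(5, 3, 5)),
      thalamus_right = list(shape = "box", center = c(17, 12, 11), size = 5),
      broca          = list(shape = "box", center = c(5, 19, 15), size = 3),
      frontal_left   = list(shape = "box", center = c(5, 15, 18), size = 3)
    ),
    critical_label = "vlpv_left",
    network_regions = c("broca", "frontal_left"),
    seed = seed
  )
}

.phantom_geometry <- function(spec) {
  # world = voxel_mm * ijk0 - offset, centering the grid near the origin so
  # a left/right (negative/positive x) convention holds like in MNI space
  aff <- diag(c(rep(spec$voxel_mm, 3), 1))
  aff[1:3, 4] <- -spec$voxel_mm * (spec$shape - 1) / 2
  volume_geometry(spec$shape, aff, "phantom")
}

.region_voxels <- function(region, shape) {
  ctr <- region$center
  if (region$shape == "box") {
    size <- rep(region$size, length.out = 3)
    if (any(size %% 2 != 1)) stop("box sizes must be odd")
    half <- (size - 1) / 2
    rng <- lapply(1:3, function(a) {
      v <- seq(ctr[a] - half[a], ctr[a] + half[a])
      if (any(v < 1 | v > shape[a])) stop("region extends outside the grid")
      v
    })
    as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  } else if (region$shape == "sphere") {
    r <- region$size
    rng <- lapply(1:3, function(a) seq(max(1, floor(ctr[a] - r)),
                                       min(shape[a], ceiling(ctr[a] + r))))
    g <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
    keep <- colSums((t(g) - ctr)^2) <= r^2
    if (floor(ctr[1] - r) < 1 || ceiling(ctr[1] + r) > shape[1] ||
        floor(ctr[2] - r) < 1 || ceiling(ctr[2] + r) > shape[2] ||
        floor(ctr[3] - r) < 1 || ceiling(ctr[3] + r) > shape[3])
      stop("region extends outside the grid")
    g[keep, , drop = FALSE]
  } else stop("unknown region shape: ", region$shape)
}

#' Build the phantom label atlas
#'
#' Regions are rasterized in spec order with labels 1..K; overlap between
#' regions is an error. The construction is fully deterministic.
#'
#' @param spec A \code{phantom_spec}.
#' @return An \code{\link{atlas_volume}} with a label table
#'   \code{(id, name)}.
#' @export
make_phantom_atlas <- function(spec) {
  geom <- .phantom_geometry(spec)
  labels <- array(0L, spec$shape)
  tab <- data.frame(id = seq_along(spec$regions), name = names(spec$regions),
                    stringsAsFactors = FALSE)
  for (k in seq_along(spec$regions)) {
    vx <- .region_voxels(spec$regions[[k]], spec$shape)
    lin <- vx[, 1] + (vx[, 2] - 1) * spec$shape[1] +
      (vx[, 3] - 1) * prod(spec$shape[1:2])
    if (any(labels[lin] != 0L))
      stop("regions overlap: ", names(spec$regions)[k])
    labels[lin] <- k
  }
  atlas_volume(labels, geom, tab)
}

#' Linear voxel indices of an atlas region
#' @param atlas An \code{atlas_volume}.
#' @param label Region name (or id).
#' @return Sorted linear indices.
#' @export
atlas_region_indices <- function(atlas, label) {
  id <- if (is.character(label)) {
    hit <- match(label, atlas$labels_table$name)
    if (is.na(hit)) stop("unknown region label: ", label)
    atlas$labels_table$id[hit]
  } else label
  which(atlas$labels == id)
}

#' Connectome simulation specification
#'
#' Per-subject BOLD-like series follow a latent-factor model: each voxel's
#' series is the sum over latent components of (region loading x latent
#' signal) plus i.i.d. Gaussian noise. Two voxels whose regions share a
#' latent with loadings l1, l2 then have expected Pearson correlation
#' \code{l1*l2 / sqrt((l1^2+s^2)(l2^2+s^2))}; background voxels carry pure
#' noise.
#'
#' @param n_subjects Number of connectome subjects (>= 1).
#' @param n_timepoints Series length (>= 8).
#' @param latent_loadings Named list, one element per latent component; each
#'   a named numeric vector of region loadings
#'   (e.g. \code{list(lang = c(vlpv_left = 0.9, broca = 0.9))}).
#' @param noise_sd Noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return An object of class \code{connectome_spec}.
#' @export
connectome_spec <- function(n_subjects = 8L, n_timepoints = 100L,
                            latent_loadings = list(
                              lang = c(vlpv_left = 0.9, broca = 0.9,
                                       frontal_left = 0.7),
                              contra = c(thalamus_right = 0.8)),
                            noise_sd = 1, seed = 1L) {
  stopifnot(n_subjects >= 1L, n_timepoints >= 8L, noise_sd >= 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_timepoints = as.integer(n_timepoints),
                 latent_loadings = latent_loadings, noise_sd = noise_sd,
                 seed = as.integer(seed)), class = "connectome_spec")
}

#' Simulate a multi-subject normative connectome
#'
#' @param atlas The phantom \code{atlas_volume}.
#' @param spec A \code{connectome_spec}; every region named in the loadings
#'   must exist in the atlas.
#' @return An object of class \code{connectome}: a list with
#'   \code{subjects} (each a timepoints x voxels matrix over the full grid,
#'   column-major voxel order) and \code{geometry}.
#' @export
simulate_connectome <- function(atlas, spec) {
  for (comp in spec$latent_loadings)
    for (nm in names(comp)) atlas_region_indices(atlas, nm)  # validates
  V <- prod(atlas$geometry$shape)
  set.seed(spec$seed)
  subjects <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    ts <- matrix(stats::rnorm(spec$n_timepoints * V, sd = spec$noise_sd),
                 spec$n_timepoints, V)
    for (comp in spec$latent_loadings) {
      sig <- stats::rnorm(spec$n_timepoints)
      for (nm in names(comp)) {
        idx <- atlas_region_indices(atlas, nm)
        ts[, idx] <- ts[, idx] + sig * comp[[nm]]
      }
    }
    subjects[[s]] <- ts
  }
  structure(list(subjects = subjects, geometry = atlas$geometry,
                 n_timepoints = spec$n_timepoints), class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %d subjects x %d timepoints, %d voxels\n",
              length(x$subjects), x$n_timepoints, ncol(x$subjects[[1]])))
  invisible(x)
}

#' Lesion cohort specification
#'
#' Spherical lesions are placed uniformly inside the thalamic placement
#' regions (side drawn per patient). For left-sided lesions the simulated
#' ACL aphasia score decreases with the lesion's fractional overlap of the
#' critical nucleus:
#' \code{score = round(clamp(148 * (1 - beta * overlap) + noise, 0, 148))}
#' (round half to even); right-sided lesions carry no effect. Subdomain
#' ordinals bin a noisy copy of the overlap into {3,2,1,0}.
#'
#' @param n_patients Cohort size (>= 4).
#' @param radius_range Lesion radius range in voxels.
#' @param placement_left,placement_right Region names lesion centers are
#'   drawn from per side.
#' @param effect_beta Effect size beta in [0, 1]; 0 gives a null cohort.
#' @param noise_sd_score SD of the Gaussian score noise (ACL points).
#' @param noise_sd_subdomain SD of the overlap noise behind the ordinals.
#' @param left_fraction Probability of a left-sided lesion.
#' @param age_range Uniform age range (years).
#' @param seed Integer seed.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_patients = 76L, radius_range = c(1.5, 3),
                        placement_left = c("vlpv_left", "thalamus_left"),
                        placement_right = "thalamus_right",
                        effect_beta = 0.25, noise_sd_score = 4,
                        noise_sd_subdomain = 0.15,
                        left_fraction = 0.7, age_range = c(35, 90),
                        seed = 1L) {
  stopifnot(n_patients >= 4L, effect_beta >= 0, effect_beta <= 1,
            left_fraction >= 0, left_fraction <= 1,
            radius_range[1] > 0, diff(radius_range) >= 0)
  structure(list(n_patients = as.integer(n_patients),
                 radius_range = radius_range,
                 placement_left = placement_left,
                 placement_right = placement_right,
                 effect_beta = effect_beta, noise_sd_score = noise_sd_score,
                 noise_sd_subdomain = noise_sd_subdomain,
                 left_fraction = left_fraction, age_range = age_range,
                 seed = as.integer(seed)), class = "cohort_spec")
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate a lesion cohort with a planted lesion-behaviour effect
#'
#' @param atlas The phantom \code{atlas_volume}.
#' @param spec A \code{cohort_spec}.
#' @return List with \code{masks} (list of \code{lesion_mask}),
#'   \code{records} (an \code{aphasia_records} data.frame) and
#'   \code{overlap} (each patient's critical-nucleus overlap fraction).
#' @export
simulate_lesion_cohort <- function(atlas, spec) {
  geom <- atlas$geometry
  shape <- geom$shape
  crit <- atlas_region_indices(atlas, attr_critical(atlas, spec))
  left_idx <- sort(unlist(lapply(spec$placement_left,
                                 function(l) atlas_region_indices(atlas, l))))
  right_idx <- sort(unlist(lapply(spec$placement_right,
                                  function(l) atlas_region_indices(atlas, l))))
  if (!length(left_idx) || !length(right_idx))
    stop("empty placement region")
  set.seed(spec$seed)
  masks <- vector("list", spec$n_patients)
  overlap <- numeric(spec$n_patients)
  rec <- vector("list", spec$n_patients)
  for (i in seq_len(spec$n_patients)) {
    side <- if (stats::runif(1) < spec$left_fraction) "left" else "right"
    pool <- if (side == "left") left_idx else right_idx
    ctr <- arrayInd(pool[sample.int(length(pool), 1)], shape)[1, ]
    r <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
    vox <- .sphere_mask(ctr, r, shape)
    if (!any(vox)) stop("lesion radius too small to cover any voxel")
    pid <- sprintf("P%03d", i)
    masks[[i]] <- lesion_mask(vox, geom, pid, side)
    ov <- if (side == "left") sum(vox[crit]) / length(crit) else 0
    overlap[i] <- ov
    noise <- stats::rnorm(1, sd = spec$noise_sd_score)
    score <- round(.clamp(ACL_MAX * (1 - spec$effect_beta * ov) + noise,
                          0, ACL_MAX))
    sub_noisy <- .clamp(ov + stats::rnorm(8, sd = spec$noise_sd_subdomain), 0, 1)
    ords <- 3L - as.integer(cut(sub_noisy, c(-Inf, 0.25, 0.5, 0.75, Inf))) + 1L
    age <- round(stats::runif(1, spec$age_range[1], spec$age_range[2]), 1)
    row <- data.frame(patient_id = pid, aphasia_score = as.integer(score),
                      age = age, lesion_volume = lesion_volume_cm3(masks[[i]]),
                      side = side, stringsAsFactors = FALSE)
    row[SUBDOMAIN_COLS] <- as.list(ords)
    rec[[i]] <- row
  }
  records <- aphasia_records(do.call(rbind, rec))
  list(masks = masks, records = records, overlap = overlap)
}

# the critical nucleus lives on the atlas' originating spec; fall back to
# the conventional default name
attr_critical <- function(atlas, spec) {
  if (!is.null(spec$critical_label)) spec$critical_label
  else if ("vlpv_left" %in% atlas$labels_table$name) "vlpv_left"
  else atlas$labels_table$name[1]
}

.sphere_mask <- function(center, radius, shape) {
  vox <- array(FALSE, shape)
  rng <- lapply(1:3, function(a) seq(max(1, floor(center[a] - radius)),
                                     min(shape[a], ceiling(center[a] + radius))))
  g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  keep <- g[colSums((t(g) - center)^2) <= radius^2, , drop = FALSE]
  if (nrow(keep) == 0L) keep <- matrix(center, 1)
  vox[keep] <- TRUE
  vox
}

#' Write a complete phantom study to disk
#'
#' Produces the same on-disk layout the real pipeline reads: atlas NIfTI +
#' label TSV, per-patient lesion masks + cohort manifest, clinical TSV, and
#' per-subject 4D connectome NIfTI volumes.
#'
#' @param dir Output directory.
#' @param phantom,connectome,cohort The three specs (defaults used when
#'   NULL).
#' @return Invisibly, a list of the written paths.
#' @export
write_phantom_study <- function(dir, phantom = default_phantom_spec(),
                                connectome = connectome_spec(),
                                cohort = cohort_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  atlas <- make_phantom_atlas(phantom)
  conn <- simulate_connectome(atlas, connectome)
  sim <- simulate_lesion_cohort(atlas, cohort)
  atlas_path <- file.path(dir, "atlas.nii.gz")
  write_volume(atlas, atlas_path)
  labels_path <- file.path(dir, "atlas_labels.tsv")
  utils::write.table(atlas$labels_table, labels_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest <- write_cohort(sim$masks, file.path(dir, "lesions"))
  clinical_path <- file.path(dir, "clinical.tsv")
  write_clinical(sim$records, clinical_path)
  conn_dir <- file.path(dir, "connectome")
  dir.create(conn_dir, showWarnings = FALSE)
  geom <- atlas$geometry
  for (s in seq_along(conn$subjects)) {
    arr <- array(t(conn$subjects[[s]]), c(geom$shape, conn$n_timepoints))
    im <- RNifti::asNifti(arr)
    im <- RNifti::`sform<-`(im, structure(geom$affine, code = 2L))
    RNifti::writeNifti(im, file.path(conn_dir, sprintf("subject%03d.nii.gz", s)))
  }
  invisible(list(atlas = atlas_path, labels = labels_path,
                 manifest = manifest, clinical = clinical_path,
                 connectome_dir = conn_dir))
}

#' Read a connectome from a directory of 4D NIfTI volumes
#' @param dir Directory of per-subject 4D .nii/.nii.gz files.
#' @param expected_geometry Optional geometry to enforce.
#' @return A \code{connectome}.
#' @export
read_connectome <- function(dir, expected_geometry = NULL) {
  files <- sort(list.files(dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE))
  if (!length(files)) stop("no NIfTI files in ", dir)
  subjects <- vector("list", length(files))
  geom <- expected_geometry
  nt <- NULL
  for (i in seq_along(files)) {
    im <- RNifti::readNifti(files[i])
    g <- volume_geometry(dim(im)[1:3], unclass(RNifti::xform(im)), "phantom")
    .check_geometry(g, geom, files[i])
    if (is.null(geom)) geom <- g
    nt <- dim(im)[4]
    subjects[[i]] <- t(matrix(as.array(im), prod(dim(im)[1:3]), nt))
  }
  structure(list(subjects = subjects, geometry = geom, n_timepoints = nt),
            class = "connectome")
}
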