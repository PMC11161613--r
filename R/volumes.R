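# Volume geometry, NIfTI I/O, lesion bookkeeping and the coverage-based
# analysis mask shared by all mapping stages.

#' Volume geometry
#'
#' Describes the voxel grid every volume in a cohort must share: the grid
#' dimensions, the 4x4 voxel-to-world affine (NIfTI convention, zero-based
#' voxel indices, millimetres) and a free-text space label.
#'
#' @param shape Integer vector of length 3 (voxels per axis).
#' @param affine 4x4 numeric voxel-to-world transform. The 3x3 block must be
#'   invertible with positive voxel volume.
#' @param space Character label for the common space (e.g. "MNI152-2mm",
#'   "phantom").
#' @return An object of class \code{volume_geometry}.
#' @export
volume_geometry <- function(shape, affine = NULL, space = "phantom") {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("shape must be 3 positive integers")
  if (is.null(affine)) affine <- diag(c(2, 2, 2, 1))
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  d <- det(affine[1:3, 1:3])
  if (!is.finite(d) || abs(d) < .Machine$double.eps)
    stop("affine 3x3 block must be invertible")
  structure(list(shape = shape, affine = affine, space = as.character(space)),
            class = "volume_geometry")
}

#' @export
print.volume_geometry <- function(x, ...) {
  cat(sprintf("<volume_geometry> %s, %d x %d x %d voxels, voxel volume %.3f mm^3\n",
              x$space, x$shape[1], x$shape[2], x$shape[3], voxel_volume_mm3(x)))
  invisible(x)
}

#' Voxel volume in cubic millimetres
#' @param geometry A \code{volume_geometry}.
#' @return Scalar voxel volume (mm^3).
#' @export
voxel_volume_mm3 <- function(geometry) {
  abs(det(geometry$affine[1:3, 1:3]))
}

#' Test two geometries for equality
#' @param a,b \code{volume_geometry} objects.
#' @param tol Numeric tolerance on affine entries.
#' @return Logical scalar.
#' @export
geometry_equal <- function(a, b, tol = 1e-4) {
  identical(a$shape, b$shape) && all(abs(a$affine - b$affine) < tol)
}

.check_geometry <- function(geometry, expected, what = "volume") {
  if (!is.null(expected) && !geometry_equal(geometry, expected))
    stop(sprintf("geometry mismatch for %s: expected %s %s, got %s %s",
                 what, expected$space, paste(expected$shape, collapse = "x"),
                 geometry$space, paste(geometry$shape, collapse = "x")))
  invisible(TRUE)
}

#' Convert voxel indices to world coordinates
#'
#' Voxel indices are one-based (R convention); the affine is applied to the
#' zero-based index per the NIfTI standard.
#'
#' @param geometry A \code{volume_geometry}.
#' @param ijk Integer vector of length 3, or an n x 3 matrix of indices.
#' @return World coordinates (mm), same shape as the input.
#' @export
voxel_to_world <- function(geometry, ijk) {
  m <- rbind2mat(ijk)
  xyz <- t(geometry$affine %*% rbind(t(m) - 1, 1))[, 1:3, drop = FALSE]
  if (is.null(dim(ijk)) || length(ijk) == 3L && !is.matrix(ijk)) drop(xyz) else xyz
}

#' Convert world coordinates to voxel indices
#' @inheritParams voxel_to_world
#' @param xyz World coordinates (length 3, or n x 3 matrix).
#' @return One-based voxel indices (rounded to nearest voxel).
#' @export
world_to_voxel <- function(geometry, xyz) {
  m <- rbind2mat(xyz)
  ijk <- t(solve(geometry$affine) %*% rbind(t(m), 1))[, 1:3, drop = FALSE] + 1
  ijk <- round(ijk)
  if (!is.matrix(xyz)) drop(ijk) else ijk
}

rbind2mat <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)

#' Binary lesion mask
#'
#' @param voxels Logical (or strictly 0/1) array over the grid; at least one
#'   voxel must be lesioned.
#' @param geometry The shared cohort \code{volume_geometry}.
#' @param patient_id Patient identifier.
#' @param side Lesion side, \code{"left"} or \code{"right"}.
#' @return An object of class \code{lesion_mask}.
#' @export
lesion_mask <- function(voxels, geometry, patient_id = "unknown",
                        side = c("left", "right")) {
  side <- match.arg(side)
  if (!is.logical(voxels)) {
    if (!all(voxels %in% c(0, 1)))
      stop("lesion mask values must be strictly binary")
    voxels <- array(voxels != 0, dim = dim(voxels))
  }
  if (!identical(as.integer(dim(voxels)), geometry$shape))
    stop("mask array dimensions do not match the geometry")
  if (!any(voxels)) stop("lesion mask must contain at least one true voxel")
  structure(list(voxels = voxels, geometry = geometry,
                 patient_id = as.character(patient_id), side = side),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %s (%s): %d voxels, %.3f cm^3\n", x$patient_id,
              x$side, sum(x$voxels), lesion_volume_cm3(x)))
  invisible(x)
}

#' Voxel-wise statistic volume
#'
#' Container for any scalar voxel map produced by the pipeline: correlation
#' (r), Fisher-z, t, TFCE, 1-P, or 0-1 lesion-symptom weights.
#'
#' @param values Numeric array over the grid.
#' @param geometry A \code{volume_geometry}.
#' @param kind One of "r", "z", "t", "tfce", "p", "one_minus_p", "weight".
#' @param analysis_mask Optional \code{voxel_set} over which values are
#'   defined; \code{NULL} means the whole grid.
#' @return An object of class \code{scalar_map}.
#' @export
scalar_map <- function(values, geometry,
                       kind = c("r", "z", "t", "tfce", "p", "one_minus_p", "weight"),
                       analysis_mask = NULL) {
  kind <- match.arg(kind)
  values <- array(as.numeric(values), dim = geometry$shape)
  idx <- if (is.null(analysis_mask)) seq_along(values) else analysis_mask$indices
  v <- values[idx]
  if (any(!is.finite(v)))
    stop("scalar_map values must be finite inside the analysis mask")
  if (kind %in% c("p", "one_minus_p", "weight") && (any(v < 0) || any(v > 1)))
    stop(sprintf("kind '%s' requires values in [0, 1]", kind))
  structure(list(values = values, geometry = geometry, kind = kind,
                 analysis_mask = analysis_mask), class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  cat(sprintf("<scalar_map> kind=%s, range [%.4g, %.4g]\n", x$kind,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Ordered set of voxel indices
#'
#' Indices are stored as sorted one-based linear indices into the grid array
#' (column-major), giving a deterministic ordering.
#'
#' @param indices Linear voxel indices (deduplicated and sorted), or an
#'   n x 3 matrix of (i, j, k) voxel coordinates.
#' @param geometry A \code{volume_geometry}.
#' @return An object of class \code{voxel_set}.
#' @export
voxel_set <- function(indices, geometry) {
  if (is.matrix(indices)) {
    if (ncol(indices) != 3L) stop("coordinate matrix must have 3 columns")
    if (any(indices < 1) || any(t(indices) > geometry$shape))
      stop("voxel coordinates out of bounds")
    indices <- indices[, 1] +
      (indices[, 2] - 1) * geometry$shape[1] +
      (indices[, 3] - 1) * prod(geometry$shape[1:2])
  }
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) && (indices[1] < 1L || indices[length(indices)] > prod(geometry$shape)))
    stop("voxel indices out of bounds")
  structure(list(indices = indices, geometry = geometry), class = "voxel_set")
}

#' @export
length.voxel_set <- function(x) length(x$indices)

#' Voxel coordinates of a voxel set
#' @param vs A \code{voxel_set}.
#' @return n x 3 integer matrix of one-based (i, j, k) coordinates.
#' @export
voxel_coords <- function(vs) {
  arrayInd(vs$indices, vs$geometry$shape)
}

# ---- NIfTI I/O --------------------------------------------------------------

.as_nifti <- function(values, geometry) {
  im <- RNifti::asNifti(array(values, dim = geometry$shape))
  RNifti::`sform<-`(im, structure(geometry$affine, code = 2L))
}

.geometry_from_nifti <- function(im, space) {
  volume_geometry(dim(im)[1:3], unclass(RNifti::xform(im)), space)
}

#' Read a scalar map from a NIfTI file
#' @param path Path to a .nii or .nii.gz file.
#' @param kind Map kind (see \code{\link{scalar_map}}).
#' @param space Space label recorded on the geometry.
#' @param expected_geometry Optional cohort geometry; a mismatch is an error.
#' @return A \code{scalar_map}.
#' @export
read_scalar_map <- function(path, kind = "z", space = "unknown",
                            expected_geometry = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  im <- RNifti::readNifti(path)
  geom <- .geometry_from_nifti(im, space)
  .check_geometry(geom, expected_geometry, path)
  if (!is.null(expected_geometry)) geom <- expected_geometry
  scalar_map(as.array(im), geom, kind)
}

#' Read a binary lesion mask from a NIfTI file
#'
#' On-disk values must be 0/1 within a rounding tolerance of 1e-6.
#'
#' @inheritParams read_scalar_map
#' @param patient_id,side Stored on the returned mask.
#' @return A \code{lesion_mask}.
#' @export
read_lesion_mask <- function(path, patient_id = "unknown", side = "left",
                             space = "unknown", expected_geometry = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  im <- RNifti::readNifti(path)
  vals <- as.array(im)
  r <- round(vals)
  if (any(abs(vals - r) > 1e-6) || !all(r %in% c(0, 1)))
    stop("mask file contains non-binary values: ", path)
  geom <- .geometry_from_nifti(im, space)
  .check_geometry(geom, expected_geometry, path)
  if (!is.null(expected_geometry)) geom <- expected_geometry
  lesion_mask(r != 0, geom, patient_id, side)
}

#' Write a volume to a NIfTI file
#'
#' Masks are written as integer 0/1 volumes, maps as float.
#'
#' @param x A \code{lesion_mask}, \code{scalar_map}, or \code{atlas_volume}.
#' @param path Output .nii/.nii.gz path.
#' @return The path, invisibly.
#' @export
write_volume <- function(x, path) {
  vals <- if (inherits(x, "lesion_mask")) array(as.integer(x$voxels), x$geometry$shape)
          else if (inherits(x, "atlas_volume")) x$labels
          else x$values
  im <- .as_nifti(vals, x$geometry)
  dt <- if (is.integer(vals)) "int16" else "float"
  RNifti::writeNifti(im, path, datatype = dt)
  invisible(path)
}

# ---- lesion bookkeeping -----------------------------------------------------

#' Coverage-based analysis mask
#'
#' Keeps the voxels lesioned in at least a given fraction of the cohort
#' (default in the pipeline: 10\%), the usual guard against rarely lesioned,
#' low-power voxels in lesion-symptom mapping. The inclusion threshold is
#' \code{max(1, ceiling(min_frac * n))} lesions.
#'
#' @param masks List of \code{lesion_mask} objects sharing one geometry.
#' @param min_frac Minimum lesion fraction in [0, 1].
#' @return A \code{voxel_set} of retained voxels (sorted linear indices).
#' @export
coverage_filter <- function(masks, min_frac = 0.10) {
  if (length(masks) == 0L) stop("empty mask list")
  if (min_frac < 0 || min_frac > 1) stop("min_frac must be in [0, 1]")
  geom <- masks[[1]]$geometry
  counts <- array(0L, geom$shape)
  for (m in masks) {
    .check_geometry(m$geometry, geom, m$patient_id)
    counts <- counts + m$voxels
  }
  thr <- max(1, ceiling(min_frac * length(masks)))
  voxel_set(which(counts >= thr), geom)
}

#' Lesion volume in cubic centimetres
#' @param mask A \code{lesion_mask}.
#' @return Lesion volume (cm^3).
#' @export
lesion_volume_cm3 <- function(mask) {
  sum(mask$voxels) * voxel_volume_mm3(mask$geometry) / 1000
}

# ---- cohort manifest --------------------------------------------------------

#' Read a lesion cohort from a manifest
#'
#' The manifest is a TSV with columns \code{patient_id}, \code{mask_path},
#' \code{side}; relative mask paths are resolved against the manifest's
#' directory. All masks must share one geometry (the first mask defines it).
#'
#' @param manifest_path Path to the manifest TSV.
#' @param verbose Log per-patient voxel counts.
#' @return A list of \code{lesion_mask} objects.
#' @export
read_cohort <- function(manifest_path, verbose = FALSE) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  tab <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  need <- c("patient_id", "mask_path", "side")
  if (!all(need %in% names(tab)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(manifest_path)
  geom <- NULL
  masks <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    p <- tab$mask_path[i]
    if (!file.exists(p)) p <- file.path(base, tab$mask_path[i])
    m <- read_lesion_mask(p, tab$patient_id[i], tab$side[i],
                          expected_geometry = geom)
    if (is.null(geom)) geom <- m$geometry
    if (verbose)
      message(sprintf("%s: %d lesioned voxels", m$patient_id, sum(m$voxels)))
    masks[[i]] <- m
  }
  masks
}

#' Write a lesion cohort and its manifest
#' @param masks List of \code{lesion_mask} objects.
#' @param dir Output directory (created if needed).
#' @return Path to the written manifest, invisibly.
#' @export
write_cohort <- function(masks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(masks, function(m) {
    f <- paste0(m$patient_id, "_lesion.nii.gz")
    write_volume(m, file.path(dir, f))
    data.frame(patient_id = m$patient_id, mask_path = f, side = m$side,
               stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "cohort_manifest.tsv")
  utils::write.table(do.call(rbind, rows), manifest, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
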