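# Post-hoc anatomy: label-atlas overlap tables, peak / centre-of-mass
# extraction, and spatial-similarity decoding against a map library.

#' Label atlas volume
#'
#' @param labels Integer array over the grid; 0 is background.
#' @param geometry A \code{volume_geometry}.
#' @param labels_table Data.frame with columns \code{id}, \code{name} naming
#'   every nonzero label.
#' @return An object of class \code{atlas_volume}.
#' @export
atlas_volume <- function(labels, geometry, labels_table) {
  labels <- array(as.integer(labels), geometry$shape)
  if (!all(c("id", "name") %in% names(labels_table)))
    stop("labels_table needs columns id, name")
  present <- setdiff(unique(as.vector(labels)), 0L)
  unnamed <- setdiff(present, labels_table$id)
  if (length(unnamed))
    stop("unnamed labels in atlas: ", paste(unnamed, collapse = ", "))
  structure(list(labels = labels, geometry = geometry,
                 labels_table = labels_table), class = "atlas_volume")
}

#' Read a label atlas (NIfTI + label TSV)
#' @param nii_path Label volume path.
#' @param labels_path TSV with columns \code{id}, \code{name}.
#' @param expected_geometry Optional geometry to enforce.
#' @return An \code{atlas_volume}.
#' @export
read_atlas <- function(nii_path, labels_path, expected_geometry = NULL) {
  im <- RNifti::readNifti(nii_path)
  geom <- volume_geometry(dim(im)[1:3], unclass(RNifti::xform(im)), "atlas")
  .check_geometry(geom, expected_geometry, nii_path)
  if (!is.null(expected_geometry)) geom <- expected_geometry
  tab <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
  atlas_volume(round(as.array(im)), geom, tab)
}

.roi_indices <- function(x, threshold = 0) {
  if (inherits(x, "lesion_mask")) which(x$voxels)
  else if (inherits(x, "voxel_set")) x$indices
  else if (inherits(x, "scalar_map")) which(x$values > threshold)
  else stop("unsupported ROI type")
}

#' Overlap of an ROI (or thresholded weight map) with atlas labels
#'
#' Voxel counts and percentages per label, sorted by share of the ROI; any
#' part of the ROI outside all labels is reported as "(unlabeled)". Voxel
#' counts are conserved: label counts plus the unlabeled remainder equal the
#' ROI size.
#'
#' @param roi A \code{lesion_mask}, \code{voxel_set}, or \code{scalar_map}
#'   (thresholded at \code{> threshold}).
#' @param atlas An \code{atlas_volume} on the same geometry.
#' @param threshold Threshold for scalar-map ROIs (default 0).
#' @return Data.frame with columns \code{label}, \code{voxels},
#'   \code{pct_roi}, \code{pct_label}.
#' @export
atlas_overlap <- function(roi, atlas, threshold = 0) {
  .check_geometry(roi$geometry, atlas$geometry, "ROI")
  idx <- .roi_indices(roi, threshold)
  if (!length(idx)) stop("empty ROI")
  lab <- atlas$labels[idx]
  rows <- lapply(seq_len(nrow(atlas$labels_table)), function(r) {
    id <- atlas$labels_table$id[r]
    n <- sum(lab == id)
    data.frame(label = atlas$labels_table$name[r], voxels = n,
               pct_roi = 100 * n / length(idx),
               pct_label = 100 * n / sum(atlas$labels == id),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  n0 <- sum(lab == 0L)
  if (n0 > 0)
    out <- rbind(out, data.frame(label = "(unlabeled)", voxels = n0,
                                 pct_roi = 100 * n0 / length(idx),
                                 pct_label = NA_real_))
  out <- out[out$voxels > 0 | out$label != "(unlabeled)", , drop = FALSE]
  out[order(-out$pct_roi, out$label), , drop = FALSE]
}

#' Peak and centre-of-mass of a map over an ROI
#'
#' The peak is the maximum-value voxel (ties broken toward the
#' lexicographically smallest (i, j, k) index); the centre of mass is the
#' value-weighted mean of the ROI voxels' world coordinates (uniform weights
#' for an all-equal map). Coordinates are reported in world mm.
#'
#' @param map A \code{scalar_map}.
#' @param roi Optional ROI (\code{voxel_set}/\code{lesion_mask}); default is
#'   the map's analysis mask, else the whole grid.
#' @return List with \code{peak_value}, \code{peak_voxel} (i, j, k),
#'   \code{peak_world} (mm), \code{center_world} (mm).
#' @export
peak_and_center <- function(map, roi = NULL) {
  idx <- if (!is.null(roi)) .roi_indices(roi)
         else if (!is.null(map$analysis_mask)) map$analysis_mask$indices
         else seq_along(map$values)
  if (!length(idx)) stop("empty ROI")
  vals <- map$values[idx]
  mx <- max(vals)
  tied <- idx[vals == mx]
  co <- arrayInd(tied, map$geometry$shape)
  pick <- order(co[, 1], co[, 2], co[, 3])[1]
  peak_vox <- co[pick, ]
  w <- vals - min(0, min(vals))      # nonnegative weights
  if (all(w == 0)) w <- rep(1, length(w))
  xyz <- voxel_to_world(map$geometry, arrayInd(idx, map$geometry$shape))
  xyz <- rbind2mat(xyz)
  list(peak_value = mx, peak_voxel = as.integer(peak_vox),
       peak_world = voxel_to_world(map$geometry, peak_vox),
       center_world = drop(crossprod(xyz, w) / sum(w)))
}

#' Decode a map against a library of named maps
#'
#' Ranks every library map by its spatial Pearson correlation with the
#' query, in descending order -- the reverse-inference style lookup used to
#' relate a derived network to known term maps.
#'
#' @param map Query \code{scalar_map}.
#' @param library Named list of \code{scalar_map}s on the same geometry.
#' @param mask Optional \code{voxel_set} restricting the comparison.
#' @return Data.frame \code{(term, r)} sorted by decreasing r.
#' @export
decode_map <- function(map, library, mask = NULL) {
  if (!length(library)) stop("empty map library")
  if (is.null(names(library))) stop("library must be named")
  idx <- if (!is.null(mask)) mask$indices else seq_along(map$values)
  q <- map$values[idx]
  if (stats::sd(q) == 0) stop("constant query map")
  r <- vapply(library, function(m) {
    .check_geometry(m$geometry, map$geometry, "library map")
    stats::cor(q, m$values[idx])
  }, numeric(1))
  out <- data.frame(term = names(library), r = unname(r),
                    stringsAsFactors = FALSE)
  out[order(-out$r), , drop = FALSE]
}
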