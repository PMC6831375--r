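#' Segment a tumor on PET with a fixed SUV threshold
#'
#' Reproduces fixed-threshold PET volumetry: within an operator-supplied
#' bounding region the voxels with SUV at or above the threshold (default
#' 2.5) are selected, and the largest 26-connected component is retained as
#' the lesion. An empty result is an explicit error rather than an empty
#' mask.
#'
#' @param volume a [suv_volume()].
#' @param seed_roi logical array congruent with `volume$values`: the
#'   operator-drawn region known to contain the lesion. May also be given as
#'   a list `list(lo = c(x, y, z), hi = c(x, y, z))` of voxel index bounds.
#' @param threshold SUV threshold; default 2.5.
#' @return An object of class `tumor_segmentation`: a list with `mask`
#'   (logical array), `threshold_suv`, `seed_roi`, `n_voxels`,
#'   `n_components` (number of supra-threshold components found before
#'   keeping the largest) and `roi_touches_boundary` (provenance flag).
#' @export
segment_fixed_threshold <- function(volume, seed_roi, threshold = 2.5) {
  stopifnot(inherits(volume, "suv_volume"))
  vals <- volume$values
  if (is.list(seed_roi) && !is.array(seed_roi)) {
    lo <- pmax(as.integer(seed_roi$lo), 1L)
    hi <- pmin(as.integer(seed_roi$hi), dim(vals))
    stop_if(any(hi < lo), "seed ROI box is empty")
    roi <- array(FALSE, dim(vals))
    roi[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    seed_roi <- roi
  }
  seed_roi <- as_array3d(seed_roi)
  stop_if(!identical(dim(seed_roi), dim(vals)), "seed ROI must be congruent with the volume")
  stop_if(!any(seed_roi), "seed ROI is empty")

  avid <- seed_roi & vals >= threshold
  if (!any(avid)) {
    stop("no avid lesion: no voxel inside the seed ROI has SUV >= ", threshold, call. = FALSE)
  }
  labels <- label_components(avid)
  sizes <- tabulate(labels[labels > 0L])
  keep <- which.max(sizes)
  mask <- labels == keep

  d <- dim(vals)
  touches <- any(seed_roi[c(1, d[1]), , ]) || any(seed_roi[, c(1, d[2]), ]) ||
    any(seed_roi[, , c(1, d[3])])

  structure(list(
    mask = mask,
    threshold_suv = threshold,
    seed_roi = seed_roi,
    n_voxels = sum(mask),
    n_components = length(sizes),
    roi_touches_boundary = touches
  ), class = "tumor_segmentation")
}

#' @export
print.tumor_segmentation <- function(x, ...) {
  cat("Tumor segmentation:", x$n_voxels, "voxels at SUV >=", x$threshold_suv, "\n")
  if (x$n_components > 1L)
    cat("  (largest of", x$n_components, "supra-threshold components kept)\n")
  invisible(x)
}

#' Metabolic indices of a segmented lesion
#'
#' Computes SUVmax, metabolic tumor volume (MTV, mL), mean SUV and total
#' lesion glycolysis (TLG = MTV x SUVmean, g/mL x mL) over a segmentation
#' mask. MTV is voxel count times voxel volume with no partial-volume
#' correction, the convention of threshold-based volumetry.
#'
#' @param volume a [suv_volume()].
#' @param seg a [segment_fixed_threshold()] result (or any list with a
#'   logical `mask` congruent with the volume).
#' @return A list of class `metabolic_indices` with `suvmax`, `suvmean`,
#'   `mtv_ml` and `tlg`.
#' @examples
#' ph <- generate_pet_phantom(phantom_spec(heterogeneity_sigma = 0, tumor_mean_suv = 5))
#' seg <- segment_fixed_threshold(ph$volume, array(TRUE, dim(ph$volume$values)))
#' metabolic_indices(ph$volume, seg)
#' @export
metabolic_indices <- function(volume, seg) {
  stopifnot(inherits(volume, "suv_volume"))
  mask <- as_array3d(seg$mask)
  stop_if(!identical(dim(mask), dim(volume$values)), "mask must be congruent with the volume")
  stop_if(!any(mask), "empty segmentation mask")
  v <- volume$values[mask]
  voxel_ml <- prod(volume$voxel_spacing_mm) / 1000
  mtv <- sum(mask) * voxel_ml
  suvmean <- mean(v)
  structure(list(
    suvmax = max(v),
    suvmean = suvmean,
    mtv_ml = mtv,
    tlg = mtv * suvmean
  ), class = "metabolic_indices")
}

#' @export
print.metabolic_indices <- function(x, ...) {
  cat(sprintf("SUVmax %.3f | SUVmean %.3f | MTV %.3f mL | TLG %.2f g/mL x mL\n",
              x$suvmax, x$suvmean, x$mtv_ml, x$tlg))
  invisible(x)
}
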