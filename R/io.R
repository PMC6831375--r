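# File I/O: NIfTI volumes via RNifti, tables as CSV, sidecars as JSON.

#' Write an SUV volume (or any 3-D/4-D array) as NIfTI
#'
#' @param x a [suv_volume()], logical mask, or numeric array.
#' @param path output `.nii`/`.nii.gz` path.
#' @param voxel_spacing_mm spacing recorded in the header (taken from the
#'   volume when `x` is an `suv_volume`).
#' @return The path, invisibly.
#' @export
write_volume_nifti <- function(x, path, voxel_spacing_mm = c(1, 1, 1)) {
  if (inherits(x, "suv_volume")) {
    voxel_spacing_mm <- x$voxel_spacing_mm
    x <- x$values
  }
  if (is.logical(x)) x <- array(as.integer(x), dim(x))
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- voxel_spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as an SUV volume
#'
#' @param path NIfTI file path.
#' @return An [suv_volume()] with spacing taken from the header.
#' @export
read_suv_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- abs(RNifti::pixdim(img)[1:3])
  suv_volume(array(as.numeric(img), dim(img)), sp, frame_of_reference = path)
}

#' Write a cohort table with its column dictionary
#'
#' @param cohort cohort data.frame.
#' @param path output CSV path; the dictionary is written next to it as
#'   `<path>.dictionary.json`.
#' @return The path, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  dict <- list(
    id = "patient identifier",
    suvmax = "maximum SUV over the segmented lesion",
    mtv_ml = "metabolic tumor volume (mL) at SUV >= 2.5",
    tlg = "total lesion glycolysis = MTV x SUVmean (g/mL x mL)",
    uniformity = "co-occurrence angular second moment",
    entropy = "co-occurrence entropy (bits)",
    dissimilarity = "co-occurrence dissimilarity",
    homogeneity = "co-occurrence homogeneity",
    inverse_difference_moment = "co-occurrence inverse difference moment",
    coarseness = "gray-tone difference coarseness",
    contrast = "gray-tone difference contrast",
    busyness = "gray-tone difference busyness",
    complexity = "gray-tone difference complexity",
    ktrans = "volume transfer constant (1/min)",
    ve = "extravascular extracellular volume fraction",
    vp = "plasma volume fraction",
    kep = "efflux rate constant ktrans/ve (1/min)",
    adc = "apparent diffusion coefficient (mm^2/s)",
    response = "treatment response: complete / non_complete",
    os_months = "overall survival time from diagnosis (months)",
    death = "1 = died, 0 = censored",
    rfs_months = "recurrence-free survival time from end of treatment (months)",
    recurrence = "1 = recurrence or death, 0 = censored"
  )
  jsonlite::write_json(dict[intersect(names(dict), names(cohort))],
                       paste0(path, ".dictionary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a cohort table
#'
#' @param path CSV path written by [write_cohort_csv()] (or matching its
#'   column contract).
#' @return A cohort data.frame.
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
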