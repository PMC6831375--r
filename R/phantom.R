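#' Specification of a digital FDG-PET phantom
#'
#' Describes an ellipsoidal FDG-avid tumor embedded in a low-uptake
#' background on a regular voxel grid. Intratumoral heterogeneity is
#' controlled by a log-normal multiplicative texture field: Gaussian white
#' noise smoothed to a chosen correlation length, standardized, scaled by
#' `heterogeneity_sigma` and exponentiated, so that `heterogeneity_sigma = 0`
#' yields a perfectly uniform tumor while the correlation length sets the
#' spatial scale (coarseness) of the heterogeneity independently of its
#' amplitude.
#'
#' @param grid_shape integer triple, grid size in voxels.
#' @param voxel_spacing_mm positive real triple, voxel spacing in mm.
#' @param tumor_center_mm real triple, ellipsoid center in mm (voxel-center
#'   coordinates; the first voxel center sits at `spacing / 2`).
#' @param tumor_radii_mm positive real triple, ellipsoid semi-axes in mm.
#' @param tumor_mean_suv positive real, mean tumor SUV; must exceed 2.5 so
#'   the fixed-threshold segmentation is well posed.
#' @param background_suv nonnegative real background SUV, strictly below 2.5.
#' @param heterogeneity_sigma nonnegative real, standard deviation of the
#'   log-scale texture field.
#' @param heterogeneity_correlation_mm positive real, correlation
#'   (smoothing) length of the texture field in mm.
#' @param background_noise_sd nonnegative real, SD of background noise
#'   (clipped so background stays below the 2.5 threshold).
#' @param rng_seed integer seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 24L),
                         voxel_spacing_mm = c(2, 2, 2),
                         tumor_center_mm = grid_shape * voxel_spacing_mm / 2,
                         tumor_radii_mm = c(12, 10, 9),
                         tumor_mean_suv = 8,
                         background_suv = 1,
                         heterogeneity_sigma = 0.25,
                         heterogeneity_correlation_mm = 4,
                         background_noise_sd = 0.05,
                         rng_seed = 1L) {
  stop_if(length(grid_shape) != 3L || any(grid_shape < 1), "grid_shape must be a positive integer triple")
  stop_if(any(voxel_spacing_mm <= 0), "voxel spacing must be strictly positive")
  stop_if(any(tumor_radii_mm <= 0), "tumor radii must be strictly positive")
  stop_if(tumor_mean_suv <= 2.5, "tumor_mean_suv must exceed the 2.5 SUV segmentation threshold")
  stop_if(background_suv < 0 || background_suv >= 2.5, "background_suv must lie in [0, 2.5)")
  stop_if(heterogeneity_sigma < 0, "heterogeneity_sigma must be nonnegative")
  stop_if(heterogeneity_correlation_mm <= 0, "heterogeneity_correlation_mm must be positive")
  extent <- grid_shape * voxel_spacing_mm
  if (any(tumor_center_mm - tumor_radii_mm < 0) || any(tumor_center_mm + tumor_radii_mm > extent)) {
    stop("tumor ellipsoid exceeds the image grid (center ", paste(tumor_center_mm, collapse = ", "),
         " mm, radii ", paste(tumor_radii_mm, collapse = ", "), " mm, extent ",
         paste(extent, collapse = ", "), " mm)", call. = FALSE)
  }
  structure(list(
    grid_shape = as.integer(grid_shape), voxel_spacing_mm = as.numeric(voxel_spacing_mm),
    tumor_center_mm = as.numeric(tumor_center_mm), tumor_radii_mm = as.numeric(tumor_radii_mm),
    tumor_mean_suv = tumor_mean_suv, background_suv = background_suv,
    heterogeneity_sigma = heterogeneity_sigma,
    heterogeneity_correlation_mm = heterogeneity_correlation_mm,
    background_noise_sd = background_noise_sd,
    rng_seed = as.integer(rng_seed)
  ), class = "phantom_spec")
}

#' SUV volume container
#'
#' A 3-D grid of standardized uptake values with its physical voxel spacing.
#'
#' @param values 3-D array of nonnegative, finite SUVs.
#' @param voxel_spacing_mm positive real triple (mm).
#' @param frame_of_reference optional identifier string.
#' @return An object of class `suv_volume`.
#' @export
suv_volume <- function(values, voxel_spacing_mm, frame_of_reference = "synthetic") {
  values <- as_array3d(values)
  stop_if(any(!is.finite(values)), "SUV values must be finite")
  stop_if(any(values < 0), "SUV values must be nonnegative")
  stop_if(length(voxel_spacing_mm) != 3L || any(voxel_spacing_mm <= 0),
          "voxel spacing must be a positive triple")
  structure(list(values = values, voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 frame_of_reference = frame_of_reference),
            class = "suv_volume")
}

#' @export
print.suv_volume <- function(x, ...) {
  cat("SUV volume:", paste(dim(x$values), collapse = " x "), "voxels @",
      paste(x$voxel_spacing_mm, collapse = " x "), "mm\n")
  cat(sprintf("  SUV range %.3f - %.3f\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Generate a digital FDG-PET phantom
#'
#' Builds an SUV volume containing an ellipsoidal tumor with multiplicative
#' log-normal heterogeneity over a noisy background, together with the exact
#' tumor mask used, so downstream segmentation and texture code can be
#' validated against known ground truth.
#'
#' Tumor voxels take the value `tumor_mean_suv * exp(G)` where `G` is a
#' centered Gaussian field with standard deviation `heterogeneity_sigma` and
#' correlation length `heterogeneity_correlation_mm`. Background voxels take
#' `background_suv` plus Gaussian noise, clipped to stay nonnegative and
#' strictly below the 2.5 SUV segmentation threshold.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` ([suv_volume()]), `tumor_mask`
#'   (logical array, the exact ellipsoid used) and `spec`.
#' @examples
#' ph <- generate_pet_phantom(phantom_spec(heterogeneity_sigma = 0))
#' range(ph$volume$values[ph$tumor_mask])  # uniform tumor
#' @export
generate_pet_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  sp <- spec$voxel_spacing_mm
  # voxel-center physical coordinates
  cx <- (seq_len(d[1]) - 0.5) * sp[1]
  cy <- (seq_len(d[2]) - 0.5) * sp[2]
  cz <- (seq_len(d[3]) - 0.5) * sp[3]
  u2 <- outer(((cx - spec$tumor_center_mm[1]) / spec$tumor_radii_mm[1])^2,
              ((cy - spec$tumor_center_mm[2]) / spec$tumor_radii_mm[2])^2, `+`)
  w2 <- ((cz - spec$tumor_center_mm[3]) / spec$tumor_radii_mm[3])^2
  mask <- outer(u2, w2, `+`) <= 1
  stop_if(!any(mask), "tumor ellipsoid contains no voxel centers; enlarge radii or refine the grid")

  withr_seed <- spec$rng_seed
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(withr_seed)

  vol <- array(spec$background_suv, d)
  if (spec$background_noise_sd > 0) {
    vol <- vol + stats::rnorm(prod(d), 0, spec$background_noise_sd)
  }
  vol <- pmin(pmax(vol, 0), 2.5 - 1e-6)

  if (spec$heterogeneity_sigma > 0) {
    field <- array(stats::rnorm(prod(d)), d)
    field <- gauss_smooth3d(field, spec$heterogeneity_correlation_mm / sp)
    field <- (field - mean(field)) / stats::sd(field)  # standardize, then scale
    g <- spec$heterogeneity_sigma * field[mask]
    tumor_vals <- spec$tumor_mean_suv * exp(g)
    # recentre so the tumor mean is attained exactly
    tumor_vals <- tumor_vals * spec$tumor_mean_suv / mean(tumor_vals)
  } else {
    tumor_vals <- rep(spec$tumor_mean_suv, sum(mask))
  }
  vol[mask] <- pmax(tumor_vals, .Machine$double.eps)

  list(volume = suv_volume(vol, sp), tumor_mask = mask, spec = spec)
}
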