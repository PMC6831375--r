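#' Variable-flip-angle T1 mapping
#'
#' Linearized SPGR fit per voxel: with `y = S/sin(a)` and `x = S/tan(a)`,
#' the steady-state equation becomes `y = E1 x + M0 (1 - E1)`, so an
#' ordinary least-squares line across flip angles gives `E1` as the slope
#' and `T1 = -TR / log(E1)`. Voxels whose slope falls outside (0, 1) are
#' nonphysical and flagged unfittable rather than clamped.
#'
#' @param vfa_signals 4-D array (x, y, z, angle) of SPGR signals, or a
#'   matrix (voxel x angle).
#' @param flips_deg flip angles (degrees), one per signal volume.
#' @param tr_ms repetition time (ms).
#' @return An object of class `t1_map`: `t10_ms`, `m0` and `fit_residual`
#'   arrays (NA where unfittable) plus logical `fittable`.
#' @export
fit_t1_vfa <- function(vfa_signals, flips_deg, tr_ms) {
  stop_if(length(unique(flips_deg)) < 2, "at least two distinct flip angles are required")
  if (is.matrix(vfa_signals)) {
    S <- vfa_signals
    d <- c(nrow(S), 1L, 1L)
  } else {
    stop_if(length(dim(vfa_signals)) != 4L, "vfa_signals must be 4-D (x, y, z, angle)")
    d <- dim(vfa_signals)[1:3]
    S <- matrix(vfa_signals, ncol = dim(vfa_signals)[4])
  }
  stop_if(ncol(S) != length(flips_deg), "one flip angle per signal volume required")
  a <- flips_deg * pi / 180
  Y <- sweep(S, 2, sin(a), `/`)
  X <- sweep(S, 2, tan(a), `/`)
  n <- length(a)
  xbar <- rowMeans(X); ybar <- rowMeans(Y)
  sxy <- rowSums(X * Y) - n * xbar * ybar
  sxx <- rowSums(X * X) - n * xbar^2
  slope <- sxy / sxx
  intercept <- ybar - slope * xbar
  fittable <- is.finite(slope) & slope > 0 & slope < 1 & rowSums(S) > 0
  t1 <- ifelse(fittable, -tr_ms / log(slope), NA_real_)
  m0 <- ifelse(fittable, intercept / (1 - slope), NA_real_)
  resid <- rowSums((Y - (slope * X + intercept))^2)
  resid[!fittable] <- NA_real_
  structure(list(t10_ms = array(t1, d), m0 = array(m0, d),
                 fit_residual = array(resid, d), fittable = array(fittable, d)),
            class = "t1_map")
}

#' Convert a dynamic SPGR series to contrast-agent concentration
#'
#' The baseline signal is the mean of the pre-contrast frames; together with
#' the baseline T1 it fixes the effective equilibrium magnetization. Each
#' dynamic frame is then inverted through the SPGR equation for `T1(t)`, and
#' concentration follows from the linear relaxivity model
#' `C(t) = (1/r1) (1/T1(t) - 1/T10)`. Negative concentrations (noise) are
#' clipped to zero and counted in the diagnostics.
#'
#' @param series a [dce_series()].
#' @param t1 a [fit_t1_vfa()] result (or list with `t10_ms` array).
#' @param relaxivity_per_s_per_mM longitudinal relaxivity r1; defaults to
#'   the value in the series acquisition.
#' @return List with `ct_mM` (4-D array), `n_clipped` (negative values
#'   clipped to zero), `flagged` (logical array of voxels with zero baseline
#'   or missing T1).
#' @export
signal_to_concentration <- function(series, t1,
                                    relaxivity_per_s_per_mM = series$acquisition$relaxivity_per_s_per_mM) {
  stopifnot(inherits(series, "dce_series"))
  acq <- series$acquisition
  d <- dim(series$frames)[1:3]
  nt <- dim(series$frames)[4]
  t10 <- as_array3d(t1$t10_ms)
  stop_if(!identical(dim(t10), d), "T1 map must be congruent with the series")
  a <- acq$dynamic_flip_deg * pi / 180
  S <- matrix(series$frames, ncol = nt)
  s0 <- rowMeans(S[, seq_len(series$n_baseline_frames), drop = FALSE])
  flagged <- s0 <= 0 | !is.finite(t10) | t10 <= 0
  e10 <- exp(-acq$tr_ms / t10)
  m0 <- s0 * (1 - as.vector(e10) * cos(a)) / (sin(a) * (1 - as.vector(e10)))
  r1_ms <- relaxivity_per_s_per_mM / 1000
  msin <- m0 * sin(a)
  ct <- matrix(0, nrow(S), nt)
  for (f in seq_len(nt)) {
    e1 <- (msin - S[, f]) / (msin - S[, f] * cos(a))
    bad <- !is.finite(e1) | e1 <= 0 | e1 >= 1
    t1f <- -acq$tr_ms / log(e1)
    c_f <- (1 / t1f - 1 / as.vector(t10)) / r1_ms
    c_f[bad] <- NA_real_
    ct[, f] <- c_f
  }
  ct[as.vector(flagged), ] <- NA_real_
  n_clipped <- sum(ct < 0, na.rm = TRUE)
  ct[!is.na(ct) & ct < 0] <- 0
  list(ct_mM = array(ct, c(d, nt)), n_clipped = n_clipped,
       flagged = array(flagged, d))
}

#' Apparent diffusion coefficient map
#'
#' `ADC = log(S0 / Sb) / b` voxel-wise (mm^2/s for `b` in s/mm^2). Voxels
#' with nonpositive signal in either volume are flagged and excluded from
#' the ROI mean; nonpositive ADC values (Sb >= S0, nonphysical for tissue)
#' are kept but flagged rather than silently dropped.
#'
#' @param s0 unweighted (b = 0) volume.
#' @param sb diffusion-weighted volume.
#' @param b diffusion weighting (s/mm^2), default 800.
#' @param roi_mask optional logical array; when given, `roi_mean` is the
#'   mean ADC over unflagged ROI voxels.
#' @return An object of class `adc_result`: `adc_map_mm2_per_s`, `flagged`
#'   (nonpositive signals), `nonphysical` (ADC <= 0), and `roi_mean`.
#' @export
adc_map <- function(s0, sb, b = 800, roi_mask = NULL) {
  stop_if(b <= 0, "b must be positive")
  s0 <- as_array3d(s0); sb <- as_array3d(sb)
  stop_if(!identical(dim(s0), dim(sb)), "volumes must be congruent")
  flagged <- s0 <= 0 | sb <= 0
  adc <- array(NA_real_, dim(s0))
  adc[!flagged] <- log(s0[!flagged] / sb[!flagged]) / b
  nonphysical <- !flagged & adc <= 0
  roi_mean <- NA_real_
  if (!is.null(roi_mask)) {
    roi_mask <- as_array3d(roi_mask)
    ok <- roi_mask & !flagged
    stop_if(!any(ok), "no usable voxel in the ROI")
    roi_mean <- mean(adc[ok])
  }
  structure(list(adc_map_mm2_per_s = adc, flagged = flagged,
                 nonphysical = nonphysical, roi_mean = roi_mean),
            class = "adc_result")
}

#' Aggregate a voxel-wise parameter map over a lesion ROI
#'
#' Per-lesion summary value: mean of the map over ROI voxels that are
#' finite and (optionally) converged/unflagged, reporting how many voxels
#' were excluded.
#'
#' @param param_map numeric array of voxel-wise estimates.
#' @param mask logical ROI array congruent with the map.
#' @param include optional logical array of voxels eligible for aggregation
#'   (e.g. a convergence flag); default all.
#' @return List with `mean`, `n_used`, `n_excluded`.
#' @export
roi_aggregate <- function(param_map, mask, include = NULL) {
  param_map <- as_array3d(param_map)
  mask <- as_array3d(mask)
  stop_if(!identical(dim(param_map), dim(mask)), "map and mask must be congruent")
  stop_if(!any(mask), "empty ROI")
  ok <- mask & is.finite(param_map)
  if (!is.null(include)) ok <- ok & as_array3d(include)
  stop_if(!any(ok), "all ROI voxels are excluded")
  list(mean = mean(param_map[ok]), n_used = sum(ok), n_excluded = sum(mask) - sum(ok))
}
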