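# Extended Kety (extended Tofts) forward model and synthetic DCE/DWI data.

# Tissue concentration on the frame grid:
#   Ct(t) = vp * Cp(t) + Ktrans * int_0^t Cp(tau) exp(-kep (t - tau)) dtau
# with the convolution evaluated by trapezoidal quadrature on the same grid
# the fitter uses. Rates in 1/min, times in seconds.
kety_ct <- function(cp_vals, t_s, ktrans_per_min, kep_per_min, vp) {
  t_min <- t_s / 60
  conv <- kety_conv(cp_vals, t_min, kep_per_min)
  vp * cp_vals + ktrans_per_min * conv

}

# Trapezoidal convolution of cp with exp(-kep t) on an arbitrary increasing
# grid (minutes). O(n^2) but n is the frame count (~80).
kety_conv <- function(cp_vals, t_min, kep_per_min) {
  n <- length(t_min)
  if (n < 2) return(numeric(n))
  dt <- diff(t_min)
  lag <- outer(t_min, t_min, `-`)          # lag[i, j] = t_i - t_j
  E <- exp(-kep_per_min * pmax(lag, 0))
  Fm <- sweep(E, 2, cp_vals, `*`)
  Fm[lag < 0] <- 0
  G <- Fm[, -n, drop = FALSE] + Fm[, -1, drop = FALSE]
  # term j covers [t_j, t_{j+1}]; it belongs to integral i iff j + 1 <= i
  valid <- outer(seq_len(n), seq_len(n - 1L), function(i, j) j < i)
  as.vector((G * valid) %*% (dt / 2))
}

#' Dynamic contrast-enhanced series container
#'
#' @param frames 4-D array (x, y, z, t) of nonnegative signals.
#' @param frame_times_s increasing vector of frame times (s).
#' @param n_baseline_frames number of pre-contrast frames.
#' @param acquisition the [acquisition_spec()] used.
#' @return An object of class `dce_series`.
#' @export
dce_series <- function(frames, frame_times_s, n_baseline_frames, acquisition) {
  stop_if(length(dim(frames)) != 4L, "frames must be a 4-D array (x, y, z, t)")
  stop_if(dim(frames)[4] != length(frame_times_s), "frame count must match frame times")
  stop_if(any(diff(frame_times_s) <= 0), "frame times must be strictly increasing")
  stop_if(n_baseline_frames >= length(frame_times_s), "baseline frames must precede dynamic frames")
  structure(list(frames = frames, frame_times_s = as.numeric(frame_times_s),
                 n_baseline_frames = as.integer(n_baseline_frames),
                 acquisition = acquisition),
            class = "dce_series")
}

#' Simulate a DCE-MRI acquisition from known kinetic ground truth
#'
#' Generates the SPGR dynamic series and the variable-flip-angle baseline
#' volumes for voxels whose kinetics follow the extended Kety model under a
#' known arterial input function. Per voxel the tissue concentration is
#' evaluated on the frame grid, converted to longitudinal relaxation rate
#' `R1(t) = 1/T10 + r1 Ct(t)` and then to SPGR signal at the dynamic flip
#' angle. The first `n_baseline_frames` frames are pre-contrast; the bolus
#' arrives at the following frame. Optional Gaussian noise is added in
#' signal space at a given SNR (baseline signal / noise SD).
#'
#' @param truth a [kinetic_truth()]; fields may be scalars (single-voxel
#'   simulation) or congruent 3-D arrays.
#' @param acq an [acquisition_spec()].
#' @param aif an `aif_model`; default: population curve with bolus onset at
#'   the first post-baseline frame.
#' @param snr signal-to-noise ratio of additive Gaussian noise; `Inf` (the
#'   default) for noiseless data.
#' @param rng_seed seed used when `snr` is finite.
#' @return A list with `series` (a [dce_series()]), `vfa` (list with
#'   `signals`, a 4-D array x,y,z,angle, and `flips_deg`), `aif`, `truth`
#'   and `ct_mM` (the noiseless concentration array, x,y,z,t).
#' @export
generate_dce_series <- function(truth, acq = acquisition_spec(), aif = NULL,
                                snr = Inf, rng_seed = 1L) {
  stopifnot(inherits(truth, "kinetic_truth"), inherits(acq, "acquisition_spec"))
  stop_if(any(truth$ktrans_per_min > 0 & truth$ve_fraction == 0),
          "ve = 0 with ktrans > 0 leaves kep undefined")
  times <- frame_times(acq)
  onset <- times[acq$n_baseline_frames] + acq$frame_interval_s / 2
  if (is.null(aif)) aif <- aif_population(onset_s = onset, hematocrit = acq$hematocrit)
  cp <- aif$cp(times)

  kt <- as_array3d(truth$ktrans_per_min)
  d <- dim(kt)
  ve <- array(rep_len(truth$ve_fraction, prod(d)), d)
  vp <- array(rep_len(truth$vp_fraction, prod(d)), d)
  t10 <- array(rep_len(truth$t10_ms, prod(d)), d)
  m0 <- array(rep_len(truth$m0, prod(d)), d)

  nt <- length(times)
  ct <- array(0, c(d, nt))
  # voxels share the AIF; group identical (ktrans, ve, vp) to avoid refits
  key <- paste(kt, ve, vp)
  for (k in unique(key)) {
    vox <- which(key == k)
    ctv <- kety_ct(cp, times, kt[vox[1]], kt[vox[1]] / ve[vox[1]], vp[vox[1]])
    for (f in seq_len(nt)) ct[vox + (f - 1L) * prod(d)] <- ctv[f]
  }

  r1_ms <- acq$relaxivity_per_s_per_mM / 1000  # 1/ms/mM
  sig <- array(0, c(d, nt))
  for (f in seq_len(nt)) {
    ctf <- array(ct[, , , f], d)
    t1f <- 1 / (1 / t10 + r1_ms * ctf)
    sig[, , , f] <- spgr_signal(m0, t1f, acq$dynamic_flip_deg, acq$tr_ms)
  }

  vfa <- array(0, c(d, length(acq$vfa_flips_deg)))
  for (a in seq_along(acq$vfa_flips_deg)) {
    vfa[, , , a] <- spgr_signal(m0, t10, acq$vfa_flips_deg[a], acq$tr_ms)
  }

  if (is.finite(snr)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(rng_seed)
    noise_sd <- mean(sig[, , , seq_len(acq$n_baseline_frames)]) / snr
    sig <- pmax(sig + stats::rnorm(length(sig), 0, noise_sd), 0)
    vfa <- pmax(vfa + stats::rnorm(length(vfa), 0, noise_sd), 0)
  }

  list(series = dce_series(sig, times, acq$n_baseline_frames, acq),
       vfa = list(signals = vfa, flips_deg = acq$vfa_flips_deg),
       aif = aif, truth = truth, ct_mM = ct)
}

#' Simulate a diffusion-weighted b0/b-weighted volume pair
#'
#' Mono-exponential decay `S_b = S0 exp(-b ADC)` voxel-wise, with optional
#' Gaussian noise at a given SNR.
#'
#' @param adc_mm2_per_s apparent diffusion coefficient, scalar or 3-D array.
#' @param b diffusion weighting (s/mm^2), default 800.
#' @param s0 unweighted signal, scalar or array congruent with `adc`.
#' @param snr signal-to-noise ratio; `Inf` for noiseless.
#' @param rng_seed seed used when `snr` is finite.
#' @return List with `s0` and `sb` (3-D arrays) and `b`.
#' @export
generate_dwi_pair <- function(adc_mm2_per_s, b = 800, s0 = 1000,
                              snr = Inf, rng_seed = 1L) {
  stop_if(any(adc_mm2_per_s <= 0), "adc must be positive")
  adc <- as_array3d(adc_mm2_per_s)
  s0a <- array(rep_len(s0, length(adc)), dim(adc))
  sb <- s0a * exp(-b * adc)
  if (is.finite(snr)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(rng_seed)
    noise_sd <- mean(s0a) / snr
    s0a <- pmax(s0a + stats::rnorm(length(s0a), 0, noise_sd), 0)
    sb <- pmax(sb + stats::rnorm(length(sb), 0, noise_sd), 0)
  }
  list(s0 = s0a, sb = sb, b = b)
}
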