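#' DCE-MRI acquisition parameters
#'
#' Parameters of the spoiled gradient-echo (SPGR) dynamic protocol and its
#' variable-flip-angle (VFA) baseline: TR/TE = 3.5/1.13 ms, a 15 degree
#' dynamic flip angle, VFA flips of 4, 8, 15 and 25 degrees, 80 dynamic
#' frames at 3.3 s temporal resolution with 4 pre-contrast baseline frames,
#' and a DWI b-value of 800 s/mm^2. Relaxivity defaults to 4.5 /s/mM
#' (Gd-DTPA at 3 T) and hematocrit to 0.42.
#'
#' @param tr_ms repetition time (ms).
#' @param te_ms echo time (ms); recorded but not used (TE effects are
#'   negligible at 1.13 ms and no T2* correction is applied).
#' @param dynamic_flip_deg flip angle of the dynamic series (degrees).
#' @param vfa_flips_deg flip angles of the pre-contrast T1-mapping scans.
#' @param n_frames number of dynamic frames.
#' @param frame_interval_s temporal resolution (s).
#' @param n_baseline_frames pre-contrast frames before bolus arrival.
#' @param b_value_s_per_mm2 DWI diffusion weighting.
#' @param relaxivity_per_s_per_mM longitudinal relaxivity r1.
#' @param hematocrit large-vessel hematocrit for blood-to-plasma conversion.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(tr_ms = 3.5, te_ms = 1.13,
                             dynamic_flip_deg = 15,
                             vfa_flips_deg = c(4, 8, 15, 25),
                             n_frames = 80L, frame_interval_s = 3.3,
                             n_baseline_frames = 4L,
                             b_value_s_per_mm2 = 800,
                             relaxivity_per_s_per_mM = 4.5,
                             hematocrit = 0.42) {
  stop_if(tr_ms <= 0 || te_ms <= 0, "TR and TE must be positive")
  stop_if(any(vfa_flips_deg <= 0) || dynamic_flip_deg <= 0, "flip angles must be positive")
  stop_if(!is_count(n_frames) || n_frames < 2, "n_frames must be an integer >= 2")
  stop_if(!is_count(n_baseline_frames) || n_baseline_frames < 1 ||
            n_baseline_frames >= n_frames,
          "n_baseline_frames must be a positive integer below n_frames")
  stop_if(frame_interval_s <= 0 || b_value_s_per_mm2 <= 0, "timings and b-value must be positive")
  stop_if(relaxivity_per_s_per_mM <= 0, "relaxivity must be positive")
  stop_if(hematocrit <= 0 || hematocrit >= 1, "hematocrit must lie in (0, 1)")
  structure(list(
    tr_ms = tr_ms, te_ms = te_ms, dynamic_flip_deg = dynamic_flip_deg,
    vfa_flips_deg = vfa_flips_deg, n_frames = as.integer(n_frames),
    frame_interval_s = frame_interval_s,
    n_baseline_frames = as.integer(n_baseline_frames),
    b_value_s_per_mm2 = b_value_s_per_mm2,
    relaxivity_per_s_per_mM = relaxivity_per_s_per_mM,
    hematocrit = hematocrit
  ), class = "acquisition_spec")
}

#' @rdname acquisition_spec
#' @param acq an `acquisition_spec`.
#' @export
frame_times <- function(acq) (seq_len(acq$n_frames) - 1L) * acq$frame_interval_s

#' Spoiled gradient-echo steady-state signal
#'
#' `S = M0 sin(a) (1 - E1) / (1 - E1 cos(a))` with `E1 = exp(-TR/T1)`.
#' Vectorized over any argument.
#'
#' @param m0 equilibrium magnetization (arbitrary units).
#' @param t1_ms longitudinal relaxation time (ms).
#' @param flip_deg flip angle (degrees).
#' @param tr_ms repetition time (ms).
#' @export
spgr_signal <- function(m0, t1_ms, flip_deg, tr_ms) {
  a <- flip_deg * pi / 180
  e1 <- exp(-tr_ms / t1_ms)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Ground-truth kinetic parameters for forward simulation
#'
#' @param ktrans_per_min volume transfer constant (1/min), scalar or array.
#' @param ve_fraction extravascular extracellular volume fraction in (0, 1].
#' @param vp_fraction plasma volume fraction in [0, 1).
#' @param t10_ms baseline T1 (ms), scalar or array.
#' @param m0 equilibrium magnetization.
#' @param adc_mm2_per_s apparent diffusion coefficient (mm^2/s).
#' @return An object of class `kinetic_truth`. `kep_per_min` is derived as
#'   `ktrans / ve`.
#' @export
kinetic_truth <- function(ktrans_per_min, ve_fraction, vp_fraction = 0,
                          t10_ms = 1000, m0 = 1000, adc_mm2_per_s = 1e-3) {
  stop_if(any(ktrans_per_min < 0), "ktrans must be nonnegative")
  stop_if(any(ve_fraction <= 0) || any(ve_fraction > 1), "ve must lie in (0, 1]")
  stop_if(any(vp_fraction < 0) || any(vp_fraction >= 1), "vp must lie in [0, 1)")
  stop_if(any(vp_fraction + ve_fraction > 1), "vp + ve must not exceed 1")
  stop_if(any(t10_ms <= 0), "t10 must be positive")
  stop_if(any(adc_mm2_per_s <= 0), "adc must be positive")
  structure(list(ktrans_per_min = ktrans_per_min, ve_fraction = ve_fraction,
                 vp_fraction = vp_fraction, kep_per_min = ktrans_per_min / ve_fraction,
                 t10_ms = t10_ms, m0 = m0, adc_mm2_per_s = adc_mm2_per_s),
            class = "kinetic_truth")
}
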