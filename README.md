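# petmriprog

Multimodal tumor-imaging quantification and prognostic modeling in R:
FDG-PET metabolic and texture analysis, DCE-MRI pharmacokinetics, DWI
diffusion mapping, and the statistical layer that turns imaging parameters
into treatment-response and survival predictors.

The package is aimed at quantitative-imaging researchers who want a
tested, reproducible implementation of this analysis chain — the kind used
to stratify chemoradiotherapy outcomes in head-and-neck cancer — together
with synthetic phantoms and cohorts so every stage can be validated
against known ground truth without any patient data.

## What it computes

**PET.** Fixed-threshold segmentation (SUV ≥ 2.5 inside an operator ROI,
largest 26-connected component), then SUVmax, metabolic tumor volume
(MTV), SUVmean and total lesion glycolysis (TLG = MTV × SUVmean); and nine
heterogeneity features from the segmented tumor — five from the normalized
gray-level co-occurrence matrix (uniformity Σp², entropy −Σp log₂p,
dissimilarity Σp|i−j|, homogeneity Σp/(1+|i−j|), inverse difference moment
Σp/(1+(i−j)²)) and four Amadasun–King features from the neighborhood
gray-tone difference matrix (coarseness, contrast, busyness, complexity).

**DCE-MRI.** Variable-flip-angle T1 mapping by the linearized SPGR fit;
signal-to-concentration conversion through the relaxivity model
C(t) = (1/r₁)(1/T₁(t) − 1/T₁₀); a population (Parker) or data-driven
arterial input function; and voxel-wise fitting of the extended Kety
(extended Tofts) model

    Ct(t) = vp·Cp(t) + Ktrans ∫₀ᵗ Cp(τ)·exp(−kep(t−τ)) dτ,  kep = Ktrans/ve

by bounded multi-start least squares, yielding K^trans, v_e, v_p and k_ep.

**DWI.** ADC = ln(S₀/S_b)/b maps with flagged nonphysical voxels and ROI
means.

**Outcomes.** Youden-optimal ROC cutoffs, chi-square association tests,
multivariable logistic response models (odds ratios), univariate-screen →
multivariable Cox survival models with Kaplan–Meier/log-rank summaries,
and additive risk scores that count a patient's independent adverse
factors and stratify response rates and survival by score.

All of this is exercised end-to-end by `run_pipeline()`, which simulates a
cohort of digital patients, measures every parameter with the package's
estimators, plants outcome effects on the true parameter values, and runs
the statistical layer on the measured ones.

## Worked example

```r
library(petmriprog)

## PET: phantom -> segmentation -> indices -> texture
ph  <- generate_pet_phantom(phantom_spec(rng_seed = 2L))
seg <- segment_fixed_threshold(ph$volume, array(TRUE, dim(ph$volume$values)))
metabolic_indices(ph$volume, seg)
#> SUVmax 13.541 | SUVmean 8.000 | MTV 4.608 mL | TLG 36.86 g/mL x mL
tex <- texture_features(ph$volume, seg)
round(tex$entropy_bits, 3)
#> [1] 9.622

## DCE-MRI: simulate at SNR 30, then recover the kinetics
acq <- acquisition_spec()            # TR/TE 3.5/1.13 ms, 80 frames @ 3.3 s
sim <- generate_dce_series(kinetic_truth(0.317, 0.35, 0.05), acq,
                           snr = 30, rng_seed = 1)
t1  <- fit_t1_vfa(sim$vfa$signals, sim$vfa$flips_deg, acq$tr_ms)
ct  <- signal_to_concentration(sim$series, t1)
fit_extended_kety(as.vector(ct$ct_mM), sim$aif, frame_times(acq))
#> Ktrans 0.2999 /min | ve 0.332 | vp 0.048 | kep 0.904 /min | RSS 0.00586 | converged

## DWI: closed-form round trip
dwi <- generate_dwi_pair(1.0e-3, b = 800, s0 = 1000)
adc_map(dwi$s0, dwi$sb, b = 800, roi_mask = array(TRUE, c(1, 1, 1)))$roi_mean
#> [1] 0.001
```

The segmented phantom tumor (576 voxels at 2 mm isotropic) gives
MTV = 4.608 mL and TLG = 36.86 g/mL × mL — TLG is exactly MTV × SUVmean.
The noisy DCE simulation planted K^trans = 0.317 min⁻¹ and recovers
0.300 min⁻¹ at SNR 30; noiseless round trips recover all parameters to
better than 0.1 % (see the tests). The ADC pair reproduces its planted
1.0 × 10⁻³ mm²/s exactly.

For the full orchestrated run:

```r
res <- run_pipeline(default_run_config(n_patients = 40, seed = 1,
                                       out_dir = "pipeline_out"))
```

writes the cohort table, cutoff/model/score tables, a markdown report and
a checksummed JSON manifest; a shell entry point with the same behavior is
in `inst/scripts/run-pipeline.R`.

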