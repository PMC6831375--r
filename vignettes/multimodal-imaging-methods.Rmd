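---
title: "Multimodal PET/MRI quantification and prognostic modeling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal PET/MRI quantification and prognostic modeling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petmriprog)
```

`petmriprog` implements a multimodal tumor-imaging analysis chain: PET
metabolic and texture quantification, DCE-MRI pharmacokinetic and DWI
parameter estimation, and a downstream statistical layer that dichotomizes
imaging parameters at ROC-derived cutoffs, models treatment response and
survival, and summarizes the independent adverse factors of each patient as
an additive risk score. Because clinical images of this kind are rarely
shareable, the package ships synthetic generators for every modality with
known ground truth, and the test suite validates each estimator against
that truth or against independent brute-force oracles. This vignette
documents the models, the tunable parameters, and the design decisions.

## PET quantification

Tumors are segmented on SUV (body-weight standardized uptake value) images
with a fixed threshold of 2.5 inside an operator-supplied bounding region,
the long-standing convention for FDG-avid head-and-neck disease. Of the
supra-threshold voxels the largest 26-connected component is kept; a
disconnected result is not an error but is recorded in provenance, and an
empty result (no voxel at or above threshold) is an explicit error rather
than an empty mask. Connectivity and multi-component handling are our
choices — fixed-threshold volumetry is usually described without them — and
26-connectivity is the permissive 3-D standard.

From the mask, `metabolic_indices()` computes SUVmax, the metabolic tumor
volume MTV (voxel count x voxel volume, mL; no partial-volume surface
correction), SUVmean, and total lesion glycolysis TLG = MTV x SUVmean.
`TLG = MTV x SUVmean` is asserted as an exact identity in the tests.

## PET texture features

Nine heterogeneity features are computed from the segmented tumor after
min–max quantization of the within-mask SUV range into `n_bins` equal-width
levels (default 64). Because quantization is relative to the mask's own
range, every feature is invariant under monotone affine rescaling of SUV.
The bin count is a genuine free parameter of this family of methods; 64 is
the common default of the co-occurrence era and is exposed as an argument.

Second-order features come from the normalized gray-level co-occurrence
matrix (NGLCM), accumulated over all 13 unique 3-D direction vectors at
distance 1 voxel, both orderings (hence symmetric), and normalized to sum
to one:

* uniformity $\sum p^2$, entropy $-\sum p \log_2 p$ (bits), dissimilarity
  $\sum p\,|i-j|$, homogeneity $\sum p/(1+|i-j|)$, inverse difference
  moment $\sum p/(1+(i-j)^2)$.

Higher-order features come from the neighborhood gray-tone difference
matrix (NGTDM): for every masked voxel with at least one masked neighbor in
its 26-neighborhood, the absolute difference between its level and its
neighborhood mean (center excluded, out-of-mask neighbors excluded)
accumulates into $s(i)$, with occurrence probabilities $p_i$. The four
Amadasun–King features follow: coarseness $1/(\varepsilon + \sum p_i s_i)$
with $\varepsilon = 10^{-6}$ capping the perfectly homogeneous case,
contrast, busyness and complexity over occupied levels. With a single
occupied level, contrast and busyness are undefined and returned as
flagged `NA`, never as zeros.

Deliberate conventions, all switchable or recorded in provenance: 3-D
matrices (no per-direction averaging; direction sums are pooled before
normalization), no isotropic resampling (voxel units used as-is), log base
2 for entropy. The implementation is validated against per-voxel
brute-force enumeration oracles to $10^{-10}$ on random phantoms.

## DCE-MRI pharmacokinetics

The kinetic model is the extended Kety (extended Tofts) model,

$$C_t(t) = v_p\,C_p(t) + K^{trans}\int_0^t C_p(\tau)\,
  e^{-k_{ep}(t-\tau)}\,d\tau, \qquad k_{ep} = K^{trans}/v_e,$$

with $K^{trans}$ (1/min) the transfer constant, $v_e$ the extravascular
extracellular fraction, $v_p$ the plasma fraction, and $C_p$ the arterial
plasma concentration. The convolution is evaluated by trapezoidal
quadrature on the native frame grid (3.3 s frames are fine relative to
physiological $k_{ep}$; supersampling was considered and not needed — the
forward generator uses the same quadrature, so noiseless round trips are
exact up to optimizer tolerance, and the noisy-recovery simulations bound
the practical error). Fitting minimizes the residual sum of squares under
bounds $K^{trans} \in [0, 5]$ 1/min, $v_e \in (0, 1]$ (numerical floor
$10^{-3}$), $v_p \in [0, 0.5]$, with L-BFGS-B started from the four
quartile crossings of the $(K^{trans}, v_e)$ box; the best residual wins
and ties resolve toward the lowest $K^{trans}$. A zero concentration curve
collapses to the boundary solution $K^{trans} = v_p = 0$ with zero
residual.

Signals follow the spoiled gradient-echo steady state
$S = M_0 \sin\alpha\,(1-E_1)/(1-E_1\cos\alpha)$, $E_1 = e^{-TR/T_1}$.
Baseline $T_{1,0}$ is estimated from variable-flip-angle scans (4, 8, 15,
25 degrees) by the standard linearization $S/\sin\alpha = E_1\,S/\tan\alpha
+ M_0(1-E_1)$; voxels with slope outside $(0,1)$ are flagged unfittable,
never clamped. Dynamic signals convert to concentration by inverting the
SPGR equation per frame and applying the linear relaxivity model
$C(t) = (1/r_1)(1/T_1(t) - 1/T_{1,0})$, with negative values clipped at
zero and counted. Defaults $r_1 = 4.5\ \mathrm{s^{-1}mM^{-1}}$ (Gd-DTPA at
3 T) and hematocrit 0.42 are conventional values, both configurable. Echo
time effects are ignored (TE = 1.13 ms); there is no B1 correction, motion
correction, or shutter-speed modeling.

The arterial input function has two modes sharing one contract. The
reproducible default is the Parker population curve (two Gaussians plus a
sigmoid-modulated exponential washout) shifted to the detected
bolus-arrival frame; arrival is the first frame whose region-mean
enhancement exceeds five baseline noise standard deviations (with an
absolute floor so noiseless data behaves). The data-driven mode decomposes
candidate-region time courses into orthogonal temporal sources (SVD of the
baseline-centered courses), selects the source with the largest peak and
earliest arrival, rescales it to the mean course of its highest-loading
voxels and divides by $1-\mathrm{Hct}$ to convert whole-blood to plasma
concentration; if no source passes the arterial criteria it falls back to
the population mode with a warning. This is a deliberately simple source
separation: it recovers planted arterial sources with shape correlation
above 0.99 in the tests, but it is not a full blind-source-separation
algorithm and the population mode is the default for that reason.

DWI reduces to the mono-exponential pair model: `adc_map()` computes
$\mathrm{ADC} = \ln(S_0/S_b)/b$ at $b = 800\ \mathrm{s/mm^2}$, flagging
nonpositive signals and nonphysical (nonpositive) ADC values rather than
dropping them. Per-lesion values of any voxel-wise map are the mean over
converged, unflagged ROI voxels (`roi_aggregate()`), with the exclusion
count reported; the mean (rather than median) is a documented choice.

## Synthetic data: what it emulates and what it does not

`generate_pet_phantom()` builds an ellipsoidal FDG-avid tumor over a noisy
background. Heterogeneity is a log-normal multiplicative field —
Gaussian white noise smoothed to a correlation length, standardized, scaled
by $\sigma$ and exponentiated — which separates the amplitude of
heterogeneity ($\sigma$) from its spatial scale (correlation length, which
drives NGTDM coarseness). $\sigma = 0$ yields an exactly uniform tumor.
Background noise is clipped below the 2.5 threshold so segmentation is
well posed by construction.

`generate_dce_series()` runs the extended Kety model forward under a known
AIF on the protocol grid (80 frames at 3.3 s, 4 pre-contrast baseline
frames, bolus arriving immediately after the baseline block) and converts
to SPGR signal, also emitting the four VFA baseline volumes from the same
$T_{1,0}$. `generate_dwi_pair()` applies the mono-exponential decay. Noise
in both is additive Gaussian in signal space at a configurable SNR — a
first-order stand-in for the Rician statistics of magnitude MRI, adequate
at the SNRs simulated here.

`generate_cohort()` draws imaging parameters from per-parameter
distributions (log-normal for volume-like MTV/TLG, normal for most
others), then generates binary response from a logistic model and OS/RFS
from exponential proportional-hazards models acting on the dichotomized
high-risk indicators, with independent exponential censoring calibrated to
a target marginal censoring fraction. The planted coefficients and
indicators are attached for recovery tests. The distribution locations and
cutoffs are illustrative magnitudes for this tumor setting, not calibrated
to any particular cohort, and are fully configurable.

None of the generators model scanner physics (no PET point-spread,
scatter, or reconstruction; no MRI inflow or B1 effects) and the phantoms
are geometric, not anthropomorphic. Passing tests therefore demonstrate
the correctness of the estimators and the statistical machinery under the
stated models — not robustness to the acquisition artifacts of real data.

## Statistical layer

Continuous imaging parameters are dichotomized at the cutoff maximizing
Youden's J (sensitivity + specificity − 1) over the midpoints of
consecutive observed values, both directions considered; ties resolve
toward higher sensitivity, then the smaller cutoff. Youden's J is the
conventional reading of "ROC-derived cutoff"; the exhaustive search is
cross-checked against `pROC` in the tests. Note that a cutoff optimized on
the observed data has a positively biased apparent J; the permutation test
in the suite quantifies this rather than hiding it.

Association of an indicator with response uses the 2x2 Pearson chi-square
without continuity correction. The multivariable response model is
ordinary logistic regression on the indicators; exponentiated coefficients
are reported as odds ratios (the clinical literature sometimes labels
these "hazard ratios"; they are odds ratios). Quasi-complete separation is
detected and refit with a weak ridge-penalized IRLS so estimates stay
finite, flagged in the output. Survival modeling screens each indicator
with a univariate Cox model and carries those with p below the entry
threshold (default 0.05, configurable) into a multivariable Cox model with
Efron tie handling; Kaplan-Meier curves and log-rank tests accompany each
retained indicator. No multiple-testing correction is applied by default,
matching the conventional two-sided 0.05 practice of this literature; the
screen-then-adjust flow's false-selection behavior under the null is
surfaced by the simulation tests rather than corrected away.

The risk score of a patient is the integer count of satisfied high-risk
rules — one point per independent adverse factor, 0 up to the number of
rules. Response scores are summarized as complete-response rates per score
level with chi-square and Cochran-Armitage trend tests; survival scores as
Kaplan-Meier strata per level with the log-rank test. On synthetic cohorts
with two planted response effects the complete-response rate is strictly
decreasing in score, and with four planted survival effects the strata are
hazard-ordered — the qualitative behavior such scoring systems are built
to show.

## The orchestrated pipeline

`run_pipeline()` ties the stages together on a fully synthetic cohort:
per patient it draws ground-truth tumor and kinetic parameters, simulates
PET/DCE/DWI data, measures every parameter with the package's own
estimators, plants response and survival outcomes on the *true* values,
and then runs the statistical layer on the *measured* values — so the
end-to-end run demonstrates that planted effects survive the full
measurement chain. Failures in one patient quarantine that patient without
aborting the run. With an output directory set, all tables, a markdown
report, the resolved configuration and a JSON manifest with per-file
checksums are written; two runs with the same configuration produce
byte-identical tables and report (the manifest additionally records
wall-clock time and is excluded from that guarantee).

Default problem sizes — 40-patient pipeline runs, 50-replicate coverage
simulations at n = 1000, 100-replicate noise studies for the kinetic fit,
oracle phantoms up to $8^3$ — were chosen so the whole validation suite
runs comfortably on a laptop-class single core while keeping binomial and
Monte-Carlo error small relative to the tolerances being asserted.

## Numerical choices and degenerate inputs

* Kety convolution: trapezoidal quadrature on the frame grid; $O(n^2)$ in
  the frame count, exact sharing between generator and fitter.
* Optimizer: L-BFGS-B, `factr` $10^4$ for the multi-start sweep and a
  polish pass at `factr` 10 from the winning start.
* Constant (degenerate) tumors: quantization flags the case, co-occurrence
  collapses to a point mass (entropy 0, uniformity 1), NGTDM coarseness is
  capped at $1/\varepsilon$, contrast/busyness are flagged `NA`.
* Single-voxel masks: no valid co-occurrence pairs or neighborhoods —
  explicit errors.
* VFA slopes outside $(0,1)$, zero baseline signals, nonpositive DWI
  signals: flagged, excluded from aggregates, never silently altered.
* Seeds: every stochastic component takes an explicit seed; the pipeline
  derives per-patient, per-stage streams from the master seed.

## Known limitations

Texture conventions (bin count, direction pooling, no resampling) follow
one reasonable convention of the co-occurrence era; other toolboxes make
other choices, and absolute feature values are not comparable across
conventions. The AIF data-driven mode is a simplified source separation.
The synthetic cohort distributions are illustrative. Response labels are
inputs (no RECIST grading from images), survival uses exponential
baselines, and nothing here addresses DICOM ingestion, registration, or
scanner reconstruction.
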