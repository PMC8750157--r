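---
title: "Methods: quantitative models, synthetic cohorts and prognostic modelling in mpfi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative models, synthetic cohorts and prognostic modelling in mpfi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpfi)
```

`mpfi` implements an early-response prediction pipeline for head-and-neck
squamous cell carcinoma (HNSCC) under (chemo)radiotherapy: quantitative
parameter extraction from diffusion-weighted MRI (ADC and IVIM), dynamic
contrast-enhanced MRI (variable-flip-angle T1 mapping plus Tofts
pharmacokinetic fitting under a population arterial input function) and
FDG-PET (SUVpeak, background-corrected MATV, TLG), paired pre-/intra-treatment
feature tables with fractional-change (delta) features, LASSO logistic and
Cox prognostic models with repeated cross-validation, and clinical
risk-stratification calculators. Because no patient data ship with the
package, every stage is exercised on synthetic phantoms and cohorts with
known ground truth. This vignette documents the models, the choices behind
them, and what the synthetic experiments do and do not demonstrate.

## Diffusion: ADC and the IVIM bi-exponential

The diffusion signal over the 10-value b-ladder
(0/10/25/50/75/150/300/500/750/1000 s/mm²) is modelled as

$$S(b) = S_0\left[f\,e^{-b D^*} + (1-f)\,e^{-b D}\right],$$

with tissue diffusion coefficient $D$, pseudo-diffusion coefficient $D^*$
(capillary perfusion mimicking fast diffusion) and perfusion fraction $f$.
`fit_adc()` is the mono-exponential special case: ordinary least squares of
$\log S$ on $b$ over all b-values, so ADC is minus the slope.

`fit_ivim()` uses the standard segmented scheme, which stabilises the weakly
identifiable perfusion compartment:

1. $D$ and the tissue intercept from a log-linear fit over
   $b \ge b_{\mathrm{split}} = 300$ s/mm² (the b-ladder has a natural gap
   between 150 and 300, and perfusion has decayed by a factor
   $e^{-300 \cdot 0.02} \approx 0.0025$ there for typical $D^*$);
2. $f = 1 - S_{0,\mathrm{high}}/S(0)$ from the intercept ratio;
3. $D^*$ from a one-parameter bounded least-squares fit with the rest fixed.

Bounds are $D \in [0, 4\times10^{-3}]$ mm²/s, $D^* \in [D, 0.5]$ mm²/s,
$f \in [0,1]$. When the fitted $f$ is numerically zero, $D^*$ carries no
information and is reported `NA`. A joint 4-parameter refinement
(`joint = TRUE`), initialised at the segmented estimates, polishes all
parameters by bounded nonlinear least squares; it is the estimator of choice
when per-voxel precision matters.

**Identifiability at realistic noise.** At Rician SNR 50 (noise
$\sigma = S_0/50$), a Fisher-information (Cramér–Rao) calculation at
$D = 1.0\times10^{-3}$, $f = 0.1$, $D^* = 20\times10^{-3}$ shows that *any*
unbiased single-voxel estimator has median relative errors of at least about
5% ($D$), 23% ($f$) and 47% ($D^*$). The package's joint fit sits essentially
at this floor (≈5.3%/24%/46% in simulation). This is why the study-level
analysis — like clinical practice — reports the *median over the ROI*, whose
error shrinks with the ROI size: over a 500-voxel ROI the median-parameter
error is below 1% for $D$ and a few percent for $f$. Per-voxel IVIM maps at
this SNR should be read as noisy; ROI medians are the reliable quantity.

ROI histogram features (`histogram_features()`) are the median, skewness
$m_3/m_2^{3/2}$ and kurtosis $m_4/m_2^2$ in the Pearson (non-excess)
convention, so a normal distribution scores 3. The convention matters when
comparing against tools that report excess kurtosis (normal = 0); the choice
is recorded in the output.

## DCE-MRI: T1 mapping, concentration conversion, Tofts model

The dynamic acquisition is a spoiled gradient echo (75 frames of 4.16 s,
TR 4.8 ms, flip angle 12°, bolus after 3 baseline frames), preceded by
variable-flip-angle (VFA) scans at 2/5/10/15/20°. The SPGR steady-state
signal is

$$S = M_0 \sin\alpha \frac{1 - E_1}{1 - E_1\cos\alpha},
\qquad E_1 = e^{-TR/T_1}.$$

`fit_t1_vfa()` estimates $(M_0, T_{1,0})$ by nonlinear least squares,
initialised from the classical linearisation ($S/\sin\alpha$ regressed on
$S/\tan\alpha$, slope $E_1$). Failure is judged by the relative residual
norm (threshold 0.1): a clean VFA series fits to machine precision while
degenerate, angle-independent signals leave more than 20% residual, so the
threshold separates the regimes cleanly. Optimiser return codes are not used
as a failure signal — a quasi-Newton line search legitimately reports an
abnormal termination when started at the exact optimum.

`signal_to_concentration()` pins the effective $M_0$ from the mean baseline
signal together with the VFA $T_{1,0}$, inverts each frame through the SPGR
equation to $R_1(t)$, and converts with relaxivity $r_1$:
$C(t) = (R_1(t) - R_{1,0})/r_1$. Frames outside the invertible signal range
are flagged rather than extrapolated. The default $r_1 = 3.5$
L·mmol⁻¹·s⁻¹ is a literature-typical value for Gd-DOTA at 3 T and is
config-overridable; no hematocrit correction is applied, and since simulator
and fitter share the same convention this cancels in recovery experiments.

The tissue model is the two-compartment Tofts model

$$C_t(t) = K^{trans}\int_0^t C_p(\tau)\,e^{-k_{ep}(t-\tau)}\,d\tau,
\qquad k_{ep} = K^{trans}/v_e,$$

evaluated by an exponential-kernel recursion that is exact for
piecewise-linear $C_p$ (so the constant-input closed form
$v_e c_0 (1 - e^{-k_{ep}t})$ is reproduced to machine precision on the
4.16 s frame grid). The plasma input $C_p$ is an analytic population AIF of
the Parker form — two Gaussian bolus passes plus an exponentially decaying
sigmoid washout — with the published population parameters as defaults
(`aif_default_params()`); simulator and fitter consume the same object, so
the particular parameter values are test-neutral. `fit_tofts()` runs bounded
least squares for $(K^{trans}, v_e)$ from a coarse log-spaced grid
initialisation; $k_{ep}$ is reported strictly as the ratio. Fitted
$v_e > 1$ — which arises in practice when the tumour curve exceeds what the
population AIF can explain — is retained and flagged, never clipped, so that
delta features remain internally consistent. A scan is excluded when more
than 30% of ROI voxels fail (`scan_fit_failure_rate()`; strictly greater
than, so 30/100 is retained and 31/100 excluded).

## PET lesion metrics

`suv_scale()` normalises a decay-corrected activity concentration by
injected dose over body weight (unit tissue density), so dose/weight maps to
SUV 1. `suv_peak()` maximises, over candidate centers, the mean SUV of the
voxels whose centers lie within 6.204 mm — the radius of an exactly 1 mL
sphere; discretisation is by voxel-center inclusion without partial volumes
(19 voxel centers at the 4 mm PET grid), and ties are broken by the first
center in column-major order. `matv_segment()` applies the
background-adapted threshold

$$T = 0.5\,(SUV_{peak} - BG) + BG,$$

with the local background $BG$ measured on a 2-voxel shell starting one
voxel outside the dilated lesion boundary, and keeps the 26-connected
component containing the peak center. MATV is the component volume,
SUV$_{mean}$ its mean and TLG = SUV$_{mean}$ × MATV by definition. The
threshold algebra is the standard "50% adapted for background" form; both
the fraction and the shell geometry are arguments.

## Feature table and univariate statistics

Fifteen imaging features are extracted per timepoint: ADC_GTV, ADC_median,
ADC_skewness, ADC_kurtosis, D, D*, f, DCE_GTV, Ktrans, ve, kep, MATV,
SUV_mean, SUV_peak and TLG, with GTVs converted from voxel counts at the
reconstructed grid spacings (1.8×1.8×2.3 mm for DWI, 1.6×1.6×2.4 mm for
DCE — protocol choices recorded in `mr_voxel_ml()`; ADC and D are reported
in 10⁻³ mm²/s). Each patient-level value is the arithmetic mean of the two
observers' per-ROI medians (`observer_average()`); the median is used
because voxel-level parameter distributions are skewed. Delta features are
the fractional change $(x_{intra} - x_{pre})/x_{pre}$, undefined when the
pretreatment value is zero. The full table carries 45 imaging columns
(15 × PRE/INTRA/delta) plus 7 clinical covariates (age, gender 0 F/1 M,
tobacco, HPV 0/1, site, T-stage, N-stage 0 = N0–1 / 1 = N2–3).
Interobserver agreement is quantified by Pearson's r (an ICC would also be
defensible; Pearson is what the screening stage consumes). Univariate
screening uses the Mann–Whitney U test (exact for ≤8 per group without
ties, tie-corrected normal approximation otherwise) and single-covariate
Cox regression with Efron ties and a Wald p-value, with monotone-likelihood
separation flagged when $|\hat\beta| \cdot sd(x) > 10$.

## Prognostic models

For each outcome (locoregional recurrence-free, distant metastasis-free and
overall survival) and each feature set (PRE, INTRA, DELTA, ALL; with or
without clinical covariates), `lasso_logistic_cv()` / `lasso_cox_cv()` run
repeated stratified 5-fold cross-validation. Within every training fold the
features are standardised and the L1 penalty is chosen by *inner* 5-fold
cross-validation (`lambda.min` by default; the 1-SE rule is available) —
nesting avoids the optimism of choosing the penalty on the full data, at the
cost of a conservative bias visible in null calibrations (mean null AUC
≈ 0.47–0.49 rather than exactly 0.50). Held-out predictions are pooled
within a repeat and scored — probabilities by the tie-corrected
Mann–Whitney AUC, linear predictors by Harrell's C — and the mean and SD
are taken across repeats. The design figure is 5 folds × 500 repeats;
tests and the shipped experiments use 10–50 repeats, which changes the
repeat-level SD estimate little because fold reshuffling, not the fit, is
the dominant noise source. For the logistic family the outcome is
dichotomised at 2 years; patients censored before 2 years without an event
carry no label and are excluded. Reported coefficients come from a refit on
all data at the inner-CV-chosen penalty. With the seed fixed, results are
bitwise reproducible.

## Risk calculators and stratification

A `risk_calculator` is an intercept plus named coefficients implementing
$Y = \beta_0 + \sum_i \beta_i x_i$, $p = 1/(1+e^{-Y})$.
`hnscc_risk_calculators()` ships the three built-in 2-year calculators
(locoregional recurrence, distant metastasis, death). The operation is
deliberately scale-agnostic: it applies the printed affine map to whatever
predictor values it is given, so inputs must be on the scale the
coefficients were derived on (note the death calculator's MATV coefficient
of 8.64 implies a transformed volume scale; the original scaling is not
recoverable from the printed form, which is why the package records which
scaling produced its inputs). Patients are stratified at fixed probability
cut points — low $p < 0.33$, medium $0.33 \le p < 0.66$, high
$p \ge 0.66$; the interval notation is ambiguous exactly at the cuts, and
the left-closed convention used here is stated in `stratify()`'s contract —
with cohort-tertile cuts available as a mode. Kaplan–Meier curves, the
log-rank test and high-risk sensitivity/specificity
($P(\mathrm{high}\mid\mathrm{event})$,
$P(\mathrm{not\ high}\mid\mathrm{no\ event})$) summarise group separation.

## The synthetic cohort: what it emulates, and what it does not

`cohort_spec()`/`simulate_cohort()` generate paired-timepoint cohorts
(default 57 patients) with patient-level truth drawn from
head-and-neck-typical distributions: $D \sim$ lognormal around
$1.0\times10^{-3}$ mm²/s, $f \approx 0.10$, $D^* \approx 20\times10^{-3}$
mm²/s, $T_{1,0} \approx 1200$ ms, $K^{trans} \approx 0.25$ min⁻¹,
$v_e \approx 0.35$, lesion SUV ≈ 9 over background 1.5, lesion volume
≈ 8 mL, and clinical covariate frequencies matching an advanced-stage HNSCC
cohort (72% male, 63% smokers, 63% N2–3, 79% oropharyngeal). Intratreatment
truth is obtained by multiplicative shifts (defaults: D ×1.2, f ×1.1,
Ktrans ×0.85, SUV ×0.7, volume ×0.8, each with lognormal patient spread) —
these are illustrative early-response effect sizes chosen once so that delta
features carry signal; no per-parameter intratreatment effect sizes are
published for calibration. DWI noise is Rician (magnitude images), DCE and
PET noise Gaussian (reconstructed data). The second observer is emulated by
random boundary-voxel flips with a Dice-overlap floor of 0.7. Outcomes
follow the same linear-logistic form as the risk calculators, with
exponential event times whose rate is solved from
$P(T \le 2\,\mathrm{y}) = 1/(1+e^{-Y})$ and administrative censoring
uniform on 2–4 years, so the 2-year logistic truth holds exactly.

The MR stages are generated at ROI level (per-voxel signal series inside
the lesion) rather than as full 4-D volumes: all downstream features use
only ROI voxels, and this keeps cohorts light. The PET stage carries a full
phantom grid because its segmentation needs spatial context. The phantoms
are deliberately simple — ellipsoidal lesions, uniform backgrounds, no
anatomy, no motion, no partial-volume effects beyond optional Gaussian
smoothing, independent voxel noise. Passing recovery tests therefore
demonstrates the correctness of the estimators and the pipeline plumbing,
*not* clinical performance on real tumours: in particular, the cohort AUCs
and C-indices reported for the original patient study are not reproducible
here (those data are not deposited), and the shipped experiments replace
them with null-calibration and planted-truth simulations at matched sample
sizes (null calibration over six 57-patient cohorts; planted truth with
three strong features in a 200-patient cohort).

## Numerical choices and problem sizes

- IVIM: segmented split at b = 300 s/mm²; joint refinement by L-BFGS-B with
  parameter scaling (S0, 0.1, 10⁻³, 10⁻²); recovery experiments use 500
  voxels.
- Tofts: coarse 10×10 log-spaced grid initialisation, L-BFGS-B with bounds
  $K^{trans} \in [0,5]$, $v_e \in [10^{-3}, 5]$; failure at relative
  residual > 0.5; recovery experiments use 200 voxels at frame-SNR 20.
- SUVpeak oracle checks run exhaustive brute force on 20³ grids (20
  replicates).
- Model calibration: 5×5 nested CV, 25–50 repeats, n = 57 (null) and
  n = 200 (planted truth); stratification power uses 25 replicate
  500-patient cohorts.
- Degenerate inputs: zero-variance ROIs flag shape statistics as NA but keep
  the median; empty masks, single-class folds and event-free groups raise
  errors at the operation level and are recorded as NA cells at the
  report level.

## Known limitations

- Single-voxel IVIM parameters at clinical SNR are near their
  information-theoretic error floor (see above); only ROI-level medians
  should be interpreted.
- The population AIF is analytic and shared between simulator and fitter;
  real-data misspecification of the AIF (which produces the flagged
  $v_e > 1$ fits) is represented only through that flag, not emulated.
- The Tofts implementation is the basic two-compartment model: no vascular
  term ($v_p$), no B1 correction, no patient-specific AIF.
- Cross-modality registration is out of scope; masks must live on each
  modality's native grid.
- The printed risk calculators are applied as-is; their predictor scaling on
  new data is the user's responsibility.
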