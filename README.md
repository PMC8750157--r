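# mpfi — multiparametric functional imaging biomarkers for chemoradiotherapy response prediction

Patients with locally advanced head-and-neck squamous cell carcinoma
(HNSCC) respond very differently to (chemo)radiotherapy. Functional imaging
acquired before treatment and again about ten days in — diffusion-weighted
MRI (ADC and the IVIM bi-exponential), dynamic contrast-enhanced MRI
(Tofts pharmacokinetics) and FDG-PET (SUVpeak, metabolically active tumor
volume, total lesion glycolysis) — captures early tumoral change, and
combinations of these parameters support prognostic models and clinical
risk calculators for 2-year locoregional recurrence-free, distant
metastasis-free and overall survival.

`mpfi` is an R package for imaging scientists and biostatisticians that
implements this pipeline end to end:

- **Quantitative fitting.** Voxelwise ADC (log-linear OLS) and segmented
  IVIM fitting of `S(b) = S0 [f e^(−b·D*) + (1−f) e^(−b·D)]`;
  variable-flip-angle T1 mapping of the spoiled-gradient-echo signal
  `S = M0 sin α (1−E1)/(1−E1 cos α)`; SPGR signal-to-concentration
  conversion and two-compartment Tofts fitting
  `Ct(t) = Ktrans ∫ Cp(τ) e^(−kep(t−τ)) dτ`, `kep = Ktrans/ve`, under a
  Parker-form population arterial input function; the >30% voxel
  fit-failure scan exclusion rule.
- **PET lesion metrics.** SUV scaling, SUVpeak over an exact 1 mL sphere,
  local-background estimation, background-adapted 50%-of-peak MATV
  segmentation, and TLG = SUVmean × MATV.
- **Feature tables.** Fifteen imaging features per timepoint, two-observer
  averaging of ROI medians, delta features `(intra − pre)/pre`, clinical
  covariates, Mann–Whitney and univariate Cox screening.
- **Prognostic models.** LASSO logistic (cross-validated AUC) and LASSO Cox
  (Harrell's C) with repeated stratified 5-fold cross-validation and nested
  penalty selection, over the PRE/INTRA/DELTA/ALL × (±clinical) model grid.
- **Risk stratification.** Linear-logistic risk calculators
  (`p = 1/(1+exp(−Y))`), including the three built-in 2-year calculators,
  low/medium/high grouping, Kaplan–Meier curves, log-rank tests and
  high-risk sensitivity/specificity.
- **Synthetic cohorts.** Phantoms and full paired-timepoint cohorts with
  known ground truth (Rician DWI noise, forward-Tofts DCE series, PET
  phantoms, simulated second observer, censored 2-year outcomes from a
  known linear predictor), so every stage is testable without patient data.

## Worked example

```r
library(mpfi)

# --- IVIM fit on a noiseless 10-b-value series ---------------------------
b <- c(0, 10, 25, 50, 75, 150, 300, 500, 750, 1000)
sig <- ivim_signal(b, S0 = 1000, f = 0.1, D = 1.0e-3, D_star = 20e-3)
fit <- fit_ivim(sig, b)
# D = 1.0005 e-3 mm^2/s, D* = 20.125 e-3, f = 0.100

# --- DCE chain: VFA T1 -> concentration -> Tofts -------------------------
truth <- list(Ktrans = 0.2, ve = 0.3, T1_0 = 1200, M0 = 1000)
s  <- simulate_dce_series(truth)           # 75 frames of 4.16 s, 3 baseline
t1 <- fit_t1_vfa(s$vfa, c(2, 5, 10, 15, 20), tr_ms = 4.8)
cc <- signal_to_concentration(s$dynamic, t1, 4.8, 12, r1 = 3.5, n_baseline = 3)
ft <- fit_tofts(cc$concentration_mM, s$cp, s$times_min)
# T1 = 1200.0 ms; Ktrans = 0.2000 /min, ve = 0.3000, kep = 0.6667 /min

# --- PET phantom metrics -------------------------------------------------
ph  <- simulate_pet_volume(list(suv_lesion = 10, lesion_volume_ml = 8),
                           background = 1)
seg <- matv_segment(ph$volume, dilate_mask(ph$lesion_mask, 2))
# SUVpeak = 10.00, MATV = 8.704 mL, SUVmean = 10.00, TLG = 87.04

# --- a built-in risk calculator ------------------------------------------
calc <- hnscc_risk_calculators()$DMFS
apply_calculator(calc, list(PRE_ADC_kurtosis = 3.4, PRE_SUV_peak = 8.2))
# DMFS 2-year risk = 0.405
```

The IVIM fit recovers the generating parameters to a fraction of a percent;
the DCE chain inverts its own forward model essentially exactly; the PET
phantom segmentation returns the full uniform lesion (the 0.704 mL excess
over the nominal 8 mL is voxel discretisation at the 4 mm grid); and the
calculator turns two pretreatment features into a 2-year metastasis
probability.

A full synthetic study — cohort simulation, feature extraction through all
three fitting chains, the 24-cell model grid, risk groups and Kaplan–Meier
report — runs from one seeded config:

```r
out <- run_pipeline(pipeline_config(n_patients = 6, seed = 1))
list.files(out)
#> features.csv, outcomes_*.csv, model_grid.csv, risks.csv, km_*.csv,
#> logrank.csv, resolved_config.yaml
```

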