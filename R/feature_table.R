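# Per-patient analysis table: 15 imaging features at PRE and INTRA, delta
# features, clinical covariates, observer averaging, and the univariate
# screening statistics (Mann-Whitney U, univariate Cox).

#' The default 15-feature imaging panel
#' @return Character vector of feature names.
#' @export
imaging_feature_names <- function() {
  c("ADC_GTV", "ADC_median", "ADC_skewness", "ADC_kurtosis",
    "D", "D_star", "f", "DCE_GTV", "Ktrans", "ve", "kep",
    "MATV", "SUV_mean", "SUV_peak", "TLG")
}

#' The default clinical covariates
#' @return Character vector of covariate names (gender: 0 female / 1 male;
#'   HPV: 0 negative / 1 positive; n_stage: 0 = N0-N1, 1 = N2-N3).
#' @export
clinical_covariate_names <- function() {
  c("age", "gender", "tobacco", "hpv", "site", "t_stage", "n_stage")
}

#' Average a feature over the two observers
#'
#' The per-patient analysis value of each imaging feature is the arithmetic
#' mean of the two per-ROI medians, one per observer. With a single observer
#' the value is passed through and flagged.
#'
#' @param obs1,obs2 Per-observer feature values (either may be `NA`).
#' @return List with `value` and `single_observer` flag.
#' @export
observer_average <- function(obs1, obs2) {
  if (is.na(obs1) && is.na(obs2)) stop("both observers missing")
  if (is.na(obs1) || is.na(obs2))
    return(list(value = ifelse(is.na(obs1), obs2, obs1),
                single_observer = TRUE))
  list(value = (obs1 + obs2) / 2, single_observer = FALSE)
}

#' Fractional intratreatment change (delta feature)
#'
#' `delta = (intra - pre) / pre`; undefined (NA) when the pretreatment value
#' is 0.
#'
#' @param pre,intra Feature values at the two timepoints.
#' @return Delta value, or `NA` when `pre == 0`.
#' @export
delta_feature <- function(pre, intra) {
  ifelse(is.na(pre) | is.na(intra) | pre == 0, NA_real_, (intra - pre) / pre)
}

#' Interobserver Pearson correlation per feature
#'
#' @param obs1,obs2 Per-patient feature values for each observer (>= 3
#'   patients).
#' @return Pearson correlation coefficient.
#' @export
interobserver_correlation <- function(obs1, obs2) {
  ok <- is.finite(obs1) & is.finite(obs2)
  if (sum(ok) < 3L) stop("need at least 3 patients")
  if (stats::sd(obs1[ok]) == 0 || stats::sd(obs2[ok]) == 0)
    stop("zero variance in one observer's values")
  stats::cor(obs1[ok], obs2[ok])
}

#' Mann-Whitney U test between two groups
#'
#' U statistic for group A with exact enumeration for small samples without
#' ties, and the tie-corrected normal approximation otherwise (via
#' [stats::wilcox.test()]).
#'
#' @param a,b Numeric vectors (both nonempty).
#' @param exact_max Use the exact distribution when both groups have at most
#'   this many observations and there are no ties (default 8).
#' @return List with `U` (statistic for group `a`), `p`.
#' @export
mann_whitney <- function(a, b, exact_max = 8) {
  if (length(a) < 1L || length(b) < 1L) stop("both groups must be nonempty")
  exact <- length(a) <= exact_max && length(b) <= exact_max &&
    !anyDuplicated(c(a, b))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Univariate Cox proportional-hazards regression
#'
#' One-feature Cox model (Efron partial likelihood) with hazard ratio and
#' Wald p-value; monotone-likelihood separation is flagged when the
#' coefficient diverges.
#'
#' @param feature Numeric covariate.
#' @param time,event Follow-up time and event indicator (0/1).
#' @return List with `hr`, `beta`, `se`, `p`, `separation` flag, `status`.
#' @export
univariate_cox <- function(feature, time, event) {
  if (sum(event) < 1L) stop("need at least one event")
  d <- data.frame(feature = feature, time = time, event = event)
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ feature, data = d,
                    ties = "efron"),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(hr = NA_real_, beta = NA_real_, se = NA_real_, p = NA_real_,
                separation = NA, status = "failed"))
  s <- summary(fit)
  beta <- unname(stats::coef(fit))
  se <- s$coefficients[1, "se(coef)"]
  sdx <- stats::sd(feature)
  separation <- is.finite(beta) && sdx > 0 && abs(beta * sdx) > 10
  list(hr = exp(beta), beta = beta, se = se,
       p = s$coefficients[1, "Pr(>|z|)"], separation = separation,
       status = "ok")
}

# --- feature extraction from a simulated cohort ---------------------------

# MR voxel volumes used to turn ROI voxel counts into GTVs (mL); the
# reconstructed in-plane grids are protocol choices recorded here.
mr_voxel_ml <- function() {
  c(dwi = 1.8 * 1.8 * 2.3 / 1000, dce = 1.6 * 1.6 * 2.4 / 1000)
}

# The 15 imaging features for one observer's ROI of one patient-timepoint.
extract_tp_features <- function(entry, meta, observer = 1L) {
  idx <- if (observer == 1L) seq_len(nrow(entry$dwi)) else entry$mr_obs2_idx
  b <- meta$b_values
  # DWI / IVIM
  dwi <- entry$dwi[idx, , drop = FALSE]
  adc <- apply(dwi, 1, function(s) fit_adc(s, b)$adc)
  ivim <- apply(dwi, 1, function(s) {
    v <- fit_ivim(s, b); c(v$D, v$D_star, v$f)
  })
  hf <- histogram_features(adc)
  # DCE / Tofts
  t1 <- fit_t1_vfa(entry$dce$vfa, meta$vfa_angles_deg, tr_ms = 4.8)
  pkm <- vapply(entry$dce$voxels[idx], function(sig) {
    conc <- signal_to_concentration(sig, t1, tr_ms = 4.8, alpha_deg = 12,
                                    r1 = meta$relaxivity_r1, n_baseline = 3L)
    ft <- fit_tofts(conc$concentration_mM, entry$dce$cp, entry$dce$times_min)
    c(ft$Ktrans, ft$ve, ft$kep, ft$status == "ok")
  }, numeric(4))
  # PET (semi-automatic segmentation seeded by the observer's mask)
  seed <- if (observer == 1L) entry$pet$obs1 else entry$pet$obs2
  pet <- matv_segment(entry$pet$volume, seed)
  vml <- mr_voxel_ml()
  c(ADC_GTV = length(idx) * vml[["dwi"]],
    ADC_median = hf$median * 1e3,          # reported in 1e-3 mm^2/s
    ADC_skewness = hf$skewness,
    ADC_kurtosis = hf$kurtosis,
    D = stats::median(ivim[1, ], na.rm = TRUE) * 1e3,
    D_star = stats::median(ivim[2, ], na.rm = TRUE) * 1e3,
    f = stats::median(ivim[3, ], na.rm = TRUE),
    DCE_GTV = length(idx) * vml[["dce"]],
    Ktrans = stats::median(pkm[1, pkm[4, ] == 1], na.rm = TRUE),
    ve = stats::median(pkm[2, pkm[4, ] == 1], na.rm = TRUE),
    kep = stats::median(pkm[3, pkm[4, ] == 1], na.rm = TRUE),
    MATV = pet$MATV_ml,
    SUV_mean = pet$SUV_mean,
    SUV_peak = pet$SUV_peak,
    TLG = pet$TLG)
}

#' Build the per-patient analysis table from a simulated cohort
#'
#' Runs the full quantitative pipeline (ADC/IVIM fits, VFA T1 + Tofts fits,
#' PET segmentation) per observer, averages the two observers' per-ROI
#' medians, and assembles 15 imaging features at PRE and INTRA plus their
#' deltas (45 imaging columns) and the 7 clinical covariates.
#'
#' @param cohort Result of [simulate_cohort()].
#' @return Data frame with one row per patient: `patient_id`,
#'   `PRE_<feature>`, `INTRA_<feature>`, `delta_<feature>` for each of the
#'   15 features, plus clinical covariates.
#' @export
build_feature_table <- function(cohort) {
  meta <- cohort$meta
  feats <- imaging_feature_names()
  rows <- lapply(names(cohort$patients), function(pid) {
    p <- cohort$patients[[pid]]
    per_tp <- lapply(c(PRE = "PRE", INTRA = "INTRA"), function(tp) {
      f1 <- extract_tp_features(p[[tp]], meta, observer = 1L)
      f2 <- extract_tp_features(p[[tp]], meta, observer = 2L)
      vapply(feats, function(nm)
        observer_average(f1[[nm]], f2[[nm]])$value, numeric(1))
    })
    delta <- delta_feature(per_tp$PRE, per_tp$INTRA)
    out <- c(per_tp$PRE, per_tp$INTRA, delta)
    names(out) <- c(paste0("PRE_", feats), paste0("INTRA_", feats),
                    paste0("delta_", feats))
    out
  })
  tab <- as.data.frame(do.call(rbind, rows))
  clin <- cohort$truth[c("patient_id", clinical_covariate_names())]
  cbind(clin, tab)
}

#' Column names of a feature set
#'
#' Maps the model-grid feature-set labels to table columns: `PRE`, `INTRA`
#' and `DELTA` are the 15 features at that timepoint (or their deltas);
#' `ALL` is all 45.
#'
#' @param set One of `"PRE"`, `"INTRA"`, `"DELTA"`, `"ALL"`.
#' @param include_clinical Append the 7 clinical covariates.
#' @return Character vector of column names.
#' @export
feature_set_columns <- function(set = c("PRE", "INTRA", "DELTA", "ALL"),
                                include_clinical = FALSE) {
  set <- match.arg(set)
  feats <- imaging_feature_names()
  cols <- switch(set,
    PRE = paste0("PRE_", feats),
    INTRA = paste0("INTRA_", feats),
    DELTA = paste0("delta_", feats),
    ALL = c(paste0("PRE_", feats), paste0("INTRA_", feats),
            paste0("delta_", feats)))
  if (include_clinical) cols <- c(cols, clinical_covariate_names())
  cols
}

#' Dichotomize survival outcomes at a horizon
#'
#' For the logistic models the outcome is event-within-horizon; patients
#' censored before the horizon without an event carry no 2-year label and
#' are excluded.
#'
#' @param time,event Follow-up time and event indicator.
#' @param horizon Dichotomization horizon (default 2 years).
#' @return Integer vector: 1 event within horizon, 0 event-free at horizon,
#'   `NA` censored before horizon.
#' @export
dichotomize_outcome <- function(time, event, horizon = 2) {
  ifelse(event == 1 & time <= horizon, 1L,
         ifelse(time >= horizon, 0L, NA_integer_))
}
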