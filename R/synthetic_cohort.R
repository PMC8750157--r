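# Synthetic phantoms and cohorts with known ground truth.
#
# The generator emulates the study design the analysis pipeline targets:
# paired pretreatment / early-intratreatment multiparametric imaging
# (10-b-value DWI with Rician noise, SPGR dynamic DCE series driven by a
# forward Tofts model under the population AIF, FDG-PET lesions on a
# 4x4x4 mm grid with local background), two-observer delineations, and
# censored 2-year outcomes generated from a known linear-logistic predictor.
# Every generator is seed-reproducible and serializes its truth so that
# recovery can be tested downstream.

#' Rician noise
#'
#' Magnitude-image noise model: the noisy signal is
#' `sqrt((S + n1)^2 + n2^2)` with `n1, n2 ~ N(0, sigma)`.
#'
#' @param signal Noiseless signal values.
#' @param sigma Noise standard deviation per channel (0 = no noise).
#' @return Noisy magnitudes.
#' @export
rician_noise <- function(signal, sigma) {
  if (sigma < 0) stop("'sigma' must be >= 0")
  if (sigma == 0) return(signal)
  n <- length(signal)
  sqrt((signal + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

#' Simulate multi-b-value DWI signals
#'
#' Forward bi-exponential IVIM signals for a set of voxels sharing one set of
#' true parameters, with optional Rician noise.
#'
#' @param truth List with `S0`, `f`, `D`, `D_star` (mm^2/s).
#' @param b_values b-values in s/mm^2.
#' @param sigma Rician noise sigma in signal units.
#' @param n_voxels Number of voxels to simulate.
#' @param seed Optional integer seed.
#' @return Matrix `n_voxels x length(b_values)` of signals.
#' @export
simulate_dwi_signals <- function(truth, b_values, sigma = 0, n_voxels = 1L,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  clean <- ivim_signal(b_values, truth$S0, truth$f, truth$D, truth$D_star)
  out <- matrix(rep(clean, each = n_voxels), nrow = n_voxels)
  if (sigma > 0) out[] <- rician_noise(out, sigma)
  out
}

#' Simulate a dynamic DCE signal series with VFA pre-scans
#'
#' Forward chain for one voxel (or a set of voxels sharing truth): Tofts
#' tissue concentration under the population AIF, converted to longitudinal
#' relaxation rate via the relaxivity, then to SPGR signal; variable
#' flip-angle pre-scans are generated from the same `T1_0` and `M0`. The
#' bolus arrives at the end of the baseline frames, so the first
#' `n_baseline` frames carry zero tissue concentration.
#'
#' @param truth List with `Ktrans` (min^-1), `ve`, `T1_0` (ms), `M0`.
#' @param n_frames Number of dynamic frames (default 75).
#' @param frame_duration_s Seconds per frame (default 4.16).
#' @param n_baseline Pre-bolus frames (default 3).
#' @param tr_ms,alpha_deg Dynamic-scan TR (ms) and flip angle (deg).
#' @param vfa_angles_deg Pre-scan flip angles.
#' @param r1 Relaxivity, L mmol^-1 s^-1.
#' @param sigma Gaussian noise sigma in signal units.
#' @param aif_params Population-AIF parameters.
#' @param seed Optional integer seed.
#' @return List with `dynamic` (signal vector), `vfa` (signal per angle),
#'   `times_min`, `ct_true`, `cp`.
#' @export
simulate_dce_series <- function(truth, n_frames = 75, frame_duration_s = 4.16,
                                n_baseline = 3L, tr_ms = 4.8, alpha_deg = 12,
                                vfa_angles_deg = c(2, 5, 10, 15, 20),
                                r1 = 3.5, sigma = 0,
                                aif_params = aif_default_params(),
                                seed = NULL) {
  if (truth$Ktrans < 0 || truth$ve <= 0) stop("invalid Tofts truth")
  if (tr_ms <= 0 || truth$T1_0 <= 0) stop("TR and T1_0 must be positive")
  if (!is.null(seed)) set.seed(seed)
  times <- (seq_len(n_frames) - 1) * frame_duration_s / 60
  bolus <- n_baseline * frame_duration_s / 60
  cp <- population_aif(times, bolus_arrival_min = bolus, params = aif_params)
  ct <- tofts_forward(truth$Ktrans, truth$ve, cp, times)
  R1 <- 1000 / truth$T1_0 + r1 * ct              # s^-1
  sig <- spgr_signal(truth$M0, 1000 / R1, tr_ms, alpha_deg)
  vfa <- spgr_signal(truth$M0, truth$T1_0, tr_ms, vfa_angles_deg)
  if (sigma > 0) {
    sig <- sig + stats::rnorm(length(sig), 0, sigma)
    vfa <- vfa + stats::rnorm(length(vfa), 0, sigma)
  }
  list(dynamic = sig, vfa = vfa, times_min = times, ct_true = ct, cp = cp)
}

# Ellipsoidal lesion mask centered in a grid.
ellipsoid_mask <- function(dims, center, radii) {
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                   z = seq_len(dims[3]))
  d2 <- ((g$x - center[1]) / radii[1])^2 + ((g$y - center[2]) / radii[2])^2 +
        ((g$z - center[3]) / radii[3])^2
  array(d2 <= 1, dims)
}

#' Simulate a PET SUV phantom
#'
#' A spherical lesion of the requested volume on a regular grid (default
#' 4x4x4 mm voxels) with uniform local background, optional Gaussian noise
#' and optional post-reconstruction Gaussian smoothing.
#'
#' @param truth List with `suv_lesion` (lesion SUV), `lesion_volume_ml`.
#' @param dims Grid dimensions (default 24^3).
#' @param spacing Voxel spacing in mm (default 4).
#' @param background Background SUV (>= 0, below lesion SUV).
#' @param sigma Gaussian noise sigma (SUV units).
#' @param smooth_fwhm_mm Optional isotropic Gaussian smoothing FWHM in mm
#'   (0 = none).
#' @param seed Optional integer seed.
#' @return List with `volume` (`image_volume` in SUV), `lesion_mask`
#'   (logical array).
#' @export
simulate_pet_volume <- function(truth, dims = c(24, 24, 24),
                                spacing = c(4, 4, 4), background = 1.5,
                                sigma = 0, smooth_fwhm_mm = 0, seed = NULL) {
  if (truth$suv_lesion <= background || background < 0)
    stop("lesion SUV must exceed background >= 0")
  if (!is.null(seed)) set.seed(seed)
  r_mm <- (3 * truth$lesion_volume_ml * 1000 / (4 * pi))^(1 / 3)
  center <- (dims + 1) / 2
  mask <- ellipsoid_mask(dims, center, r_mm / spacing)
  if (!any(mask)) stop("lesion smaller than one voxel at this spacing")
  if (sum(mask) == prod(dims)) stop("lesion larger than the grid")
  vox <- array(background, dims)
  vox[mask] <- truth$suv_lesion
  if (smooth_fwhm_mm > 0) vox <- gaussian_smooth3(vox, smooth_fwhm_mm, spacing)
  if (sigma > 0) vox <- vox + array(stats::rnorm(length(vox), 0, sigma), dims)
  list(volume = image_volume(vox, spacing = spacing), lesion_mask = mask)
}

# Separable 3-D Gaussian smoothing (reflected edges), FWHM in mm.
gaussian_smooth3 <- function(arr, fwhm_mm, spacing) {
  sd_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / spacing
  for (axis in 1:3) {
    s <- sd_vox[axis]
    if (s < 1e-6) next
    half <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-half:half, sd = s)
    k <- k / sum(k)
    arr <- apply_along(arr, axis, function(v) {
      n <- length(v)
      vp <- c(rev(v[seq_len(half)]), v, rev(v[(n - half + 1):n]))
      stats::filter(vp, k, sides = 2)[(half + 1):(half + n)]
    })
  }
  arr
}

apply_along <- function(arr, axis, fn) {
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  d <- dim(a)
  a <- matrix(a, nrow = d[1])
  a <- apply(a, 2, fn)
  dim(a) <- d
  aperm(a, order(perm))
}

#' Simulate censored 2-year outcomes from a linear-logistic predictor
#'
#' The true model has the same linear-logistic form as the clinical risk
#' calculators: `Y = intercept + sum(coef_i * x_i)`, and the probability of
#' an event within the follow-up horizon is `1 / (1 + exp(-Y))`. Event times
#' are exponential with the rate chosen so that
#' `P(T <= horizon) = 1/(1+exp(-Y))`; administrative censoring is uniform
#' between the horizon and `censor_max_years`.
#'
#' @param features Data frame (or matrix) of predictor values.
#' @param coefficients Named numeric vector; names must match feature
#'   columns.
#' @param intercept Intercept of the linear predictor.
#' @param horizon_years Follow-up horizon (default 2).
#' @param censor_max_years Upper bound of administrative censoring
#'   (default 4).
#' @param seed Optional integer seed.
#' @return Data frame with `time` (years), `event` (0/1), `event_2y`
#'   (event within the horizon, uncensored truth), `linear_predictor`,
#'   `prob_event`.
#' @export
simulate_outcomes <- function(features, coefficients, intercept = 0,
                              horizon_years = 2, censor_max_years = 4,
                              seed = NULL) {
  features <- as.data.frame(features)
  if (!all(names(coefficients) %in% names(features)))
    stop("coefficient names not found in features: ",
         paste(setdiff(names(coefficients), names(features)), collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  x <- as.matrix(features[names(coefficients)])
  Y <- as.numeric(intercept + x %*% coefficients)
  p <- stats::plogis(Y)
  rate <- -log(1 - p) / horizon_years
  n <- length(Y)
  t_event <- ifelse(rate > 0, stats::rexp(n, pmax(rate, 1e-12)), Inf)
  t_cens <- stats::runif(n, horizon_years, censor_max_years)
  data.frame(time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens),
             event_2y = as.integer(t_event <= horizon_years),
             linear_predictor = Y, prob_event = p)
}

#' Perturb an ROI mask to emulate a second observer
#'
#' Random flips of boundary voxels (each boundary voxel, inside or outside
#' the contour, flips independently with probability `magnitude`), keeping
#' the perturbed mask nonempty and above a Dice-overlap floor with the
#' original.
#'
#' @param mask `roi_mask` or logical array.
#' @param magnitude Flip probability for boundary voxels in \[0, 1\]
#'   (default 0.15; 0 returns the mask unchanged).
#' @param dice_floor Minimum allowed Dice overlap (default 0.7); resampled
#'   up to 20 times before erroring.
#' @param seed Optional integer seed.
#' @return An `roi_mask` with `observer_id = 2`.
#' @export
perturb_roi <- function(mask, magnitude = 0.15, dice_floor = 0.7,
                        seed = NULL) {
  m0 <- if (inherits(mask, "roi_mask")) mask$mask else mask
  lesion_id <- if (inherits(mask, "roi_mask")) mask$lesion_id else "primary"
  if (!any(m0)) stop("empty mask")
  if (magnitude < 0 || magnitude > 1) stop("'magnitude' must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (magnitude == 0) return(roi_mask(m0, observer_id = 2L, lesion_id = lesion_id))
  inner_border <- m0 & !erode_mask(m0)
  outer_border <- dilate_mask(m0) & !m0
  cand <- which(inner_border | outer_border)
  for (try in 1:20) {
    m <- m0
    flip <- cand[stats::runif(length(cand)) < magnitude]
    m[flip] <- !m[flip]
    dice <- 2 * sum(m & m0) / (sum(m) + sum(m0))
    if (any(m) && dice >= dice_floor)
      return(roi_mask(m, observer_id = 2L, lesion_id = lesion_id))
  }
  stop("could not perturb mask within the Dice floor")
}

#' Cohort specification
#'
#' Study-design constants and truth distributions for a full synthetic
#' cohort. Defaults mirror the targeted study design: 57 patients, paired
#' PRE/INTRA timepoints, the 10-b-value DWI ladder, a 75-frame 4.16 s DCE
#' acquisition with 3 baseline frames and 2/5/10/15/20 degree VFA pre-scans,
#' and PET on a 4 mm grid. Truth distributions are typical head-and-neck
#' tumor values; intratreatment shifts are illustrative multiplicative
#' factors so that delta features carry signal.
#'
#' @param n_patients Cohort size (default 57).
#' @param seed Integer seed recorded in all outputs.
#' @param dwi_sigma Rician noise sigma relative to S0 (default 0.02,
#'   i.e. SNR 50).
#' @param dce_sigma Gaussian DCE noise in signal units (default 0).
#' @param pet_sigma Gaussian PET noise in SUV (default 0.1).
#' @param observer_magnitude Boundary-flip probability for the simulated
#'   second observer (default 0.15).
#' @param shifts Named list of multiplicative intratreatment shifts applied
#'   to the true parameters (mean values; each patient draws a lognormal
#'   factor around them).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 57, seed = 1, dwi_sigma = 0.02,
                        dce_sigma = 0, pet_sigma = 0.1,
                        observer_magnitude = 0.15,
                        shifts = list(D = 1.2, f = 1.1, Ktrans = 0.85,
                                      ve = 1.1, suv = 0.7, volume = 0.8)) {
  if (n_patients < 2) stop("'n_patients' must be >= 2")
  if (any(c(dwi_sigma, dce_sigma, pet_sigma) < 0)) stop("sigmas must be >= 0")
  structure(list(n_patients = n_patients, seed = seed,
                 dwi_sigma = dwi_sigma, dce_sigma = dce_sigma,
                 pet_sigma = pet_sigma,
                 observer_magnitude = observer_magnitude, shifts = shifts),
            class = "cohort_spec")
}

# Draw patient-level ground truth for one cohort.
draw_cohort_truth <- function(spec) {
  n <- spec$n_patients
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    D = stats::rlnorm(n, log(1.0e-3), 0.15),
    D_star = stats::rlnorm(n, log(20e-3), 0.25),
    f = pmin(pmax(stats::rnorm(n, 0.10, 0.03), 0.01), 0.4),
    S0 = rep(1000, n),
    T1_0 = stats::rlnorm(n, log(1200), 0.10),
    M0 = rep(1000, n),
    Ktrans = stats::rlnorm(n, log(0.25), 0.30),
    ve = pmin(pmax(stats::rnorm(n, 0.35, 0.10), 0.05), 0.9),
    suv_lesion = stats::rlnorm(n, log(9), 0.25),
    suv_background = rep(1.5, n),
    lesion_volume_ml = stats::rlnorm(n, log(8), 0.4),
    age = round(stats::rnorm(n, 63, 8)),
    gender = stats::rbinom(n, 1, 0.72),
    tobacco = stats::rbinom(n, 1, 0.63),
    hpv = stats::rbinom(n, 1, 0.35),
    site = stats::rbinom(n, 1, 0.79),      # 1 oropharynx, 0 hypopharynx
    t_stage = sample(2:4, n, replace = TRUE, prob = c(0.31, 0.26, 0.43)),
    n_stage = stats::rbinom(n, 1, 0.63)    # 1 = N2-N3
  )
}

# Multiplicative intratreatment shift with patient-level lognormal spread.
shift_truth <- function(truth, shifts, sd_log = 0.10) {
  n <- nrow(truth)
  fac <- function(mu) stats::rlnorm(n, log(mu), sd_log)
  intra <- truth
  intra$D <- truth$D * fac(shifts$D)
  intra$D_star <- truth$D_star
  intra$f <- pmin(truth$f * fac(shifts$f), 0.6)
  intra$Ktrans <- truth$Ktrans * fac(shifts$Ktrans)
  intra$ve <- pmin(truth$ve * fac(shifts$ve), 1.2)
  intra$suv_lesion <- pmax(truth$suv_lesion * fac(shifts$suv),
                           truth$suv_background + 1)
  intra$lesion_volume_ml <- pmax(truth$lesion_volume_ml * fac(shifts$volume),
                                 0.5)
  intra
}

#' Simulate a full imaging cohort
#'
#' Draws patient-level ground truth, applies intratreatment shifts, and for
#' each patient and timepoint generates lesion DWI signals, a lesion DCE
#' series with VFA pre-scans, a PET phantom and two observer masks. Images
#' are kept at the lesion-ROI level (a matrix of voxel signal series per
#' modality) to keep cohorts light; the PET stage carries a full phantom
#' grid.
#'
#' @param spec A [cohort_spec()].
#' @param meta An [acquisition_meta()] (b-values, VFA angles, relaxivity).
#' @param n_roi_voxels Voxels per lesion ROI for the MR modalities
#'   (default 40).
#' @param heterogeneity Lognormal sd of intra-lesion parameter spread
#'   (default 0.05).
#' @return List with `spec`, `meta`, `truth` (PRE), `truth_intra`, and
#'   `patients`: per patient a list of `PRE`/`INTRA` entries, each holding
#'   `dwi` (voxel x b matrix), `dce` (list of per-voxel dynamic series and
#'   shared `vfa`, `times_min`, `cp`), `pet` (phantom + masks for two
#'   observers).
#' @export
simulate_cohort <- function(spec = cohort_spec(), meta = acquisition_meta(),
                            n_roi_voxels = 40, heterogeneity = 0.05) {
  set.seed(spec$seed)
  truth <- draw_cohort_truth(spec)
  truth_intra <- shift_truth(truth, spec$shifts)
  patients <- vector("list", spec$n_patients)
  names(patients) <- truth$patient_id
  for (i in seq_len(spec$n_patients)) {
    patients[[i]] <- list(
      PRE = simulate_patient_tp(truth[i, ], spec, meta, n_roi_voxels,
                                heterogeneity),
      INTRA = simulate_patient_tp(truth_intra[i, ], spec, meta, n_roi_voxels,
                                  heterogeneity))
  }
  list(spec = spec, meta = meta, truth = truth, truth_intra = truth_intra,
       patients = patients)
}

# One patient-timepoint: ROI-level DWI + DCE voxel series, PET phantom,
# and two observer masks over a synthetic ROI grid.
simulate_patient_tp <- function(tr, spec, meta, n_roi_voxels, heterogeneity) {
  het <- function(mu, n) mu * stats::rlnorm(n, 0, heterogeneity)
  nv <- n_roi_voxels
  # DWI: per-voxel heterogeneous parameters around the patient truth
  dwi <- t(vapply(seq_len(nv), function(v) {
    rician_noise(ivim_signal(meta$b_values, tr$S0, min(het(tr$f, 1), 0.95),
                             het(tr$D, 1), het(tr$D_star, 1)),
                 spec$dwi_sigma * tr$S0)
  }, numeric(length(meta$b_values))))
  # DCE: per-voxel dynamic series sharing timing and AIF
  dce_vox <- vector("list", nv)
  times <- NULL; cp <- NULL; vfa <- NULL
  for (v in seq_len(nv)) {
    s <- simulate_dce_series(
      list(Ktrans = het(tr$Ktrans, 1), ve = min(het(tr$ve, 1), 1.2),
           T1_0 = tr$T1_0, M0 = tr$M0),
      vfa_angles_deg = meta$vfa_angles_deg, r1 = meta$relaxivity_r1,
      sigma = spec$dce_sigma)
    dce_vox[[v]] <- s$dynamic
    if (v == 1L) { times <- s$times_min; cp <- s$cp; vfa <- s$vfa }
  }
  # PET phantom with two observer seed masks
  pet <- simulate_pet_volume(
    list(suv_lesion = tr$suv_lesion, lesion_volume_ml = tr$lesion_volume_ml),
    background = tr$suv_background, sigma = spec$pet_sigma)
  obs1 <- roi_mask(dilate_mask(pet$lesion_mask, 1L), observer_id = 1L)
  obs2 <- perturb_roi(obs1, magnitude = spec$observer_magnitude)
  # synthetic MR ROI masks: two observers over a notional nv-voxel ROI,
  # realized as index subsets (observer 2 drops/keeps boundary voxels)
  n2 <- max(3L, round(nv * (1 - spec$observer_magnitude / 2)))
  obs2_idx <- sort(sample(seq_len(nv), n2))
  list(dwi = dwi, dce = list(voxels = dce_vox, vfa = vfa, times_min = times,
                             cp = cp),
       pet = list(volume = pet$volume, lesion_mask = pet$lesion_mask,
                  obs1 = obs1, obs2 = obs2),
       mr_obs2_idx = obs2_idx)
}

#' Simulate a feature-level cohort with known prognostic truth
#'
#' Bypasses the imaging stages: draws a patient-by-feature matrix of
#' standard-normal features and generates censored outcomes from a known
#' linear-logistic predictor over a subset of them. Used to calibrate and
#' power-test the modelling stage (null cohorts with `beta = NULL`,
#' recoverable-truth cohorts with nonzero coefficients).
#'
#' @param n_patients Number of patients.
#' @param n_features Number of features (named `F1..Fn`).
#' @param beta Named coefficient vector over feature names (`NULL` = null
#'   cohort, outcome independent of all features).
#' @param intercept Intercept of the linear predictor.
#' @param seed Integer seed.
#' @return List with `features` (data frame) and `outcomes` (from
#'   [simulate_outcomes()]).
#' @export
simulate_feature_cohort <- function(n_patients, n_features = 15,
                                    beta = NULL, intercept = 0, seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n_patients * n_features), n_patients)
  colnames(x) <- paste0("F", seq_len(n_features))
  features <- as.data.frame(x)
  if (is.null(beta)) beta <- stats::setNames(0, "F1")
  outcomes <- simulate_outcomes(features, beta, intercept = intercept)
  list(features = features, outcomes = outcomes)
}

#' Write a simulated cohort to disk
#'
#' Serializes the PET phantoms and masks as NIfTI, acquisition metadata as
#' JSON, and the truth and clinical tables as CSV (the MR stages are
#' ROI-level matrices and are stored as CSV per patient). The seed is
#' recorded in every table.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- cohort$truth; truth$seed <- cohort$spec$seed
  truth_intra <- cohort$truth_intra; truth_intra$seed <- cohort$spec$seed
  utils::write.csv(truth, file.path(dir, "truth_pre.csv"), row.names = FALSE)
  utils::write.csv(truth_intra, file.path(dir, "truth_intra.csv"),
                   row.names = FALSE)
  write_meta(cohort$meta, file.path(dir, "acquisition.json"))
  for (pid in names(cohort$patients)) {
    pdir <- file.path(dir, pid)
    dir.create(pdir, showWarnings = FALSE)
    for (tp in c("PRE", "INTRA")) {
      e <- cohort$patients[[pid]][[tp]]
      write_volume(e$pet$volume, file.path(pdir, paste0("pet_", tp, ".nii.gz")))
      write_volume(e$pet$obs1, file.path(pdir, paste0("mask1_", tp, ".nii.gz")))
      write_volume(e$pet$obs2, file.path(pdir, paste0("mask2_", tp, ".nii.gz")))
      utils::write.csv(as.data.frame(e$dwi),
                       file.path(pdir, paste0("dwi_", tp, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(dir)
}
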