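# Voxelwise ADC and IVIM (intravoxel incoherent motion) fitting, plus ROI
# histogram features.
#
# The IVIM signal model is the bi-exponential
#   S(b) = S0 * ( f * exp(-b * D*) + (1 - f) * exp(-b * D) )
# with tissue diffusion coefficient D, pseudo-diffusion coefficient D* and
# perfusion fraction f. Diffusivities are carried in mm^2/s (so a typical
# tissue D is 1e-3); b-values in s/mm^2.

#' Forward IVIM signal
#'
#' @param b b-values in s/mm^2.
#' @param S0 Signal at b = 0.
#' @param f Perfusion fraction in \[0, 1\].
#' @param D Diffusion coefficient, mm^2/s.
#' @param D_star Pseudo-diffusion coefficient, mm^2/s (ignored when `f = 0`).
#' @return Noiseless signal values.
#' @export
#' @examples
#' ivim_signal(1000, S0 = 1000, f = 0, D = 1e-3, D_star = 0)  # 1000 * exp(-1)
ivim_signal <- function(b, S0, f, D, D_star) {
  if (f < 0 || f > 1) stop("'f' must be in [0, 1]")
  if (D < 0 || D_star < 0 || S0 < 0) stop("parameters must be nonnegative")
  S0 * (f * exp(-b * D_star) + (1 - f) * exp(-b * D))
}

#' Fit the apparent diffusion coefficient
#'
#' Log-linear ordinary least squares of `log(S)` against b over all supplied
#' b-values; ADC is minus the slope.
#'
#' @param signals Signal values (same length as `b_values`).
#' @param b_values b-values in s/mm^2.
#' @return List with `adc` (mm^2/s), `S0`, `status` (`"ok"`/`"failed"`).
#' @export
fit_adc <- function(signals, b_values) {
  stopifnot(length(signals) == length(b_values))
  use <- is.finite(signals) & signals > 0
  if (sum(use) < 2L || length(unique(b_values[use])) < 2L)
    return(list(adc = NA_real_, S0 = NA_real_, status = "failed"))
  fit <- stats::lm.fit(cbind(1, b_values[use]), log(signals[use]))
  list(adc = -unname(fit$coefficients[2]),
       S0 = exp(unname(fit$coefficients[1])),
       status = "ok")
}

#' Fit the IVIM bi-exponential model (segmented)
#'
#' Two-stage segmented fit, the standard stabilization for the weakly
#' identifiable pseudo-diffusion compartment:
#' 1. D and the tissue intercept from a log-linear fit over `b >= b_split`,
#'    where perfusion has decayed away;
#' 2. f from the intercept ratio, `f = 1 - S0_high / S0_all` with `S0_all`
#'    the measured b = 0 signal;
#' 3. D* from a one-parameter bounded least-squares fit over the full series
#'    with D, f and S0 held fixed.
#'
#' Bounds: D in \[0, 4e-3\], D* in \[D, 0.5\] mm^2/s, f in \[0, 1\]. A joint
#' 4-parameter refinement (`joint = TRUE`) polishes all parameters by bounded
#' nonlinear least squares initialized at the segmented estimates.
#'
#' @param signals Full signal series, one value per b.
#' @param b_values b-values in s/mm^2 (e.g. the 10-value ladder).
#' @param b_split Threshold above which perfusion is assumed decayed
#'   (default 300 s/mm^2).
#' @param joint Also run a joint 4-parameter refinement (default FALSE).
#' @return List with `D`, `D_star`, `f`, `S0`, `status`. When the fitted f is
#'   ~0 the pseudo-diffusion coefficient is not identifiable and `D_star` is
#'   `NA`.
#' @export
fit_ivim <- function(signals, b_values, b_split = 300, joint = FALSE) {
  stopifnot(length(signals) == length(b_values))
  failed <- list(D = NA_real_, D_star = NA_real_, f = NA_real_,
                 S0 = NA_real_, status = "failed")
  if (any(!is.finite(signals)) || any(signals <= 0)) return(failed)

  hi <- b_values >= b_split
  if (sum(hi) < 2L) return(failed)
  hi_fit <- fit_adc(signals[hi], b_values[hi])
  if (hi_fit$status != "ok") return(failed)
  D <- min(max(hi_fit$adc, 0), 4e-3)

  S0_all <- signals[which.min(b_values)]
  f <- 1 - hi_fit$S0 / S0_all
  f <- min(max(f, 0), 1)

  D_star <- NA_real_
  if (f > 1e-6) {
    sse <- function(ds)
      sum((signals - ivim_signal(b_values, S0_all, f, D, ds))^2)
    opt <- stats::optimize(sse, lower = D, upper = 0.5)
    D_star <- opt$minimum
  }

  if (joint && f > 1e-6) {
    obj <- function(p) {
      sum((signals - ivim_signal(b_values, p[1], p[2], p[3], p[4]))^2)
    }
    res <- tryCatch(
      stats::optim(c(S0_all, f, D, D_star), obj, method = "L-BFGS-B",
                   lower = c(0, 0, 0, 1e-6), upper = c(Inf, 1, 4e-3, 0.5),
                   control = list(parscale = c(S0_all, 0.1, 1e-3, 1e-2))),
      error = function(e) NULL)
    if (!is.null(res) && res$convergence == 0) {
      S0_all <- res$par[1]; f <- res$par[2]; D <- res$par[3]
      D_star <- max(res$par[4], D)
    }
  }

  list(D = D, D_star = D_star, f = f, S0 = S0_all, status = "ok")
}

#' Voxelwise ADC / IVIM maps over an ROI
#'
#' @param dwi A `dynamic_series`-like 4-D array or `dynamic_series` whose 4th
#'   dimension indexes b-values.
#' @param mask `roi_mask` or logical array selecting voxels to fit.
#' @param b_values b-values matching the 4th dimension.
#' @param ... Passed to [fit_ivim()].
#' @return Data frame with one row per masked voxel: `adc`, `D`, `D_star`,
#'   `f`, `S0`, `status`.
#' @export
fit_ivim_map <- function(dwi, mask, b_values, ...) {
  arr <- if (inherits(dwi, "dynamic_series")) dwi$frames else as.array(dwi)
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  stopifnot(identical(dim(arr)[1:3], dim(m)), dim(arr)[4] == length(b_values))
  idx <- which(m)
  nvox <- prod(dim(arr)[1:3])
  out <- lapply(idx, function(i) {
    sig <- arr[i + (seq_along(b_values) - 1L) * nvox]
    a <- fit_adc(sig, b_values)
    v <- fit_ivim(sig, b_values, ...)
    data.frame(adc = a$adc, D = v$D, D_star = v$D_star, f = v$f,
               S0 = v$S0, status = v$status)
  })
  do.call(rbind, out)
}

#' ROI histogram features
#'
#' Median, skewness and kurtosis of the voxel-value distribution inside an
#' ROI. Skewness is `m3 / m2^1.5` and kurtosis `m4 / m2^2` in the Pearson
#' (non-excess) convention, so a normal distribution has kurtosis 3.
#'
#' @param values Numeric vector of ROI voxel values (n >= 3 for
#'   skewness/kurtosis).
#' @return List with `median`, `skewness`, `kurtosis`, `n_voxels`. With zero
#'   variance the shape statistics are `NA` (flagged via `degenerate = TRUE`)
#'   but the median is still returned.
#' @export
histogram_features <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 1L) stop("no finite values")
  med <- stats::median(values)
  m2 <- mean((values - mean(values))^2)
  if (n < 3L || m2 == 0)
    return(list(median = med, skewness = NA_real_, kurtosis = NA_real_,
                n_voxels = n, degenerate = TRUE))
  m3 <- mean((values - mean(values))^3)
  m4 <- mean((values - mean(values))^4)
  list(median = med, skewness = m3 / m2^1.5, kurtosis = m4 / m2^2,
       n_voxels = n, degenerate = FALSE)
}
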