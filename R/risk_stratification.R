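# Clinical risk calculators and Kaplan-Meier risk-group stratification.
#
# A risk calculator is an intercept plus named coefficients implementing a
# linear-logistic score: Y = intercept + sum(coef_i * x_i),
# p = 1 / (1 + exp(-Y)). The three built-in calculators predict 2-year
# locoregional recurrence, distant metastasis and death from pretreatment
# and delta imaging features (plus clinical covariates for death). The
# calculators are scale-agnostic: they apply the printed affine map to
# whatever predictor values they are given, so inputs must be on the scale
# the coefficients were derived on.

#' Construct a risk calculator
#'
#' @param name Outcome name (`"LRFFS"`, `"DMFS"` or `"OS"`).
#' @param intercept Intercept of the linear predictor.
#' @param coefficients Named numeric vector of predictor coefficients.
#' @return An object of class `risk_calculator`.
#' @export
risk_calculator <- function(name, intercept, coefficients) {
  if (is.null(names(coefficients)) || any(names(coefficients) == ""))
    stop("coefficients must be named")
  if (any(!is.finite(c(intercept, coefficients))))
    stop("intercept and coefficients must be finite")
  structure(list(name = name, intercept = intercept,
                 coefficients = coefficients),
            class = "risk_calculator")
}

#' @export
print.risk_calculator <- function(x, ...) {
  cat(sprintf("<risk_calculator> %s: Y = %.6f +\n", x$name, x$intercept))
  for (nm in names(x$coefficients))
    cat(sprintf("  %+.6f * %s\n", x$coefficients[[nm]], nm))
  invisible(x)
}

#' The three built-in 2-year risk calculators
#'
#' Locoregional-recurrence, distant-metastasis and death risk scores over
#' pretreatment (PRE) and fractional-change (delta) imaging features;
#' the death calculator additionally uses gender (0 female / 1 male), HPV
#' status (0/1) and N-stage (0 = N0-N1, 1 = N2-N3).
#'
#' @return Named list of `risk_calculator` objects (`LRFFS`, `DMFS`, `OS`).
#' @export
hnscc_risk_calculators <- function() {
  list(
    LRFFS = risk_calculator("LRFFS", -2.173498, c(
      PRE_ADC_kurtosis = 0.317326,
      PRE_kep = 0.168844,
      PRE_SUV_peak = 1.469971,
      delta_ADC_skewness = 0.010764,
      delta_f = -0.036035,
      delta_SUV_peak = -0.190617,
      delta_TLG = -0.008579)),
    DMFS = risk_calculator("DMFS", -5.950312, c(
      PRE_ADC_kurtosis = 1.233603,
      PRE_SUV_peak = 0.167255)),
    OS = risk_calculator("OS", -1.387043, c(
      gender = -0.685436,
      hpv = -3.196345,
      n_stage = 0.908168,
      PRE_ADC_skewness = 0.925759,
      PRE_D = -0.138775,
      PRE_f = -0.277885,
      PRE_MATV = 8.640004,
      PRE_SUV_mean = -0.836001,
      PRE_SUV_peak = 1.885920)))
}

#' Apply a risk calculator
#'
#' @param calculator A `risk_calculator`.
#' @param data Data frame (or named list/vector) containing every named
#'   predictor.
#' @return Numeric vector of event probabilities `1 / (1 + exp(-Y))`.
#' @export
apply_calculator <- function(calculator, data) {
  data <- as.data.frame(as.list(data) |> (\(l) l[lengths(l) > 0])(),
                        optional = TRUE)
  missing <- setdiff(names(calculator$coefficients), names(data))
  if (length(missing))
    stop("missing predictors: ", paste(missing, collapse = ", "))
  x <- as.matrix(data[names(calculator$coefficients)])
  Y <- calculator$intercept + as.numeric(x %*% calculator$coefficients)
  stats::plogis(Y)
}

#' Stratify patients into low / medium / high risk groups
#'
#' Fixed probability cut points: low `p < 0.33`, medium `0.33 <= p < 0.66`,
#' high `p >= 0.66`. With `mode = "tertile"` the cohort's own probability
#' tertiles are used instead.
#'
#' @param probabilities Per-patient event probabilities (>= 3 patients).
#' @param mode `"fixed"` (default) or `"tertile"`.
#' @param cuts Cut points for fixed mode (default `c(0.33, 0.66)`).
#' @return List with `group` (factor low/medium/high), `cut_points`.
#' @export
stratify <- function(probabilities, mode = c("fixed", "tertile"),
                     cuts = c(0.33, 0.66)) {
  mode <- match.arg(mode)
  if (length(probabilities) < 3L) stop("need at least 3 patients")
  if (mode == "tertile")
    cuts <- unname(stats::quantile(probabilities, c(1 / 3, 2 / 3)))
  group <- cut(probabilities, breaks = c(-Inf, cuts, Inf),
               labels = c("low", "medium", "high"), right = FALSE)
  list(group = group, cut_points = cuts)
}

#' Kaplan-Meier estimator per risk group
#'
#' Product-limit survival estimate per group with steps at event times.
#'
#' @param time,event Follow-up time and event indicator.
#' @param group Group labels (>= 1 subject per group).
#' @return Data frame with `group`, `time`, `n_risk`, `n_event`, `survival`.
#' @export
km_estimator <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (any(table(group) < 1L)) stop("empty group")
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  strata <- if (is.null(fit$strata)) {
    rep(levels(group)[1], length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  data.frame(group = strata, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, survival = fit$surv)
}

#' Survival probability at a time point from a KM table
#' @param km Result of [km_estimator()].
#' @param group Group label.
#' @param t Time point.
#' @return Estimated S(t) for that group (1 before the first event).
#' @export
km_survival_at <- function(km, group, t) {
  g <- km[km$group == group & km$time <= t, ]
  if (nrow(g) == 0) return(1)
  g$survival[which.max(g$time)]
}

#' Log-rank test across risk groups
#'
#' @param time,event Follow-up time and event indicator (>= 1 event).
#' @param group Group labels (>= 2 nonempty groups).
#' @return List with `chisq`, `df`, `p`.
#' @export
log_rank <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (sum(event) < 1L) stop("need at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  list(chisq = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Sensitivity and specificity of the high-risk group
#'
#' Treats high vs not-high as a binary test of the event:
#' sensitivity = P(high | event), specificity = P(not high | no event).
#'
#' @param group Risk-group labels (factor with a `"high"` level).
#' @param event Binary event indicator.
#' @return List with `sensitivity`, `specificity`.
#' @export
high_risk_sens_spec <- function(group, event) {
  event <- as.integer(event)
  if (sum(event == 1) < 1L || sum(event == 0) < 1L)
    stop("need at least one event and one non-event")
  high <- group == "high"
  list(sensitivity = mean(high[event == 1]),
       specificity = mean(!high[event == 0]))
}
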