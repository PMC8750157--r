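# LASSO prognostic models with repeated cross-validation.
#
# Logistic models score pooled held-out probabilities by AUC; Cox models
# score pooled held-out linear predictors by Harrell's C. The penalty is
# chosen by nested (inner) cross-validation within each training fold, so
# the reported metrics are free of selection optimism. The study design is
# 5 folds x 500 repeats; repeats are configurable for runtime.

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, ties counting one half.
#'
#' @param scores Predicted scores or probabilities.
#' @param labels Binary labels (0/1), both classes present.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Harrell's concordance index
#'
#' Fraction of usable pairs (the member with the shorter follow-up time had
#' an event) in which the higher-risk prediction belongs to the
#' shorter-surviving member; predictor ties count one half.
#'
#' @param lp Linear predictor (higher = higher risk).
#' @param time,event Follow-up time and event indicator.
#' @return C index in \[0, 1\].
#' @export
harrell_c <- function(lp, time, event) {
  n <- length(lp)
  stopifnot(length(time) == n, length(event) == n)
  conc <- 0; ties <- 0; usable <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # the pair is usable iff the earlier time is an observed event
      if (time[i] == time[j]) {
        if (event[i] == 1 && event[j] == 1) {
          usable <- usable + 1; ties <- ties + 1  # no ordering information
        }
        next
      }
      short <- if (time[i] < time[j]) i else j
      long <- if (time[i] < time[j]) j else i
      if (event[short] != 1) next
      usable <- usable + 1
      if (lp[short] > lp[long]) conc <- conc + 1
      else if (lp[short] == lp[long]) ties <- ties + 1
    }
  }
  if (usable == 0) stop("no comparable pairs")
  (conc + 0.5 * ties) / usable
}

# Stratified fold assignment: classes (or event status) spread evenly.
make_folds <- function(strata, k) {
  folds <- integer(length(strata))
  for (lev in unique(strata)) {
    idx <- which(strata == lev)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Repeated cross-validated LASSO logistic regression
#'
#' Within each training fold, features are standardized and the penalty is
#' chosen by inner 5-fold cross-validation (lambda.min by default); held-out
#' predicted probabilities are pooled within a repeat and scored by AUC.
#' The mean and sd are taken across repeats. Folds are stratified by
#' outcome; the final reported coefficients come from a refit on all data
#' at the inner-CV-chosen penalty.
#'
#' @param x Numeric feature matrix (or data frame of numerics).
#' @param y Binary outcome (0/1); rows with `NA` outcome are dropped.
#' @param folds Number of outer folds (default 5).
#' @param repeats Number of repeats (default 500; scale down for quick runs).
#' @param seed Integer seed.
#' @param lambda_rule `"lambda.min"` (default) or `"lambda.1se"`.
#' @return An object of class `cv_result`: `metric` (`"AUC"`), `mean`, `sd`,
#'   `per_repeat`, `selection_frequency`, `final_coefficients`, `n`,
#'   `n_features`.
#' @export
lasso_logistic_cv <- function(x, y, folds = 5, repeats = 500, seed = 1,
                              lambda_rule = c("lambda.min", "lambda.1se")) {
  lambda_rule <- match.arg(lambda_rule)
  x <- as.matrix(x); storage.mode(x) <- "double"
  keep <- !is.na(y) & stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]; y <- as.integer(y[keep])
  if (sum(y == 1) < 5 || sum(y == 0) < 5)
    stop("need at least 5 events and 5 non-events")
  set.seed(seed)
  p <- ncol(x)
  sel <- numeric(p); names(sel) <- colnames(x)
  nfit <- 0
  per_repeat <- numeric(repeats)
  for (r in seq_len(repeats)) {
    fold <- make_folds(y, folds)
    pred <- numeric(length(y))
    for (k in seq_len(folds)) {
      tr <- fold != k
      cvfit <- glmnet::cv.glmnet(x[tr, , drop = FALSE], y[tr],
                                 family = "binomial", nfolds = 5,
                                 standardize = TRUE)
      lam <- cvfit[[lambda_rule]]
      pred[!tr] <- stats::predict(cvfit, x[!tr, , drop = FALSE],
                                  s = lam, type = "response")
      cf <- as.numeric(stats::coef(cvfit, s = lam))[-1]
      sel <- sel + (cf != 0)
      nfit <- nfit + 1
    }
    per_repeat[r] <- auc(pred, y)
  }
  final <- glmnet::cv.glmnet(x, y, family = "binomial", nfolds = 5,
                             standardize = TRUE)
  fc <- as.numeric(stats::coef(final, s = final[[lambda_rule]]))
  names(fc) <- c("(Intercept)", colnames(x))
  structure(list(metric = "AUC", mean = mean(per_repeat),
                 sd = stats::sd(per_repeat), per_repeat = per_repeat,
                 selection_frequency = sel / nfit,
                 final_coefficients = fc, n = length(y), n_features = p),
            class = "cv_result")
}

#' Repeated cross-validated LASSO Cox regression
#'
#' As [lasso_logistic_cv()] with the partial-likelihood deviance driving the
#' inner penalty choice; pooled held-out linear predictors are scored by
#' Harrell's C per repeat. Folds are stratified by event status.
#'
#' @param x Numeric feature matrix.
#' @param time,event Follow-up time and event indicator.
#' @param folds,repeats,seed,lambda_rule As in [lasso_logistic_cv()].
#' @return A `cv_result` with `metric = "C"`.
#' @export
lasso_cox_cv <- function(x, time, event, folds = 5, repeats = 500, seed = 1,
                         lambda_rule = c("lambda.min", "lambda.1se")) {
  lambda_rule <- match.arg(lambda_rule)
  x <- as.matrix(x); storage.mode(x) <- "double"
  keep <- is.finite(time) & !is.na(event) & stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]
  time <- time[keep]; event <- as.integer(event[keep])
  if (sum(event) < 5) stop("need at least 5 events")
  set.seed(seed)
  p <- ncol(x)
  sel <- numeric(p); names(sel) <- colnames(x)
  nfit <- 0
  per_repeat <- numeric(repeats)
  ysurv <- survival::Surv(time, event)
  for (r in seq_len(repeats)) {
    fold <- make_folds(event, folds)
    lp <- numeric(length(time))
    for (k in seq_len(folds)) {
      tr <- fold != k
      cvfit <- glmnet::cv.glmnet(x[tr, , drop = FALSE], ysurv[tr],
                                 family = "cox", nfolds = 5,
                                 standardize = TRUE)
      lam <- cvfit[[lambda_rule]]
      lp[!tr] <- stats::predict(cvfit, x[!tr, , drop = FALSE],
                                s = lam, type = "link")
      cf <- as.numeric(stats::coef(cvfit, s = lam))
      sel <- sel + (cf != 0)
      nfit <- nfit + 1
    }
    per_repeat[r] <- harrell_c(lp, time, event)
  }
  final <- glmnet::cv.glmnet(x, ysurv, family = "cox", nfolds = 5,
                             standardize = TRUE)
  fc <- as.numeric(stats::coef(final, s = final[[lambda_rule]]))
  names(fc) <- colnames(x)
  structure(list(metric = "C", mean = mean(per_repeat),
                 sd = stats::sd(per_repeat), per_repeat = per_repeat,
                 selection_frequency = sel / nfit,
                 final_coefficients = fc, n = length(time), n_features = p),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s = %.3f (sd %.3f), n = %d, %d features\n",
              x$metric, x$mean, x$sd, x$n, x$n_features))
  invisible(x)
}

#' Run the full model-comparison grid
#'
#' One row per combination of outcome (LRFFS, DMFS, OS) x feature set
#' (PRE, INTRA, DELTA, ALL) x clinical-covariate mode (without / with), for
#' both the logistic (AUC at the 2-year dichotomized outcome) and Cox
#' (Harrell's C) model families: 24 rows per family.
#'
#' @param features Feature table from [build_feature_table()].
#' @param outcomes Named list of outcome data frames (`LRFFS`, `DMFS`, `OS`),
#'   each with `time` and `event` aligned to `features` rows.
#' @param family `"logistic"`, `"cox"` or `"both"`.
#' @param folds,repeats,seed Cross-validation settings.
#' @param horizon Dichotomization horizon for the logistic family (years).
#' @return Data frame with columns `outcome`, `feature_set`, `clinical`,
#'   `family`, `metric`, `n`, `n_features`, `mean`, `sd`.
#' @export
model_grid <- function(features, outcomes, family = c("both", "logistic", "cox"),
                       folds = 5, repeats = 25, seed = 1, horizon = 2) {
  family <- match.arg(family)
  fams <- if (family == "both") c("logistic", "cox") else family
  rows <- list()
  for (oc in names(outcomes)) {
    for (fs in c("PRE", "INTRA", "DELTA", "ALL")) {
      for (clin in c(FALSE, TRUE)) {
        cols <- feature_set_columns(fs, include_clinical = clin)
        xm <- as.matrix(features[cols])
        for (fam in fams) {
          # a cell with too few events (tiny cohorts) is reported as NA
          # rather than aborting the grid
          res <- tryCatch(
            if (fam == "logistic") {
              y2 <- dichotomize_outcome(outcomes[[oc]]$time,
                                        outcomes[[oc]]$event, horizon)
              lasso_logistic_cv(xm, y2, folds = folds, repeats = repeats,
                                seed = seed)
            } else {
              lasso_cox_cv(xm, outcomes[[oc]]$time, outcomes[[oc]]$event,
                           folds = folds, repeats = repeats, seed = seed)
            },
            error = function(e) list(metric = if (fam == "logistic") "AUC"
                                     else "C", n = nrow(xm),
                                     n_features = ncol(xm),
                                     mean = NA_real_, sd = NA_real_))
          rows[[length(rows) + 1L]] <- data.frame(
            outcome = oc, feature_set = fs, clinical = clin, family = fam,
            metric = res$metric, n = res$n, n_features = res$n_features,
            mean = res$mean, sd = res$sd)
        }
      }
    }
  }
  do.call(rbind, rows)
}
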