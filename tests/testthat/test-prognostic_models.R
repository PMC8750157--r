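test_that("AUC follows the Mann-Whitney formulation", {
  expect_equal(auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1.0)
  expect_equal(auc(rep(5, 10), rep(0:1, 5)), 0.5)
  set.seed(51)
  s <- rnorm(30); l <- rbinom(30, 1, 0.5)
  l[1] <- 0; l[2] <- 1
  expect_equal(auc(s, l), brute_auc(s, l), tolerance = 1e-12)
  # with ties
  st <- sample(1:5, 30, replace = TRUE)
  expect_equal(auc(st, l), brute_auc(st, l), tolerance = 1e-12)
  expect_error(auc(s, rep(1, 30)), "both classes")
})

test_that("Harrell's C matches brute-force pair enumeration", {
  # predictor equal to -time with all events: perfect concordance
  t <- c(5, 3, 8, 1, 4)
  expect_equal(harrell_c(-t, t, rep(1, 5)), 1.0)
  set.seed(52)
  for (i in 1:3) {
    n <- 20
    lp <- rnorm(n); tt <- rexp(n); ev <- rbinom(n, 1, 0.7)
    expect_equal(harrell_c(lp, tt, ev), brute_harrell_c(lp, tt, ev),
                 tolerance = 1e-12)
    # cross-check against the survival package's concordance
    cs <- survival::concordance(survival::Surv(tt, ev) ~ lp,
                                reverse = TRUE)$concordance
    expect_equal(harrell_c(lp, tt, ev), cs, tolerance = 1e-12)
  }
  # random predictor hovers at 0.5
  set.seed(53)
  cs <- replicate(100, harrell_c(rnorm(30), rexp(30), rbinom(30, 1, 0.8)))
  expect_lt(abs(mean(cs) - 0.5), 0.03)
  expect_error(harrell_c(1:3, rep(1, 3), c(0, 0, 0)), "comparable")
})

test_that("time reversal of a perfect predictor maps C to 1 - C", {
  t <- c(2, 5, 1, 9, 4, 7)
  lp <- -t
  expect_equal(harrell_c(lp, t, rep(1, 6)), 1.0)
  expect_equal(harrell_c(lp, max(t) + 1 - t, rep(1, 6)), 0.0)
})

test_that("repeated-CV LASSO is reproducible and recovers truth", {
  beta <- c(F1 = 1.5, F2 = -1.5, F3 = 1.2)
  coh <- simulate_feature_cohort(120, 10, beta = beta, seed = 54)
  y2 <- dichotomize_outcome(coh$outcomes$time, coh$outcomes$event)
  r1 <- lasso_logistic_cv(coh$features, y2, repeats = 5, seed = 55)
  r2 <- lasso_logistic_cv(coh$features, y2, repeats = 5, seed = 55)
  expect_identical(r1$per_repeat, r2$per_repeat)  # bitwise under the seed
  expect_gt(r1$mean, 0.8)
  expect_true(all(r1$selection_frequency[c("F1", "F2", "F3")] > 0.8))
  expect_lte(max(r1$per_repeat), 1)
  expect_gte(min(r1$per_repeat), 0)
})

test_that("duplicating a feature column leaves pooled AUC within the sd", {
  beta <- c(F1 = 1.5, F2 = -1.2)
  coh <- simulate_feature_cohort(100, 6, beta = beta, seed = 56)
  y2 <- dichotomize_outcome(coh$outcomes$time, coh$outcomes$event)
  base <- lasso_logistic_cv(coh$features, y2, repeats = 10, seed = 57)
  dup <- coh$features
  dup$F1_copy <- dup$F1
  with_dup <- lasso_logistic_cv(dup, y2, repeats = 10, seed = 57)
  expect_lt(abs(with_dup$mean - base$mean),
            2 * max(base$sd, with_dup$sd, 0.02))
})

test_that("LASSO Cox scores a strong single-feature hazard above 0.7", {
  set.seed(58)
  n <- 200
  x <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("F", 1:5)))
  t_event <- rexp(n, 0.2 * exp(log(3) * x[, 1]))  # HR = 3 per unit
  cens <- runif(n, 0.5, 6)
  time <- pmin(t_event, cens); event <- as.integer(t_event <= cens)
  r <- lasso_cox_cv(x, time, event, repeats = 5, seed = 59)
  expect_gt(r$mean, 0.7)
  expect_gt(r$selection_frequency["F1"], 0.8)
  r2 <- lasso_cox_cv(x, time, event, repeats = 5, seed = 59)
  expect_identical(r$per_repeat, r2$per_repeat)
})

test_that("the model grid covers every outcome/set/clinical cell", {
  # synthetic feature table with the full column dictionary
  set.seed(60)
  n <- 60
  cols <- feature_set_columns("ALL", include_clinical = TRUE)
  tab <- as.data.frame(matrix(rnorm(n * length(cols)), n,
                              dimnames = list(NULL, cols)))
  tab$patient_id <- sprintf("P%02d", 1:n)
  outcomes <- lapply(c(LRFFS = 1, DMFS = 2, OS = 3), function(i) {
    set.seed(60 + i)
    data.frame(time = rexp(n, 0.3) + 0.01, event = rbinom(n, 1, 0.6))
  })
  grid <- model_grid(tab, outcomes, family = "logistic", folds = 3,
                     repeats = 1, seed = 61)
  expect_equal(nrow(grid), 24L)
  expect_equal(unname(table(grid$outcome)), rep(8L, 3), ignore_attr = TRUE)
  expect_true(all(grid$mean >= 0 & grid$mean <= 1))
  expect_equal(unique(grid$n_features[grid$feature_set == "ALL" &
                                        grid$clinical]), 52L)
})
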