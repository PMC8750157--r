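test_that("the printed calculators evaluate their logistic form", {
  calcs <- hnscc_risk_calculators()
  zero_lrffs <- setNames(as.list(rep(0, 7)), names(calcs$LRFFS$coefficients))
  p <- apply_calculator(calcs$LRFFS, zero_lrffs)
  expect_equal(p, 1 / (1 + exp(2.173498)), tolerance = 1e-12)
  expect_equal(round(p, 3), 0.102)

  zero_dmfs <- setNames(as.list(rep(0, 2)), names(calcs$DMFS$coefficients))
  p2 <- apply_calculator(calcs$DMFS, zero_dmfs)
  expect_equal(p2, 1 / (1 + exp(5.950312)), tolerance = 1e-12)
  expect_lt(abs(p2 - 0.0026), 2e-4)

  # Y = 0 is the logistic midpoint: solve one predictor to cancel the
  # intercept
  x <- zero_dmfs
  x$PRE_ADC_kurtosis <- 5.950312 / 1.233603
  expect_equal(apply_calculator(calcs$DMFS, x), 0.5, tolerance = 1e-9)

  expect_error(apply_calculator(calcs$LRFFS, list(PRE_SUV_peak = 1)),
               "missing predictors")
})

test_that("calculator probabilities are monotone in each coefficient's sign", {
  calcs <- hnscc_risk_calculators()
  for (calc in calcs) {
    base <- setNames(as.list(rep(0.5, length(calc$coefficients))),
                     names(calc$coefficients))
    p0 <- apply_calculator(calc, base)
    for (nm in names(calc$coefficients)) {
      up <- base; up[[nm]] <- up[[nm]] + 0.1
      dp <- apply_calculator(calc, up) - p0
      expect_equal(sign(dp), sign(calc$coefficients[[nm]]))
    }
  }
})

test_that("risk groups use fixed cut points with the stated boundaries", {
  s <- stratify(c(0.1, 0.5, 0.9))
  expect_equal(as.character(s$group), c("low", "medium", "high"))
  # boundary: exactly 0.33 is medium, exactly 0.66 is high
  b <- stratify(c(0.33, 0.66, 0.2))
  expect_equal(as.character(b$group), c("medium", "high", "low"))
  # partition: group sizes always sum to the cohort size
  set.seed(71)
  for (i in 1:5) {
    p <- runif(40)
    g <- stratify(p)$group
    expect_equal(sum(table(g)), 40)
    expect_false(anyNA(g))
  }
  # tertile mode splits the cohort into thirds
  p <- runif(99)
  g3 <- stratify(p, mode = "tertile")$group
  expect_true(all(table(g3) == 33))
})

test_that("the KM estimator reproduces hand product-limit results", {
  # n = 2, events at t = 1 and 2: S(1) = 1/2, S(2) = 0
  km <- km_estimator(c(1, 2), c(1, 1), c("a", "a"))
  expect_equal(km$survival, c(0.5, 0))
  # no events: S stays 1
  km2 <- km_estimator(c(1, 2, 3), c(0, 0, 0), rep("a", 3))
  expect_true(all(km2$survival == 1))
  # one event at t1 among n = 5, rest censored later: S(t1) = 1 - 1/5
  km3 <- km_estimator(c(1, 2, 2, 2, 2), c(1, 0, 0, 0, 0), rep("a", 5))
  expect_equal(km_survival_at(km3, "a", 1), 0.8)
})

test_that("the log-rank test matches a hand-computed two-group table", {
  # identical groups (duplicated data): no difference
  t0 <- c(1, 2, 3); e0 <- c(1, 1, 0)
  lr0 <- log_rank(c(t0, t0), c(e0, e0), rep(c("a", "b"), each = 3))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)

  # 6-subject example, hand O-E/V arithmetic:
  # group a: events at 1, 2; censored 4. group b: events at 3, 5; censored 6.
  t <- c(1, 2, 4, 3, 5, 6); e <- c(1, 1, 0, 1, 1, 0)
  g <- rep(c("a", "b"), each = 3)
  # risk sets: t=1 (3a,3b) E_a=1/2 V=(3*3*5)/(36*5)=0.25
  # t=2 (2a,3b) E_a=2/5 V=6/25; t=3 (1a,3b) E_a=1/4 V=3/16
  # t=5 (0a,2b) E_a=0 V=0
  Ea <- 1 / 2 + 2 / 5 + 1 / 4 + 0
  V <- 1 * 3 * 3 / 36 + 1 * 2 * 3 / 25 + 1 * 1 * 3 / 16
  chi <- (2 - Ea)^2 / V
  lr <- log_rank(t, e, g)
  expect_equal(lr$chisq, chi, tolerance = 1e-10)
  expect_equal(lr$df, 1L)

  expect_error(log_rank(t, e, rep("a", 6)), "2 groups")
  expect_error(log_rank(t, rep(0, 6), g), "one event")
})

test_that("null log-rank p-values are approximately uniform", {
  set.seed(72)
  ps <- replicate(300, {
    t <- rexp(40); e <- rbinom(40, 1, 0.7); g <- rep(0:1, 20)
    log_rank(t, e, g)$p
  })
  # calibration: empirical rejection near nominal at two levels
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.035)
  expect_lt(abs(mean(ps < 0.5) - 0.5), 0.09)
})

test_that("high-risk sensitivity/specificity match the 2x2 table", {
  g <- factor(c("high", "high", "low", "medium", "low"),
              levels = c("low", "medium", "high"))
  e <- c(1, 1, 0, 0, 0)
  r <- high_risk_sens_spec(g, e)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)

  set.seed(73)
  g2 <- factor(sample(c("low", "medium", "high"), 60, replace = TRUE),
               levels = c("low", "medium", "high"))
  e2 <- rbinom(60, 1, 0.4)
  if (sum(e2) > 0 && sum(1 - e2) > 0) {
    r2 <- high_risk_sens_spec(g2, e2)
    tab_sens <- sum(g2 == "high" & e2 == 1) / sum(e2 == 1)
    tab_spec <- sum(g2 != "high" & e2 == 0) / sum(e2 == 0)
    expect_equal(r2$sensitivity, tab_sens)
    expect_equal(r2$specificity, tab_spec)
  }
  expect_error(high_risk_sens_spec(g, rep(1, 5)), "non-event")
})
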