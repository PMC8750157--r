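test_that("SPGR signal matches the closed form", {
  # linear in M0
  expect_equal(spgr_signal(2, 1000, dce_tr, dce_alpha),
               2 * spgr_signal(1, 1000, dce_tr, dce_alpha))
  # TR >> T1: full recovery, S -> M0 sin(alpha)
  expect_equal(spgr_signal(1, 10, 1e5, 30), sin(30 * pi / 180),
               tolerance = 1e-9)
  # independent scalar evaluation at alpha 12 deg, TR 4.8 ms, T1 1000 ms
  E1 <- exp(-4.8 / 1000)
  a <- 12 * pi / 180
  expect_equal(spgr_signal(1, 1000, 4.8, 12),
               sin(a) * (1 - E1) / (1 - E1 * cos(a)), tolerance = 1e-12)
  expect_error(spgr_signal(1, -5, 4.8, 12), "positive")
  expect_error(spgr_signal(1, 1000, 4.8, 95), "0, 90")
})

test_that("VFA T1 fitting recovers noiseless T1 and is scale-invariant", {
  s <- spgr_signal(1000, 1000, dce_tr, vfa_angles)
  fit <- fit_t1_vfa(s, vfa_angles, dce_tr)
  expect_equal(fit$status, "ok")
  expect_lt(abs(fit$T1_ms - 1000) / 1000, 0.001)

  fit3 <- fit_t1_vfa(3 * s, vfa_angles, dce_tr)
  expect_equal(fit3$T1_ms, fit$T1_ms, tolerance = 1e-6)
  expect_equal(fit3$M0, 3 * fit$M0, tolerance = 1e-4)

  expect_equal(fit_t1_vfa(rep(5, 5), vfa_angles, dce_tr)$status, "failed")
})

test_that("signal-to-concentration inverts the SPGR forward chain", {
  T1_0 <- 1200; M0 <- 1000; r1 <- 3.5
  ct <- c(0, 0, 0, 0.1, 0.4, 0.8, 0.5, 0.3, 0.2, 0.15)
  R1 <- 1000 / T1_0 + r1 * ct
  sig <- spgr_signal(M0, 1000 / R1, dce_tr, dce_alpha)
  t1f <- list(T1_ms = T1_0, M0 = M0, status = "ok")
  conv <- signal_to_concentration(sig, t1f, dce_tr, dce_alpha, r1,
                                  n_baseline = 3)
  expect_equal(conv$concentration_mM, ct, tolerance = 5e-3)
  # baseline frames map to ~0
  expect_lt(max(abs(conv$concentration_mM[1:3])), 1e-10)
  # doubling r1 halves the nonzero concentrations
  conv2 <- signal_to_concentration(sig, t1f, dce_tr, dce_alpha, 2 * r1,
                                   n_baseline = 3)
  expect_equal(conv2$concentration_mM[4:10], ct[4:10] / 2, tolerance = 5e-3)
  # frames identical to baseline -> 0 everywhere
  base <- signal_to_concentration(rep(sig[1], 10), t1f, dce_tr, dce_alpha,
                                  r1, n_baseline = 3)
  expect_equal(base$concentration_mM, rep(0, 10), tolerance = 1e-10)
})

test_that("the population AIF is causal and nonnegative", {
  tt <- seq(0, 6, by = 0.05)
  cp <- population_aif(tt, bolus_arrival_min = 0.5)
  expect_true(all(cp[tt <= 0.5] == 0))
  expect_true(all(cp >= 0))
  expect_gt(max(cp), 1)  # first-pass peak of several mM
})

test_that("tofts_forward matches the constant-input closed form", {
  expect_equal(tofts_forward(0, 0.3, rep(1, 10), 0:9), rep(0, 10))
  # kep is the definitional ratio
  expect_equal(0.2 / 0.4, 0.5)
  # constant Cp on the study's frame grid: < 0.1% of the closed form
  tt <- (0:74) * 4.16 / 60
  ct <- tofts_forward(0.2, 0.4, rep(2, 75), tt)
  closed <- 0.4 * 2 * (1 - exp(-(0.2 / 0.4) * tt))
  expect_lt(max(abs(ct[-1] - closed[-1]) / pmax(closed[-1], 1e-12)), 0.001)
  expect_error(tofts_forward(-0.1, 0.4, rep(1, 5), 0:4), ">= 0")
  expect_error(tofts_forward(0.1, 0, rep(1, 5), 0:4), "positive")
})

test_that("fit_tofts recovers noiseless parameters within 1%", {
  tt <- (0:74) * 4.16 / 60
  cp <- population_aif(tt, bolus_arrival_min = 3 * 4.16 / 60)
  ct <- tofts_forward(0.2, 0.3, cp, tt)
  fit <- fit_tofts(ct, cp, tt)
  expect_equal(fit$status, "ok")
  expect_lt(abs(fit$Ktrans - 0.2) / 0.2, 0.01)
  expect_lt(abs(fit$ve - 0.3) / 0.3, 0.01)
  expect_equal(fit$kep, fit$Ktrans / fit$ve, tolerance = 1e-12)
  expect_false(fit$ve_gt_1)

  # coarse grid-search oracle: the fit is at least as good as any grid point
  sse <- function(K, v) sum((ct - tofts_forward(K, v, cp, tt))^2)
  grid <- expand.grid(K = seq(0.05, 0.5, by = 0.05),
                      v = seq(0.1, 0.6, by = 0.05))
  expect_lte(sse(fit$Ktrans, fit$ve), min(mapply(sse, grid$K, grid$v)) + 1e-8)

  # zero curve -> Ktrans = 0
  z <- fit_tofts(rep(0, 75), cp, tt)
  expect_equal(z$Ktrans, 0)

  # ve > 1 is retained and flagged, not clipped
  ct_hot <- tofts_forward(0.3, 1.3, cp, tt)
  hot <- fit_tofts(ct_hot, cp, tt)
  expect_equal(hot$status, "ok")
  expect_gt(hot$ve, 1)
  expect_true(hot$ve_gt_1)
})

test_that("the scan exclusion rule uses a strict 30% threshold", {
  s31 <- rep(c("failed", "ok"), c(31, 69))
  expect_true(scan_fit_failure_rate(s31)$excluded)
  s30 <- rep(c("failed", "ok"), c(30, 70))
  r30 <- scan_fit_failure_rate(s30)
  expect_false(r30$excluded)
  expect_equal(r30$fraction_failed, 0.30)
  clean <- scan_fit_failure_rate(rep("ok", 50))
  expect_false(clean$excluded)
  expect_equal(clean$fraction_failed, 0)
  expect_error(scan_fit_failure_rate(character(0)), "no voxels")
})

test_that("the full DCE round trip recovers Tofts parameters", {
  truth <- list(Ktrans = 0.2, ve = 0.3, T1_0 = 1200, M0 = 1000)
  s <- simulate_dce_series(truth)
  t1 <- fit_t1_vfa(s$vfa, vfa_angles, dce_tr)
  conc <- signal_to_concentration(s$dynamic, t1, dce_tr, dce_alpha, 3.5, 3)
  fit <- fit_tofts(conc$concentration_mM, s$cp, s$times_min)
  expect_lt(abs(fit$Ktrans - 0.2) / 0.2, 0.02)
  expect_lt(abs(fit$ve - 0.3) / 0.3, 0.02)
  expect_equal(fit$kep, fit$Ktrans / fit$ve, tolerance = 1e-12)
})
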