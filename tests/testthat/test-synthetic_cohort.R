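test_that("forward DWI signals follow the bi-exponential exactly", {
  # mono-exponential limit: f = 0, b*D = 1
  expect_equal(ivim_signal(1000, S0 = 1000, f = 0, D = 1e-3, D_star = 0),
               1000 * exp(-1), tolerance = 1e-12)
  # hand evaluation of the two-compartment sum
  expect_equal(ivim_signal(50, S0 = 1, f = 0.1, D = 1e-3, D_star = 20e-3),
               0.1 * exp(-1) + 0.9 * exp(-0.05), tolerance = 1e-12)
  expect_equal(round(ivim_signal(50, 1, 0.1, 1e-3, 20e-3), 4), 0.8929)
})

test_that("DWI simulation is seed-reproducible and noiseless without sigma", {
  truth <- list(S0 = 1000, f = 0.1, D = 1e-3, D_star = 20e-3)
  a <- simulate_dwi_signals(truth, b_ladder, sigma = 0, n_voxels = 3, seed = 5)
  b <- simulate_dwi_signals(truth, b_ladder, sigma = 0, n_voxels = 3, seed = 5)
  expect_identical(a, b)
  expect_equal(a[1, ], ivim_signal(b_ladder, 1000, 0.1, 1e-3, 20e-3))
  n1 <- simulate_dwi_signals(truth, b_ladder, sigma = 20, n_voxels = 3, seed = 5)
  n2 <- simulate_dwi_signals(truth, b_ladder, sigma = 20, n_voxels = 3, seed = 5)
  expect_identical(n1, n2)
})

test_that("DCE simulation honours baseline frames and determinism", {
  truth <- list(Ktrans = 0, ve = 0.3, T1_0 = 1200, M0 = 1000)
  s <- simulate_dce_series(truth)
  expect_equal(s$ct_true, rep(0, 75))
  expect_equal(s$dynamic, rep(s$dynamic[1], 75))  # constant at baseline

  truth2 <- list(Ktrans = 0.2, ve = 0.3, T1_0 = 1200, M0 = 1000)
  s2 <- simulate_dce_series(truth2)
  expect_equal(s2$ct_true[1:3], rep(0, 3))  # pre-bolus frames are clean
  a <- simulate_dce_series(truth2, sigma = 1, seed = 9)
  b <- simulate_dce_series(truth2, sigma = 1, seed = 9)
  expect_identical(a, b)
})

test_that("constant plasma input drives tissue concentration to ve * c0", {
  tt <- seq(0, 60, by = 0.1)
  ct <- tofts_forward(0.3, 0.4, rep(2, length(tt)), tt)
  expect_equal(ct[length(ct)], 0.4 * 2, tolerance = 1e-6)
})

test_that("PET phantom carries lesion and background values", {
  ph <- simulate_pet_volume(list(suv_lesion = 10, lesion_volume_ml = 8),
                            background = 1, sigma = 0)
  expect_equal(max(ph$volume$voxels), 10)
  expect_equal(ph$volume$voxels[1, 1, 1], 1)  # far corner = background
  # discretized lesion volume within one voxel shell of the request
  vol_vox <- sum(ph$lesion_mask) * 0.064
  shell <- sum(dilate_mask(ph$lesion_mask) & !ph$lesion_mask) * 0.064
  expect_lt(abs(vol_vox - 8), shell)
  a <- simulate_pet_volume(list(suv_lesion = 10, lesion_volume_ml = 8),
                           background = 1, sigma = 0.2, seed = 3)
  b <- simulate_pet_volume(list(suv_lesion = 10, lesion_volume_ml = 8),
                           background = 1, sigma = 0.2, seed = 3)
  expect_identical(a, b)
  expect_error(simulate_pet_volume(list(suv_lesion = 1, lesion_volume_ml = 8),
                                   background = 2), "exceed")
})

test_that("outcome generator matches its linear-logistic truth", {
  f <- data.frame(x = rep(0, 100))
  out <- simulate_outcomes(f, c(x = 0), intercept = 0, seed = 1)
  expect_equal(out$prob_event, rep(0.5, 100))

  # Monte-Carlo event rate at fixed Y vs closed form, 3 standard errors
  n <- 1e5
  f2 <- data.frame(x = rep(1, n))
  for (Y in c(-1, 0.5)) {
    out2 <- simulate_outcomes(f2, c(x = Y), intercept = 0, seed = 42)
    p <- plogis(Y)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(out2$event_2y) - p), 3 * se)
  }

  # deeply negative intercept: no events
  out3 <- simulate_outcomes(f, c(x = 0), intercept = -50, seed = 2)
  expect_equal(sum(out3$event_2y), 0L)
  expect_error(simulate_outcomes(f, c(nope = 1)), "not found")
})

test_that("observer perturbation preserves overlap and reproducibility", {
  m <- ellipsoid <- array(FALSE, c(12, 12, 12))
  m[4:9, 4:9, 4:9] <- TRUE
  same <- perturb_roi(m, magnitude = 0)
  expect_identical(same$mask, m)
  expect_equal(same$observer_id, 2L)
  p1 <- perturb_roi(m, magnitude = 0.15, seed = 4)
  p2 <- perturb_roi(m, magnitude = 0.15, seed = 4)
  expect_identical(p1$mask, p2$mask)
  dice <- 2 * sum(p1$mask & m) / (sum(p1$mask) + sum(m))
  expect_gte(dice, 0.7)
  expect_error(perturb_roi(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("cohort generators are reproducible under a fixed seed", {
  c1 <- simulate_feature_cohort(20, 5, beta = c(F1 = 1), seed = 3)
  c2 <- simulate_feature_cohort(20, 5, beta = c(F1 = 1), seed = 3)
  expect_identical(c1, c2)
  spec <- cohort_spec(n_patients = 2, seed = 6, dwi_sigma = 0.02)
  a <- simulate_cohort(spec, n_roi_voxels = 5)
  b <- simulate_cohort(spec, n_roi_voxels = 5)
  expect_identical(a$truth, b$truth)
  expect_identical(a$patients, b$patients)
})
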