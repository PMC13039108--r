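# fBM diagnostics: velocity autocorrelation closed forms, displacement
# Gaussianity scoring, and the PCA minor-axis drift control.

test_that("velocity autocorrelation matches fGn and noise closed forms", {
  acq <- acquisition_params(n_frames = 300)
  # anti-persistent fBM: vac(1) = 2^(alpha-1) - 1
  trs <- simulate_tracks(120, sim_params(alpha_true = 0.5, D_true = 0.01,
                                         sigma_loc = 0, seed = 3), acq)
  v <- velocity_autocorrelation(trs, acq, max_lag = 5)
  expect_equal(v$vac[1], 1)
  expect_equal(v$vac[2], 2^(0.5 - 1) - 1, tolerance = 0.02)
  # Brownian: independent increments
  trb <- simulate_tracks(120, sim_params(alpha_true = 1, D_true = 0.01,
                                         sigma_loc = 0, seed = 4), acq)
  vb <- velocity_autocorrelation(trb, acq, max_lag = 5)
  expect_lt(abs(vb$vac[2]), 0.02)
  # static spot + localization noise: vac(1) -> -1/2
  trs0 <- simulate_tracks(120, sim_params(alpha_true = 0.5, D_true = 0,
                                          sigma_loc = 0.02, seed = 5), acq)
  v0 <- velocity_autocorrelation(trs0, acq, max_lag = 5)
  expect_equal(v0$vac[2], -0.5, tolerance = 0.02)
})

test_that("displacement CDF separates one-population from mixed-D ensembles", {
  acq <- acquisition_params(n_frames = 200)
  one <- simulate_tracks(60, sim_params(alpha_true = 0.5, D_true = 0.01,
                                        sigma_loc = 0, seed = 11), acq)
  mix <- c(simulate_tracks(30, sim_params(alpha_true = 0.5, D_true = 0.01,
                                          sigma_loc = 0, seed = 12), acq),
           simulate_tracks(30, sim_params(alpha_true = 0.5, D_true = 0.05,
                                          sigma_loc = 0, seed = 13), acq))
  g1 <- displacement_gaussianity(one, acq)
  g2 <- displacement_gaussianity(mix, acq)
  expect_lt(g1$ks_stat, 0.02)
  expect_gt(g2$ks_stat, 3 * g1$ks_stat)
  # symmetric displacements: empirical CDF crosses 0 near 1/2
  below <- mean(g1$displacements < 0)
  expect_equal(below, 0.5, tolerance = 0.02)
})

test_that("identical displacements are flagged degenerate", {
  tr <- new_track(1, 0:9, cbind(seq(0, 0.9, by = 0.1), seq(0, 0.9, by = 0.1)))
  g <- suppressWarnings(displacement_gaussianity(list(tr)))
  expect_true(g$degenerate)
})

test_that("the PCA minor axis cancels linear drift", {
  acq <- acquisition_params(n_frames = 400)
  trs <- simulate_tracks(40, sim_params(alpha_true = 0.5, D_true = 0.01,
                                        sigma_loc = 0,
                                        drift_velocity = c(0.05, 0),
                                        seed = 21), acq)
  a2d <- fit_tracks(trs, acq)$alpha
  a1d <- vapply(trs, function(t) pca_1d_diffusion(t, acq)$alpha, numeric(1))
  expect_gt(median(a2d), 0.6)            # drift inflates the 2D exponent
  expect_lt(abs(median(a1d) - 0.5), 0.1) # minor axis recovers the truth
})

test_that("pure drift is rejected as collinear", {
  tr <- new_track(1, 0:99, cbind((0:99) * 0.01, (0:99) * 0.005))
  expect_error(pca_1d_diffusion(tr, acquisition_params(n_frames = 100)),
               "collinear")
})

test_that("isotropic tracks give comparable minor-axis and 2D exponents", {
  acq <- acquisition_params(n_frames = 500)
  trs <- simulate_tracks(60, sim_params(alpha_true = 0.5, D_true = 0.01,
                                        sigma_loc = 0, seed = 31), acq)
  ratios <- vapply(trs, function(t) pca_1d_diffusion(t, acq)$var_ratio,
                   numeric(1))
  expect_gt(median(ratios), 0.3)  # no dominant axis without drift
  a1d <- vapply(trs, function(t) pca_1d_diffusion(t, acq)$alpha, numeric(1))
  a2d <- fit_tracks(trs, acq)$alpha
  expect_lt(abs(median(a1d) - median(a2d)), 0.1)
})
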