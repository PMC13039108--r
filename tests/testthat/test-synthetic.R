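# The trajectory generator must be exact: fGn covariance, MSD scaling,
# the Brownian and immobile limits, drift, and seed determinism.

test_that("Brownian limit gives i.i.d. Gaussian increments of variance 2*D*dt", {
  acq <- acquisition_params(n_frames = 400)
  trs <- simulate_tracks(50, sim_params(alpha_true = 1, D_true = 0.01,
                                        sigma_loc = 0, seed = 11), acq)
  inc <- unlist(lapply(trs, function(t) diff(t$xy[, 1L])))
  expect_lt(abs(mean(inc)), 2e-3)
  expect_equal(var(inc), 2 * 0.01 * 0.1, tolerance = 0.05)
  # successive increments uncorrelated in the Brownian case
  expect_lt(abs(cor(inc[-1], inc[-length(inc)])), 0.03)
})

test_that("normalized increment autocovariance at lag 1 matches the fGn closed form", {
  # fGn: corr(lag 1) = (2^alpha - 2) / 2
  for (alpha in c(0.3, 0.5)) {
    trs <- simulate_tracks(200, sim_params(alpha_true = alpha, D_true = 0.01,
                                           sigma_loc = 0, seed = 21),
                           acquisition_params(n_frames = 300))
    inc <- do.call(rbind, lapply(trs, function(t) apply(t$xy, 2L, diff)))
    ac <- mean(apply(inc, 2L, function(v)
      mean(v[-1] * v[-length(v)]) / mean(v^2)))
    expect_equal(ac, (2^alpha - 2) / 2, tolerance = 0.02)
  }
})

test_that("empirical MSD matches 2*n*D*(lag*dt)^alpha within Monte-Carlo error", {
  acq <- acquisition_params(n_frames = 64)
  n_tr <- 400
  for (alpha in c(0.3, 0.5, 1.0)) {
    trs <- simulate_tracks(n_tr, sim_params(alpha_true = alpha, D_true = 0.01,
                                            sigma_loc = 0, seed = 31), acq)
    for (lag in c(1L, 5L, 10L)) {
      sq <- unlist(lapply(trs, function(t)
        rowSums((t$xy[-(1:lag), , drop = FALSE] -
                   t$xy[seq_len(64 - lag), , drop = FALSE])^2)))
      theo <- 2 * 2 * 0.01 * (lag * 0.1)^alpha
      se <- sd(sq) / sqrt(n_tr * 10)  # conservative effective count
      expect_lt(abs(mean(sq) - theo), 3 * se + 0.02 * theo)
    }
  }
})

test_that("identical parameters and seed reproduce bit-identical tracks", {
  sp <- sim_params(alpha_true = 0.4, D_true = 0.02, sigma_loc = 0.01,
                   drift_velocity = c(0.01, 0), seed = 77)
  acq <- acquisition_params(n_frames = 100)
  expect_identical(simulate_tracks(3, sp, acq), simulate_tracks(3, sp, acq))
})

test_that("immobile spot with localization noise has flat ETA-MSD at 4*sigma^2", {
  acq <- acquisition_params(n_frames = 200)
  trs <- simulate_tracks(150, sim_params(alpha_true = 0.5, D_true = 0,
                                         sigma_loc = 0.02, seed = 41), acq)
  e <- eta_msd(trs, acq, max_lag = 30)
  # MSD(delta) = 4 sigma^2 in 2D, independent of the lag
  expect_equal(e$msd[1], 4 * 0.02^2, tolerance = 0.05)
  expect_equal(e$msd[30], 4 * 0.02^2, tolerance = 0.05)
})

test_that("drift adds v*t to the trajectory", {
  tr <- simulate_fbm_track(sim_params(alpha_true = 1, D_true = 0, sigma_loc = 0,
                                      drift_velocity = c(0.05, -0.02), seed = 5),
                           acquisition_params(n_frames = 50))
  tsec <- (0:49) * 0.1
  expect_equal(tr$xy[, 1L], 0.05 * tsec)
  expect_equal(tr$xy[, 2L], -0.02 * tsec)
})

test_that("anomalous exponents outside (0, 2) are rejected", {
  expect_error(sim_params(alpha_true = 0), "alpha")
  expect_error(sim_params(alpha_true = 2), "alpha")
  expect_error(sim_params(alpha_true = -0.5), "alpha")
})

test_that("fgn_sample reproduces the fGn autocovariance beyond lag 1", {
  set.seed(61)
  H <- 0.25
  X <- fgn_sample(48, H, n_cols = 3000)
  emp <- tcrossprod(X) / ncol(X)
  k <- 0:4
  theo <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  for (kk in k) {
    idx <- cbind(1:(48 - kk), (1:(48 - kk)) + kk)
    expect_lt(abs(mean(emp[idx]) - theo[kk + 1]), 0.012)
  }
})
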