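# TA-MSD / ETA-MSD formula fidelity against brute-force double loops,
# the power-law fit, and the lag-window rule.

test_that("TA-MSD of the unit square path is [1, 2, 1] um^2", {
  acq <- acquisition_params(dt = 0.1, n_frames = 4)
  tr <- new_track(1, 0:3, matrix(c(0, 1, 1, 0, 0, 0, 1, 1), 4, 2))
  cv <- ta_msd(tr, acq)
  expect_equal(cv$msd, c(1, 2, 1))
  expect_equal(cv$n_pairs, c(3L, 2L, 1L))
  expect_equal(cv$lag_s, c(0.1, 0.2, 0.3))
})

test_that("TA-MSD equals the brute-force double loop, including gapped tracks", {
  set.seed(5)
  acq <- acquisition_params(n_frames = 60)
  for (rep in 1:10) {
    frames <- sort(sample(0:59, sample(20:50, 1)))
    xy <- matrix(rnorm(2 * length(frames)), ncol = 2)
    tr <- new_track(rep, frames, xy)
    cv <- ta_msd(tr, acq)
    expect_equal(cv$msd, brute_ta_msd(frames, xy))
  }
})

test_that("static and ballistic limits behave as expected", {
  acq <- acquisition_params(n_frames = 50)
  static <- new_track(1, 0:49, matrix(1.5, 50, 2))
  expect_true(all(ta_msd(static, acq)$msd == 0))
  # x = v t with v = 1 um/frame: TA-MSD(d) = d^2, fitted alpha = 2
  bal <- new_track(2, 0:49, cbind(0:49, 0))
  cv <- ta_msd(bal, acq)
  expect_equal(cv$msd, (1:49)^2)
  ft <- fit_power_law(cv, n_dims = 2, acq = acq, T_frames = 50)
  expect_equal(ft$alpha, 2, tolerance = 1e-10)
})

test_that("ETA-MSD is the unweighted mean of TA-MSD curves", {
  acq <- acquisition_params(n_frames = 4)
  sq <- new_track(1, 0:3, matrix(c(0, 1, 1, 0, 0, 0, 1, 1), 4, 2))
  # N identical tracks: ETA-MSD equals the single TA-MSD
  e <- eta_msd(list(sq, sq, sq), acq)
  expect_equal(e$msd, c(1, 2, 1))
  # two tracks with TA-MSD(1) of 1.0 and 3.0: mean is 2.0
  sq3 <- new_track(2, 0:3, matrix(sqrt(3) * c(0, 1, 1, 0, 0, 0, 1, 1), 4, 2))
  e2 <- eta_msd(list(sq, sq3), acq)
  expect_equal(e2$msd[1], 2)
  expect_error(eta_msd(list(), acq), "at least one")
})

test_that("ETA-MSD of a union is the track-count-weighted mean of subset curves", {
  set.seed(9)
  acq <- acquisition_params(n_frames = 30)
  mk <- function(n) lapply(seq_len(n), function(i)
    new_track(i, 0:29, matrix(cumsum(rnorm(60, sd = 0.1)), ncol = 2)))
  a <- mk(3); b <- mk(5)
  ea <- eta_msd(a, acq); eb <- eta_msd(b, acq)
  eu <- eta_msd(c(a, b), acq)
  expect_equal(eu$msd, (3 * ea$msd + 5 * eb$msd) / 8)
})

test_that("the fit window is max(round(0.10 T), 10), capped at available lags", {
  expect_equal(fit_window(50), 10)
  expect_equal(fit_window(100), 10)
  expect_equal(fit_window(989), 99)
  expect_equal(fit_window(1000), 100)
})

test_that("noiseless power-law curves invert exactly", {
  acq <- acquisition_params(dt = 0.1)
  mk_curve <- function(msd_fun, n = 100, span = 1000) {
    cv <- data.frame(lag_frames = 1:n, lag_s = (1:n) * 0.1)
    cv$msd <- msd_fun(cv$lag_s); cv$n_pairs <- 1L
    class(cv) <- c("msd_curve", "data.frame")
    attr(cv, "span") <- span
    cv
  }
  # MSD = 2*2*0.05*t^0.5 -> alpha 0.5, D 0.05 (2D)
  ft <- fit_power_law(mk_curve(function(t) 2 * 2 * 0.05 * t^0.5), 2, acq)
  expect_equal(ft$alpha, 0.5, tolerance = 1e-12)
  expect_equal(ft$D, 0.05, tolerance = 1e-12)
  expect_equal(ft$fit_lags, c(1L, 100L))
  # Brownian: MSD = 4 D t with D = 0.01
  ft2 <- fit_power_law(mk_curve(function(t) 4 * 0.01 * t), 2, acq)
  expect_equal(ft2$alpha, 1, tolerance = 1e-12)
  expect_equal(ft2$D, 0.01, tolerance = 1e-12)
  # 1D convention: MSD = 2 D t^alpha
  ft3 <- fit_power_law(mk_curve(function(t) 2 * 0.02 * t^0.7), 1, acq)
  expect_equal(ft3$alpha, 0.7, tolerance = 1e-12)
  expect_equal(ft3$D, 0.02, tolerance = 1e-12)
})

test_that("degenerate inputs error cleanly", {
  acq <- acquisition_params(n_frames = 10)
  expect_error(ta_msd(new_track(1, 0, matrix(0, 1, 2)), acq), "at least 2")
  flat <- new_track(1, 0:9, matrix(2, 10, 2))
  cv <- ta_msd(flat, acq)
  expect_error(suppressMessages(fit_power_law(cv, 2, acq, T_frames = 10)),
               "fewer than 3")
})
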