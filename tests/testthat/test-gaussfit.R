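# Bounded 2D Gaussian refinement: accuracy on analytic fixtures, the
# fallback rule, bound enforcement, and per-frame bookkeeping.

test_that("noiseless Gaussian is recovered to fitter precision", {
  img <- analytic_frame(80, 80, matrix(c(40.30, 40.70), 1, 2), 1.2, 500, 100)
  ft <- refine_spot(img, c(40, 41))
  expect_true(ft$success)
  expect_equal(ft$source, "gaussian-fit")
  expect_lt(abs(ft$x - 40.30), 0.01)
  expect_lt(abs(ft$y - 40.70), 0.01)
  expect_equal(ft$sigma_psf, 1.2, tolerance = 0.01)
  expect_equal(ft$amplitude, 500, tolerance = 1)
  expect_equal(ft$background, 100, tolerance = 1)
  # independent route: unbounded least squares on the same 9x9 patch
  patch <- img[38:46, 37:45]   # rows = y 37..45, cols = x 36..44
  xg <- rep(36:44, each = 9); yg <- rep(37:45, times = 9)
  ora <- nls(z ~ bg + amp * exp(-((xg - x)^2 + (yg - y)^2) / (2 * s^2)),
             data = data.frame(z = as.vector(patch), xg = xg, yg = yg),
             start = list(x = 40, y = 41, s = 1.5, amp = 400, bg = 90),
             control = nls.control(maxiter = 200, scaleOffset = 1))
  expect_equal(unname(coef(ora)[c("x", "y")]), c(ft$x, ft$y),
               tolerance = 1e-4)
})

test_that("refinement RMSE stays below 0.1 px at amplitude 300 with readout noise 10", {
  set.seed(23)
  errs <- unlist(replicate(40, {
    cx <- 30 + runif(1) - 0.5; cy <- 30 + runif(1) - 0.5
    img <- analytic_frame(60, 60, matrix(c(cx, cy), 1, 2), 1.5, 300, 100) +
      matrix(rnorm(3600, sd = 10), 60, 60)
    ft <- refine_spot(img, c(round(cx), round(cy)))
    c(ft$x - cx, ft$y - cy)
  }, simplify = FALSE))
  expect_lt(sqrt(mean(errs^2)), 0.1)
})

test_that("flat patches fall back to the initial coordinate", {
  ft <- refine_spot(matrix(100, 20, 20), c(10, 10))
  expect_false(ft$success)
  expect_equal(ft$source, "fallback-initial")
  expect_equal(c(ft$x, ft$y), c(10, 10))
})

test_that("a spot wider than the sigma bound is rejected at the bounds", {
  img <- analytic_frame(80, 80, matrix(c(40, 40), 1, 2), 5.0, 300, 100)
  ft <- refine_spot(img, c(40, 40))
  expect_false(ft$success)
  expect_equal(c(ft$x, ft$y), c(40, 40))
})

test_that("patches at the image edge are flagged as padded", {
  img <- analytic_frame(40, 40, matrix(c(2, 20), 1, 2), 1.5, 300, 100)
  ft <- refine_spot(img, c(2, 20))
  expect_true(ft$padded)
})

test_that("refinement is deterministic", {
  set.seed(31)
  img <- analytic_frame(60, 60, matrix(c(30.4, 30.1), 1, 2), 1.5, 300, 100) +
    matrix(rnorm(3600, sd = 10), 60, 60)
  expect_identical(refine_spot(img, c(30, 30)), refine_spot(img, c(30, 30)))
})

test_that("refine_track yields one fit per frame with flags preserved", {
  acq <- acquisition_params(n_frames = 6, pixel_size = 0.1)
  stack <- array(100, dim = c(40, 40, 6))
  for (f in 1:4)  # frames 0-3 have a spot; 4-5 are flat -> fallback
    stack[, , f] <- analytic_frame(40, 40, matrix(c(20.3, 18.6), 1, 2),
                                   1.5, 300, 100)
  track_px <- data.frame(frame = 0:5, x = 20, y = 19)
  res <- refine_track(stack, track_px, acq = acq, track_id = 7)
  expect_equal(nrow(res$fits), 6L)
  expect_equal(res$fits$success, c(rep(TRUE, 4), FALSE, FALSE))
  expect_equal(res$fits$source[5:6], rep("fallback-initial", 2))
  # fallback frames keep the input coordinate exactly (in um)
  expect_equal(res$track$xy[5:6, 1L], rep(20 * 0.1, 2))
  # fitted frames land on the true centre
  expect_equal(res$track$xy[1:4, 1L], rep(20.3 * 0.1, 4), tolerance = 1e-3)
})

test_that("a track whose every fit fails returns the input coordinates exactly", {
  acq <- acquisition_params(n_frames = 3, pixel_size = 0.05)
  stack <- array(100, dim = c(30, 30, 3))
  track_px <- data.frame(frame = 0:2, x = c(10, 11, 12), y = c(15, 15, 16))
  res <- refine_track(stack, track_px, acq = acq)
  expect_false(any(res$fits$success))
  expect_equal(res$track$xy, cbind(track_px$x, track_px$y) * 0.05)
})
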