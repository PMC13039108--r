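# Exact synthesis of fractional Gaussian noise by circulant embedding
# (Davies-Harte), with a jittered Cholesky fallback should the embedding
# ever fail to be non-negative definite.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Autocovariance of unit-variance fGn with Hurst exponent H at lags 0..n
fgn_acov <- function(n, H) {
  k <- 0:n
  0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
}

#' Sample fractional Gaussian noise exactly
#'
#' Draws `n_cols` independent fGn series of length `n`, each with Hurst
#' exponent `H` and unit marginal variance, by circulant embedding of the
#' fGn covariance. The embedding is exact: the sampled series has the target
#' covariance to machine precision. If the circulant eigenvalues are negative
#' beyond numerical tolerance (does not occur for fGn, but guarded), the
#' function falls back to a Cholesky factorization of the Toeplitz covariance
#' with diagonal jitter and says so via `message()`.
#'
#' Uses the current RNG stream; callers manage seeding.
#'
#' @param n Series length (>= 1).
#' @param H Hurst exponent in (0, 1).
#' @param n_cols Number of independent series to draw.
#' @return An `n` x `n_cols` numeric matrix.
#' @export
fgn_sample <- function(n, H, n_cols = 1L) {
  stopifnot(n >= 1, H > 0, H < 1, n_cols >= 1)
  if (n == 1L) return(matrix(stats::rnorm(n_cols), 1L, n_cols))
  g <- fgn_acov(n, H)
  ce <- c(g[1:n], g[n + 1L], g[n:2])           # circulant first row, length 2n
  lam <- Re(stats::fft(ce))
  m <- length(ce)
  if (min(lam) < -1e-8 * max(lam)) {
    message("circulant embedding not non-negative definite; ",
            "falling back to jittered Cholesky")
    return(fgn_sample_chol(n, H, n_cols))
  }
  lam <- pmax(lam, 0)
  half <- m %/% 2L
  out <- matrix(0, n, n_cols)
  for (j in seq_len(n_cols)) {
    w <- complex(length.out = m)
    w[1L] <- sqrt(lam[1L]) * stats::rnorm(1L)
    w[half + 1L] <- sqrt(lam[half + 1L]) * stats::rnorm(1L)
    k <- 2:half
    a <- stats::rnorm(half - 1L)
    b <- stats::rnorm(half - 1L)
    w[k] <- sqrt(lam[k] / 2) * complex(real = a, imaginary = b)
    w[m + 2L - k] <- Conj(w[k])
    x <- Re(stats::fft(w)) / sqrt(m)
    out[, j] <- x[1:n]
  }
  out
}

fgn_sample_chol <- function(n, H, n_cols) {
  g <- fgn_acov(n - 1L, H)
  cov <- stats::toeplitz(g)
  diag(cov) <- diag(cov) + 1e-10
  L <- t(chol(cov))
  L %*% matrix(stats::rnorm(n * n_cols), n, n_cols)
}

#' Simulate one fractional Brownian motion track
#'
#' Generates a trajectory whose noise-free per-axis displacement variance over
#' a lag of `delta` frames is `2 * D_true * (delta * dt)^alpha_true`, so that
#' the population MSD in `n_dims` dimensions follows
#' `MSD(lag) = 2 * n_dims * D_true * lag^alpha_true` with lag in seconds.
#' Axes are independent. Localization error is appended as i.i.d. Gaussian
#' noise per axis per frame; drift adds `v * t`.
#'
#' @param sim A [sim_params()] object.
#' @param acq An [acquisition_params()] object.
#' @param track_id Identifier for the returned track.
#' @param seed Optional override of `sim$seed` (used when generating many
#'   tracks from one parameter set).
#' @return A [new_track()] object with `acq$n_frames` consecutive frames,
#'   coordinates in um.
#' @export
#' @examples
#' tr <- simulate_fbm_track(sim_params(alpha_true = 0.5, D_true = 0.01),
#'                          acquisition_params(n_frames = 100))
simulate_fbm_track <- function(sim, acq, track_id = 1L, seed = sim$seed) {
  stopifnot(inherits(sim, "sim_params"), inherits(acq, "acquisition_params"))
  with_seed(seed, simulate_fbm_track_impl(sim, acq, track_id))
}

simulate_fbm_track_impl <- function(sim, acq, track_id) {
  n <- acq$n_frames
  d <- acq$n_dims
  H <- sim$alpha_true / 2
  pos <- matrix(0, n, d)
  if (sim$D_true > 0) {
    step_sd <- sqrt(2 * sim$D_true * acq$dt^sim$alpha_true)
    incr <- fgn_sample(n - 1L, H, n_cols = d) * step_sd
    pos[2:n, ] <- apply(incr, 2L, cumsum)
  }
  if (!is.null(sim$drift_velocity)) {
    v <- rep_len(sim$drift_velocity, d)
    tsec <- (seq_len(n) - 1L) * acq$dt
    pos <- pos + outer(tsec, v)
  }
  if (sim$sigma_loc > 0)
    pos <- pos + matrix(stats::rnorm(n * d, sd = sim$sigma_loc), n, d)
  new_track(track_id, frames = 0:(n - 1L), xy = pos,
            pixel_size = acq$pixel_size)
}

#' Simulate an ensemble of fBM tracks
#'
#' Draws `n_tracks` independent trajectories from one parameter set. The
#' whole ensemble is reproducible from `sim$seed`; tracks are generated
#' sequentially from a single RNG stream.
#'
#' @param n_tracks Number of tracks.
#' @inheritParams simulate_fbm_track
#' @param id_offset Added to 1-based track numbering for unique ids across
#'   conditions.
#' @return List of `locus_track` objects.
#' @export
simulate_tracks <- function(n_tracks, sim, acq, id_offset = 0L) {
  stopifnot(n_tracks >= 1)
  with_seed(sim$seed, lapply(seq_len(n_tracks), function(i)
    simulate_fbm_track_impl(sim, acq, track_id = i + id_offset)))
}
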