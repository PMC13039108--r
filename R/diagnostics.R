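# Fractional-Brownian-motion diagnostics and the PCA drift control.
#
# Under fBM the one-frame displacement process is fractional Gaussian noise,
# whose normalized autocorrelation at lag 1 is 2^(alpha - 1) - 1: negative
# (anti-persistent) for alpha < 1, zero for Brownian motion. A static spot
# observed with pure localization noise gives -0.5. Displacements of an fBM
# should also be Gaussian with a variance that scales self-similarly; the
# empirical CDF of pooled one-frame displacements against a matched Gaussian
# quantifies departures.

#' Ensemble velocity autocorrelation
#'
#' Velocities are one-frame displacement vectors (consecutive stored frames
#' only; gaps break the velocity sequence). The autocovariance is averaged
#' over time and tracks and normalized by the lag-0 value.
#'
#' @param tracks List of `locus_track` objects.
#' @param acq An [acquisition_params()] object.
#' @param max_lag Largest lag in frames (default 20).
#' @return data.frame `lag_frames, lag_s, vac, n_pairs` with `vac[lag 0] = 1`.
#'   Tracks contributing fewer than 2 velocities are skipped.
#' @export
velocity_autocorrelation <- function(tracks, acq = acquisition_params(),
                                     max_lag = 20L) {
  sums <- numeric(max_lag + 1L)
  counts <- numeric(max_lag + 1L)
  for (tr in tracks) {
    if (length(tr$frames) < 3L) next
    consec <- which(diff(tr$frames) == 1L)
    if (length(consec) < 2L) next
    v <- tr$xy[consec + 1L, , drop = FALSE] - tr$xy[consec, , drop = FALSE]
    vt <- tr$frames[consec]                     # time index of each velocity
    for (d in 0:max_lag) {
      i <- seq_len(length(consec))
      j <- match(vt + d, vt)
      ok <- !is.na(j)
      if (!any(ok)) next
      sums[d + 1L] <- sums[d + 1L] +
        sum(rowSums(v[i[ok], , drop = FALSE] * v[j[ok], , drop = FALSE]))
      counts[d + 1L] <- counts[d + 1L] + sum(ok)
    }
  }
  if (counts[1L] == 0) stop("no usable velocity pairs")
  ac <- ifelse(counts > 0, sums / counts, NA_real_)
  data.frame(lag_frames = 0:max_lag, lag_s = (0:max_lag) * acq$dt,
             vac = ac / ac[1L], n_pairs = counts)
}

#' Gaussianity of one-frame displacements
#'
#' Pools the X and Y one-frame displacements of all tracks, forms their
#' empirical CDF together with a Gaussian reference of matched mean and
#' variance, and scores the departure with the Kolmogorov-Smirnov statistic
#' (larger = less Gaussian). A warning is raised below 100 pooled
#' displacements; a degenerate (zero-variance) pool is flagged.
#'
#' @param tracks List of `locus_track` objects.
#' @param acq An [acquisition_params()] object (unused numerically; kept for
#'   interface symmetry).
#' @return List with `displacements` (sorted pooled values), `cdf`
#'   (data.frame `x, empirical, gaussian`), `ks_stat`, `mean`, `sd`,
#'   `degenerate`.
#' @export
displacement_gaussianity <- function(tracks, acq = acquisition_params()) {
  disp <- unlist(lapply(tracks, function(tr) {
    consec <- which(diff(tr$frames) == 1L)
    if (length(consec) == 0L) return(numeric())
    as.vector(tr$xy[consec + 1L, , drop = FALSE] -
                tr$xy[consec, , drop = FALSE])
  }))
  if (length(disp) < 100L)
    warning("fewer than 100 pooled displacements; CDF will be coarse")
  x <- sort(disp)
  n <- length(x)
  mu <- mean(x); s <- stats::sd(x)
  degenerate <- !is.finite(s) || s < .Machine$double.eps
  gauss <- if (degenerate) as.numeric(x >= mu) else stats::pnorm(x, mu, s)
  emp_hi <- seq_len(n) / n
  emp_lo <- (seq_len(n) - 1L) / n
  ks <- max(pmax(abs(emp_hi - gauss), abs(emp_lo - gauss)))
  list(displacements = x,
       cdf = data.frame(x = x, empirical = emp_hi, gaussian = gauss),
       ks_stat = ks, mean = mu, sd = if (degenerate) 0 else s,
       degenerate = degenerate)
}

#' Drift-robust 1D diffusion via the PCA minor axis
#'
#' Computes the principal axes of the track's coordinates, projects the
#' positions onto the minor (lowest-variance) axis - the direction
#' perpendicular to the longest axis, which is the one most affected by
#' substrate drift - and runs the TA-MSD power-law fit in one dimension on
#' the projected coordinates.
#'
#' @param track A 2D `locus_track`.
#' @param acq An [acquisition_params()] object.
#' @param var_ratio_min Minimum minor/major eigenvalue ratio below which the
#'   track is considered collinear and rejected (default 1e-6).
#' @return A `motion_fit` with `n_dims = 1`, plus elements `axis` (unit
#'   vector of the minor axis) and `var_ratio`.
#' @export
pca_1d_diffusion <- function(track, acq = acquisition_params(),
                             var_ratio_min = 1e-6) {
  stopifnot(inherits(track, "locus_track"), ncol(track$xy) == 2L)
  cv <- stats::cov(track$xy)
  eg <- eigen(cv, symmetric = TRUE)
  ratio <- eg$values[2L] / eg$values[1L]
  if (!is.finite(ratio) || ratio < var_ratio_min)
    stop("pca_1d_diffusion: track is (near-)collinear; minor axis degenerate")
  minor <- eg$vectors[, 2L]
  proj <- as.vector(track$xy %*% minor)
  tr1 <- new_track(track$track_id, track$frames, matrix(proj, ncol = 1L),
                   pixel_size = track$pixel_size)
  cvv <- ta_msd(tr1, acq, max_lag = fit_window(track_span(tr1)))
  ft <- fit_power_law(cvv, n_dims = 1L, acq = acq,
                      T_frames = track_span(tr1))
  ft$axis <- minor
  ft$var_ratio <- ratio
  ft
}
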