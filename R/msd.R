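# Mean-squared-displacement analysis.
#
# For a trajectory r(t) observed at T discrete times the time-averaged MSD
# at a lag of delta frames is
#     TA-MSD(delta) = 1/(T - delta) * sum_i | r(t_i) - r(t_i + delta) |^2 ,
# and the ensemble time-averaged MSD over N tracks is the unweighted mean
#     ETA-MSD(delta) = 1/N * sum_i TA-MSD_i(delta) .
# With gaps, the average runs over the realized pairs only and the divisor
# is the realized pair count. Curves are fitted with the power law
#     MSD(dt) ~ 2 n D dt^alpha
# by ordinary least squares in log-log space over lags
# 1 .. max(round(0.10 * T), 10) frames.

#' Time-averaged MSD of one track
#'
#' @param track A `locus_track` (1D or 2D, um).
#' @param acq An [acquisition_params()] object (frame interval for the
#'   seconds axis).
#' @param max_lag Largest lag in frames (default: span - 1).
#' @return An `msd_curve`: data.frame `lag_frames, lag_s, msd, n_pairs` with
#'   attribute `kind = "time-averaged"`; lags with no realized pair have
#'   `msd = NA`.
#' @export
ta_msd <- function(track, acq = acquisition_params(), max_lag = NULL) {
  stopifnot(inherits(track, "locus_track"))
  if (length(track$frames) < 2L)
    stop("TA-MSD needs a track with at least 2 detections")
  span <- track_span(track)
  if (is.null(max_lag)) max_lag <- span - 1L
  max_lag <- min(max_lag, span - 1L)
  f0 <- min(track$frames)
  # scatter positions into a frame-indexed matrix; NA rows are gaps
  pos <- matrix(NA_real_, span, ncol(track$xy))
  pos[track$frames - f0 + 1L, ] <- track$xy
  present <- !is.na(pos[, 1L])
  msd <- rep(NA_real_, max_lag)
  npair <- integer(max_lag)
  for (d in seq_len(max_lag)) {
    i <- seq_len(span - d)
    ok <- present[i] & present[i + d]
    npair[d] <- sum(ok)
    if (npair[d] > 0L) {
      sq <- (pos[i + d, , drop = FALSE] - pos[i, , drop = FALSE])^2
      msd[d] <- sum(sq[ok, , drop = FALSE]) / npair[d]
    }
  }
  out <- data.frame(lag_frames = seq_len(max_lag),
                    lag_s = seq_len(max_lag) * acq$dt,
                    msd = msd, n_pairs = npair)
  attr(out, "kind") <- "time-averaged"
  attr(out, "span") <- span
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Ensemble time-averaged MSD of a set of tracks
#'
#' The unweighted mean of the per-track TA-MSD curves; at each lag the mean
#' runs over the tracks that have that lag, and the number of contributing
#' tracks is recorded.
#'
#' @param tracks Non-empty list of `locus_track` objects.
#' @param acq An [acquisition_params()] object.
#' @param max_lag Largest lag in frames (default: largest span - 1).
#' @return An `msd_curve` with `kind = "ensemble"`; `n_tracks` per lag.
#' @export
eta_msd <- function(tracks, acq = acquisition_params(), max_lag = NULL) {
  if (length(tracks) == 0L) stop("ETA-MSD needs at least one track")
  spans <- vapply(tracks, track_span, integer(1L))
  if (is.null(max_lag)) max_lag <- max(spans) - 1L
  curves <- lapply(tracks, function(tr)
    ta_msd(tr, acq, max_lag = min(max_lag, track_span(tr) - 1L)))
  vals <- matrix(NA_real_, max_lag, length(tracks))
  for (k in seq_along(curves)) {
    cv <- curves[[k]]
    vals[cv$lag_frames, k] <- cv$msd
  }
  n_tracks <- rowSums(!is.na(vals))
  msd <- rowMeans(vals, na.rm = TRUE)
  msd[n_tracks == 0L] <- NA_real_
  out <- data.frame(lag_frames = seq_len(max_lag),
                    lag_s = seq_len(max_lag) * acq$dt,
                    msd = msd, n_tracks = n_tracks)
  attr(out, "kind") <- "ensemble"
  attr(out, "span") <- max(spans)
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Lag window used for power-law fitting
#'
#' Either 10% of the maximum track length or at least 10 frames, i.e.
#' `max(round(0.10 * T), 10)`, capped at the available lags.
#'
#' @param T_frames Maximum track length in frames.
#' @return Largest lag (frames) included in the fit.
#' @export
fit_window <- function(T_frames) {
  max(round(0.10 * T_frames), 10L)
}

#' Fit the MSD power law to extract alpha and D
#'
#' Ordinary least squares of `log(MSD)` on `log(lag in seconds)` over the
#' window from [fit_window()]: the slope is the anomalous exponent alpha and
#' `D = exp(intercept) / (2 * n_dims)` in um^2/s^alpha. Non-positive or
#' missing MSD values inside the window are dropped (and counted); fewer
#' than 3 usable lags is an error.
#'
#' @param curve An `msd_curve` from [ta_msd()] or [eta_msd()].
#' @param n_dims Number of spatial dimensions of the underlying coordinates
#'   (2 for image-plane tracks, 1 for projected ones).
#' @param acq An [acquisition_params()] object.
#' @param T_frames Track length governing the window; defaults to the span
#'   recorded on the curve.
#' @return A `motion_fit` list: `alpha`, `D`, `n_dims`, `fit_lags`,
#'   `n_lags_used`, `n_lags_dropped`, `r_squared`, `residual_sd`,
#'   `fit_space = "log-log OLS"`.
#' @export
fit_power_law <- function(curve, n_dims = 2L, acq = acquisition_params(),
                          T_frames = attr(curve, "span")) {
  stopifnot(inherits(curve, "msd_curve"))
  if (is.null(T_frames)) T_frames <- max(curve$lag_frames) + 1L
  wmax <- min(fit_window(T_frames), max(curve$lag_frames))
  sub <- curve[curve$lag_frames <= wmax, , drop = FALSE]
  usable <- is.finite(sub$msd) & sub$msd > 0
  n_dropped <- sum(!usable)
  if (n_dropped > 0L)
    message(sprintf("fit_power_law: dropped %d non-positive/missing lag(s)",
                    n_dropped))
  sub <- sub[usable, , drop = FALSE]
  if (nrow(sub) < 3L)
    stop("fit_power_law: fewer than 3 usable lags in the fit window")
  lx <- log(sub$lag_s)
  ly <- log(sub$msd)
  fit <- stats::lm(ly ~ lx)
  alpha <- unname(stats::coef(fit)[2L])
  D <- exp(unname(stats::coef(fit)[1L])) / (2 * n_dims)
  sst <- sum((ly - mean(ly))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  structure(list(alpha = alpha, D = D, n_dims = as.integer(n_dims),
                 fit_lags = c(1L, wmax), n_lags_used = nrow(sub),
                 n_lags_dropped = n_dropped,
                 r_squared = r2,
                 residual_sd = stats::sd(stats::residuals(fit)),
                 fit_space = "log-log OLS"),
            class = "motion_fit")
}

#' @export
print.motion_fit <- function(x, ...) {
  cat(sprintf(
    "<motion_fit> alpha = %.4f, D = %.5g um^2/s^alpha (%dD, lags %d-%d, R2 = %.3f)\n",
    x$alpha, x$D, x$n_dims, x$fit_lags[1L], x$fit_lags[2L], x$r_squared))
  invisible(x)
}

#' Per-track motion parameters for a set of tracks
#'
#' Convenience wrapper: TA-MSD plus power-law fit per track.
#'
#' @param tracks List of `locus_track` objects.
#' @param acq An [acquisition_params()] object.
#' @param n_dims Dimensionality passed to [fit_power_law()].
#' @return data.frame `track_id, alpha, D, n_dims, fit_lag_max, r2`; tracks
#'   whose fit fails are dropped with a message.
#' @export
fit_tracks <- function(tracks, acq = acquisition_params(), n_dims = 2L) {
  rows <- lapply(tracks, function(tr) {
    res <- tryCatch({
      cv <- ta_msd(tr, acq, max_lag = fit_window(track_span(tr)))
      ft <- fit_power_law(cv, n_dims = n_dims, acq = acq,
                          T_frames = track_span(tr))
      data.frame(track_id = tr$track_id, alpha = ft$alpha, D = ft$D,
                 n_dims = ft$n_dims, fit_lag_max = ft$fit_lags[2L],
                 r2 = ft$r_squared)
    }, error = function(e) NULL)
    res
  })
  failed <- sum(vapply(rows, is.null, logical(1L)))
  if (failed > 0L)
    message(sprintf("fit_tracks: %d track(s) could not be fitted", failed))
  do.call(rbind, rows)
}
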