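# Subpixel spot refinement: bounded 2D Gaussian fitting on a small patch,
# initialized at the tracker's coordinate. Two stages:
#   1. greedy stage — a grid over PSF sigma with the configured step; for
#      each sigma the best amplitude is the linear least-squares solution
#      snapped to the intensity step, with a constant background estimated
#      as the median of the patch border; the (sigma, amplitude) pair with
#      the smallest SSE wins;
#   2. refinement stage — bounded Levenberg-Marquardt least squares over
#      (x, y, sigma, amplitude, background).
# If the fit does not converge, lands on a bound, or moves more than 2 px
# from the initial coordinate, the initial coordinate is kept and the fit is
# flagged as a fallback.

extract_patch <- function(img, cx, cy, size) {
  half <- (size - 1L) %/% 2L
  ci <- round(cy) + 1L            # matrix row of the centre pixel (1-based)
  cj <- round(cx) + 1L
  rows <- (ci - half):(ci + half)
  cols <- (cj - half):(cj + half)
  padded <- any(rows < 1L | rows > nrow(img) | cols < 1L | cols > ncol(img))
  rows <- pmin(pmax(rows, 1L), nrow(img))   # edge replication
  cols <- pmin(pmax(cols, 1L), ncol(img))
  list(patch = img[rows, cols, drop = FALSE],
       x0 = cj - 1L - half, y0 = ci - 1L - half,  # pixel coords of patch[1,1]
       padded = padded)
}

patch_border_median <- function(patch) {
  n <- nrow(patch)
  stats::median(c(patch[1L, ], patch[n, ], patch[2:(n - 1L), 1L],
                  patch[2:(n - 1L), n]))
}

gauss2d_model <- function(xg, yg, x, y, sigma, amp, bg) {
  bg + amp * exp(-((xg - x)^2 + (yg - y)^2) / (2 * sigma^2))
}

#' Refine one spot position by bounded 2D Gaussian fitting
#'
#' @param frame_image 2D matrix of counts.
#' @param init_xy Numeric length-2 initial (x, y) in 0-based pixel
#'   coordinates, typically a detector/linker coordinate.
#' @param settings A [gaussfit_settings()] object.
#' @return A one-row data.frame
#'   `x, y, sigma_psf, amplitude, background, success, source, padded`;
#'   on failure `x, y` equal `init_xy` and `source` is `"fallback-initial"`.
#' @export
refine_spot <- function(frame_image, init_xy, settings = gaussfit_settings()) {
  cx <- init_xy[1L]; cy <- init_xy[2L]
  p <- extract_patch(frame_image, cx, cy, settings$patch_size)
  patch <- p$patch
  n <- settings$patch_size
  xg <- matrix(rep(p$x0 + 0:(n - 1L), each = n), n, n)
  yg <- matrix(rep(p$y0 + 0:(n - 1L), times = n), n, n)

  fallback <- data.frame(x = cx, y = cy, sigma_psf = NA_real_,
                         amplitude = NA_real_, background = NA_real_,
                         success = FALSE, source = "fallback-initial",
                         padded = p$padded)
  rng <- diff(range(patch))
  if (!is.finite(rng) || rng < .Machine$double.eps) return(fallback)
  if (all(patch >= 65535)) return(fallback)

  bg0 <- patch_border_median(patch)
  g0x <- round(cx); g0y <- round(cy)

  # greedy stage: sigma grid with the configured step; closed-form best
  # amplitude per sigma, snapped to the intensity step
  sigmas <- seq(settings$min_sigma, settings$max_sigma, by = settings$sigma_step)
  resid0 <- patch - bg0
  best <- NULL
  for (s in sigmas) {
    shape <- exp(-((xg - g0x)^2 + (yg - g0y)^2) / (2 * s^2))
    a <- sum(shape * resid0) / sum(shape * shape)
    a <- round(a / settings$intensity_step) * settings$intensity_step
    a <- min(max(a, settings$min_intensity), settings$max_intensity)
    sse <- sum((resid0 - a * shape)^2)
    if (is.null(best) || sse < best$sse) best <- list(sigma = s, amp = a, sse = sse)
  }

  dat <- data.frame(z = as.vector(patch), xg = as.vector(xg), yg = as.vector(yg))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ bg + amp * exp(-((xg - x)^2 + (yg - y)^2) / (2 * sigma^2)),
      data = dat,
      start = list(x = cx, y = cy, sigma = best$sigma, amp = best$amp, bg = bg0),
      lower = c(p$x0, p$y0, settings$min_sigma, settings$min_intensity,
                -65535),
      upper = c(p$x0 + n - 1L, p$y0 + n - 1L, settings$max_sigma,
                settings$max_intensity, 65535),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(fallback)
  cf <- stats::coef(fit)
  eps <- 1e-9
  in_bounds <- cf[["sigma"]] > settings$min_sigma + eps &&
    cf[["sigma"]] < settings$max_sigma - eps &&
    cf[["amp"]] > settings$min_intensity + eps &&
    cf[["amp"]] < settings$max_intensity - eps &&
    cf[["x"]] > p$x0 + eps && cf[["x"]] < p$x0 + n - 1L - eps &&
    cf[["y"]] > p$y0 + eps && cf[["y"]] < p$y0 + n - 1L - eps
  moved <- sqrt((cf[["x"]] - cx)^2 + (cf[["y"]] - cy)^2)
  if (!in_bounds || moved >= 2) return(fallback)
  data.frame(x = unname(cf[["x"]]), y = unname(cf[["y"]]),
             sigma_psf = unname(cf[["sigma"]]),
             amplitude = unname(cf[["amp"]]),
             background = unname(cf[["bg"]]),
             success = TRUE, source = "gaussian-fit", padded = p$padded)
}

#' Refine every frame of a linked track
#'
#' Runs [refine_spot()] once per stored frame, initialized at the linker's
#' coordinate for that frame, and returns the refined track in um together
#' with per-frame fit details. Frames whose fit falls back keep the input
#' coordinate exactly.
#'
#' @param stack h x w x n_frames counts array.
#' @param track_px data.frame `frame, x, y` in 0-based pixel coordinates
#'   (one row per stored frame of one track).
#' @param settings A [gaussfit_settings()] object.
#' @param acq An [acquisition_params()] object (pixel size for um
#'   conversion).
#' @param track_id Identifier for the returned track.
#' @return List with `track` (a `locus_track`, um; fitted amplitude stored as
#'   per-frame intensity) and `fits` (per-frame data.frame with the
#'   `success`/`source` flags).
#' @export
refine_track <- function(stack, track_px, settings = gaussfit_settings(),
                         acq = acquisition_params(), track_id = 1L) {
  stopifnot(all(c("frame", "x", "y") %in% names(track_px)))
  fits <- do.call(rbind, lapply(seq_len(nrow(track_px)), function(i) {
    f <- track_px$frame[i]
    ft <- refine_spot(stack[, , f + 1L], c(track_px$x[i], track_px$y[i]),
                      settings)
    cbind(frame = f, ft)
  }))
  trk <- new_track(track_id, fits$frame,
                   cbind(fits$x, fits$y) * acq$pixel_size,
                   intensity = fits$amplitude,
                   pixel_size = acq$pixel_size)
  list(track = trk, fits = fits)
}
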