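#' Acquisition parameters
#'
#' Describes the imaging geometry and timing shared by simulation, rendering
#' and analysis: the frame interval, the pixel size and the number of frames.
#' Defaults correspond to a spinning-disk acquisition at 100 ms per frame,
#' 67 nm pixels, 1000 frames.
#'
#' @param dt Frame interval in seconds. Must be > 0.
#' @param pixel_size Pixel size in micrometres per pixel. Must be > 0.
#' @param n_frames Number of frames. Must be >= 2.
#' @param n_dims Spatial dimensionality of the analysis: 2 for image-plane
#'   coordinates, 1 for projected (e.g. PCA minor-axis) coordinates.
#' @return An object of class `acquisition_params`.
#' @export
#' @examples
#' acquisition_params()                 # 100 ms frames, 67 nm pixels
#' acquisition_params(n_frames = 200)
acquisition_params <- function(dt = 0.1, pixel_size = 0.067,
                               n_frames = 1000L, n_dims = 2L) {
  stopifnot(is.numeric(dt), length(dt) == 1L, dt > 0,
            is.numeric(pixel_size), length(pixel_size) == 1L, pixel_size > 0,
            is.numeric(n_frames), length(n_frames) == 1L, n_frames >= 2,
            n_dims %in% c(1L, 2L))
  structure(list(dt = as.numeric(dt), pixel_size = as.numeric(pixel_size),
                 n_frames = as.integer(n_frames), n_dims = as.integer(n_dims)),
            class = "acquisition_params")
}

#' Simulation parameters for fractional Brownian motion trajectories
#'
#' @param alpha_true Anomalous exponent of the generative fractional Brownian
#'   motion, strictly inside (0, 2). `alpha_true = 1` is ordinary Brownian
#'   motion.
#' @param D_true Generalized diffusion coefficient in um^2/s^alpha (>= 0).
#'   `D_true = 0` together with `sigma_loc > 0` is the immobile,
#'   fixed-cell-like regime.
#' @param sigma_loc Localization error standard deviation per axis, in um.
#' @param drift_velocity Optional constant drift velocity, um/s. A numeric
#'   vector of length 2 (or 1 for 1D), or `NULL` for no drift.
#' @param seed Integer RNG seed; all randomness in the generator derives from
#'   it, so identical parameters give bit-identical trajectories.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(alpha_true = 0.5, D_true = 0.01, sigma_loc = 0.02,
                       drift_velocity = NULL, seed = 1L) {
  stopifnot(is.numeric(alpha_true), length(alpha_true) == 1L,
            alpha_true > 0, alpha_true < 2,
            is.numeric(D_true), length(D_true) == 1L, D_true >= 0,
            is.numeric(sigma_loc), length(sigma_loc) == 1L, sigma_loc >= 0)
  if (!is.null(drift_velocity)) {
    stopifnot(is.numeric(drift_velocity), length(drift_velocity) %in% c(1L, 2L))
    drift_velocity <- as.numeric(drift_velocity)
  }
  structure(list(alpha_true = as.numeric(alpha_true),
                 D_true = as.numeric(D_true),
                 sigma_loc = as.numeric(sigma_loc),
                 drift_velocity = drift_velocity,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Rendering parameters for synthetic image stacks
#'
#' Controls how simulated spots are drawn: an isotropic 2D Gaussian
#' point-spread function on a constant background with optional Poisson shot
#' noise and Gaussian readout noise. Rendered intensities are clipped to the
#' unsigned 16-bit range.
#'
#' @param psf_sigma PSF standard deviation in pixels (> 0).
#' @param amplitude Peak spot intensity above background, in counts (> 0).
#' @param background Mean background level, counts.
#' @param readout_sd Gaussian readout noise standard deviation, counts
#'   (0 disables).
#' @param shot_noise Logical; add Poisson shot noise on the noiseless image.
#' @param image_shape Integer (height, width) in pixels.
#' @return An object of class `render_params`.
#' @export
render_params <- function(psf_sigma = 1.5, amplitude = 300, background = 100,
                          readout_sd = 10, shot_noise = FALSE,
                          image_shape = c(64L, 64L)) {
  stopifnot(psf_sigma > 0, amplitude > 0, background >= 0, readout_sd >= 0,
            length(image_shape) == 2L, all(image_shape >= 8))
  structure(list(psf_sigma = as.numeric(psf_sigma),
                 amplitude = as.numeric(amplitude),
                 background = as.numeric(background),
                 readout_sd = as.numeric(readout_sd),
                 shot_noise = isTRUE(shot_noise),
                 image_shape = as.integer(image_shape)),
            class = "render_params")
}

#' Settings for bounded 2D Gaussian spot refinement
#'
#' Defaults mirror a published spot-refinement dialog: intensity bounded in
#' \[10, 65000\] counts, PSF sigma in \[0.36, 3.60\] pixels, greedy-search steps
#' of 1.0 counts and 0.040 pixels, and a 9x9-pixel fitting patch.
#'
#' @param min_intensity,max_intensity Amplitude bounds, counts above background.
#' @param min_sigma,max_sigma PSF sigma bounds, pixels.
#' @param intensity_step,sigma_step Grid steps for the greedy search stage.
#' @param patch_size Side of the square fitting patch, pixels; must be odd.
#' @return An object of class `gaussfit_settings`.
#' @export
gaussfit_settings <- function(min_intensity = 10, max_intensity = 65000,
                              min_sigma = 0.36, max_sigma = 3.60,
                              intensity_step = 1.0, sigma_step = 0.040,
                              patch_size = 9L) {
  stopifnot(min_intensity < max_intensity, min_sigma < max_sigma,
            intensity_step > 0, sigma_step > 0,
            patch_size %% 2 == 1, patch_size >= 5)
  structure(list(min_intensity = as.numeric(min_intensity),
                 max_intensity = as.numeric(max_intensity),
                 min_sigma = as.numeric(min_sigma),
                 max_sigma = as.numeric(max_sigma),
                 intensity_step = as.numeric(intensity_step),
                 sigma_step = as.numeric(sigma_step),
                 patch_size = as.integer(patch_size)),
            class = "gaussfit_settings")
}

#' Linking parameters for the LAP tracker
#'
#' Defaults follow the tracker settings used for single-locus data: linking
#' max distance 5 px, gap-closing max distance 5 px, max frame gap 3, and a
#' minimum track span of 50 frames.
#'
#' @param max_link_dist Maximum frame-to-frame linking distance, pixels.
#' @param max_gap_dist Maximum gap-closing distance, pixels.
#' @param max_frame_gap Maximum number of consecutive missing frames bridged
#'   by gap closing.
#' @param min_span Minimum span (last - first frame + 1) a track must cover
#'   to be kept.
#' @return An object of class `link_params`.
#' @export
link_params <- function(max_link_dist = 5, max_gap_dist = 5,
                        max_frame_gap = 3L, min_span = 50L) {
  stopifnot(max_link_dist > 0, max_gap_dist > 0,
            max_frame_gap >= 0, min_span >= 1)
  structure(list(max_link_dist = as.numeric(max_link_dist),
                 max_gap_dist = as.numeric(max_gap_dist),
                 max_frame_gap = as.integer(max_frame_gap),
                 min_span = as.integer(min_span)),
            class = "link_params")
}
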