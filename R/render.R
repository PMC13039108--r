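# Rendering of synthetic image stacks: one isotropic 2D Gaussian per spot
# per frame on a constant background, plus optional shot and readout noise.
#
# Coordinate convention used throughout the package: pixel coordinates are
# 0-based with the origin at the centre of the top-left pixel; x indexes
# columns, y indexes rows; frames are 0-based.

render_frame <- function(coords_px, rp) {
  h <- rp$image_shape[1L]; w <- rp$image_shape[2L]
  img <- matrix(rp$background, h, w)
  if (!is.null(coords_px) && nrow(coords_px) > 0L) {
    xs <- 0:(w - 1L); ys <- 0:(h - 1L)
    s2 <- 2 * rp$psf_sigma^2
    for (i in seq_len(nrow(coords_px))) {
      gx <- exp(-(xs - coords_px[i, 1L])^2 / s2)
      gy <- exp(-(ys - coords_px[i, 2L])^2 / s2)
      img <- img + rp$amplitude * outer(gy, gx)
    }
  }
  img
}

#' Render a synthetic image stack from tracks
#'
#' Converts track coordinates from um to pixels with `acq$pixel_size`, draws
#' each spot as an isotropic 2D Gaussian of s.d. `rp$psf_sigma` and peak
#' `rp$amplitude` above a constant background, adds optional Poisson shot
#' noise and Gaussian readout noise, and clips to the unsigned 16-bit range.
#' Spots whose centre falls outside the image are truncated at the boundary
#' (the Gaussian tail inside the frame is still drawn) and flagged in the
#' ground-truth table.
#'
#' @param tracks List of `locus_track` objects (2D, um).
#' @param rp A [render_params()] object.
#' @param acq An [acquisition_params()] object (supplies `pixel_size`; the
#'   number of rendered frames is `acq$n_frames`).
#' @param seed Integer seed for the noise draws.
#' @return A list with `stack` (h x w x n_frames array of counts) and
#'   `ground_truth` (data.frame `track_id,frame,x_um,y_um,x_px,y_px,in_bounds`).
#' @export
render_stack <- function(tracks, rp, acq, seed = 1L) {
  stopifnot(inherits(rp, "render_params"), inherits(acq, "acquisition_params"))
  h <- rp$image_shape[1L]; w <- rp$image_shape[2L]
  nf <- acq$n_frames
  gt <- tracks_to_df(tracks)
  if (nrow(gt) > 0L) {
    gt$x_px <- gt$x_um / acq$pixel_size
    gt$y_px <- gt$y_um / acq$pixel_size
    gt$in_bounds <- gt$x_px >= 0 & gt$x_px <= (w - 1L) &
      gt$y_px >= 0 & gt$y_px <= (h - 1L)
  } else {
    gt <- data.frame(track_id = integer(), frame = integer(),
                     x_um = numeric(), y_um = numeric(),
                     x_px = numeric(), y_px = numeric(), in_bounds = logical())
  }
  stack <- array(0, dim = c(h, w, nf))
  with_seed(seed, {
    for (f in seq_len(nf) - 1L) {
      sub <- gt[gt$frame == f, , drop = FALSE]
      img <- render_frame(as.matrix(sub[, c("x_px", "y_px")]), rp)
      if (rp$shot_noise)
        img <- matrix(stats::rpois(length(img), lambda = pmax(img, 0)), h, w)
      if (rp$readout_sd > 0)
        img <- img + matrix(stats::rnorm(length(img), sd = rp$readout_sd), h, w)
      stack[, , f + 1L] <- pmin(pmax(img, 0), 65535)
    }
  })
  list(stack = stack, ground_truth = gt)
}

#' Write an image stack as a multi-page 16-bit TIFF
#'
#' @param stack h x w x n_frames array of counts in \[0, 65535\].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  pages <- lapply(seq_len(dim(stack)[3L]),
                  function(k) stack[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF into a counts array
#'
#' @param path TIFF file path.
#' @return h x w x n_frames array of counts (16-bit scale).
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1L]])[1:2], length(pages)))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1L]
    arr[, , k] <- pg * 65535
  }
  arr
}
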