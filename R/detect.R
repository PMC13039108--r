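# Spot detection on single frames: scale-normalized Laplacian-of-Gaussian
# response or determinant-of-Hessian response, local maxima above a quality
# threshold, with subpixel refinement of the maximum by separable quadratic
# interpolation.
#
# These detectors follow the standard blob-detection constructions. The
# quality scales are a documented dialect: the LoG quality is the
# scale-normalized response sigma^2 * |laplacian(G * I)| at the maximum (so
# the default threshold of 25 counts is an absolute contrast scale); the
# Hessian quality is the scale-normalized determinant-of-Hessian response
# normalized to [0, 1] by the frame maximum (so the default threshold 0.7 is
# relative). Exact score reproduction of other software is not attempted.

.smooth_cache <- new.env(parent = emptyenv())

smooth_mat <- function(n, sigma) {
  key <- sprintf("%d_%.6f", n, sigma)
  if (!is.null(.smooth_cache[[key]])) return(.smooth_cache[[key]])
  idx <- seq_len(n)
  K <- exp(-outer(idx, idx, "-")^2 / (2 * sigma^2))
  K[abs(outer(idx, idx, "-")) > ceiling(4 * sigma)] <- 0
  K <- K / rowSums(K)
  .smooth_cache[[key]] <- K
  K
}

gaussian_smooth <- function(img, sigma) {
  smooth_mat(nrow(img), sigma) %*% img %*% t(smooth_mat(ncol(img), sigma))
}

# 5-point Laplacian with replicate edges
laplacian <- function(img) {
  h <- nrow(img); w <- ncol(img)
  up <- img[c(1L, seq_len(h - 1L)), ]
  dn <- img[c(seq_len(h - 1L) + 1L, h), ]
  lf <- img[, c(1L, seq_len(w - 1L))]
  rt <- img[, c(seq_len(w - 1L) + 1L, w)]
  up + dn + lf + rt - 4 * img
}

quad_offset <- function(fm, f0, fp) {
  den <- fp + fm - 2 * f0
  if (!is.finite(den) || abs(den) < .Machine$double.eps) return(0)
  off <- (fm - fp) / (2 * den)
  max(min(off, 0.5), -0.5)
}

local_maxima <- function(resp, threshold) {
  h <- nrow(resp); w <- ncol(resp)
  if (h < 3L || w < 3L) return(cbind(row = integer(), col = integer()))
  core <- resp[2:(h - 1L), 2:(w - 1L)]
  is_max <- core > threshold
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    is_max <- is_max & core > resp[2:(h - 1L) + di, 2:(w - 1L) + dj]
  }
  which(is_max, arr.ind = TRUE) + 1L
}

#' Detect candidate spots in one frame
#'
#' Filters the frame with a blob detector at the scale implied by the
#' expected object diameter (`sigma = diameter / (2 * sqrt(2))`), finds local
#' maxima of the response above the quality threshold and refines each
#' maximum to subpixel precision by quadratic interpolation along each axis.
#'
#' @param frame_image 2D numeric matrix of counts.
#' @param diameter_px Expected spot diameter, pixels (default 10).
#' @param method `"log"` (Laplacian of Gaussian) or `"hessian"`
#'   (determinant of Hessian).
#' @param quality_threshold Minimum quality; defaults to 25 for the LoG
#'   response and 0.7 for the frame-normalized Hessian response.
#' @param frame 0-based frame index recorded in the output.
#' @return data.frame `frame, x, y, quality` (0-based pixel coordinates,
#'   subpixel), sorted by descending quality. Empty for flat or subthreshold
#'   frames.
#' @export
detect_spots <- function(frame_image, diameter_px = 10,
                         method = c("log", "hessian"),
                         quality_threshold = NULL, frame = 0L) {
  method <- match.arg(method)
  if (is.null(quality_threshold))
    quality_threshold <- if (method == "log") 25 else 0.7
  sigma <- diameter_px / (2 * sqrt(2))
  sm <- gaussian_smooth(frame_image, sigma)
  if (method == "log") {
    resp <- -sigma^2 * laplacian(sm)
    thr <- quality_threshold
  } else {
    h <- nrow(sm); w <- ncol(sm)
    ixx <- sm[, c(1L, seq_len(w - 1L))] + sm[, c(seq_len(w - 1L) + 1L, w)] - 2 * sm
    iyy <- sm[c(1L, seq_len(h - 1L)), ] + sm[c(seq_len(h - 1L) + 1L, h), ] - 2 * sm
    ix <- (sm[, c(seq_len(w - 1L) + 1L, w)] - sm[, c(1L, seq_len(w - 1L))]) / 2
    ixy <- (ix[c(seq_len(h - 1L) + 1L, h), ] - ix[c(1L, seq_len(h - 1L)), ]) / 2
    resp <- sigma^4 * (ixx * iyy - ixy^2) * sign(-ixx - iyy)
    mx <- max(resp)
    if (mx <= 0) return(empty_candidates())
    resp <- resp / mx
    thr <- quality_threshold
  }
  pk <- local_maxima(resp, thr)
  if (nrow(pk) == 0L) return(empty_candidates())
  out <- data.frame(frame = as.integer(frame),
                    x = numeric(nrow(pk)), y = numeric(nrow(pk)),
                    quality = numeric(nrow(pk)))
  for (k in seq_len(nrow(pk))) {
    i <- pk[k, 1L]; j <- pk[k, 2L]
    dy <- quad_offset(resp[i - 1L, j], resp[i, j], resp[i + 1L, j])
    dx <- quad_offset(resp[i, j - 1L], resp[i, j], resp[i, j + 1L])
    out$x[k] <- (j - 1L) + dx
    out$y[k] <- (i - 1L) + dy
    out$quality[k] <- resp[i, j]
  }
  out[order(-out$quality), , drop = FALSE]
}

empty_candidates <- function() {
  data.frame(frame = integer(), x = numeric(), y = numeric(),
             quality = numeric())
}

#' Detect spots in every frame of a stack
#'
#' @param stack h x w x n_frames counts array.
#' @inheritParams detect_spots
#' @return data.frame of candidates across frames (frame 0-based).
#' @export
detect_stack <- function(stack, diameter_px = 10, method = c("log", "hessian"),
                         quality_threshold = NULL) {
  method <- match.arg(method)
  nf <- dim(stack)[3L]
  res <- lapply(seq_len(nf) - 1L, function(f)
    detect_spots(stack[, , f + 1L], diameter_px, method,
                 quality_threshold, frame = f))
  do.call(rbind, res)
}
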