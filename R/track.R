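#' Construct a track
#'
#' A track is the time-ordered sequence of localizations of one locus:
#' strictly increasing 0-based frame indices and an n x d coordinate matrix
#' in micrometres (d = 2 for image-plane tracks, d = 1 for projected tracks).
#' Missing frames between stored ones are implicit gaps.
#'
#' @param track_id Identifier (integer or character).
#' @param frames Integer vector of 0-based frame indices, strictly increasing.
#' @param xy Numeric matrix (length(frames) x d) of coordinates in um, or a
#'   numeric vector for d = 1.
#' @param intensity Optional per-frame fitted intensity, counts.
#' @param pixel_size Optional um-per-pixel factor recorded for provenance.
#' @return An object of class `locus_track`.
#' @export
new_track <- function(track_id, frames, xy, intensity = NULL,
                      pixel_size = NA_real_) {
  frames <- as.integer(frames)
  if (is.null(dim(xy))) xy <- matrix(as.numeric(xy), ncol = 1L)
  xy <- as.matrix(xy)
  storage.mode(xy) <- "double"
  stopifnot(nrow(xy) == length(frames), ncol(xy) %in% c(1L, 2L))
  if (length(frames) > 1L && any(diff(frames) <= 0L))
    stop("track frames must be strictly increasing")
  if (any(frames < 0L)) stop("track frames must be 0-based non-negative")
  if (!is.null(intensity)) stopifnot(length(intensity) == length(frames))
  structure(list(track_id = track_id, frames = frames, xy = xy,
                 intensity = intensity, pixel_size = as.numeric(pixel_size)),
            class = "locus_track")
}

#' @export
print.locus_track <- function(x, ...) {
  cat(sprintf("<locus_track %s> %d detections, frames %d-%d (span %d), %dD\n",
              as.character(x$track_id), length(x$frames),
              min(x$frames), max(x$frames), track_span(x), ncol(x$xy)))
  invisible(x)
}

#' Track span in frames
#'
#' Span is measured first-to-last detection inclusive, so a track detected in
#' frames 0 and 49 spans 50 frames even if intermediate frames are gaps.
#'
#' @param track A `locus_track`.
#' @return Integer span.
#' @export
track_span <- function(track) {
  as.integer(max(track$frames) - min(track$frames) + 1L)
}

#' Convert a list of tracks to a long data frame
#'
#' @param tracks List of `locus_track` objects.
#' @return A data.frame with columns `track_id`, `frame`, `x_um`, `y_um`
#'   (y omitted for 1D tracks) and `intensity` when present.
#' @export
tracks_to_df <- function(tracks) {
  if (length(tracks) == 0L)
    return(data.frame(track_id = integer(), frame = integer(),
                      x_um = numeric(), y_um = numeric()))
  do.call(rbind, lapply(tracks, function(tr) {
    d <- data.frame(track_id = tr$track_id, frame = tr$frames,
                    x_um = tr$xy[, 1L])
    if (ncol(tr$xy) == 2L) d$y_um <- tr$xy[, 2L]
    if (!is.null(tr$intensity)) d$intensity <- tr$intensity
    d
  }))
}

#' Build tracks from a long data frame
#'
#' @param df Data frame with columns `track_id`, `frame`, `x_um` and
#'   optionally `y_um`, `intensity`.
#' @param pixel_size Recorded um-per-pixel factor.
#' @return List of `locus_track` objects, ordered by first appearance.
#' @export
df_to_tracks <- function(df, pixel_size = NA_real_) {
  stopifnot(all(c("track_id", "frame", "x_um") %in% names(df)))
  ids <- unique(df$track_id)
  lapply(ids, function(id) {
    sub <- df[df$track_id == id, , drop = FALSE]
    o <- order(sub$frame)
    if (any(o != seq_along(o))) {
      warning("frames out of order for track ", id, "; sorting")
      sub <- sub[o, , drop = FALSE]
    }
    xy <- if ("y_um" %in% names(sub)) cbind(sub$x_um, sub$y_um) else
      matrix(sub$x_um, ncol = 1L)
    new_track(id, sub$frame, xy,
              intensity = if ("intensity" %in% names(sub)) sub$intensity,
              pixel_size = pixel_size)
  })
}
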