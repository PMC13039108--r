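# Track file formats: a TrackMate-export-shaped XML dialect
# (<Tracks><particle><detection t= x= y=/></particle></Tracks>, coordinates
# in pixels) and a CSV mirror (track_id,frame,x_um,y_um). Round-trips are
# exact on frames and ids and good to 6 decimals on coordinates.

#' Write tracks to the track-XML dialect
#'
#' One `<particle>` element per track with `<detection t="frame" x="px"
#' y="px"/>` children; coordinates are converted from um to pixels with the
#' track's recorded pixel size (or `pixel_size`).
#'
#' @param tracks List of 2D `locus_track` objects.
#' @param path Output path.
#' @param pixel_size um per pixel used when a track records none.
#' @return `path`, invisibly.
#' @export
write_tracks_xml <- function(tracks, path, pixel_size = 0.067) {
  doc <- xml2::xml_new_root("Tracks",
                            nTracks = as.character(length(tracks)))
  for (tr in tracks) {
    ps <- if (is.finite(tr$pixel_size)) tr$pixel_size else pixel_size
    pnode <- xml2::xml_add_child(doc, "particle",
                                 nSpots = as.character(length(tr$frames)))
    for (i in seq_along(tr$frames)) {
      xml2::xml_add_child(pnode, "detection",
                          t = as.character(tr$frames[i]),
                          x = sprintf("%.6f", tr$xy[i, 1L] / ps),
                          y = sprintf("%.6f", tr$xy[i, 2L] / ps))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read tracks from the track-XML dialect
#'
#' @param path XML file with a `<Tracks>` root.
#' @param acq An [acquisition_params()] object (pixel size for um
#'   conversion).
#' @return List of `locus_track` objects in um. A detection missing a
#'   `t`, `x` or `y` attribute is an error naming the element.
#' @export
read_tracks_xml <- function(path, acq = acquisition_params()) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "Tracks")
    stop("expected <Tracks> root, found <", xml2::xml_name(doc), ">")
  particles <- xml2::xml_find_all(doc, "./particle")
  out <- vector("list", length(particles))
  for (k in seq_along(particles)) {
    dets <- xml2::xml_find_all(particles[[k]], "./detection")
    t <- xml2::xml_attr(dets, "t")
    x <- xml2::xml_attr(dets, "x")
    y <- xml2::xml_attr(dets, "y")
    bad <- which(is.na(t) | is.na(x) | is.na(y))
    if (length(bad))
      stop(sprintf(
        "particle %d: <detection> #%d missing a t/x/y attribute",
        k, bad[1L]))
    o <- order(as.integer(t))
    out[[k]] <- new_track(k, as.integer(t)[o],
                          cbind(as.numeric(x)[o], as.numeric(y)[o]) *
                            acq$pixel_size,
                          pixel_size = acq$pixel_size)
  }
  out
}

#' Write tracks to CSV
#'
#' Header `track_id,frame,x_um,y_um` (frame 0-based), plus `intensity` when
#' present.
#'
#' @param tracks List of `locus_track` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  utils::write.csv(tracks_to_df(tracks), path, row.names = FALSE)
  invisible(path)
}

#' Read tracks from CSV
#'
#' Frames out of order within a track are sorted with a warning.
#'
#' @param path CSV with header `track_id,frame,x_um[,y_um][,intensity]`.
#' @param pixel_size Recorded um-per-pixel factor.
#' @return List of `locus_track` objects.
#' @export
read_tracks_csv <- function(path, pixel_size = NA_real_) {
  df <- utils::read.csv(path)
  df_to_tracks(df, pixel_size = pixel_size)
}

#' Read or write a run configuration
#'
#' The run configuration is a YAML mapping with sections `acquisition`,
#' `simulation`, `render`, `detection`, `linking`, `gaussfit`, `stats`, plus
#' top-level `seed` and `out_dir`; any omitted field takes the package
#' default. [write_run_config()] writes the fully resolved configuration, so
#' write-then-read is the identity.
#'
#' @param path YAML file path.
#' @return For [read_run_config()], a named list of parameter objects
#'   (class `run_config`).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  resolve_run_config(raw)
}

#' @rdname read_run_config
#' @param config A `run_config` (or plain list accepted by
#'   `resolve_run_config()`).
#' @export
write_run_config <- function(config, path) {
  config <- resolve_run_config(unclass(config))
  plain <- list(
    acquisition = unclass(config$acquisition),
    simulation = lapply(unclass(config$simulation), identity),
    render = unclass(config$render),
    detection = config$detection,
    linking = unclass(config$linking),
    gaussfit = unclass(config$gaussfit),
    stats = config$stats,
    conditions = config$conditions,
    seed = config$seed,
    out_dir = config$out_dir)
  plain$render$image_shape <- as.integer(plain$render$image_shape)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname read_run_config
#' @param raw Named list of (possibly partial) configuration sections.
#' @export
resolve_run_config <- function(raw = list()) {
  take <- function(section, ctor) {
    args <- raw[[section]]
    if (is.null(args)) args <- list()
    do.call(ctor, args)
  }
  det <- utils::modifyList(
    list(diameter_px = 10, method = "log", quality_threshold = NULL),
    if (is.null(raw$detection)) list() else raw$detection)
  sts <- utils::modifyList(
    list(metric = "D", p_adjust = "holm", dip_n_boot = 2000L),
    if (is.null(raw$stats)) list() else raw$stats)
  structure(list(
    acquisition = take("acquisition", acquisition_params),
    simulation = take("simulation", sim_params),
    render = take("render", render_params),
    detection = det,
    linking = take("linking", link_params),
    gaussfit = take("gaussfit", gaussfit_settings),
    stats = sts,
    conditions = raw$conditions,
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
    out_dir = if (is.null(raw$out_dir)) "locusmotion-run" else raw$out_dir),
    class = "run_config")
}
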