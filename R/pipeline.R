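# End-to-end orchestration: simulate (or load) image stacks, detect, link,
# filter, refine, fit motion parameters in 2D and on the PCA minor axis,
# and compare conditions. Every run writes its resolved configuration, a
# structured per-stage log and a checksummed manifest beside the outputs,
# so identical configuration + seed reproduces identical artifacts.

pipeline_log <- function(lines, msg) {
  message(msg)
  c(lines, msg)
}

#' Run the full analysis pipeline
#'
#' Stages: simulate tracks per condition -> render image stacks (one locus
#' per region of interest, i.e. per stack) -> detect spots -> LAP-link ->
#' span filter -> Gaussian refinement -> TA-MSD power-law fits (2D and PCA
#' minor-axis 1D) -> group statistics (Kruskal-Wallis + Dunn on the chosen
#' metric, dip test per condition, descriptives). In `"tracks"` mode the
#' imaging stages are skipped and the simulated trajectories are analysed
#' directly.
#'
#' @param config A `run_config` from [read_run_config()] /
#'   [resolve_run_config()]. Conditions are taken from `config$conditions`,
#'   a named list of [sim_params()] overrides (default: a single condition
#'   named `"all"`).
#' @param n_tracks Tracks (regions of interest) per condition.
#' @param mode `"stack"` (render + detect + refine) or `"tracks"`
#'   (trajectory-only).
#' @param write_outputs Write CSV/XML/YAML/JSON artifacts into
#'   `config$out_dir` (default TRUE).
#' @return List with `fits` (per-track data.frame: `condition, track_id,
#'   alpha, D, alpha_1d, D_1d`), `stats` (`group_stats` when >= 2
#'   conditions), `dip` (per-condition dip tests), `descriptives`, `qc`,
#'   `counts` (per-stage), `log`, `manifest`.
#' @export
run_pipeline <- function(config, n_tracks = 12L,
                         mode = c("stack", "tracks"),
                         write_outputs = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "run_config"))
  acq <- config$acquisition
  lg <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  conditions <- config$conditions
  if (is.null(conditions)) conditions <- list(all = list())

  all_fits <- list()
  all_tracks <- list()
  counts <- list()
  for (ci in seq_along(conditions)) {
    cname <- names(conditions)[ci]
    sim <- utils::modifyList(unclass(config$simulation), conditions[[ci]])
    sim$seed <- sim$seed + 1000L * ci + config$seed
    sim <- do.call(sim_params, sim)
    lg <- pipeline_log(lg, sprintf(
      "[simulate] condition '%s': %d tracks, alpha=%.3g D=%.3g seed=%d",
      cname, n_tracks, sim$alpha_true, sim$D_true, sim$seed))
    truth <- stage("simulate",
                   simulate_tracks(n_tracks, sim, acq,
                                   id_offset = 10000L * ci))

    if (mode == "stack") {
      tracks <- vector("list", n_tracks)
      keep <- logical(n_tracks)
      n_cand <- 0L
      centre <- (config$render$image_shape - 1) / 2 * acq$pixel_size
      for (k in seq_len(n_tracks)) {
        tr <- truth[[k]]
        tr$xy <- sweep(tr$xy, 2L, centre[2:1] - tr$xy[1L, ], "+")
        rend <- stage("render",
                      render_stack(list(tr), config$render, acq,
                                   seed = sim$seed + k))
        det <- stage("detect", do.call(detect_stack, c(
          list(rend$stack), config$detection)))
        n_cand <- n_cand + nrow(det)
        linked <- stage("link", link_spots(det, config$linking))
        linked <- suppressMessages(
          filter_tracks(linked, config$linking$min_span))
        if (nrow(linked) == 0L) next
        main_id <- names(which.max(table(linked$track_id)))
        linked <- linked[linked$track_id == main_id, , drop = FALSE]
        ref <- stage("refine",
                     refine_track(rend$stack, linked, config$gaussfit, acq,
                                  track_id = tr$track_id))
        tracks[[k]] <- ref$track
        keep[k] <- TRUE
      }
      tracks <- tracks[keep]
      lg <- pipeline_log(lg, sprintf(
        "[detect/link/refine] condition '%s': %d candidates, %d/%d tracks past the %d-frame filter",
        cname, n_cand, length(tracks), n_tracks, config$linking$min_span))
    } else {
      tracks <- suppressMessages(
        filter_tracks(truth, config$linking$min_span))
      lg <- pipeline_log(lg, sprintf(
        "[filter] condition '%s': %d/%d tracks past the %d-frame filter",
        cname, length(tracks), n_tracks, config$linking$min_span))
    }
    if (length(tracks) == 0L) next

    fits2d <- stage("analyze", fit_tracks(tracks, acq, n_dims = 2L))
    fits1d <- lapply(tracks, function(tr)
      tryCatch(pca_1d_diffusion(tr, acq), error = function(e) NULL))
    f1a <- vapply(fits1d, function(f) if (is.null(f)) NA_real_ else f$alpha,
                  numeric(1L))
    f1d <- vapply(fits1d, function(f) if (is.null(f)) NA_real_ else f$D,
                  numeric(1L))
    ids <- vapply(tracks, function(t) t$track_id, numeric(1L))
    fits <- merge(fits2d,
                  data.frame(track_id = ids, alpha_1d = f1a, D_1d = f1d),
                  by = "track_id")
    fits <- cbind(condition = cname, fits)
    all_fits[[cname]] <- fits
    all_tracks[[cname]] <- tracks
    counts[[cname]] <- list(simulated = n_tracks, analysed = length(tracks))
  }

  fits <- do.call(rbind, all_fits)
  if (is.null(fits) || nrow(fits) == 0L)
    stop("pipeline produced no analysable tracks ",
         "(all removed by the span filter?)", call. = FALSE)
  rownames(fits) <- NULL

  metric <- config$stats$metric
  gstats <- NULL
  if (length(unique(fits$condition)) >= 2L) {
    gstats <- stage("stats", kruskal_dunn(fits[[metric]], fits$condition,
                                          p_adjust = config$stats$p_adjust))
    lg <- pipeline_log(lg, sprintf(
      "[stats] Kruskal-Wallis on %s: H = %.3f, p = %.3g", metric,
      gstats$kw_H, gstats$kw_p))
  }
  dips <- lapply(split(fits[[metric]], fits$condition), function(v) {
    if (length(v) >= 4L)
      dip_test(v, n_boot = config$stats$dip_n_boot, seed = config$seed)
    else NULL
  })
  descr <- summarize_groups(fits[[metric]], fits$condition)
  qc <- track_qc(do.call(c, all_tracks))

  manifest <- NULL
  if (write_outputs) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      config = file.path(config$out_dir, "config.yaml"),
      fits = file.path(config$out_dir, "fits.csv"),
      tracks = file.path(config$out_dir, "tracks.csv"),
      tracks_xml = file.path(config$out_dir, "tracks.xml"),
      stats = file.path(config$out_dir, "group_stats.csv"),
      log = file.path(config$out_dir, "run.log"))
    write_run_config(config, paths[["config"]])
    utils::write.csv(fits, paths[["fits"]], row.names = FALSE)
    flat <- do.call(c, all_tracks)
    write_tracks_csv(flat, paths[["tracks"]])
    write_tracks_xml(flat, paths[["tracks_xml"]], acq$pixel_size)
    utils::write.csv(descr, paths[["stats"]], row.names = FALSE)
    writeLines(lg, paths[["log"]])
    sums <- tools::md5sum(unname(paths))
    ver <- tryCatch(as.character(utils::packageVersion("locusmotion")),
                    error = function(e) NA_character_)
    manifest <- list(package = "locusmotion", version = ver,
                     seed = config$seed,
                     files = as.list(sums))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  list(fits = fits, stats = gstats, dip = dips, descriptives = descr,
       qc = qc, counts = counts, log = lg, manifest = manifest)
}
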