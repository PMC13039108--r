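# Track linking as a two-stage linear assignment problem: frame-to-frame
# linking with squared-distance costs and an alternative (no-link) cost of
# (1.05 * max distance)^2, then a second assignment over segment end/start
# pairs for gap closing. Splitting and merging are not modelled (one locus
# per region of interest).

BIG_COST <- 1e12

# Minimum-cost assignment (Hungarian algorithm with potentials, O(n^3)).
# cost: n x m with n <= m; returns for each row the assigned column.
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  u <- numeric(n + 1L); v <- numeric(m + 1L)
  p <- integer(m + 1L)            # p[j] = row assigned to column j (0 = none)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[m + 1L] <- i                # virtual column 0 stored at m+1
    j0 <- m + 1L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in seq_len(m)) {
        if (used[j]) next
        cur <- cost[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(m + 1L)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == m + 1L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0L) assign[p[j]] <- j
  assign
}

# Pairwise link assignment between two point sets with forbidden links
# beyond max_dist; returns integer vector over rows of pts1 (NA = no link).
lap_link <- function(pts1, pts2, max_dist) {
  n1 <- nrow(pts1); n2 <- nrow(pts2)
  if (n1 == 0L || n2 == 0L) return(rep(NA_integer_, n1))
  d2 <- outer(pts1[, 1L], pts2[, 1L], "-")^2 +
        outer(pts1[, 2L], pts2[, 2L], "-")^2
  b <- (1.05 * max_dist)^2
  N <- n1 + n2
  C <- matrix(BIG_COST, N, N)
  link <- d2
  link[d2 > max_dist^2] <- BIG_COST
  C[1:n1, 1:n2] <- link
  for (i in seq_len(n1)) C[i, n2 + i] <- b
  for (j in seq_len(n2)) C[n1 + j, j] <- b
  C[(n1 + 1L):N, (n2 + 1L):N] <- 0
  a <- solve_assignment(C)
  out <- rep(NA_integer_, n1)
  for (i in seq_len(n1)) {
    if (a[i] <= n2 && link[i, a[i]] < BIG_COST) out[i] <- a[i]
  }
  out
}

#' Link per-frame spot candidates into tracks
#'
#' Two-stage linear-assignment linking: consecutive-frame links with squared
#' Euclidean distance costs (forbidden beyond `max_link_dist`), then gap
#' closing between segment ends and starts separated by 2 to
#' `max_frame_gap + 1` frames within `max_gap_dist`. Operates in pixel
#' units. Deterministic given the input ordering.
#'
#' @param candidates data.frame `frame, x, y` (0-based frames, pixel
#'   coordinates), e.g. from [detect_stack()]; extra columns are carried
#'   through.
#' @param lp A [link_params()] object.
#' @return data.frame `track_id, frame, x, y, ...`, one row per linked
#'   detection, ordered by track then frame. Empty input gives an empty
#'   result.
#' @export
link_spots <- function(candidates, lp = link_params()) {
  if (nrow(candidates) == 0L)
    return(cbind(data.frame(track_id = integer()), candidates))
  candidates <- candidates[order(candidates$frame), , drop = FALSE]
  frames <- sort(unique(candidates$frame))
  rows_by_frame <- split(seq_len(nrow(candidates)), candidates$frame)
  seg <- rep(NA_integer_, nrow(candidates))
  next_seg <- 1L
  # stage 1: consecutive-frame links
  for (k in seq_along(frames)) {
    rows_k <- rows_by_frame[[k]]
    unassigned <- rows_k[is.na(seg[rows_k])]
    if (length(unassigned)) {
      seg[unassigned] <- next_seg:(next_seg + length(unassigned) - 1L)
      next_seg <- next_seg + length(unassigned)
    }
    if (k == length(frames) || frames[k + 1L] != frames[k] + 1L) next
    rows_n <- rows_by_frame[[k + 1L]]
    a <- lap_link(cbind(candidates$x[rows_k], candidates$y[rows_k]),
                  cbind(candidates$x[rows_n], candidates$y[rows_n]),
                  lp$max_link_dist)
    for (i in seq_along(rows_k)) {
      if (!is.na(a[i])) seg[rows_n[a[i]]] <- seg[rows_k[i]]
    }
  }
  # stage 2: gap closing over segment ends and starts
  seg_ids <- sort(unique(seg))
  info <- do.call(rbind, lapply(seg_ids, function(s) {
    r <- which(seg == s)
    r_first <- r[which.min(candidates$frame[r])]
    r_last <- r[which.max(candidates$frame[r])]
    data.frame(seg = s,
               f0 = candidates$frame[r_first], f1 = candidates$frame[r_last],
               x0 = candidates$x[r_first], y0 = candidates$y[r_first],
               x1 = candidates$x[r_last], y1 = candidates$y[r_last])
  }))
  if (lp$max_frame_gap > 0L && nrow(info) > 1L) {
    dt_mat <- outer(info$f0, info$f1, "-")          # start minus end frames
    d2 <- outer(info$x0, info$x1, "-")^2 + outer(info$y0, info$y1, "-")^2
    feas <- t(dt_mat) >= 2 & t(dt_mat) <= lp$max_frame_gap + 1L &
      t(d2) <= lp$max_gap_dist^2                    # [end, start] orientation
    if (any(feas)) {
      b <- (1.05 * lp$max_gap_dist)^2
      ns <- nrow(info)
      C <- matrix(BIG_COST, 2L * ns, 2L * ns)
      costs <- t(d2)
      costs[!feas] <- BIG_COST
      C[1:ns, 1:ns] <- costs
      for (i in seq_len(ns)) { C[i, ns + i] <- b; C[ns + i, i] <- b }
      C[(ns + 1L):(2L * ns), (ns + 1L):(2L * ns)] <- 0
      a <- solve_assignment(C)
      succ <- rep(NA_integer_, ns)                  # segment continued by
      for (i in seq_len(ns)) {
        if (a[i] <= ns && costs[i, a[i]] < BIG_COST) succ[i] <- a[i]
      }
      # merge chains end -> start (strictly forward in time, so acyclic)
      root <- seq_len(ns)
      for (i in seq_len(ns)) {
        j <- succ[i]
        if (!is.na(j)) root[j] <- i
      }
      final <- seq_len(ns)
      for (i in seq_len(ns)) {
        r <- i
        while (root[r] != r) r <- root[r]
        final[i] <- r
      }
      seg <- final[match(seg, info$seg)]
      seg <- info$seg[seg]
    }
  }
  out <- candidates
  out$track_id <- match(seg, unique(seg[order(candidates$frame)]))
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("track_id", setdiff(names(candidates), "track_id")), drop = FALSE]
}

#' Filter tracks by minimum frame span
#'
#' Span is last minus first detected frame plus one, inclusive of gaps, so a
#' track must cover at least `min_span` frames of the movie to survive.
#'
#' @param tracks Either a list of `locus_track` objects or a linked
#'   data.frame from [link_spots()].
#' @param min_span Minimum span in frames (default 50).
#' @return Object of the same shape as `tracks` with only surviving tracks;
#'   the number removed is reported via `message()`.
#' @export
filter_tracks <- function(tracks, min_span = 50L) {
  if (is.data.frame(tracks)) {
    spans <- tapply(tracks$frame, tracks$track_id,
                    function(f) max(f) - min(f) + 1L)
    keep_ids <- names(spans)[spans >= min_span]
    out <- tracks[as.character(tracks$track_id) %in% keep_ids, , drop = FALSE]
    message(sprintf("filter_tracks: kept %d of %d tracks (min span %d)",
                    length(keep_ids), length(spans), min_span))
    return(out)
  }
  spans <- vapply(tracks, track_span, integer(1L))
  keep <- spans >= min_span
  message(sprintf("filter_tracks: kept %d of %d tracks (min span %d)",
                  sum(keep), length(tracks), min_span))
  tracks[keep]
}

#' Convert a linked pixel-coordinate table to um tracks
#'
#' @param linked data.frame `track_id, frame, x, y` in pixels.
#' @param acq An [acquisition_params()] object.
#' @return List of `locus_track` objects in um.
#' @export
linked_to_tracks <- function(linked, acq = acquisition_params()) {
  ids <- unique(linked$track_id)
  lapply(ids, function(id) {
    sub <- linked[linked$track_id == id, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    new_track(id, sub$frame, cbind(sub$x, sub$y) * acq$pixel_size,
              intensity = if ("intensity" %in% names(sub)) sub$intensity,
              pixel_size = acq$pixel_size)
  })
}

#' Track quality-control summary
#'
#' Reports track-length statistics (detection counts and first-to-last
#' spans) and, when per-frame intensities are present, the mean fitted
#' intensity per frame with an ordinary-least-squares slope — a
#' photobleaching check: a clearly negative slope indicates intensity loss
#' over the acquisition.
#'
#' @param tracks List of `locus_track` objects.
#' @return List with `n_tracks`, `length_summary` (quantiles of detection
#'   counts), `span_summary`, `median_length`, `median_span`, and when
#'   intensities exist `intensity_vs_frame` (data.frame `frame,
#'   mean_intensity`) plus `intensity_slope` (counts per frame).
#' @export
track_qc <- function(tracks) {
  if (length(tracks) == 0L)
    return(list(n_tracks = 0L, median_length = NA_real_,
                median_span = NA_real_))
  lens <- vapply(tracks, function(t) length(t$frames), integer(1L))
  spans <- vapply(tracks, track_span, integer(1L))
  out <- list(n_tracks = length(tracks),
              length_summary = stats::quantile(lens, c(0, .25, .5, .75, 1)),
              span_summary = stats::quantile(spans, c(0, .25, .5, .75, 1)),
              median_length = stats::median(lens),
              median_span = stats::median(spans))
  has_int <- vapply(tracks, function(t) !is.null(t$intensity), logical(1L))
  if (any(has_int)) {
    df <- tracks_to_df(tracks[has_int])
    agg <- stats::aggregate(intensity ~ frame, data = df, FUN = mean)
    names(agg) <- c("frame", "mean_intensity")
    fitl <- stats::lm(mean_intensity ~ frame, data = agg)
    out$intensity_vs_frame <- agg
    out$intensity_slope <- unname(stats::coef(fitl)[2L])
  }
  out
}
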