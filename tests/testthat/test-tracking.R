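# LAP linking: optimality against exhaustive assignment, gap-closing
# boundary behaviour, the span filter, and QC summaries.

test_that("per-step assignment cost equals the exhaustive minimum", {
  set.seed(13)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    C <- matrix(runif(n * n, 0, 10), n, n)
    a <- locusmotion:::solve_assignment(C)
    expect_equal(sum(C[cbind(seq_len(n), a)]), brute_assignment_cost(C))
  }
})

test_that("one moving spot links into a single full-length track", {
  cand <- data.frame(frame = 0:29, x = (0:29) * 1.0, y = 2.0)
  linked <- link_spots(cand, link_params())
  expect_equal(length(unique(linked$track_id)), 1L)
  expect_equal(nrow(linked), 30L)
})

test_that("gap closing bridges up to 3 missing frames and no more", {
  base <- data.frame(frame = 0:19, x = (0:19) * 0.5, y = 0)
  # 3-frame gap (frames 10-12 missing): one gap-closed track
  g3 <- link_spots(base[!(base$frame %in% 10:12), ], link_params())
  expect_equal(length(unique(g3$track_id)), 1L)
  # 4-frame gap: two tracks
  g4 <- link_spots(base[!(base$frame %in% 10:13), ], link_params())
  expect_equal(length(unique(g4$track_id)), 2L)
  # 3-frame gap but reappearing beyond the gap distance: two tracks
  far <- base
  far$x[far$frame >= 13] <- far$x[far$frame >= 13] + 10
  gfar <- link_spots(far[!(far$frame %in% 10:12), ], link_params())
  expect_equal(length(unique(gfar$track_id)), 2L)
})

test_that("two parallel spots never swap identity", {
  cand <- rbind(data.frame(frame = 0:19, x = (0:19) * 1.0, y = 0),
                data.frame(frame = 0:19, x = (0:19) * 1.0, y = 10))
  cand <- cand[order(cand$frame), ]
  linked <- link_spots(cand, link_params())
  expect_equal(length(unique(linked$track_id)), 2L)
  swaps <- tapply(linked$y, linked$track_id, function(v) length(unique(v)))
  expect_true(all(swaps == 1L))
})

test_that("linked detections are a subset of the input candidates", {
  set.seed(7)
  cand <- data.frame(frame = rep(0:9, each = 3),
                     x = runif(30, 0, 50), y = runif(30, 0, 50))
  linked <- link_spots(cand, link_params())
  expect_equal(nrow(linked), nrow(cand))
  expect_setequal(paste(linked$frame, linked$x, linked$y),
                  paste(cand$frame, cand$x, cand$y))
})

test_that("span filter keeps spans >= 50, measured first-to-last inclusive", {
  mk <- function(id, f) new_track(id, f, matrix(0, length(f), 2))
  trs <- list(mk(1, c(0, 48)), mk(2, c(0, 49)), mk(3, c(5, 993)))
  kept <- suppressMessages(filter_tracks(trs, 50))
  expect_equal(vapply(kept, track_span, integer(1)), c(50L, 989L))
  expect_length(suppressMessages(filter_tracks(list(), 50)), 0L)
})

test_that("raising the span threshold never increases the survivor count", {
  set.seed(19)
  trs <- lapply(1:20, function(i) {
    span <- sample(10:200, 1)
    new_track(i, c(0, span - 1L), matrix(0, 2, 2))
  })
  counts <- vapply(c(10, 50, 100, 150),
                   function(ms) length(suppressMessages(filter_tracks(trs, ms))),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("track QC reports the median length and detects bleaching", {
  mk <- function(id, n, intens) new_track(id, 0:(n - 1L),
                                          matrix(0, n, 2), intensity = intens)
  trs <- list(mk(1, 100, rep(500, 100)), mk(2, 989, rep(500, 989)),
              mk(3, 1000, rep(500, 1000)))
  qc <- track_qc(trs)
  expect_equal(qc$median_length, 989)
  expect_equal(qc$intensity_slope, 0, tolerance = 1e-10)
  # exponential bleaching: clearly negative fitted slope
  bleach <- list(mk(1, 200, 500 * exp(-(0:199) / 100)))
  expect_lt(track_qc(bleach)$intensity_slope, -0.5)
})
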