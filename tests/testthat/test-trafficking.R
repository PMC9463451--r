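test_that("pixel-to-micron conversion matches the imaging scale", {
  expect_equal(px_to_um(7.5), 5.63, tolerance = 0.01)
  expect_equal(px_to_um(20), 15.03, tolerance = 0.01)
  expect_equal(px_to_um(20.5), 15.41, tolerance = 0.01)
  expect_identical(px_to_um(0), 0)
  expect_error(px_to_um(5, 0), "positive")
})

test_that("trafficking thresholds are index-aligned and unit-consistent", {
  thr <- trafficking_thresholds()
  expect_equal(thr$windows_s, c(0.6, 0.8, 1.0))
  expect_equal(thr$windows_frames, c(3L, 4L, 5L))
  expect_equal(thr$displacement_px, c(20.5, 22.5, 22.5))
  expect_equal(thr$consistency_deg, c(58, 58, 58))
  expect_equal(thr$quality, c(1.6, 1.65, 1.75))
  expect_true(all(abs(thr$displacement_um -
                        thr$displacement_px / 1.33) < 0.01))
})

test_that("rolling-median background removes statics, keeps transients", {
  const <- video_stack(array(0.8, c(32, 32, 40)))
  expect_true(all(subtract_background(const)$frames == 0))

  # static texture plus a particle visiting each pixel for <= 1 frame
  set.seed(3)
  tex <- matrix(runif(64 * 64, 0.3, 0.7), 64)
  frames <- array(rep(tex, 40), c(64, 64, 40))
  amp <- 0.9
  for (t in 1:40) frames[20, 10 + t, t] <- frames[20, 10 + t, t] + amp
  bg <- subtract_background(video_stack(frames))
  peaks <- vapply(1:40, function(t) bg$frames[20, 10 + t, t], numeric(1))
  expect_true(all(peaks >= 0.9 * amp))
  off <- bg$frames[40:60, 40:60, 20]
  expect_lt(max(abs(off)), 0.01 * amp)

  # boundary contract: truncated window at the first frame
  small <- video_stack(array(rnorm(16 * 16 * 20), c(16, 16, 20)))
  got <- subtract_background(small)
  w <- round(6 / 0.2); half <- w %/% 2
  want1 <- small$frames[, , 1] -
    apply(small$frames[, , 1:(1 + half)], c(1, 2), median)
  expect_equal(got$frames[, , 1], want1)

  slow <- video_stack(array(0.5, c(32, 32, 10)), frame_interval_s = 3)
  expect_error(subtract_background(slow), "too short")
})

test_that("DoG detection finds planted blobs at subpixel accuracy", {
  expect_identical(nrow(detect_spots(matrix(0, 64, 64))), 0L)

  ii <- 1:64
  sb <- 7.5 / sqrt(2)
  one <- 0.6 * exp(-outer((ii - 30.3)^2, (ii - 41.7)^2, "+") / (2 * sb^2))
  d1 <- detect_spots(one)
  expect_identical(nrow(d1), 1L)
  expect_lt(abs(d1$y - 30.3), 0.5)
  expect_lt(abs(d1$x - 41.7), 0.5)
  expect_gt(d1$quality, 1.6)

  two <- one + 0.6 * exp(-outer((ii - 30.3)^2, (ii - 11.7)^2, "+") / (2 * sb^2))
  expect_identical(nrow(detect_spots(two)), 2L)
})

test_that("linking follows the max-distance rule and LAP optimality", {
  # one spot moving 5 px/frame for 10 frames -> one 10-detection tracklet
  dets <- lapply(1:10, function(t)
    data.frame(x = 10 + 5 * t, y = 20, quality = 2))
  tr <- link_detections(dets)
  expect_length(tr, 1)
  expect_identical(nrow(tr[[1]]$detections), 10L)

  # 25 px jump exceeds the 20 px gate -> two tracklets
  jump <- lapply(1:4, function(t)
    data.frame(x = c(10, 10, 35, 35)[t], y = 20, quality = 2))
  # two frames at x=10, then two frames at x=35
  tr2 <- link_detections(jump)
  expect_length(tr2, 2)
  expect_true(all(vapply(tr2, function(x) nrow(x$detections), integer(1)) == 2))

  # optimality vs brute force on random instances with <= 4 detections/frame
  set.seed(14)
  for (rep in 1:25) {
    dets <- lapply(1:3, function(t) {
      n <- sample(0:4, 1)
      data.frame(x = runif(n, 0, 60), y = runif(n, 0, 60),
                 quality = rep(2, n))
    })
    tr <- link_detections(dets)
    for (t in 1:2) {
      want <- brute_force_link_cost(dets[[t]], dets[[t + 1]])
      got <- realized_link_cost(tr, t, dets[[t]], dets[[t + 1]])
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("no tracklet contains a link longer than the gate", {
  tr <- attr(trafficking_counts_fixture(), "tracklets")
  expect_gt(length(tr), 0)
  for (t in tr) {
    d <- t$detections
    expect_true(all(diff(d$frame) == 1))
    steps <- sqrt(diff(d$x)^2 + diff(d$y)^2)
    expect_true(all(steps <= 20))
  }
})

test_that("tracklet features follow their definitions", {
  straight <- make_tracklet(cbind(10 + 6 * (0:4), rep(5, 5)))
  f <- compute_tracklet_features(straight)
  expect_equal(f$displacement_px, 24)
  expect_equal(f$displacement_um, 24 / 1.33, tolerance = 1e-9)
  expect_equal(f$consistency_deg, 0)
  expect_equal(f$duration_s, 1.0)

  zig <- make_tracklet(cbind(c(0, 1, 1, 2, 2), c(0, 0, 1, 1, 2)))
  expect_equal(compute_tracklet_features(zig)$consistency_deg, 90)

  stuck <- make_tracklet(cbind(c(1, 1, 1), c(2, 2, 2)))
  expect_equal(compute_tracklet_features(stuck)$consistency_deg, 0)

  expect_error(compute_tracklet_features(make_tracklet(cbind(1, 1))),
               "at least 2")
})

test_that("tracklet filtering applies the per-window thresholds", {
  thr <- trafficking_thresholds()
  straight <- make_tracklet(cbind(10 + 6 * (0:4), rep(5, 5)), quality = 2.0)
  jitter <- make_tracklet(cbind(10 + c(0, 1.5, 0, 1.5, 3), rep(5, 5)),
                          quality = 2.0)
  kept <- filter_tracklets(list(straight, jitter), thr, 1)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$detections$x, straight$detections$x)
  for (w in 1:3)
    expect_length(filter_tracklets(list(jitter), thr, w), 0)
  expect_error(filter_tracklets(list(straight), thr, 4), "window_index")

  # monotone in every threshold: raising a threshold never keeps more
  g <- trafficking_counts_fixture()
  tr <- attr(g, "tracklets")
  base <- length(filter_tracklets(tr, thr, 1))
  harder <- thr
  harder$displacement_px[1] <- thr$displacement_px[1] + 10
  expect_lte(length(filter_tracklets(tr, harder, 1)), base)
  harder2 <- thr; harder2$quality[1] <- thr$quality[1] + 0.5
  expect_lte(length(filter_tracklets(tr, harder2, 1)), base)
  harder3 <- thr; harder3$consistency_deg[1] <- thr$consistency_deg[1] - 30
  expect_lte(length(filter_tracklets(tr, harder3, 1)), base)
})

test_that("end-to-end counts recover planted cells and are window-monotone", {
  counts <- trafficking_counts_fixture()
  expect_lte(abs(counts[[1]] - 6), 1)
  expect_true(counts[[3]] <= counts[[2]])
  expect_true(counts[[2]] <= counts[[1]])

  static <- generate_rcm_video(128, 128, 12, n_vessels = 1,
                               n_trafficking_cells = 0,
                               vessel_jitter_sd = 0, speckle_contrast = 0,
                               seed = 3)
  expect_equal(unname(count_trafficking(static$video)), c(0L, 0L, 0L),
               ignore_attr = TRUE)
})
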