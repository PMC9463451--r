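test_that("video generator is deterministic and records planted structure", {
  a <- generate_rcm_video(96, 96, 6, n_vessels = 2, n_trafficking_cells = 3,
                          seed = 5)
  b <- generate_rcm_video(96, 96, 6, n_vessels = 2, n_trafficking_cells = 3,
                          seed = 5)
  expect_identical(a$video$frames, b$video$frames)
  expect_identical(a$truth, b$truth)

  lab <- rcmtime:::.label_components_cpp(
    matrix(as.integer(a$truth$vessel_mask), 96, 96), 8L)
  expect_identical(max(lab), 2L)
  expect_identical(length(unique(a$truth$particle_tracks$track_id)), 3L)

  # particle positions inside the frame and within the dilated vessel mask
  tr <- a$truth$particle_tracks
  expect_true(all(tr$x >= 1 & tr$x <= 96 & tr$y >= 1 & tr$y <= 96))
  dil <- EBImage::dilate(a$truth$vessel_mask,
                         EBImage::makeBrush(7, "disc")) > 0
  expect_true(all(dil[cbind(round(tr$y), round(tr$x))]))
})

test_that("video generator validates inputs and applies bounded drift", {
  expect_error(generate_rcm_video(32, 96, 4), "at least 64")
  expect_error(generate_rcm_video(96, 96, 1), "n_frames")
  expect_error(generate_rcm_video(96, 96, 4, n_vessels = 0,
                                  n_trafficking_cells = 2), "vessel")
  g <- generate_rcm_video(96, 96, 10, n_vessels = 1, drift_amplitude_px = 3,
                          seed = 2)
  expect_equal(dim(g$truth$applied_drift), c(10, 2))
  expect_true(all(abs(g$truth$applied_drift) <= 3))
  expect_true(any(g$truth$applied_drift != 0))
  # drift resampling pads with exact zeros at out-of-view borders
  expect_true(any(g$video$frames == 0))
})

test_that("planted vessel area fraction is in a plausible range at defaults", {
  g <- vessel_video_fixture()
  frac <- mean(g$truth$vessel_mask)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.15)
})

test_that("immune label generator plants the requested morphology counts", {
  z <- generate_immune_labelmap(96, 96, 0, 0, seed = 1)
  expect_true(all(z$labels == 3L))

  a <- generate_immune_labelmap(128, 128, 10, 0, seed = 3)
  b <- generate_immune_labelmap(128, 128, 10, 0, seed = 3)
  expect_identical(a$image, b$image)
  expect_identical(a$labels, b$labels)
  comp <- rcmtime:::.label_components_cpp(
    matrix(as.integer(a$labels == 2), 128, 128), 8L)
  expect_identical(max(comp), 10L)
  # labelled objects render brighter than the textured background
  expect_gt(mean(a$image[a$labels == 2]), mean(a$image[a$labels == 3]) + 0.2)
})

test_that("feature-table generator reproduces cluster means and responses", {
  spec <- list(list(mean = rep(1, 4), n = 3, response_prob = 1),
               list(mean = rep(2, 4), n = 3, response_prob = 0))
  g <- generate_feature_table(6, spec, noise_sd = 0, seed = 1)
  expect_true(all(g$table$grades[1:3, ] == 1L))
  expect_true(all(g$table$grades[4:6, ] == 2L))
  expect_identical(g$table$response, c(1L, 1L, 1L, 0L, 0L, 0L))

  # law of large numbers at n = 60/cluster, noise 0.1
  spec2 <- list(list(mean = rep(0, 6), n = 60, response_prob = 0.5),
                list(mean = rep(3, 6), n = 60, response_prob = 0.5))
  g2 <- generate_feature_table(120, spec2, noise_sd = 0.1, seed = 2)
  m1 <- colMeans(g2$table$grades[g2$truth$cluster_of_sample == 1, ])
  m2 <- colMeans(g2$table$grades[g2$truth$cluster_of_sample == 2, ])
  expect_true(all(abs(m1 - 0) < 0.2))
  expect_true(all(abs(m2 - 3) < 0.2))
  expect_true(all(g2$table$grades %in% 0:3))

  expect_error(generate_feature_table(5, spec, noise_sd = 0), "sum")
  bad <- list(list(mean = c(4, 0), n = 2, response_prob = 0.5))
  expect_error(generate_feature_table(2, bad), "\\[0, 3\\]")
})

test_that("feature tables round-trip through CSV", {
  g <- generate_feature_table(10, list(
    list(mean = rep(1, 6), n = 5, response_prob = 0.4),
    list(mean = rep(2, 6), n = 5, response_prob = 0.6)), seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(g$table, path)
  back <- read_feature_table(path)
  expect_identical(back$grades, g$table$grades)
  expect_identical(back$response, g$table$response)
  expect_identical(back$feature_names, g$table$feature_names)
})

test_that("video stacks round-trip through multi-page TIFF", {
  g <- generate_rcm_video(64, 64, 3, n_vessels = 1, seed = 4)
  path <- withr::local_tempfile(fileext = ".tif")
  write_video_tiff(g$video, path)
  back <- read_video_tiff(path)
  expect_equal(dim(back), dim(g$video))
  expect_equal(back$frames, g$video$frames, tolerance = 1e-6)
})
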