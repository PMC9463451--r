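# Shared synthetic fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# default vessel video: 256^2, 50 frames, 2 vessels
vessel_video_fixture <- function() {
  fixture("vessel_video", function()
    generate_rcm_video(256, 256, 50, n_vessels = 2, n_trafficking_cells = 0,
                       seed = 7))
}

# trafficking video: 6 planted cells moving 6 px/frame along 2 vessels
trafficking_video_fixture <- function() {
  fixture("trafficking_video", function()
    generate_rcm_video(256, 256, 12, n_vessels = 2, n_trafficking_cells = 6,
                       particle_speed_px_per_frame = 6,
                       speckle_contrast = 0.05, seed = 11))
}

trafficking_counts_fixture <- function() {
  fixture("trafficking_counts", function()
    count_trafficking(trafficking_video_fixture()$video))
}

# paper-like 3-phenotype table spec (vascular block, inflammation block)
three_cluster_spec <- function() {
  list(list(mean = c(3, 3, 3, 0, 0, 0), n = 11, response_prob = 0),
       list(mean = c(0, 0, 0, 3, 3, 3), n = 7, response_prob = 1),
       list(mean = c(3, 3, 3, 3, 3, 3), n = 9, response_prob = 0.5))
}

# 4-corner table: all Inflam/Vasc combinations, decorrelated blocks
four_corner_spec <- function() {
  list(list(mean = c(3, 3, 3, 0, 0, 0), n = 8, response_prob = 0),
       list(mean = c(0, 0, 0, 2.4, 2.4, 2.4), n = 8, response_prob = 1),
       list(mean = c(3, 3, 3, 2.4, 2.4, 2.4), n = 8, response_prob = 0.5),
       list(mean = c(0, 0, 0, 0, 0, 0), n = 8, response_prob = 0.5))
}

# small labelled immune image set at desk scale
immune_set_fixture <- function() {
  fixture("immune_set", function() {
    data <- lapply(1:25, function(i)
      generate_immune_labelmap(96, 96, n_round_cells = 4,
                               n_dendritic_cells = 3, seed = i))
    list(images = lapply(data, `[[`, "image"),
         labels = lapply(data, `[[`, "labels"))
  })
}

immune_segmenter_fixture <- function() {
  fixture("immune_segmenter", function() {
    d <- immune_set_fixture()
    train_segmenter(d$images, d$labels,
                    segmenter_config(input_size_px = 96, n_trees = 100,
                                     pixels_per_image = 1500,
                                     val_fraction = 0.2, seed = 42))
  })
}

# brute-force minimum frame-pair linking cost (links + birth/death penalties)
brute_force_link_cost <- function(prev, cur, max_link_px = 20,
                                  birth_factor = 1.05) {
  b <- (birth_factor * max_link_px)^2
  n <- nrow(prev); m <- nrow(cur)
  if (n == 0 || m == 0) return(b * (n + m))
  d2 <- outer(prev$y, cur$y, "-")^2 + outer(prev$x, cur$x, "-")^2
  feas <- d2 <= max_link_px^2
  best <- Inf
  # enumerate all injective partial matchings prev -> cur
  recurse <- function(i, used, cost) {
    if (cost >= best) return()
    if (i > n) {
      total <- cost + b * sum(!used) # unmatched current detections
      if (total < best) best <<- total
      return()
    }
    recurse(i + 1, used, cost + b) # detection i unmatched
    for (j in seq_len(m)) {
      if (!used[j] && feas[i, j]) {
        used[j] <- TRUE
        recurse(i + 1, used, cost + d2[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1, rep(FALSE, m), 0)
  best
}

# realized cost of a linking solution over one frame pair
realized_link_cost <- function(tracklets, t, prev, cur, max_link_px = 20,
                               birth_factor = 1.05) {
  b <- (birth_factor * max_link_px)^2
  links <- 0; cost <- 0
  for (tr in tracklets) {
    d <- tr$detections
    k <- which(d$frame == t)
    if (length(k) == 1 && k < nrow(d) && d$frame[k + 1] == t + 1) {
      cost <- cost + (d$x[k + 1] - d$x[k])^2 + (d$y[k + 1] - d$y[k])^2
      links <- links + 1
    }
  }
  cost + b * (nrow(prev) - links) + b * (nrow(cur) - links)
}

# step-by-step reimplementation of the weighted agreement coefficient
gwet_oracle <- function(a, b, cats, linear = TRUE) {
  K <- length(cats); n <- length(a)
  w <- matrix(0, K, K)
  for (i in 1:K) for (j in 1:K)
    w[i, j] <- if (linear) 1 - abs(i - j) / (K - 1) else as.numeric(i == j)
  pa <- 0
  for (i in seq_len(n))
    pa <- pa + w[match(a[i], cats), match(b[i], cats)] / n
  pik <- numeric(K)
  for (k in 1:K)
    pik[k] <- (sum(a == cats[k]) + sum(b == cats[k])) / (2 * n)
  pe <- sum(w) / (K * (K - 1)) * sum(pik * (1 - pik))
  (pa - pe) / (1 - pe)
}

# cleanly separable response table (margin on the "til" feature)
separable_table <- function() {
  grades <- cbind(til = c(3L, 2L, 3L, 3L, 2L, 3L, 0L, 1L, 0L, 0L, 1L, 0L),
                  noise = rep(c(0L, 1L, 2L), 4))
  feature_table(grades, response = rep(c(1L, 0L), each = 6))
}

# hand-built tracklet from a coordinate matrix
make_tracklet <- function(xy, quality = 2, start_frame = 1) {
  structure(list(detections = data.frame(
    frame = start_frame + seq_len(nrow(xy)) - 1,
    x = xy[, 1], y = xy[, 2],
    quality = rep_len(quality, nrow(xy)))), class = "tracklet")
}
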