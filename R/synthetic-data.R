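#' Synthetic RCM-like video with planted vessels and trafficking cells
#'
#' Generates a grayscale video that emulates the properties the
#' quantification pipeline relies on, with full ground truth: static
#' speckle-textured tissue, tubular vessel regions whose intensity
#' fluctuates frame to frame, bright round particles travelling along
#' vessel centerlines (leukocyte trafficking), a bounded random-walk global
#' drift and a smooth random nonlinear deformation. Out-of-view pixels
#' introduced by drift/deformation are filled with 0, the pipeline's
#' "blank" value.
#'
#' Vessels are laid out as non-overlapping sinuous horizontal bands, so
#' with `n_vessels = k` the planted mask has exactly `k` 8-connected
#' components. Particles start at staggered positions along the centerline
#' and reflect at the vessel ends.
#'
#' @param width_px,height_px frame size in pixels (at least 64).
#' @param n_frames number of frames (at least 2).
#' @param frame_interval_s seconds between frames. The default 0.2 s (5
#'   frames per second) makes 3/4/5-frame tracklets span 0.6/0.8/1.0 s.
#' @param n_vessels number of planted vessels.
#' @param n_trafficking_cells number of bright moving particles; requires
#'   `n_vessels > 0` when positive.
#' @param particle_speed_px_per_frame centerline speed of each particle.
#' @param drift_amplitude_px bound on the global random-walk translation.
#' @param deformation_amplitude_px peak magnitude of the smooth nonlinear
#'   displacement field.
#' @param speckle_contrast contrast of the multiplicative gamma speckle
#'   (shape `1/speckle_contrast^2`); 0 disables speckle.
#' @param vessel_radius_px half-thickness of the planted vessels.
#' @param vessel_jitter_sd per-frame i.i.d. intensity jitter inside vessels;
#'   this frame-to-frame fluctuation is what the temporal-variation vessel
#'   segmentation keys on.
#' @param particle_amplitude brightness of the moving particles above the
#'   local background.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return A list with `video` (a [video_stack]) and `truth`, a list holding
#'   `vessel_mask` (logical `H x W`), `particle_tracks` (data.frame with
#'   `track_id`, `frame`, `x`, `y` in undistorted coordinates; `x` is the
#'   column, `y` the row), `applied_drift` (`T x 2` matrix of (dy, dx)
#'   translations) and `applied_deformation` (per-frame peak displacement
#'   magnitude in px).
#' @export
generate_rcm_video <- function(width_px = 256, height_px = 256, n_frames = 50,
                               frame_interval_s = 0.2, n_vessels = 2,
                               n_trafficking_cells = 0,
                               particle_speed_px_per_frame = 6,
                               drift_amplitude_px = 0,
                               deformation_amplitude_px = 0,
                               speckle_contrast = 0.15,
                               vessel_radius_px = 6,
                               vessel_jitter_sd = 0.12,
                               particle_amplitude = 0.6,
                               seed = 1L) {
  if (width_px < 64 || height_px < 64) stop("dimensions must be at least 64 px")
  if (n_frames < 2) stop("n_frames must be at least 2")
  if (drift_amplitude_px < 0 || deformation_amplitude_px < 0)
    stop("amplitudes must be non-negative")
  if (n_trafficking_cells > 0 && n_vessels == 0)
    stop("trafficking particles need at least one vessel path")
  set.seed(seed)

  H <- height_px; W <- width_px; T <- n_frames
  background <- smooth_noise_field(H, W, sigma = 6, lo = 0.35, hi = 0.6)

  # vessel centerlines: one sinuous path per horizontal band
  vessel_mask <- matrix(FALSE, H, W)
  centerlines <- vector("list", n_vessels)
  if (n_vessels > 0) {
    band <- H / (n_vessels + 1)
    for (v in seq_len(n_vessels)) {
      yc <- band * v
      amp <- max(0, min(12, band / 2 - vessel_radius_px - 3))
      freq <- runif(1, 1, 2)
      phase <- runif(1, 0, 2 * pi)
      xs <- seq(vessel_radius_px + 2, W - vessel_radius_px - 1, by = 0.5)
      ys <- yc + amp * sin(2 * pi * freq * xs / W + phase)
      centerlines[[v]] <- arclength_path(xs, ys)
      vessel_mask <- stamp_disks(vessel_mask, xs, ys, vessel_radius_px)
    }
  }

  # particle itineraries along centerlines, reflecting at the ends
  tracks <- NULL
  particle_pos <- NULL # T x n x 2 array of (y, x)
  if (n_trafficking_cells > 0) {
    particle_pos <- array(NA_real_, c(T, n_trafficking_cells, 2))
    vpick <- rep(seq_len(n_vessels), length.out = n_trafficking_cells)
    rows <- vector("list", n_trafficking_cells)
    for (i in seq_len(n_trafficking_cells)) {
      cl <- centerlines[[vpick[i]]]
      L <- max(cl$s)
      # stagger starting offsets so same-vessel particles stay apart; when
      # the itinerary fits, keep it clear of the vessel ends so particles
      # never reverse (reflection at the ends is the fallback)
      k <- sum(vpick[seq_len(i)] == vpick[i])
      n_on <- sum(vpick == vpick[i])
      path_len <- particle_speed_px_per_frame * (T - 1)
      avail <- L - path_len - 10
      s0 <- if (avail > 0) 5 + avail * (k - 0.5) / n_on
      else (L * (k - 0.5) / n_on) %% L
      s_t <- reflect_path(s0 + particle_speed_px_per_frame * (seq_len(T) - 1), L)
      px <- approx(cl$s, cl$x, xout = s_t)$y
      py <- approx(cl$s, cl$y, xout = s_t)$y
      particle_pos[, i, 1] <- py
      particle_pos[, i, 2] <- px
      rows[[i]] <- data.frame(track_id = i, frame = seq_len(T), x = px, y = py)
    }
    tracks <- do.call(rbind, rows)
  }

  # drift: bounded gaussian random walk, one (dy, dx) per frame
  drift <- matrix(0, T, 2)
  if (drift_amplitude_px > 0) {
    for (k in 1:2) {
      w <- cumsum(rnorm(T, sd = drift_amplitude_px / 3))
      drift[, k] <- pmin(pmax(w, -drift_amplitude_px), drift_amplitude_px)
    }
    drift[1, ] <- 0
  }

  # smooth deformation: fixed random unit field, sinusoidal time modulation
  tmod <- sin(2 * pi * (seq_len(T) - 1) / T)
  deform_mag <- rep(0, T)
  if (deformation_amplitude_px > 0) {
    gy <- coarse_random_field(H, W)
    gx <- coarse_random_field(H, W)
    m <- max(sqrt(gy^2 + gx^2))
    gy <- gy / m; gx <- gx / m
    deform_mag <- abs(tmod) * deformation_amplitude_px
  }

  sigma_blob <- 7.5 / sqrt(2) # particle size matched to the 7.5 px DoG radius
  frames <- array(0, c(H, W, T))
  shape <- if (speckle_contrast > 0) 1 / speckle_contrast^2 else Inf
  for (t in seq_len(T)) {
    f <- background
    if (n_vessels > 0) {
      nv <- sum(vessel_mask)
      f[vessel_mask] <- 0.42 + rnorm(nv, sd = vessel_jitter_sd)
    }
    if (n_trafficking_cells > 0)
      for (i in seq_len(n_trafficking_cells))
        f <- add_gaussian_blob(f, particle_pos[t, i, 1], particle_pos[t, i, 2],
                               particle_amplitude, sigma_blob)
    if (speckle_contrast > 0)
      f <- f * matrix(rgamma(H * W, shape = shape, rate = shape), H, W)
    if (any(drift[t, ] != 0) || deform_mag[t] > 0) {
      if (deform_mag[t] > 0) {
        dy <- drift[t, 1] + deformation_amplitude_px * tmod[t] * gy
        dx <- drift[t, 2] + deformation_amplitude_px * tmod[t] * gx
      } else {
        dy <- matrix(drift[t, 1], 1, 1); dx <- matrix(drift[t, 2], 1, 1)
      }
      f <- .warp_bilinear_cpp(f, as.matrix(dy), as.matrix(dx), 0)
    }
    frames[, , t] <- pmax(f, 0)
  }

  video <- video_stack(frames, frame_interval_s = frame_interval_s,
                       source_id = sprintf("synthetic-%d", seed))
  truth <- list(vessel_mask = vessel_mask, particle_tracks = tracks,
                applied_drift = drift, applied_deformation = deform_mag)
  list(video = video, truth = truth)
}

#' Synthetic immune-cell image with a 3-class pixel label map
#'
#' Emulates the two immune morphologies the segmenter distinguishes on RCM:
#' class 1 dendritic cells/macrophages (elongated, branched bright shapes),
#' class 2 round-ellipsoid leukocyte-like cells, class 3 background (all
#' remaining pixels). Objects are placed with a minimum separation so each
#' planted cell is its own connected component in the label map.
#'
#' @param width_px,height_px image size in pixels.
#' @param n_round_cells number of class-2 round/ellipsoid cells.
#' @param n_dendritic_cells number of class-1 branched cells.
#' @param seed integer seed.
#' @return A list with `image` (numeric `H x W`) and `labels` (integer
#'   `H x W` map with values in 1:3).
#' @export
generate_immune_labelmap <- function(width_px = 128, height_px = 128,
                                     n_round_cells = 8, n_dendritic_cells = 4,
                                     seed = 1L) {
  if (n_round_cells < 0 || n_dendritic_cells < 0) stop("counts must be >= 0")
  set.seed(seed)
  H <- height_px; W <- width_px
  labels <- matrix(3L, H, W)
  image <- smooth_noise_field(H, W, sigma = 4, lo = 0.2, hi = 0.45)

  n_total <- n_round_cells + n_dendritic_cells
  centers <- place_separated(n_total, H, W, margin = 12, min_dist = 24)
  idx <- 0L
  for (i in seq_len(n_dendritic_cells)) {
    idx <- idx + 1L
    cy <- centers[idx, 1]; cx <- centers[idx, 2]
    n_branch <- sample(3:5, 1)
    for (b in seq_len(n_branch)) {
      ang <- runif(1, 0, 2 * pi)
      len <- runif(1, 7, 10)
      steps <- seq(0, len, by = 0.5)
      curve <- runif(1, -0.06, 0.06)
      ys <- cy + steps * sin(ang + curve * steps)
      xs <- cx + steps * cos(ang + curve * steps)
      keep <- ys >= 2 & ys <= H - 1 & xs >= 2 & xs <= W - 1
      m <- stamp_disks(matrix(FALSE, H, W), xs[keep], ys[keep], 1.4)
      labels[m] <- 1L
      image[m] <- 0.8
    }
  }
  for (i in seq_len(n_round_cells)) {
    idx <- idx + 1L
    cy <- centers[idx, 1]; cx <- centers[idx, 2]
    a <- runif(1, 3, 5); b <- runif(1, 2.5, a)
    th <- runif(1, 0, pi)
    m <- ellipse_mask(H, W, cy, cx, a, b, th)
    labels[m] <- 2L
    image[m] <- 0.9
  }
  image <- EBImage::gblur(image, sigma = 0.7)
  image <- image + matrix(rnorm(H * W, sd = 0.02), H, W)
  list(image = image, labels = labels)
}

#' Synthetic graded TiME feature table with planted phenotype clusters
#'
#' Draws each lesion's feature vector as its cluster mean plus Gaussian
#' noise, rounded and clipped to the ordinal 0-3 grading scale used for
#' manual RCM evaluation, and assigns a binary treatment response per
#' cluster-specific Bernoulli probability.
#'
#' @param n_samples total number of lesions; cluster sizes must sum to this.
#' @param cluster_spec list of clusters, each a list with `mean` (per-feature
#'   grade means in \[0, 3\]), `n` (cluster size) and `response_prob`
#'   (Bernoulli response probability in \[0, 1\]).
#' @param noise_sd standard deviation of the pre-rounding Gaussian noise.
#' @param feature_names optional feature names; defaults to the canonical
#'   six TiME features when the means have six entries.
#' @param seed integer seed.
#' @return A list with `table` (a [feature_table]) and `truth`, a list with
#'   `cluster_of_sample`, `cluster_means` and `response_prob_by_cluster`.
#' @export
generate_feature_table <- function(n_samples, cluster_spec, noise_sd = 0.3,
                                   feature_names = NULL, seed = 1L) {
  set.seed(seed)
  sizes <- vapply(cluster_spec, function(cs) as.integer(cs$n), integer(1))
  if (sum(sizes) != n_samples) stop("cluster sizes must sum to n_samples")
  means <- do.call(rbind, lapply(cluster_spec, function(cs) cs$mean))
  if (any(means < 0 | means > 3)) stop("cluster means must lie in [0, 3]")
  probs <- vapply(cluster_spec, function(cs) cs$response_prob, numeric(1))
  if (any(probs < 0 | probs > 1)) stop("response probabilities must lie in [0, 1]")
  p <- ncol(means)
  if (is.null(feature_names)) {
    feature_names <- if (p == 6) canonical_time_features() else
      sprintf("feature_%02d", seq_len(p))
  }
  cluster_of_sample <- rep(seq_along(sizes), sizes)
  grades <- means[cluster_of_sample, , drop = FALSE] +
    matrix(rnorm(n_samples * p, sd = noise_sd), n_samples, p)
  grades <- matrix(pmin(pmax(round(grades), 0L), 3L), n_samples, p)
  storage.mode(grades) <- "integer"
  response <- rbinom(n_samples, 1, probs[cluster_of_sample])
  tab <- feature_table(grades, feature_names = feature_names,
                       sample_ids = sprintf("lesion_%03d", seq_len(n_samples)),
                       response = response)
  truth <- list(cluster_of_sample = cluster_of_sample, cluster_means = means,
                response_prob_by_cluster = probs)
  list(table = tab, truth = truth)
}

#' Canonical TiME feature names
#'
#' The six features graded 0-3 on manual RCM evaluation.
#' @return Character vector of feature names.
#' @export
canonical_time_features <- function() {
  c("number_of_vessels", "dilated_vessels", "trafficking",
    "intratumor_inflammation", "peritumor_inflammation",
    "perivascular_inflammation")
}

# ---- internal helpers -------------------------------------------------------

smooth_noise_field <- function(H, W, sigma, lo, hi) {
  f <- EBImage::gblur(matrix(runif(H * W), H, W), sigma = sigma)
  r <- range(f)
  if (diff(r) == 0) return(matrix((lo + hi) / 2, H, W))
  lo + (f - r[1]) / diff(r) * (hi - lo)
}

# smooth random field in [-1, 1] built by bilinear upsampling of an 8x8 grid
coarse_random_field <- function(H, W, n0 = 8) {
  base <- matrix(runif(n0 * n0, -1, 1), n0, n0)
  resize_field(base, H, W)
}

arclength_path <- function(xs, ys) {
  s <- c(0, cumsum(sqrt(diff(xs)^2 + diff(ys)^2)))
  list(x = xs, y = ys, s = s)
}

# reflect positions s into [0, L] (triangle-wave folding)
reflect_path <- function(s, L) {
  s <- s %% (2 * L)
  ifelse(s > L, 2 * L - s, s)
}

stamp_disks <- function(mask, xs, ys, radius) {
  H <- nrow(mask); W <- ncol(mask)
  r <- ceiling(radius)
  for (k in seq_along(xs)) {
    i0 <- max(1, floor(ys[k]) - r); i1 <- min(H, ceiling(ys[k]) + r)
    j0 <- max(1, floor(xs[k]) - r); j1 <- min(W, ceiling(xs[k]) + r)
    ii <- i0:i1; jj <- j0:j1
    d2 <- outer((ii - ys[k])^2, (jj - xs[k])^2, "+")
    mask[ii, jj] <- mask[ii, jj] | (d2 <= radius^2)
  }
  mask
}

ellipse_mask <- function(H, W, cy, cx, a, b, theta) {
  r <- ceiling(a) + 1
  i0 <- max(1, floor(cy) - r); i1 <- min(H, ceiling(cy) + r)
  j0 <- max(1, floor(cx) - r); j1 <- min(W, ceiling(cx) + r)
  m <- matrix(FALSE, H, W)
  ii <- i0:i1; jj <- j0:j1
  dy <- outer(ii - cy, rep(1, length(jj)))
  dx <- outer(rep(1, length(ii)), jj - cx)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  m[ii, jj] <- (u / a)^2 + (v / b)^2 <= 1
  m
}

place_separated <- function(n, H, W, margin, min_dist, max_tries = 5000) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  pts <- matrix(NA_real_, n, 2)
  placed <- 0
  for (try in seq_len(max_tries)) {
    cand <- c(runif(1, margin, H - margin), runif(1, margin, W - margin))
    ok <- placed == 0 ||
      min(sqrt(rowSums((pts[seq_len(placed), , drop = FALSE] -
                          matrix(cand, placed, 2, byrow = TRUE))^2))) >= min_dist
    if (ok) {
      placed <- placed + 1
      pts[placed, ] <- cand
      if (placed == n) return(pts)
    }
  }
  stop("could not place ", n, " objects with the requested separation")
}

add_gaussian_blob <- function(f, cy, cx, amplitude, sigma) {
  H <- nrow(f); W <- ncol(f)
  r <- ceiling(3 * sigma)
  i0 <- max(1, floor(cy) - r); i1 <- min(H, ceiling(cy) + r)
  j0 <- max(1, floor(cx) - r); j1 <- min(W, ceiling(cx) + r)
  ii <- i0:i1; jj <- j0:j1
  g <- amplitude * exp(-outer((ii - cy)^2, (jj - cx)^2, "+") / (2 * sigma^2))
  f[ii, jj] <- f[ii, jj] + g
  f
}
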