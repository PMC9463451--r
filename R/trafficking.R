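#' Tracklet filtering thresholds for leukocyte trafficking
#'
#' The per-window thresholds used to separate genuine trafficking events
#' from spurious tracklets. Three temporal windows of 3/4/5 frames
#' (0.6 s / 0.8 s / 1.0 s at 5 frames per second) are evaluated; a tracklet
#' is counted for a window if its duration reaches the window length, its
#' start-to-end displacement and mean detection quality reach the window's
#' minima, and its motion consistency (mean turning angle) stays below the
#' angular cap.
#'
#' @param pixel_per_um spatial scale used for the micron equivalents.
#' @return An object of class `trafficking_thresholds` with index-aligned
#'   vectors `windows_s`, `windows_frames`, `displacement_px`,
#'   `displacement_um`, `consistency_deg` and `quality`.
#' @export
trafficking_thresholds <- function(pixel_per_um = 1.33) {
  structure(list(
    windows_s = c(0.6, 0.8, 1.0),
    windows_frames = c(3L, 4L, 5L),
    displacement_px = c(20.5, 22.5, 22.5),
    displacement_um = round(c(20.5, 22.5, 22.5) / pixel_per_um, 2),
    consistency_deg = c(58, 58, 58),
    quality = c(1.6, 1.65, 1.75)),
    class = "trafficking_thresholds")
}

#' Rolling-median background subtraction
#'
#' Estimates a per-frame background as the per-pixel median over a temporal
#' window (default 6 s) centered on the current frame, truncated at the
#' video boundaries, and subtracts it. Static tissue texture cancels while
#' transient bright objects (moving cells) are preserved; the output is
#' signed.
#'
#' @param video a [video_stack].
#' @param window_s temporal window in seconds; converted to
#'   `round(window_s / frame_interval_s)` frames (must be at least 3).
#' @return A [video_stack] of background-subtracted (signed) frames.
#' @export
subtract_background <- function(video, window_s = 6) {
  stopifnot(inherits(video, "video_stack"))
  if (n_frames(video) < 2) stop("background subtraction needs at least 2 frames")
  w <- round(window_s / video$frame_interval_s)
  if (w < 3) stop("temporal window of ", w, " frames is too short (need >= 3)")
  bg <- .temporal_median_cpp(video$frames, w %/% 2)
  out <- video
  out$frames <- video$frames - bg
  out
}

#' Subpixel difference-of-Gaussians spot detection
#'
#' Band-pass blob detection tuned to a given spot radius: the frame is
#' filtered with a difference of Gaussians (`sigma = radius/sqrt(2)`, ratio
#' 1.6), positive local maxima are refined to subpixel positions by a 2-D
#' quadratic fit, and each detection's quality is the blob-amplitude
#' estimate implied by the DoG response (the center response of a matched
#' Gaussian blob of unit amplitude is known in closed form) times
#' `quality_scale`. Quality is therefore in arbitrary units, calibrated so
#' the default detection threshold of 1.6 sits between the speckle noise
#' floor and the response of a typical trafficking cell.
#'
#' @param frame numeric matrix (background-subtracted, signed allowed; only
#'   bright spots are detected).
#' @param radius_px expected spot radius in px.
#' @param quality_threshold minimum quality for a detection.
#' @param quality_scale arbitrary-unit scaling of the amplitude estimate.
#' @return data.frame with `x` (column), `y` (row), subpixel, and `quality`;
#'   zero rows when nothing exceeds the threshold.
#' @export
detect_spots <- function(frame, radius_px = 7.5, quality_threshold = 1.6,
                         quality_scale = 4) {
  stopifnot(all(is.finite(frame)))
  s1 <- radius_px / sqrt(2)
  s2 <- 1.6 * s1
  dog <- EBImage::gblur(frame, sigma = s1) - EBImage::gblur(frame, sigma = s2)
  # center response of a matched unit-amplitude Gaussian blob (2-D)
  resp <- s1^2 / (s1^2 + s1^2) - s1^2 / (s1^2 + s2^2)
  q <- dog / resp * quality_scale
  H <- nrow(q); W <- ncol(q)
  if (H < 3 || W < 3) return(empty_detections())
  core <- q[2:(H - 1), 2:(W - 1)]
  is_max <- core >= quality_threshold
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max <- is_max & (core > q[2:(H - 1) + di, 2:(W - 1) + dj] -
                          .Machine$double.eps * 4)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty_detections())
  rows <- idx[, 1] + 1L
  cols <- idx[, 2] + 1L
  out <- data.frame(x = numeric(nrow(idx)), y = numeric(nrow(idx)),
                    quality = q[cbind(rows, cols)])
  for (k in seq_len(nrow(idx))) {
    off <- quadratic_subpixel(q, rows[k], cols[k])
    out$y[k] <- rows[k] + off[1]
    out$x[k] <- cols[k] + off[2]
  }
  out[order(-out$quality), , drop = FALSE]
}

empty_detections <- function() {
  data.frame(x = numeric(0), y = numeric(0), quality = numeric(0))
}

# 2-D quadratic interpolation of a local maximum from its 3x3 neighbourhood
quadratic_subpixel <- function(q, i, j) {
  n <- q[(i - 1):(i + 1), (j - 1):(j + 1)]
  gy <- (n[3, 2] - n[1, 2]) / 2
  gx <- (n[2, 3] - n[2, 1]) / 2
  hyy <- n[3, 2] - 2 * n[2, 2] + n[1, 2]
  hxx <- n[2, 3] - 2 * n[2, 2] + n[2, 1]
  hxy <- (n[3, 3] - n[3, 1] - n[1, 3] + n[1, 1]) / 4
  det <- hyy * hxx - hxy^2
  if (!is.finite(det) || abs(det) < 1e-12) return(c(0, 0))
  dy <- -(hxx * gy - hxy * gx) / det
  dx <- -(hyy * gx - hxy * gy) / det
  pmin(pmax(c(dy, dx), -0.5), 0.5)
}

#' Link detections across frames by minimum-cost linear assignment
#'
#' Frame-to-frame linking with squared-distance costs, a maximum match
#' distance, and no splitting, merging or gap closing: unmatched detections
#' start or terminate tracklets. Each frame pair is solved as a linear
#' assignment problem augmented with birth/death slots at cost
#' `(1.05 * max_link_px)^2`, so a link is made exactly when it is cheaper
#' than letting both endpoints go unmatched.
#'
#' @param detections list of per-frame data.frames as returned by
#'   [detect_spots] (consecutive frames; empty frames allowed).
#' @param max_link_px maximum link distance in px.
#' @return List of `tracklet` objects; each holds a `detections` data.frame
#'   with `frame`, `x`, `y`, `quality` over strictly consecutive frames and
#'   at least 2 detections.
#' @export
link_detections <- function(detections, max_link_px = 20) {
  T <- length(detections)
  b <- (1.05 * max_link_px)^2
  # open[[k]]: growing chains, each a data.frame of detections
  chains <- list()
  open <- integer(0) # chain index per detection alive in current frame
  finished <- list()
  prev <- NULL
  for (t in seq_len(T)) {
    cur <- detections[[t]]
    if (is.null(cur)) cur <- empty_detections()
    n <- if (is.null(prev)) 0L else nrow(prev)
    m <- nrow(cur)
    link_to <- rep(NA_integer_, m) # index into prev for each current det
    if (n > 0 && m > 0) {
      d2 <- outer(prev$y, cur$y, "-")^2 + outer(prev$x, cur$x, "-")^2
      feas <- d2 <= max_link_px^2
      if (any(feas)) {
        BIG <- (max(d2[feas], b) + b) * (n + m + 1)
        cost <- matrix(0, n + m, n + m)
        cost[1:n, 1:m] <- ifelse(feas, d2, BIG)
        cost[1:n, (m + 1):(m + n)] <- BIG
        cost[(n + 1):(n + m), 1:m] <- BIG
        for (i in 1:n) cost[i, m + i] <- b
        for (j in 1:m) cost[n + j, j] <- b
        a <- solve_lap(cost)
        for (i in 1:n)
          if (a[i] <= m && feas[i, a[i]]) link_to[a[i]] <- i
      }
    }
    new_open <- integer(m)
    if (m > 0) {
      for (j in 1:m) {
        det_row <- data.frame(frame = t, x = cur$x[j], y = cur$y[j],
                              quality = cur$quality[j])
        if (!is.na(link_to[j])) {
          ci <- open[link_to[j]]
          chains[[ci]] <- rbind(chains[[ci]], det_row)
          new_open[j] <- ci
        } else {
          chains[[length(chains) + 1]] <- det_row
          new_open[j] <- length(chains)
        }
      }
    }
    open <- new_open
    prev <- cur
  }
  chains <- Filter(function(ch) nrow(ch) >= 2, chains)
  lapply(chains, function(ch) structure(list(detections = ch), class = "tracklet"))
}

#' Derived tracklet features
#'
#' @param tracklet a `tracklet` from [link_detections].
#' @param pixel_per_um spatial scale in pixels per micron.
#' @param frame_interval_s frame interval in seconds.
#' @return List with `displacement_px`, `displacement_um` (straight-line
#'   start-to-end distance), `duration_s` (`n_detections * frame_interval_s`,
#'   so 3/4/5-frame tracklets at 5 fps span 0.6/0.8/1.0 s), `consistency_deg`
#'   (mean absolute angle between successive motion vectors; zero-length
#'   steps are skipped, and a tracklet with no usable step pair has
#'   consistency 0) and `mean_quality`.
#' @export
compute_tracklet_features <- function(tracklet, pixel_per_um = 1.33,
                                      frame_interval_s = 0.2) {
  d <- tracklet$detections
  nd <- nrow(d)
  if (nd < 2) stop("a tracklet needs at least 2 detections")
  disp <- sqrt((d$x[nd] - d$x[1])^2 + (d$y[nd] - d$y[1])^2)
  vx <- diff(d$x); vy <- diff(d$y)
  len <- sqrt(vx^2 + vy^2)
  angles <- numeric(0)
  for (i in seq_len(nd - 2)) {
    if (len[i] == 0 || len[i + 1] == 0) next
    cosang <- (vx[i] * vx[i + 1] + vy[i] * vy[i + 1]) / (len[i] * len[i + 1])
    angles <- c(angles, acos(pmin(pmax(cosang, -1), 1)) * 180 / pi)
  }
  list(displacement_px = disp,
       displacement_um = px_to_um(disp, pixel_per_um),
       duration_s = nd * frame_interval_s,
       consistency_deg = if (length(angles)) mean(angles) else 0,
       mean_quality = mean(d$quality))
}

#' Filter tracklets with the per-window thresholds
#'
#' Keeps tracklets with `duration_s >= windows_s[i]`,
#' `displacement_px >= displacement_px[i]`,
#' `consistency_deg <= consistency_deg[i]` and
#' `mean_quality >= quality[i]` for window `i`.
#'
#' @param tracklets list of tracklets.
#' @param thresholds a [trafficking_thresholds].
#' @param window_index window 1, 2 or 3 (the 0.6 s / 0.8 s / 1.0 s windows).
#' @param pixel_per_um,frame_interval_s calibration for the derived features.
#' @return The surviving tracklets.
#' @export
filter_tracklets <- function(tracklets, thresholds = trafficking_thresholds(),
                             window_index, pixel_per_um = 1.33,
                             frame_interval_s = 0.2) {
  if (!window_index %in% 1:3) stop("window_index must be 1, 2 or 3")
  i <- window_index
  keep <- vapply(tracklets, function(tr) {
    f <- compute_tracklet_features(tr, pixel_per_um, frame_interval_s)
    f$duration_s >= thresholds$windows_s[i] - 1e-9 &&
      f$displacement_px >= thresholds$displacement_px[i] &&
      f$consistency_deg <= thresholds$consistency_deg[i] &&
      f$mean_quality >= thresholds$quality[i]
  }, logical(1))
  tracklets[keep]
}

#' Count leukocyte-trafficking events per temporal window
#'
#' Runs the full trafficking pipeline on a stabilized video: rolling-median
#' background subtraction, per-frame subpixel DoG spot detection,
#' linear-assignment linking and per-window tracklet filtering. Each
#' surviving tracklet counts once.
#'
#' @param video a stabilized [video_stack].
#' @param thresholds a [trafficking_thresholds].
#' @param radius_px,quality_scale,max_link_px,window_s stage parameters, see
#'   [detect_spots], [link_detections] and [subtract_background].
#' @return Named integer vector of counts for the 0.6 s, 0.8 s and 1.0 s
#'   windows, with the tracklet list attached as attribute `tracklets`.
#' @export
count_trafficking <- function(video, thresholds = trafficking_thresholds(),
                              radius_px = 7.5, quality_scale = 4,
                              max_link_px = 20, window_s = 6) {
  bg <- subtract_background(video, window_s = window_s)
  dets <- lapply(seq_len(n_frames(bg)), function(t)
    detect_spots(bg$frames[, , t], radius_px = radius_px,
                 quality_threshold = min(thresholds$quality),
                 quality_scale = quality_scale))
  tracklets <- link_detections(dets, max_link_px = max_link_px)
  counts <- vapply(1:3, function(w)
    length(filter_tracklets(tracklets, thresholds, w,
                            pixel_per_um = video$pixel_per_um,
                            frame_interval_s = video$frame_interval_s)),
    integer(1))
  names(counts) <- sprintf("window_%.1fs", thresholds$windows_s)
  attr(counts, "tracklets") <- tracklets
  counts
}
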