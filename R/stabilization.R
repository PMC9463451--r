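#' Linear keypoint pre-alignment of a video
#'
#' First stabilization step: removes large-scale motion by registering every
#' frame to the first frame with a rigid (default) or affine transform
#' estimated from matched scale-invariant blob keypoints. Keypoints are
#' difference-of-Gaussians extrema detected at two scales, described by
#' normalized intensity patches and matched by normalized cross-correlation
#' with a ratio test; the transform is fit by least squares with iterative
#' outlier trimming. Frames whose match support is too weak (< 4 consistent
#' matches) keep the identity transform and raise a warning. Out-of-view
#' pixels are filled with 0 (the pipeline's "blank" value).
#'
#' @param video a [video_stack] with at least 2 frames.
#' @param transform `"rigid"` (rotation + translation) or `"affine"`.
#' @return List with `video` (the pre-aligned [video_stack]) and
#'   `transforms`, a list of per-frame 2 x 3 matrices `[A | t]` mapping
#'   reference (row, col) coordinates to source-frame coordinates.
#' @export
prealign_linear <- function(video, transform = c("rigid", "affine")) {
  stopifnot(inherits(video, "video_stack"))
  transform <- match.arg(transform)
  T <- n_frames(video)
  if (T < 2) stop("pre-alignment needs at least 2 frames")
  ref <- video$frames[, , 1]
  kp_ref <- keypoints_with_descriptors(ref)
  out <- video$frames
  identity_tf <- cbind(diag(2), c(0, 0))
  transforms <- rep(list(identity_tf), T)
  for (t in 2:T) {
    mov <- video$frames[, , t]
    kp_mov <- keypoints_with_descriptors(mov)
    mt <- match_keypoints(kp_ref, kp_mov)
    tf <- NULL
    if (nrow(mt) >= 4)
      tf <- fit_point_transform(kp_ref$pts[mt[, 1], , drop = FALSE],
                                kp_mov$pts[mt[, 2], , drop = FALSE], transform)
    if (is.null(tf)) {
      warning(sprintf("frame %d: fewer than 4 consistent keypoint matches; using identity", t))
      next
    }
    transforms[[t]] <- tf
    out[, , t] <- apply_linear_transform(mov, tf)
  }
  res <- video
  res$frames <- out
  list(video = res, transforms = transforms)
}

#' Automatic cropping of blank borders
#'
#' Computes the temporal-minimum image of an aligned video (a pixel is
#' "blank", value exactly 0, iff it fell out of view in at least one frame)
#' and iteratively removes, among the four current boundary lines (top row,
#' bottom row, left column, right column), the one containing the most
#' blank pixels, until every boundary line has a blank fraction at or below
#' `blank_fraction`. Ties are broken in the order top, bottom, left, right.
#'
#' @param video a [video_stack] (already aligned) or an `H x W x T` array.
#' @param blank_fraction stopping threshold on the boundary blank fraction.
#' @param min_size smallest allowed height/width; cropping below it errors.
#' @return The crop rectangle as a list `(row0, col0, height, width)` in
#'   0-based half-open pixel coordinates.
#' @export
auto_crop <- function(video, blank_fraction = 0.75, min_size = 16) {
  frames <- if (inherits(video, "video_stack")) video$frames else video
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1))
  tmin <- apply(frames, c(1, 2), min)
  blank <- tmin == 0
  r0 <- 1L; r1 <- nrow(blank); c0 <- 1L; c1 <- ncol(blank)
  repeat {
    counts <- c(top = sum(blank[r0, c0:c1]),
                bottom = sum(blank[r1, c0:c1]),
                left = sum(blank[r0:r1, c0]),
                right = sum(blank[r0:r1, c1]))
    lens <- c(c1 - c0 + 1L, c1 - c0 + 1L, r1 - r0 + 1L, r1 - r0 + 1L)
    frac <- counts / lens
    if (all(frac <= blank_fraction)) break
    side <- which.max(counts) # ties: top, bottom, left, right precedence
    if (side <= 2 && r1 - r0 < min_size)
      stop("auto_crop would reduce height below ", min_size, " px")
    if (side > 2 && c1 - c0 < min_size)
      stop("auto_crop would reduce width below ", min_size, " px")
    if (side == 1) r0 <- r0 + 1L
    else if (side == 2) r1 <- r1 - 1L
    else if (side == 3) c0 <- c0 + 1L
    else c1 <- c1 - 1L
  }
  list(row0 = r0 - 1L, col0 = c0 - 1L,
       height = r1 - r0 + 1L, width = c1 - c0 + 1L)
}

#' Crop a video to a rectangle from [auto_crop]
#'
#' @param video a [video_stack].
#' @param rect crop rectangle `(row0, col0, height, width)`, 0-based.
#' @return The cropped [video_stack].
#' @export
crop_video <- function(video, rect) {
  rows <- (rect$row0 + 1):(rect$row0 + rect$height)
  cols <- (rect$col0 + 1):(rect$col0 + rect$width)
  out <- video
  out$frames <- video$frames[rows, cols, , drop = FALSE]
  out
}

#' Chained nonlinear (demons) stabilization
#'
#' Second stabilization step: removes smooth tissue deformation by chaining
#' demons nonlinear registration through the video. Frame t+1 is first
#' histogram-matched to the already-stabilized frame t (256 quantile bins),
#' then registered to it with multi-resolution demons (default 4 pyramid
#' levels with steeply decreasing iterations `[100, 50, 10, 1]` from
#' coarsest to finest, Gaussian field smoothing sigma 1 at each level);
#' frame t+2 registers to the transformed t+1, and so on. A second
#' [auto_crop] pass then removes regions not in view throughout the movie.
#'
#' @param video a [video_stack], already linearly pre-aligned and cropped.
#' @param pyramid_levels number of resolution levels.
#' @param iterations_per_level iterations per level, coarsest first.
#' @param smoothing_sigma Gaussian smoothing of the displacement field.
#' @param blank_fraction threshold for the final cropping pass.
#' @return An object of class `stabilization_result`: `stabilized` (the
#'   cropped [video_stack]), `crop_rect`, and `residual_motion_score` (mean
#'   per-pixel temporal variance after stabilization). A single-frame video
#'   is returned unchanged with identity fields.
#' @export
stabilize_nonlinear <- function(video, pyramid_levels = 4,
                                iterations_per_level = c(100, 50, 10, 1),
                                smoothing_sigma = 1.0, blank_fraction = 0.75) {
  stopifnot(inherits(video, "video_stack"))
  T <- n_frames(video)
  if (T == 1) {
    return(structure(list(stabilized = video,
                          crop_rect = list(row0 = 0L, col0 = 0L,
                                           height = dim(video)[1],
                                           width = dim(video)[2]),
                          residual_motion_score = 0),
                     class = "stabilization_result"))
  }
  out <- video$frames
  for (t in 2:T) {
    ref <- out[, , t - 1]
    mov <- histogram_match(video$frames[, , t], ref)
    field <- demons_register(ref, mov, pyramid_levels, iterations_per_level,
                             smoothing_sigma)
    out[, , t] <- .warp_bilinear_cpp(mov, field$dy, field$dx, 0)
  }
  res <- video
  res$frames <- out
  rect <- auto_crop(res, blank_fraction = blank_fraction)
  res <- crop_video(res, rect)
  structure(list(stabilized = res, crop_rect = rect,
                 residual_motion_score = mean_pixel_variance(res$frames)),
            class = "stabilization_result")
}

#' @export
print.stabilization_result <- function(x, ...) {
  cat(sprintf("stabilization_result: %s, residual motion %.4g\n",
              paste(dim(x$stabilized$frames), collapse = " x "),
              x$residual_motion_score))
  invisible(x)
}

# ---- internal: keypoints ----------------------------------------------------

# DoG blob keypoints at two scales with normalized 11x11 patch descriptors
keypoints_with_descriptors <- function(img, radii = c(4, 8), n_per_scale = 80,
                                       patch = 5L) {
  pts <- NULL
  H <- nrow(img); W <- ncol(img)
  for (r in radii) {
    s1 <- r / sqrt(2)
    dog <- EBImage::gblur(img, sigma = s1) - EBImage::gblur(img, sigma = 1.6 * s1)
    a <- abs(dog)
    core <- a[2:(H - 1), 2:(W - 1)]
    is_max <- core > 0
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      is_max <- is_max & (core >= a[2:(H - 1) + di, 2:(W - 1) + dj])
    }
    idx <- which(is_max, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    resp <- core[idx]
    ord <- order(-resp)
    idx <- idx[ord[seq_len(min(n_per_scale, length(ord)))], , drop = FALSE]
    pts <- rbind(pts, cbind(idx[, 1] + 1L, idx[, 2] + 1L))
  }
  if (is.null(pts)) pts <- matrix(numeric(0), 0, 2)
  keep <- pts[, 1] > patch & pts[, 1] <= H - patch &
    pts[, 2] > patch & pts[, 2] <= W - patch
  pts <- pts[keep, , drop = FALSE]
  desc <- matrix(NA_real_, nrow(pts), (2 * patch + 1)^2)
  ok <- rep(TRUE, nrow(pts))
  for (k in seq_len(nrow(pts))) {
    p <- img[(pts[k, 1] - patch):(pts[k, 1] + patch),
             (pts[k, 2] - patch):(pts[k, 2] + patch)]
    s <- sd(p)
    if (!is.finite(s) || s == 0) { ok[k] <- FALSE; next }
    desc[k, ] <- (p - mean(p)) / s
  }
  list(pts = pts[ok, , drop = FALSE], desc = desc[ok, , drop = FALSE])
}

# mutual-best NCC matching with a ratio test
match_keypoints <- function(a, b, min_ncc = 0.8, ratio = 1.02) {
  na <- nrow(a$pts); nb <- nrow(b$pts)
  if (na == 0 || nb == 0) return(matrix(integer(0), 0, 2))
  ncc <- a$desc %*% t(b$desc) / (ncol(a$desc) - 1)
  best_b <- max.col(ncc)
  best_a <- max.col(t(ncc))
  out <- NULL
  for (i in seq_len(na)) {
    j <- best_b[i]
    if (best_a[j] != i) next
    v <- ncc[i, j]
    if (v < min_ncc) next
    second <- if (nb > 1) max(ncc[i, -j]) else -Inf
    if (is.finite(second) && second > 0 && v < second * ratio) next
    out <- rbind(out, c(i, j))
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# least-squares rigid/affine fit mapping ref points -> moving points,
# with iterative residual trimming; NULL if support collapses
fit_point_transform <- function(ref_pts, mov_pts, transform,
                                max_rounds = 3, inlier_px = 2) {
  ref <- ref_pts; mov <- mov_pts
  for (round in seq_len(max_rounds)) {
    if (nrow(ref) < 4) return(NULL)
    tf <- if (transform == "rigid") fit_rigid(ref, mov) else fit_affine(ref, mov)
    if (is.null(tf)) return(NULL)
    pred <- ref %*% t(tf[, 1:2]) + matrix(tf[, 3], nrow(ref), 2, byrow = TRUE)
    res <- sqrt(rowSums((pred - mov)^2))
    thr <- max(inlier_px, 3 * median(res))
    keep <- res <= thr
    if (all(keep)) break
    ref <- ref[keep, , drop = FALSE]
    mov <- mov[keep, , drop = FALSE]
  }
  if (nrow(ref) < 4 || mean(res[res <= thr]) > inlier_px) return(NULL)
  tf
}

# Kabsch fit of mov ~ ref %*% R + t (points as (row, col) row vectors);
# returned as 2x3 [A | t] acting on column vectors, A = t(R)
fit_rigid <- function(ref, mov) {
  cr <- colMeans(ref); cm <- colMeans(mov)
  X <- sweep(ref, 2, cr); Y <- sweep(mov, 2, cm)
  s <- svd(t(X) %*% Y)
  d <- det(s$u) * det(s$v)
  R <- s$u %*% diag(c(1, d)) %*% t(s$v)
  A <- t(R)
  cbind(A, cm - as.vector(A %*% cr))
}

fit_affine <- function(ref, mov) {
  X <- cbind(ref, 1)
  fit <- tryCatch(qr.solve(X, mov), error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cbind(t(fit[1:2, ]), fit[3, ])
}

# resample a frame through a 2x3 transform [A | t] on (row, col) coordinates
apply_linear_transform <- function(img, tf) {
  H <- nrow(img); W <- ncol(img)
  rows <- matrix(seq_len(H) - 1, H, W)
  cols <- matrix(seq_len(W) - 1, H, W, byrow = TRUE)
  sy <- tf[1, 1] * rows + tf[1, 2] * cols + tf[1, 3]
  sx <- tf[2, 1] * rows + tf[2, 2] * cols + tf[2, 3]
  .warp_bilinear_cpp(img, sy - rows, sx - cols, 0)
}

# ---- internal: demons -------------------------------------------------------

# quantile-based histogram matching (256 bins)
histogram_match <- function(src, ref, n_bins = 256) {
  qs <- seq(0, 1, length.out = n_bins + 1)
  src_q <- quantile(src, qs, names = FALSE)
  ref_q <- quantile(ref, qs, names = FALSE)
  if (diff(range(src_q)) == 0) return(src + (mean(ref) - mean(src)))
  matrix(approx(src_q, ref_q, xout = src, ties = mean, rule = 2)$y,
         nrow(src), ncol(src))
}

# multi-resolution demons registration; returns displacement fields (dy, dx)
# such that moving(p + d(p)) ~ fixed(p)
demons_register <- function(fixed, moving, pyramid_levels, iterations,
                            smoothing_sigma) {
  stopifnot(length(iterations) == pyramid_levels)
  # keep the coarsest level at >= 16 px so the Gaussian kernels fit
  max_levels <- max(1, floor(log2(min(dim(fixed)) / 16)) + 1)
  if (pyramid_levels > max_levels) {
    iterations <- iterations[seq_len(max_levels)]
    pyramid_levels <- max_levels
  }
  pyr_f <- build_pyramid(fixed, pyramid_levels)
  pyr_m <- build_pyramid(moving, pyramid_levels)
  dy <- dx <- NULL
  for (level in pyramid_levels:1) {
    f <- pyr_f[[level]]; m <- pyr_m[[level]]
    if (is.null(dy)) {
      dy <- matrix(0, nrow(f), ncol(f)); dx <- dy
    } else {
      dy <- resize_field(dy, nrow(f), ncol(f)) * 2
      dx <- resize_field(dx, nrow(f), ncol(f)) * 2
    }
    gy <- grad_y(f); gx <- grad_x(f)
    g2 <- gy^2 + gx^2
    for (it in seq_len(iterations[pyramid_levels - level + 1])) {
      warped <- .warp_bilinear_cpp(m, dy, dx, 0)
      diff <- f - warped
      denom <- g2 + diff^2
      step <- ifelse(denom > 1e-9, diff / denom, 0)
      dy <- EBImage::gblur(dy + step * gy, sigma = smoothing_sigma)
      dx <- EBImage::gblur(dx + step * gx, sigma = smoothing_sigma)
    }
  }
  list(dy = dy, dx = dx)
}

build_pyramid <- function(img, levels) {
  pyr <- vector("list", levels)
  pyr[[1]] <- img
  for (l in seq_len(levels - 1)) {
    prev <- pyr[[l]]
    sm <- EBImage::gblur(prev, sigma = 1)
    pyr[[l + 1]] <- resize_field(sm, ceiling(nrow(prev) / 2), ceiling(ncol(prev) / 2))
  }
  pyr
}

# bilinear resize of a matrix to explicit dimensions
resize_field <- function(m, new_h, new_w) {
  H <- nrow(m); W <- ncol(m)
  ri <- seq(1, H, length.out = new_h)
  ci <- seq(1, W, length.out = new_w)
  rows <- matrix(ri, new_h, new_w)
  cols <- matrix(ci, new_h, new_w, byrow = TRUE)
  i0 <- pmin(floor(rows), H - 1); j0 <- pmin(floor(cols), W - 1)
  fy <- rows - i0; fx <- cols - j0
  m00 <- matrix(m[cbind(as.vector(i0), as.vector(j0))], new_h, new_w)
  m01 <- matrix(m[cbind(as.vector(i0), as.vector(j0 + 1))], new_h, new_w)
  m10 <- matrix(m[cbind(as.vector(i0 + 1), as.vector(j0))], new_h, new_w)
  m11 <- matrix(m[cbind(as.vector(i0 + 1), as.vector(j0 + 1))], new_h, new_w)
  (1 - fy) * ((1 - fx) * m00 + fx * m01) + fy * ((1 - fx) * m10 + fx * m11)
}

grad_y <- function(m) {
  H <- nrow(m)
  rbind(m[2, ] - m[1, ],
        (m[3:H, , drop = FALSE] - m[1:(H - 2), , drop = FALSE]) / 2,
        m[H, ] - m[H - 1, ])
}

grad_x <- function(m) t(grad_y(t(m)))
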