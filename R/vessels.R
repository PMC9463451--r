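#' Temporal-variation map of a stabilized video
#'
#' Blood vessels appear in stabilized RCM videos as the regions of high
#' frame-to-frame intensity variation (flowing blood cells change the
#' backscatter signal while the surrounding tissue is static). Each frame
#' is Gaussian-smoothed to suppress speckle, a temporal finite-impulse-
#' response high-pass filter is applied across consecutive frames, the
#' absolute response is median-filtered spatially, each variation frame has
#' its mean subtracted (negatives clipped to 0) to remove slowly varying
#' areas, and the result is accumulated as the mean over frames.
#'
#' The FIR kernel (0.5, -1, 0.5) is a second difference: it annihilates
#' constant and linearly ramping intensities, so only genuine frame-to-frame
#' fluctuation survives.
#'
#' @param video a [video_stack] with at least 3 frames (after any stride).
#' @param gaussian_sigma_px spatial smoothing sigma in px.
#' @param fir_kernel temporal high-pass kernel.
#' @param median_window_px side of the square spatial median window.
#' @param frame_stride use every `frame_stride`-th frame (1 = all frames).
#' @return An object of class `variation_map` with `values` (non-negative
#'   `H x W` map) and `n_frames_used`.
#' @export
variation_map <- function(video, gaussian_sigma_px = 1,
                          fir_kernel = c(0.5, -1, 0.5),
                          median_window_px = 7, frame_stride = 1) {
  stopifnot(inherits(video, "video_stack"))
  frames <- video$frames
  if (frame_stride > 1)
    frames <- frames[, , seq(1, dim(frames)[3], by = frame_stride), drop = FALSE]
  T <- dim(frames)[3]
  k <- length(fir_kernel)
  if (T < k) stop("variation map needs at least ", k, " frames")
  smoothed <- frames
  for (t in seq_len(T))
    smoothed[, , t] <- EBImage::gblur(frames[, , t], sigma = gaussian_sigma_px)
  H <- dim(frames)[1]; W <- dim(frames)[2]
  radius <- (median_window_px - 1) %/% 2
  acc <- matrix(0, H, W)
  n_used <- T - k + 1
  for (t in seq_len(n_used)) {
    v <- matrix(0, H, W)
    for (j in seq_len(k)) v <- v + fir_kernel[j] * smoothed[, , t + j - 1]
    v <- .median_filter2d_cpp(abs(v), radius)
    v <- v - mean(v)
    acc <- acc + pmax(v, 0)
  }
  structure(list(values = acc / n_used, n_frames_used = n_used),
            class = "variation_map")
}

#' Segment vessels from a variation map
#'
#' Otsu thresholding on the accumulated variation map, followed by
#' morphological closing (disk structuring element) and removal of
#' connected components smaller than `min_area_frac` or larger than
#' `max_area_frac` of the frame.
#'
#' @param vmap a [variation_map] (or a plain non-negative matrix).
#' @param min_area_frac,max_area_frac component-size gates as fractions of
#'   the frame area; components with
#'   `ceiling(min_area_frac * N) <= size <= floor(max_area_frac * N)` px
#'   are kept.
#' @param closing_radius_px disk radius of the closing structuring element.
#' @return An object of class `vessel_mask` with logical `mask` and
#'   `connectivity = 8`. A degenerate all-equal map yields an empty mask
#'   with a warning (no threshold exists).
#' @export
segment_vessels <- function(vmap, min_area_frac = 0.001, max_area_frac = 0.10,
                            closing_radius_px = 3) {
  values <- if (inherits(vmap, "variation_map")) vmap$values else vmap
  H <- nrow(values); W <- ncol(values)
  empty <- function() structure(list(mask = matrix(FALSE, H, W), connectivity = 8L),
                                class = "vessel_mask")
  if (diff(range(values)) == 0) {
    warning("variation map is constant; returning an empty vessel mask")
    return(empty())
  }
  norm <- (values - min(values)) / diff(range(values))
  th <- EBImage::otsu(norm, range = c(0, 1), levels = 256L)
  mask <- norm > th
  if (closing_radius_px > 0) {
    brush <- EBImage::makeBrush(2 * closing_radius_px + 1, shape = "disc")
    mask <- EBImage::closing(mask, brush) > 0
  }
  lab <- .label_components_cpp(matrix(as.integer(mask), H, W), 8L)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    lo <- ceiling(min_area_frac * H * W)
    hi <- floor(max_area_frac * H * W)
    keep <- which(sizes >= lo & sizes <= hi)
    mask <- matrix(lab %in% keep, H, W)
  }
  structure(list(mask = mask, connectivity = 8L), class = "vessel_mask")
}

#' Vessel count, area fraction and diameters
#'
#' Components are counted with 8-connectivity. Per-component diameters are
#' taken as twice the Euclidean distance-transform value sampled along the
#' morphological skeleton (centerline) of the mask, converted to microns.
#'
#' @param mask a [segment_vessels] result or a logical matrix.
#' @param pixel_per_um spatial scale in pixels per micron.
#' @return An object of class `vessel_metrics`: `n_vessels`,
#'   `area_fraction`, and `diameters_um`, a data.frame with one row per
#'   component (`component`, `area_px`, `mean_diameter_um`,
#'   `max_diameter_um`).
#' @export
vessel_metrics <- function(mask, pixel_per_um = 1.33) {
  m <- if (inherits(mask, "vessel_mask")) mask$mask else mask
  H <- nrow(m); W <- ncol(m)
  if (!any(m)) {
    return(structure(list(n_vessels = 0L, area_fraction = 0,
                          diameters_um = data.frame(component = integer(0),
                                                    area_px = integer(0),
                                                    mean_diameter_um = numeric(0),
                                                    max_diameter_um = numeric(0))),
                     class = "vessel_metrics"))
  }
  lab <- .label_components_cpp(matrix(as.integer(m), H, W), 8L)
  n <- max(lab)
  dist <- EBImage::distmap(m)
  skel <- .thin_skeleton_cpp(matrix(as.integer(m), H, W)) > 0
  rows <- lapply(seq_len(n), function(cc) {
    sel <- skel & lab == cc
    if (!any(sel)) sel <- lab == cc # degenerate: thinning removed everything
    d <- 2 * dist[sel]
    data.frame(component = cc, area_px = sum(lab == cc),
               mean_diameter_um = px_to_um(mean(d), pixel_per_um),
               max_diameter_um = px_to_um(max(d), pixel_per_um))
  })
  structure(list(n_vessels = n, area_fraction = sum(m) / (H * W),
                 diameters_um = do.call(rbind, rows)),
            class = "vessel_metrics")
}

#' @export
print.vessel_metrics <- function(x, ...) {
  cat(sprintf("vessel_metrics: %d vessels, area fraction %.4f\n",
              x$n_vessels, x$area_fraction))
  if (x$n_vessels > 0) print(x$diameters_um, row.names = FALSE)
  invisible(x)
}

#' Dice similarity coefficient of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param mask_a,mask_b logical matrices of identical shape (or
#'   [segment_vessels] results).
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_coefficient <- function(mask_a, mask_b) {
  a <- if (inherits(mask_a, "vessel_mask")) mask_a$mask else mask_a
  b <- if (inherits(mask_b, "vessel_mask")) mask_b$mask else mask_b
  if (!identical(dim(a), dim(b))) stop("masks must have identical shape")
  a <- a > 0; b <- b > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
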