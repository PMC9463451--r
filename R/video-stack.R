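#' Video stack container
#'
#' An RCM video is held as an `H x W x T` numeric array of grayscale frames
#' together with its temporal and spatial calibration. Individual frames
#' cover 0.75 x 0.75 mm of skin at a scale of 1.33 pixels per micron on the
#' clinical devices this pipeline targets; both values are carried as
#' metadata so all downstream conversions (e.g. vessel diameters in microns)
#' are explicit.
#'
#' @param frames numeric `H x W x T` array (a single matrix is promoted to
#'   `T = 1`). All intensities must be finite.
#' @param frame_interval_s time between consecutive frames in seconds.
#' @param pixel_per_um spatial scale in pixels per micron (default 1.33).
#' @param source_id free-text identifier carried through reports.
#' @return An object of class `video_stack`.
#' @export
video_stack <- function(frames, frame_interval_s = 0.2, pixel_per_um = 1.33,
                        source_id = "") {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  d <- dim(frames)
  if (d[1] < 16 || d[2] < 16) stop("frames must be at least 16 x 16 pixels")
  if (d[3] < 1) stop("video must contain at least one frame")
  if (!all(is.finite(frames))) stop("all frame intensities must be finite")
  if (frame_interval_s <= 0) stop("frame_interval_s must be positive")
  if (pixel_per_um <= 0) stop("pixel_per_um must be positive")
  structure(
    list(frames = frames, frame_interval_s = frame_interval_s,
         pixel_per_um = pixel_per_um, source_id = as.character(source_id)),
    class = "video_stack")
}

#' @export
print.video_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("video_stack: %d frames of %d x %d px, %.3g s/frame, %.3g px/um\n",
              d[3], d[1], d[2], x$frame_interval_s, x$pixel_per_um))
  invisible(x)
}

#' @export
dim.video_stack <- function(x) dim(x$frames)

n_frames <- function(video) dim(video$frames)[3]

#' Read a multi-page TIFF as a video stack
#'
#' @param path TIFF / OME-TIFF file with one grayscale page per frame.
#' @inheritParams video_stack
#' @return A [video_stack].
#' @export
read_video_tiff <- function(path, frame_interval_s = 0.2, pixel_per_um = 1.33) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1] # drop extra channels
    p
  })
  frames <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    info <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    frames <- info$intensity_min +
      frames * (info$intensity_max - info$intensity_min)
    if (!is.null(info$frame_interval_s)) frame_interval_s <- info$frame_interval_s
    if (!is.null(info$pixel_per_um)) pixel_per_um <- info$pixel_per_um
  }
  video_stack(frames, frame_interval_s, pixel_per_um, source_id = basename(path))
}

#' Write a video stack as a multi-page 32-bit float TIFF
#'
#' Intensities are rescaled to the \[0, 1\] storage range; the original
#' range and the temporal/spatial calibration are written to a JSON
#' sidecar (`<path>.json`) so [read_video_tiff] restores them.
#'
#' @param video a [video_stack].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_video_tiff <- function(video, path) {
  rng <- range(video$frames)
  span <- if (diff(rng) > 0) diff(rng) else 1
  jsonlite::write_json(list(intensity_min = rng[1],
                            intensity_max = rng[1] + span,
                            frame_interval_s = video$frame_interval_s,
                            pixel_per_um = video$pixel_per_um),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  frames <- lapply(seq_len(n_frames(video)), function(t)
    (video$frames[, , t] - rng[1]) / span)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Convert a pixel measurement to microns
#'
#' Uses the imaging scale of the RCM device (1.33 px/um by default), e.g.
#' a 7.5 px spot radius corresponds to 5.63 um.
#'
#' @param value_px measurement in pixels.
#' @param pixel_per_um scale in pixels per micron; must be positive.
#' @return The value in microns.
#' @export
px_to_um <- function(value_px, pixel_per_um = 1.33) {
  if (!is.numeric(pixel_per_um) || pixel_per_um <= 0)
    stop("pixel_per_um must be positive")
  value_px / pixel_per_um
}

# mean per-pixel temporal variance (residual-motion score);
# loop form avoids materialising apply(frames, c(1,2), var)
mean_pixel_variance <- function(frames) {
  T <- dim(frames)[3]
  if (T < 2) return(0)
  mu <- rowMeans(frames, dims = 2)
  ss <- 0
  for (t in seq_len(T)) ss <- ss + (frames[, , t] - mu)^2
  mean(ss) / (T - 1)
}
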