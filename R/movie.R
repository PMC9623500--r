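#' Two-channel colony movie container
#'
#' A `movie_stack` holds co-registered live-reporter and dead-stain intensity
#' stacks together with acquisition metadata. Frames are stored as a list of
#' numeric matrices (one per time point, identical dimensions in both
#' channels), frame times in hours, and the pixel size in mm/px.
#'
#' @param frames_live,frames_dead lists of numeric matrices (same length,
#'   same dimensions), non-negative intensities.
#' @param frame_times_h strictly increasing numeric vector of frame times (h).
#' @param pixel_size_mm physical pixel size, mm per pixel.
#' @return an object of class `movie_stack`.
#' @export
movie_stack <- function(frames_live, frames_dead, frame_times_h, pixel_size_mm) {
  stopifnot(is.list(frames_live), is.list(frames_dead))
  if (length(frames_live) != length(frames_dead))
    stop("live and dead channels must have the same number of frames")
  if (length(frames_live) != length(frame_times_h))
    stop("frame_times_h must have one entry per frame")
  if (length(frame_times_h) > 1 && any(diff(frame_times_h) <= 0))
    stop("frame times must be strictly increasing")
  d <- dim(frames_live[[1]])
  for (i in seq_along(frames_live)) {
    if (!identical(dim(frames_live[[i]]), d) || !identical(dim(frames_dead[[i]]), d))
      stop("all frames in both channels must share one dimension")
  }
  if (pixel_size_mm <= 0) stop("pixel_size_mm must be positive")
  structure(
    list(frames_live = frames_live, frames_dead = frames_dead,
         frame_times_h = as.numeric(frame_times_h),
         pixel_size_mm = as.numeric(pixel_size_mm)),
    class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames_live[[1]])
  cat(sprintf("movie_stack: %d frames, %d x %d px, %.4g mm/px, t = %.3g..%.3g h\n",
              length(x$frames_live), d[1], d[2], x$pixel_size_mm,
              min(x$frame_times_h), max(x$frame_times_h)))
  invisible(x)
}

n_frames <- function(stack) length(stack$frames_live)

frame_dim <- function(stack) dim(stack$frames_live[[1]])

#' Get one channel of a movie as a list of matrices
#' @param stack a `movie_stack`.
#' @param channel `"live"` or `"dead"`.
#' @return list of matrices.
#' @export
movie_channel <- function(stack, channel = c("live", "dead")) {
  channel <- match.arg(channel)
  if (channel == "live") stack$frames_live else stack$frames_dead
}

#' Write a movie to disk as two multi-page TIFFs plus a YAML sidecar
#'
#' Each channel is written as a 32-bit float multi-page TIFF
#' (`live.tif`, `dead.tif`); frame times, pixel size and any extra metadata
#' go to `movie.yaml` in the same directory.
#'
#' @param stack a `movie_stack`.
#' @param dir output directory (created if missing).
#' @param extra named list merged into the YAML sidecar (e.g. seed, params).
#' @return `dir`, invisibly.
#' @export
write_movie <- function(stack, dir, extra = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scale <- max(1, max(vapply(stack$frames_live, max, 0)),
               max(vapply(stack$frames_dead, max, 0)))
  ## tiff stores [0,1] floats; record the scale used so reading round-trips
  tiff::writeTIFF(lapply(stack$frames_live, function(m) m / scale),
                  file.path(dir, "live.tif"), bits.per.sample = 32L)
  tiff::writeTIFF(lapply(stack$frames_dead, function(m) m / scale),
                  file.path(dir, "dead.tif"), bits.per.sample = 32L)
  meta <- c(list(frame_times_h = stack$frame_times_h,
                 pixel_size_mm = stack$pixel_size_mm,
                 intensity_scale = scale), extra)
  yaml::write_yaml(meta, file.path(dir, "movie.yaml"))
  invisible(dir)
}

#' Read a movie written by [write_movie()]
#' @param dir directory containing `live.tif`, `dead.tif`, `movie.yaml`.
#' @return a `movie_stack`.
#' @export
read_movie <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "movie.yaml"))
  scale <- meta$intensity_scale %||% 1
  rd <- function(f) lapply(tiff::readTIFF(f, all = TRUE), function(m) m * scale)
  movie_stack(rd(file.path(dir, "live.tif")), rd(file.path(dir, "dead.tif")),
              as.numeric(unlist(meta$frame_times_h)), meta$pixel_size_mm)
}
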