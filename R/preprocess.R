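#' Rolling-ball background subtraction
#'
#' Estimates a smooth background as the grayscale opening of the image with
#' a flat disc structuring element of the given radius and subtracts it,
#' clipping at zero. Structures wider than the element survive in the
#' background and are removed; narrow bright features are preserved. The
#' documented full-scale default radius is 1000 px; for small synthetic
#' images a radius of twice the image width behaves as a flat-field
#' (background = global minimum).
#'
#' @param image 2-D numeric matrix.
#' @param radius_px element radius in pixels (>= 1).
#' @return background-subtracted matrix, pixel-wise `<=` the input and `>= 0`.
#' @export
rolling_ball_subtract <- function(image, radius_px) {
  if (radius_px < 1) stop("radius_px must be >= 1")
  bg <- rolling_ball_background(image, radius_px)
  pmax(image - bg, 0)
}

rolling_ball_background <- function(image, radius_px) {
  r <- floor(radius_px)
  d <- 2 * r + 1
  if (d >= min(dim(image))) return(matrix(min(image), nrow(image), ncol(image)))
  brush <- EBImage::makeBrush(d, shape = "disc")
  ## replicate-pad so the morphology clips the element at the borders
  ## (matching the min/max over the valid window) instead of zero-padding
  ri <- c(rep(1, r), seq_len(nrow(image)), rep(nrow(image), r))
  ci <- c(rep(1, r), seq_len(ncol(image)), rep(ncol(image), r))
  padded <- image[ri, ci]
  ## grayscale morphology operates on [0, 1]; rescale around the opening
  lo <- min(padded); hi <- max(padded)
  if (hi <= lo) return(matrix(lo, nrow(image), ncol(image)))
  opened01 <- as.matrix(EBImage::opening((padded - lo) / (hi - lo), brush))
  opened <- lo + opened01 * (hi - lo)
  opened[r + seq_len(nrow(image)), r + seq_len(ncol(image))]
}

#' Rigid (translation + rotation) transform
#'
#' @param dx_px,dy_px translation in pixels (columns, rows).
#' @param theta_deg rotation about the image centre, degrees.
#' @return a `rigid_transform` list.
#' @export
rigid_transform <- function(dx_px = 0, dy_px = 0, theta_deg = 0) {
  stopifnot(is.finite(dx_px), is.finite(dy_px), is.finite(theta_deg))
  structure(list(dx_px = dx_px, dy_px = dy_px, theta_deg = theta_deg),
            class = "rigid_transform")
}

#' Apply a rigid transform to an image
#'
#' Rotation (about the image centre, bilinear interpolation) followed by
#' translation. Integer translations with zero rotation are exact.
#'
#' @param image 2-D matrix.
#' @param tf a [rigid_transform()].
#' @return transformed matrix, same size.
#' @export
apply_rigid <- function(image, tf) {
  out <- image
  if (abs(tf$theta_deg) > 1e-9)
    out <- rotate_about_center(out, tf$theta_deg)
  if (abs(tf$dy_px) > 1e-9 || abs(tf$dx_px) > 1e-9)
    out <- shift_matrix_subpx(out, tf$dy_px, tf$dx_px)
  out
}

rotate_about_center <- function(image, theta_deg) {
  n <- dim(image)
  ctr <- (n + 1) / 2
  th <- theta_deg * pi / 180
  rr <- matrix(seq_len(n[1]), n[1], n[2]) - ctr[1]
  cc <- matrix(seq_len(n[2]), n[1], n[2], byrow = TRUE) - ctr[2]
  ## inverse mapping: sample source at -theta
  sr <- cos(th) * rr + sin(th) * cc + ctr[1]
  sc <- -sin(th) * rr + cos(th) * cc + ctr[2]
  bilinear_sample(image, sr, sc)
}

bilinear_sample <- function(m, r, c, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  gv <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    v <- matrix(fill, nrow(r), ncol(r))
    v[ok] <- m[cbind(ri[ok], ci[ok])]
    v
  }
  (1 - fr) * (1 - fc) * gv(r0, c0) + (1 - fr) * fc * gv(r0, c0 + 1) +
    fr * (1 - fc) * gv(r0 + 1, c0) + fr * fc * gv(r0 + 1, c0 + 1)
}

#' Estimate the rigid transform aligning one frame onto a reference
#'
#' Coarse-to-fine: translation by FFT cross-correlation, then a bounded
#' golden-section search over rotation angle (default +/- 5 degrees) with
#' translation re-estimated at each candidate angle.
#'
#' @param fixed,moving 2-D matrices.
#' @param max_rotation_deg rotation search bound.
#' @param estimate_rotation set FALSE for translation-only estimation.
#' @return a [rigid_transform()] such that `apply_rigid(moving, tf)` aligns
#'   onto `fixed`.
#' @export
estimate_rigid <- function(fixed, moving, max_rotation_deg = 5,
                           estimate_rotation = TRUE) {
  score <- function(theta) {
    rot <- if (abs(theta) > 1e-9) rotate_about_center(moving, theta) else moving
    sh <- estimate_translation(fixed, rot)
    al <- shift_matrix_subpx(rot, sh[1], sh[2])
    list(cor = sum(al * fixed), sh = sh)
  }
  best_theta <- 0
  if (estimate_rotation && max_rotation_deg > 0) {
    thetas <- seq(-max_rotation_deg, max_rotation_deg, by = 0.5)
    cors <- vapply(thetas, function(th) score(th)$cor, 0)
    best_theta <- thetas[which.max(cors)]
    fine <- seq(best_theta - 0.5, best_theta + 0.5, by = 0.1)
    cors <- vapply(fine, function(th) score(th)$cor, 0)
    best_theta <- fine[which.max(cors)]
  }
  sh <- score(best_theta)$sh
  rigid_transform(dx_px = sh[["dx"]], dy_px = sh[["dy"]], theta_deg = best_theta)
}

#' Rigid-body registration of a two-channel movie
#'
#' Estimates a per-frame rigid transform on the live channel against the
#' reference frame and applies it to both channels, mirroring rigid-body
#' stack registration as used for time projections.
#'
#' @param stack a [movie_stack()].
#' @param reference reference frame index.
#' @param estimate_rotation search for rotation as well as translation.
#' @param max_rotation_deg rotation search bound, degrees.
#' @return list with `stack` (registered movie) and `transforms` (list of
#'   [rigid_transform()], one per frame).
#' @export
register_rigid_stack <- function(stack, reference = 1L, estimate_rotation = TRUE,
                                 max_rotation_deg = 5) {
  Tn <- n_frames(stack)
  if (Tn < 1) stop("empty stack")
  ref <- stack$frames_live[[reference]]
  tfs <- vector("list", Tn)
  for (k in seq_len(Tn)) {
    if (k == reference) { tfs[[k]] <- rigid_transform(); next }
    if (max(stack$frames_live[[k]]) <= 0) {
      warning("frame ", k, " is all zero; using identity transform")
      tfs[[k]] <- rigid_transform(); next
    }
    tfs[[k]] <- estimate_rigid(ref, stack$frames_live[[k]],
                               max_rotation_deg = max_rotation_deg,
                               estimate_rotation = estimate_rotation)
  }
  out <- stack
  for (k in seq_len(Tn)) {
    if (identical(unclass(tfs[[k]]), unclass(rigid_transform()))) next
    out$frames_live[[k]] <- apply_rigid(stack$frames_live[[k]], tfs[[k]])
    out$frames_dead[[k]] <- apply_rigid(stack$frames_dead[[k]], tfs[[k]])
  }
  list(stack = out, transforms = tfs)
}

#' Maximum-intensity time projection
#'
#' Collapses all frames whose acquisition time falls inside `t_window`
#' (inclusive) to a per-pixel maximum.
#'
#' @param stack a [movie_stack()].
#' @param channel `"live"` or `"dead"`.
#' @param t_window numeric length-2, hours; `NULL` for the whole movie.
#' @return a `projection` list: `image`, `channel`, `t_window_h`,
#'   `pixel_size_mm`, and `mask` (NULL until cropped).
#' @export
max_time_projection <- function(stack, channel = c("live", "dead"), t_window = NULL) {
  channel <- match.arg(channel)
  if (is.null(t_window)) t_window <- range(stack$frame_times_h)
  sel <- which(stack$frame_times_h >= t_window[1] & stack$frame_times_h <= t_window[2])
  if (length(sel) == 0) stop("time window contains no frames")
  frames <- movie_channel(stack, channel)[sel]
  img <- Reduce(pmax, frames)
  structure(list(image = img, channel = channel, t_window_h = t_window,
                 pixel_size_mm = stack$pixel_size_mm, mask = NULL,
                 floor = NULL), class = "projection")
}

#' Ratio image of two projections
#'
#' Divides the numerator by the denominator pixel-wise, with the denominator
#' floored at `floor` to avoid unstable ratios in dim regions; sub-floor
#' pixels are flagged in the projection mask. The default floor is 1e-3 of
#' the denominator's dynamic range. Optionally log10-transforms the result.
#'
#' @param numerator,denominator `projection` objects (or bare matrices) of
#'   equal size; conventionally dead over live.
#' @param floor positive intensity floor; `NULL` for the default.
#' @param log10 return `log10` of the ratio.
#' @return a `projection` with channel `"ratio"` (or `"ratio_log10"`).
#' @export
ratio_image <- function(numerator, denominator, floor = NULL, log10 = FALSE) {
  num <- if (inherits(numerator, "projection")) numerator$image else numerator
  den <- if (inherits(denominator, "projection")) denominator$image else denominator
  if (!all(dim(num) == dim(den))) stop("numerator and denominator shapes differ")
  if (is.null(floor)) floor <- max(1e-3 * (max(den) - min(den)), 1e-9)
  if (floor <= 0) stop("floor must be positive")
  ratio <- num / pmax(den, floor)
  if (log10) ratio <- log10(pmax(ratio, 1e-12))
  px <- if (inherits(numerator, "projection")) numerator$pixel_size_mm else NA_real_
  structure(list(image = ratio, channel = if (log10) "ratio_log10" else "ratio",
                 t_window_h = if (inherits(numerator, "projection")) numerator$t_window_h else NULL,
                 pixel_size_mm = px, mask = den >= floor, floor = floor),
            class = "projection")
}

#' Zero a projection outside a colony mask
#'
#' @param projection a `projection` (or matrix).
#' @param colony_mask logical matrix of the same size, TRUE inside the colony.
#' @return the projection with outside-mask pixels set to zero and the mask
#'   stored.
#' @export
crop_to_colony <- function(projection, colony_mask) {
  img <- if (inherits(projection, "projection")) projection$image else projection
  if (!all(dim(img) == dim(colony_mask))) stop("mask shape differs from image")
  if (!any(colony_mask)) stop("colony mask is empty")
  img[!colony_mask] <- 0
  if (inherits(projection, "projection")) {
    projection$image <- img
    projection$mask <- colony_mask
    projection
  } else {
    structure(list(image = img, channel = "unknown", t_window_h = NULL,
                   pixel_size_mm = NA_real_, mask = colony_mask, floor = NULL),
              class = "projection")
  }
}

#' Threshold-based colony mask from a projection
#'
#' The colony footprint is the largest connected component above a fixed
#' fraction of the maximum intensity, morphologically closed and hole-filled.
#'
#' @param image matrix or `projection`.
#' @param alpha threshold as a fraction of the image maximum.
#' @return logical matrix.
#' @export
colony_mask_from_image <- function(image, alpha = 0.1) {
  img <- if (inherits(image, "projection")) image$image else image
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  b <- img >= alpha * max(img)
  b <- EBImage::closing(matrix(as.numeric(b), nrow(img)), EBImage::makeBrush(7, "disc"))
  b <- EBImage::fillHull(b)
  lab <- label_components8(as.matrix(b) > 0)
  if (max(lab) == 0) return(matrix(FALSE, nrow(img), ncol(img)))
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}
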