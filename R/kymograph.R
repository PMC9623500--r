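#' Pie-slice region of interest for kymograph extraction
#'
#' A wedge is the radial section over which circumferential averaging is
#' performed; angles are measured counter-clockwise (atan2 convention) and
#' the wedge spans from `theta_min` to `theta_max` counter-clockwise.
#'
#' @param theta_min,theta_max wedge limits, radians; width must lie in
#'   (0, 2*pi].
#' @param center_px optional (row, col) centre the wedge is anchored to.
#' @param sector_free logical flag recording that the wedge was verified
#'   (automatically or manually) to avoid sectored regions.
#' @return a `wedge` object.
#' @export
wedge <- function(theta_min = 0, theta_max = 2 * pi, center_px = NULL,
                  sector_free = FALSE) {
  width <- (theta_max - theta_min) %% (2 * pi)
  if (width == 0) width <- 2 * pi
  if (width <= 0 || width > 2 * pi) stop("wedge width must lie in (0, 2*pi]")
  structure(list(theta_min = theta_min, theta_max = theta_max,
                 center_px = center_px, sector_free = sector_free),
            class = "wedge")
}

#' Iterative intensity-weighted centroid of a colony frame
#'
#' Starting from `init`, repeatedly computes the intensity-weighted centroid
#' of the pixels within a support disk (the current colony-radius estimate
#' inflated by 1.2) centred on the running estimate, until the update moves
#' less than `tol_px` or `max_iter` is reached.
#'
#' @param frame 2-D intensity matrix (live channel).
#' @param init initial (row, col) estimate; defaults to the image centre.
#' @param support_radius_px radius of the support disk; `NULL` uses the
#'   whole frame.
#' @param tol_px convergence tolerance in pixels.
#' @param max_iter maximum iterations; non-convergence returns the last
#'   estimate with a warning.
#' @param cap optional intensity cap applied to the weights
#'   (`pmin(frame, cap)`): saturating the bright interior makes the
#'   estimate track the colony footprint rather than interior intensity
#'   structure (sectors, death trails), which would otherwise bias the
#'   centre by a few pixels.
#' @return numeric (row, col) centre.
#' @export
locate_centroid <- function(frame, init = NULL, support_radius_px = NULL,
                            tol_px = 0.5, max_iter = 50L, cap = NULL) {
  if (max(frame) <= 0) stop("cannot locate centroid of an all-zero frame")
  if (!is.null(cap)) frame <- pmin(frame, cap)
  nr <- nrow(frame); nc <- ncol(frame)
  est <- init %||% c((nr + 1) / 2, (nc + 1) / 2)
  for (i in seq_len(max_iter)) {
    if (!is.null(support_radius_px)) {
      rad <- 1.2 * support_radius_px
      ri <- max(1L, floor(est[1] - rad)):min(nr, ceiling(est[1] + rad))
      ci <- max(1L, floor(est[2] - rad)):min(nc, ceiling(est[2] + rad))
      sub <- frame[ri, ci, drop = FALSE]
      sub[outer((ri - est[1])^2, (ci - est[2])^2, `+`) > rad^2] <- 0
      if (sum(sub) <= 0) { sub <- frame; ri <- seq_len(nr); ci <- seq_len(nc) }
    } else {
      sub <- frame; ri <- seq_len(nr); ci <- seq_len(nc)
    }
    tot <- sum(sub)
    new <- c(sum(rowSums(sub) * ri), sum(colSums(sub) * ci)) / tot
    if (sqrt(sum((new - est)^2)) < tol_px) return(new)
    est <- new
  }
  warning("centroid iteration did not converge; returning last estimate")
  est
}

#' Track colony centres through a movie
#'
#' Applies [locate_centroid()] frame by frame, initialising each frame at
#' the previous frame's result (the first frame at the image centre) and
#' using the previous frame's detected colony radius as the support-disk
#' radius. Tracking begins at the first acquisition.
#'
#' @param stack a [movie_stack()].
#' @param alpha boundary threshold fraction passed to
#'   [detect_colony_radius()] for the support-radius update.
#' @return list with `centers` (T x 2 matrix) and `radius_px` (numeric T).
#' @export
track_centroids <- function(stack, alpha = 0.1) {
  Tn <- n_frames(stack)
  centers <- matrix(NA_real_, Tn, 2)
  radius <- numeric(Tn)
  max_int <- max(vapply(stack$frames_live, max, 0))
  prev_center <- NULL
  prev_radius <- NULL
  for (k in seq_len(Tn)) {
    fr <- stack$frames_live[[k]]
    centers[k, ] <- locate_centroid(fr, init = prev_center,
                                    support_radius_px = prev_radius,
                                    cap = 0.25 * max_int)
    nb <- if (is.null(prev_radius)) NULL else
      ceiling(prev_radius + 8)  # colonies grow ~2 px/frame at most
    radius[k] <- detect_colony_radius(fr, centers[k, ], alpha = alpha,
                                      max_intensity = max_int, n_bins = nb)
    if (k > 1) radius[k] <- max(radius[k], radius[k - 1])  # monotone growth
    prev_center <- centers[k, ]
    prev_radius <- radius[k]
  }
  list(centers = centers, radius_px = radius)
}

#' Colony radius from a fixed intensity threshold
#'
#' The colony boundary is the largest radial bin whose circumferential mean
#' intensity is at least `alpha` times the movie-wide maximum intensity
#' (the frame maximum if no movie-wide value is supplied).
#'
#' @param frame 2-D intensity matrix (live channel).
#' @param center (row, col) colony centre.
#' @param alpha threshold fraction in (0, 1).
#' @param max_intensity reference maximum intensity; defaults to
#'   `max(frame)`.
#' @param bin_width_px radial bin width.
#' @param pixel_size_mm if given, the radius is returned in mm (bin outer
#'   edge times pixel size); otherwise in px.
#' @param n_bins cap on the searched radial extent (bins); `NULL` searches
#'   the largest fully contained disk.
#' @return colony radius (px or mm).
#' @export
detect_colony_radius <- function(frame, center, alpha = 0.1,
                                 max_intensity = NULL, bin_width_px = 1,
                                 pixel_size_mm = NULL, n_bins = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (max(frame) <= 0) stop("cannot detect a colony radius in an all-zero frame")
  max_intensity <- max_intensity %||% max(frame)
  prof <- circumferential_average(frame, wedge(center_px = center),
                                  bin_width_px = bin_width_px, n_bins = n_bins)
  pass <- which(prof >= alpha * max_intensity)
  if (length(pass) == 0) stop("no radial bin exceeds the boundary threshold")
  r_px <- max(pass) * bin_width_px
  if (is.null(pixel_size_mm)) r_px else r_px * pixel_size_mm
}

#' Circumferential average of a frame within a wedge
#'
#' Pixels are assigned to radial bins by `floor(distance / bin_width)`;
#' within each bin, the mean intensity over pixels whose angle falls inside
#' the wedge is returned. Bins that contain no pixels are linearly
#' interpolated from their neighbours (leading/trailing empties are
#' filled from the nearest populated bin).
#'
#' @param frame 2-D matrix.
#' @param wedge a [wedge()] carrying the centre; a full-circle wedge
#'   averages over all angles.
#' @param bin_width_px radial bin width, px.
#' @param n_bins number of bins; defaults to the largest disk fully
#'   contained in the frame.
#' @return numeric vector of per-bin means, with attributes `counts`
#'   (pixels per bin) and `bin_edges_px`.
#' @export
circumferential_average <- function(frame, wedge, bin_width_px = 1,
                                    n_bins = NULL) {
  if (bin_width_px <= 0) stop("bin_width_px must be positive")
  ctr <- wedge$center_px %||% c((nrow(frame) + 1) / 2, (ncol(frame) + 1) / 2)
  n_bins <- n_bins %||% floor(min(ctr[1] - 1, nrow(frame) - ctr[1],
                                  ctr[2] - 1, ncol(frame) - ctr[2]) / bin_width_px)
  if (n_bins < 1) stop("frame too small for any radial bin")
  ## crop to the bounding box of the wedge's disk section
  r_max <- n_bins * bin_width_px
  width0 <- (wedge$theta_max - wedge$theta_min) %% (2 * pi)
  if (width0 == 0) {
    dyr <- c(-1, 1); dxr <- c(-1, 1)
  } else {
    th <- wedge$theta_min + seq(0, width0, length.out = 64)
    dyr <- range(sin(th), 0); dxr <- range(cos(th), 0)
  }
  ri <- max(1L, floor(ctr[1] + dyr[1] * r_max - 1)):min(nrow(frame), ceiling(ctr[1] + dyr[2] * r_max + 1))
  ci <- max(1L, floor(ctr[2] + dxr[1] * r_max - 1)):min(ncol(frame), ceiling(ctr[2] + dxr[2] * r_max + 1))
  dy <- ri - ctr[1]; dx <- ci - ctr[2]
  r <- sqrt(outer(dy^2, dx^2, `+`))
  width <- (wedge$theta_max - wedge$theta_min) %% (2 * pi)
  full <- width == 0
  sel <- if (full) TRUE else {
    ## wedge membership via half-plane tests (no atan2): the point angle
    ## lies in [theta1, theta2] iff it is counter-clockwise of theta1 and
    ## clockwise of theta2 (complement logic for reflex wedges)
    vy <- matrix(dy, length(ri), length(ci))
    vx <- matrix(dx, length(ri), length(ci), byrow = TRUE)
    in_cw <- function(a1, a2) {
      c1 <- cos(a1) * vy - sin(a1) * vx   # cross(u1, v) >= 0
      c2 <- cos(a2) * vy - sin(a2) * vx   # cross(u2, v) <= 0
      (c1 >= 0) & (c2 <= 0)
    }
    if (width <= pi) in_cw(wedge$theta_min, wedge$theta_min + width)
    else !in_cw(wedge$theta_min + width, wedge$theta_min + 2 * pi)
  }
  bin <- floor(r / bin_width_px) + 1L
  keep <- (bin <= n_bins) & sel
  if (!any(keep)) stop("wedge contains no pixels")
  b <- bin[keep]
  sums <- rowsum(frame[ri, ci, drop = FALSE][keep], b)
  counts <- tabulate(b, nbins = n_bins)
  means <- rep(NA_real_, n_bins)
  means[as.integer(rownames(sums))] <- sums / counts[as.integer(rownames(sums))]
  if (anyNA(means)) {
    idx <- which(!is.na(means))
    means <- approx(idx, means[idx], xout = seq_len(n_bins), rule = 2)$y
  }
  attr(means, "counts") <- counts
  attr(means, "bin_edges_px") <- seq(0, n_bins) * bin_width_px
  means
}

#' Translation-only registration with mechanical-jump removal
#'
#' Estimates the frame-to-frame translation on the live channel by FFT
#' cross-correlation. Per-frame displacements larger than
#' `jump_threshold_px` (in either axis) are treated as sudden mechanical
#' shifts and removed (their cumulative sum is subtracted, rounded to
#' integer pixels); smaller displacements -- genuine slow drift and colony
#' growth -- are left intact for the centroid tracker to follow.
#'
#' @param stack a [movie_stack()].
#' @param jump_threshold_px threshold separating jumps from drift.
#' @param downsample integer block-mean downsampling factor used for the
#'   shift estimation only (1 = full resolution); factor 2 speeds up long
#'   full-size movies with negligible loss for jump detection.
#' @return list with `stack` (corrected movie), `frame_shifts` (T x 2
#'   estimated per-frame displacements) and `corrections` (T x 2 integer
#'   shifts applied).
#' @export
register_translation_stack <- function(stack, jump_threshold_px = 3,
                                       downsample = 1L) {
  Tn <- n_frames(stack)
  if (Tn < 1) stop("empty stack")
  ds <- function(m) {
    if (downsample <= 1L) return(m)
    f <- downsample
    nr <- floor(nrow(m) / f) * f; nc <- floor(ncol(m) / f) * f
    m <- m[seq_len(nr), seq_len(nc)]
    ## block mean via row/col group sums
    rg <- rowsum(m, rep(seq_len(nr / f), each = f))
    t(rowsum(t(rg), rep(seq_len(nc / f), each = f))) / f^2
  }
  rel <- matrix(0, Tn, 2)
  prev <- ds(stack$frames_live[[1]])
  for (k in seq_len(Tn)[-1]) {
    cur <- ds(stack$frames_live[[k]])
    sh <- estimate_translation(prev, cur)
    rel[k, ] <- -sh * downsample  # displacement of frame k relative to k-1
    prev <- cur
  }
  jumps <- rel
  jumps[abs(jumps) <= jump_threshold_px] <- 0
  corr <- round(apply(jumps, 2, cumsum))
  if (all(corr == 0)) return(list(stack = stack, frame_shifts = rel, corrections = corr))
  out <- stack
  for (k in seq_len(Tn)) {
    if (all(corr[k, ] == 0)) next
    out$frames_live[[k]] <- shift_matrix(stack$frames_live[[k]], -corr[k, 1], -corr[k, 2])
    out$frames_dead[[k]] <- shift_matrix(stack$frames_dead[[k]], -corr[k, 1], -corr[k, 2])
  }
  list(stack = out, frame_shifts = rel, corrections = corr)
}

.full_wedge <- function() wedge()

new_kymograph <- function(values, bin_edges_mm, times_h, channel, wedge,
                          pixel_size_mm, radius_mm = NULL) {
  structure(list(values = values, bin_edges_mm = bin_edges_mm,
                 frame_times_h = times_h, channel = channel, wedge = wedge,
                 pixel_size_mm = pixel_size_mm, radius_mm = radius_mm),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph [%s]: %d radial bins x %d frames, r <= %.3g mm\n",
              x$channel, nrow(x$values), ncol(x$values), max(x$bin_edges_mm)))
  invisible(x)
}

#' Radial bin centres of a kymograph, mm
#' @param kymo a kymograph.
#' @return numeric vector.
#' @export
kymo_bin_centers_mm <- function(kymo) {
  e <- kymo$bin_edges_mm
  (head(e, -1) + tail(e, -1)) / 2
}

#' Build live and dead space-time kymographs
#'
#' For every frame, the colony centre is tracked with [track_centroids()]
#' and both channels are circumferentially averaged within the wedge about
#' that centre; column t of each kymograph is the radial profile of frame t.
#' The radial axis is converted to mm and the detected (monotone) colony
#' radius per frame is stored.
#'
#' @param stack a [movie_stack()] (already jump-corrected if needed).
#' @param wedge a [wedge()]; its centre is overridden per frame by the
#'   tracked centroid. `NULL` means full circle.
#' @param bin_width_px radial bin width in px.
#' @param alpha boundary threshold fraction for radius detection.
#' @param tracking optional precomputed [track_centroids()] result, to avoid
#'   re-tracking when several kymographs are built from one movie.
#' @return list with `live` and `dead` kymographs, `centers` (T x 2) and
#'   `radius_mm` (numeric T).
#' @export
build_kymographs <- function(stack, wedge = NULL, bin_width_px = 1, alpha = 0.1,
                             tracking = NULL) {
  wd <- wedge %||% .full_wedge()
  tr <- tracking %||% track_centroids(stack, alpha = alpha)
  Tn <- n_frames(stack)
  d <- frame_dim(stack)
  margin <- 2
  n_bins <- floor((min(d) / 2 - max(abs(tr$centers - (min(d) + 1) / 2)) - margin) /
                    bin_width_px)
  vals_live <- matrix(NA_real_, n_bins, Tn)
  vals_dead <- matrix(NA_real_, n_bins, Tn)
  bin_centers_px <- (seq_len(n_bins) - 0.5) * bin_width_px
  for (k in seq_len(Tn)) {
    wk <- wd; wk$center_px <- tr$centers[k, ]
    vals_live[, k] <- circumferential_average(stack$frames_live[[k]], wk,
                                              bin_width_px, n_bins = n_bins)
    vals_dead[, k] <- circumferential_average(stack$frames_dead[[k]], wk,
                                              bin_width_px, n_bins = n_bins)
    ## bins at or beyond the colony boundary are flagged missing: the
    ## outermost ~2 px carry the antialiased rim edge, where the dim live
    ## signal makes ratios meaningless
    beyond <- bin_centers_px > tr$radius_px[k] - 2 * bin_width_px
    vals_live[beyond, k] <- NA
    vals_dead[beyond, k] <- NA
  }
  edges_mm <- seq(0, n_bins) * bin_width_px * stack$pixel_size_mm
  radius_mm <- tr$radius_px * stack$pixel_size_mm
  list(live = new_kymograph(vals_live, edges_mm, stack$frame_times_h, "live",
                            wd, stack$pixel_size_mm, radius_mm),
       dead = new_kymograph(vals_dead, edges_mm, stack$frame_times_h, "dead",
                            wd, stack$pixel_size_mm, radius_mm),
       centers = tr$centers, radius_mm = radius_mm)
}

#' Ratio kymograph (dead over live)
#'
#' Element-wise `dead / max(live, floor)`; optionally log10-transformed to
#' emphasise low-magnitude death signal. The default floor is 1e-3 of the
#' live kymograph's dynamic range.
#'
#' @param dead,live kymographs on identical axes.
#' @param log10 return the log10 ratio.
#' @param floor intensity floor for the denominator.
#' @return a kymograph with channel `"ratio_linear"` or `"ratio_log10"`.
#' @export
ratio_kymograph <- function(dead, live, log10 = FALSE, floor = NULL) {
  if (!identical(dim(dead$values), dim(live$values)) ||
      max(abs(dead$bin_edges_mm - live$bin_edges_mm)) > 1e-9 ||
      max(abs(dead$frame_times_h - live$frame_times_h)) > 1e-9)
    stop("dead and live kymographs must share identical axes")
  if (is.null(floor))
    floor <- max(1e-3 * (max(live$values, na.rm = TRUE) - min(live$values, na.rm = TRUE)),
                 1e-9)
  if (floor <= 0) stop("floor must be positive")
  v <- dead$values / pmax(live$values, floor)
  if (log10) v <- log10(pmax(v, 1e-12))
  out <- new_kymograph(v, dead$bin_edges_mm, dead$frame_times_h,
                       if (log10) "ratio_log10" else "ratio_linear",
                       dead$wedge, dead$pixel_size_mm, dead$radius_mm)
  out$floor <- floor
  out
}

#' Write a kymograph as CSV (rows = radial bins, columns = frame times)
#' @param kymo a kymograph.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_kymograph_csv <- function(kymo, path) {
  df <- data.frame(r_inner_mm = head(kymo$bin_edges_mm, -1),
                   r_outer_mm = tail(kymo$bin_edges_mm, -1),
                   kymo$values, check.names = FALSE)
  names(df)[-(1:2)] <- sprintf("t_%gh", kymo$frame_times_h)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Render a kymograph to PNG
#' @param kymo a kymograph.
#' @param path output PNG path.
#' @param log10 plot log10 of the values.
#' @return `path`, invisibly.
#' @export
plot_kymograph_png <- function(kymo, path, log10 = FALSE) {
  grDevices::png(path, width = 800, height = 600)
  on.exit(grDevices::dev.off())
  v <- kymo$values
  if (log10) v <- base::log10(pmax(v, 1e-12))
  graphics::image(x = kymo$frame_times_h, y = kymo_bin_centers_mm(kymo),
                  z = t(v), xlab = "time (h)", ylab = "radius (mm)",
                  main = paste("kymograph:", kymo$channel),
                  col = grDevices::hcl.colors(64, "Inferno"), useRaster = TRUE)
  invisible(path)
}
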