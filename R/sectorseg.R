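.default_scales <- c(1, 2, 4, 8, 16)

#' Multi-scale per-pixel feature stack
#'
#' Computes, per pixel: the raw intensity and, at each smoothing scale
#' sigma, the Gaussian blur, gradient magnitude (central differences of the
#' blurred image), Laplacian (4-neighbour discrete), difference of
#' Gaussians (`blur(sigma) - blur(2 sigma)`) and local variance
#' (`blur(x^2) - blur(x)^2`). The feature set mirrors the defaults of
#' trainable-segmentation tools; the computation is fully deterministic.
#'
#' @param image 2-D matrix.
#' @param scales positive smoothing sigmas, px.
#' @return 3-D array (rows x cols x features) with named feature slices.
#' @export
compute_feature_stack <- function(image, scales = .default_scales) {
  if (length(scales) == 0) stop("scales must be non-empty")
  if (any(scales <= 0)) stop("scales must be positive")
  blur <- function(m, s) {
    ## EBImage's Gaussian brush must fit inside the image; replicate-pad
    ## small images so large-scale features remain defined
    need <- 2 * ceiling(3 * s) + 1
    if (need >= min(dim(m))) {
      p <- need
      ri <- c(rep(1, p), seq_len(nrow(m)), rep(nrow(m), p))
      ci <- c(rep(1, p), seq_len(ncol(m)), rep(ncol(m), p))
      out <- as.matrix(EBImage::gblur(m[ri, ci], sigma = s))
      out[p + seq_len(nrow(m)), p + seq_len(ncol(m))]
    } else as.matrix(EBImage::gblur(m, sigma = s))
  }
  grad_mag <- function(m) {
    gy <- m; gx <- m
    gy[2:(nrow(m) - 1), ] <- (m[3:nrow(m), ] - m[1:(nrow(m) - 2), ]) / 2
    gy[c(1, nrow(m)), ] <- 0
    gx[, 2:(ncol(m) - 1)] <- (m[, 3:ncol(m)] - m[, 1:(ncol(m) - 2)]) / 2
    gx[, c(1, ncol(m))] <- 0
    sqrt(gx^2 + gy^2)
  }
  laplace <- function(m) {
    out <- matrix(0, nrow(m), ncol(m))
    i <- 2:(nrow(m) - 1); j <- 2:(ncol(m) - 1)
    out[i, j] <- m[i - 1, j] + m[i + 1, j] + m[i, j - 1] + m[i, j + 1] - 4 * m[i, j]
    out
  }
  feats <- list(raw = image)
  for (s in scales) {
    g <- blur(image, s)
    feats[[sprintf("gauss_s%g", s)]] <- g
    feats[[sprintf("gradmag_s%g", s)]] <- grad_mag(g)
    feats[[sprintf("laplace_s%g", s)]] <- laplace(g)
    feats[[sprintf("dog_s%g", s)]] <- g - blur(image, 2 * s)
    feats[[sprintf("var_s%g", s)]] <- pmax(blur(image^2, s) - g^2, 0)
  }
  arr <- array(unlist(feats, use.names = FALSE),
               dim = c(nrow(image), ncol(image), length(feats)),
               dimnames = list(NULL, NULL, names(feats)))
  arr
}

features_to_df <- function(stack, idx = NULL) {
  n <- dim(stack)[1] * dim(stack)[2]
  m <- matrix(stack, nrow = n)
  colnames(m) <- dimnames(stack)[[3]]
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  as.data.frame(m)
}

#' Train a random-forest pixel classifier for sector segmentation
#'
#' Labeled pixels (1 = sector, 2 = non-sector, 0 = unlabeled in the label
#' masks) from the training images are converted to multi-scale feature
#' vectors and a probability random forest is fitted. Deterministic given
#' the seed.
#'
#' @param images list of 2-D matrices (typically dead-channel
#'   time projections).
#' @param label_masks list of integer matrices matching `images`.
#' @param n_trees forest size.
#' @param seed RNG seed (forest and pixel subsampling).
#' @param scales feature scales.
#' @param max_per_class at most this many labeled pixels per class are used
#'   (sampled with the seed).
#' @return a `pixel_classifier` with the fitted forest, the scales, and the
#'   out-of-bag accuracy estimate.
#' @export
train_pixel_classifier <- function(images, label_masks, n_trees = 100L,
                                   seed = 0L, scales = .default_scales,
                                   max_per_class = 20000L) {
  stopifnot(length(images) == length(label_masks), length(images) >= 1)
  xs <- list(); ys <- list()
  for (i in seq_along(images)) {
    lm <- label_masks[[i]]
    idx <- which(lm > 0)
    if (length(idx) == 0) next
    st <- compute_feature_stack(images[[i]], scales)
    xs[[length(xs) + 1]] <- features_to_df(st, idx)
    ys[[length(ys) + 1]] <- lm[idx]
  }
  x <- do.call(rbind, xs)
  y <- unlist(ys)
  if (length(unique(y)) < 2)
    stop("training labels must contain both classes (1 = sector, 2 = non-sector)")
  keep <- with_seed(seed + 1L, {
    unlist(lapply(split(seq_along(y), y), function(ii) {
      if (length(ii) > max_per_class) sample(ii, max_per_class) else ii
    }), use.names = FALSE)
  })
  x <- x[keep, , drop = FALSE]
  y <- factor(ifelse(y[keep] == 1, "sector", "non_sector"),
              levels = c("sector", "non_sector"))
  fit <- ranger::ranger(x = x, y = y, num.trees = n_trees, probability = TRUE,
                        seed = seed, num.threads = 1)
  structure(list(model = fit, scales = scales, n_trees = n_trees, seed = seed,
                 classes = levels(y),
                 n_labeled = as.list(table(y)),
                 oob_accuracy = 1 - fit$prediction.error),
            class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf("pixel_classifier: %d trees, scales {%s}, OOB accuracy %.3f\n",
              x$n_trees, paste(x$scales, collapse = ","), x$oob_accuracy))
  invisible(x)
}

#' Per-pixel sector probability image
#'
#' @param classifier a [train_pixel_classifier()] result.
#' @param image 2-D matrix.
#' @param mask optional logical matrix; prediction is restricted to TRUE
#'   pixels (others get probability 0), which is much faster on large
#'   images with a known colony footprint.
#' @return matrix of sector-class probabilities in `[0, 1]`.
#' @export
predict_probability <- function(classifier, image, mask = NULL) {
  if (!inherits(classifier, "pixel_classifier")) stop("not a pixel_classifier")
  st <- compute_feature_stack(image, classifier$scales)
  if (!identical(dimnames(st)[[3]], classifier$model$forest$independent.variable.names))
    stop("feature scales of image and classifier do not match")
  idx <- if (is.null(mask)) seq_len(nrow(image) * ncol(image)) else which(mask)
  df <- features_to_df(st, idx)
  pr <- predict(classifier$model, data = df, num.threads = 1)$predictions
  out <- matrix(0, nrow(image), ncol(image))
  out[idx] <- pr[, "sector"]
  out
}

#' Renyi-entropy automatic threshold
#'
#' Histogram-based automatic threshold combining the optimal thresholds of
#' the order-alpha Renyi entropies for alpha in {0.5, 1, 2} by the
#' published three-threshold weighting rule (as implemented in common
#' automatic-threshold plugins); the alpha = 1 order is the Kapur
#' maximum-entropy threshold. The image is binned to `n_bins` grey levels
#' between its minimum and maximum.
#'
#' @param image 2-D matrix with at least two distinct values.
#' @param n_bins histogram size (256 mirrors 8-bit behaviour).
#' @return threshold on the intensity scale of `image` (pixels strictly
#'   above it are foreground), with attribute `per_order` giving the three
#'   per-order thresholds as bin indices (0-based).
#' @export
renyi_entropy_threshold <- function(image, n_bins = 256L) {
  v <- as.numeric(image)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop("cannot threshold a constant image")
  bin <- pmin(floor((v - lo) / (hi - lo) * n_bins), n_bins - 1L)
  h <- tabulate(bin + 1L, nbins = n_bins)
  p <- h / sum(h)
  t_half <- renyi_best_threshold(p, 0.5)
  t_one <- renyi_best_threshold(p, 1)
  t_two <- renyi_best_threshold(p, 2)
  ts <- sort(c(t_half, t_one, t_two))
  t1 <- ts[1]; t2 <- ts[2]; t3 <- ts[3]
  P <- cumsum(p)
  if (abs(t1 - t2) <= 5) {
    if (abs(t2 - t3) <= 5) { b1 <- 1; b2 <- 2; b3 <- 1 }
    else { b1 <- 0; b2 <- 1; b3 <- 3 }
  } else {
    if (abs(t2 - t3) <= 5) { b1 <- 3; b2 <- 1; b3 <- 0 }
    else { b1 <- 1; b2 <- 2; b3 <- 1 }
  }
  omega <- P[t3 + 1] - P[t1 + 1]
  t_opt <- t1 * (P[t1 + 1] + 0.25 * omega * b1) +
    0.25 * t2 * omega * b2 +
    t3 * (1 - P[t3 + 1] + 0.25 * omega * b3)
  thr <- lo + (t_opt + 0.5) / n_bins * (hi - lo)
  attr(thr, "per_order") <- c(alpha_0.5 = t_half, alpha_1 = t_one, alpha_2 = t_two)
  thr
}

## Optimal single threshold for the order-alpha Renyi entropy sum
## (foreground + background); alpha = 1 reduces to Kapur's entropy.
## Thresholds are 0-based bin indices; background = bins 0..t.
renyi_best_threshold <- function(p, alpha) {
  n <- length(p)
  P1 <- cumsum(p)
  best <- -Inf; best_t <- 0L
  for (t in 0:(n - 2)) {
    w1 <- P1[t + 1]; w2 <- 1 - w1
    if (w1 <= 0 || w2 <= 0) next
    pb <- p[1:(t + 1)] / w1
    pf <- p[(t + 2):n] / w2
    if (alpha == 1) {
      ent <- -sum(pb[pb > 0] * log(pb[pb > 0])) - sum(pf[pf > 0] * log(pf[pf > 0]))
    } else {
      ent <- (log(sum(pb^alpha)) + log(sum(pf^alpha))) / (1 - alpha)
    }
    if (ent > best) { best <- ent; best_t <- t }
  }
  best_t
}

#' Extract sector regions of interest from a binary segmentation
#'
#' Connected components (8-connectivity) of `binary` restricted to the
#' colony mask, filtered by a particle-size cutoff. Each component carries
#' which filters it passed; a reproducible drop-list stands in for manual
#' curation of mis-segmented regions.
#'
#' @param binary logical/0-1 matrix (thresholded probability image).
#' @param min_area_px particle-size cutoff, px.
#' @param colony_mask logical matrix restricting the analysis.
#' @param prob_image optional probability image for per-ROI mean
#'   probability.
#' @param min_mean_prob class-probability filter: ROIs whose mean sector
#'   probability falls below this are rejected (guards against automatic
#'   thresholds collapsing into the background mode when sectors occupy
#'   little area). Ignored when no probability image is supplied.
#' @param pixel_size_mm optional, adds areas in mm^2.
#' @param drop_ids integer ids to drop (curation hook).
#' @return list with `rois` (data.frame: id, area_px, area_mm2, mean_prob,
#'   pass_min_area, pass_prob, dropped, kept) and `labels` (labeled matrix;
#'   all components, including filtered ones).
#' @export
extract_sector_rois <- function(binary, min_area_px, colony_mask,
                                prob_image = NULL, min_mean_prob = 0.5,
                                pixel_size_mm = NULL,
                                drop_ids = integer()) {
  if (!all(dim(binary) == dim(colony_mask))) stop("masks must share one shape")
  lab <- label_components8((binary > 0) & colony_mask)
  n <- max(lab)
  if (n == 0)
    return(list(rois = data.frame(id = integer(), area_px = integer(),
                                  area_mm2 = numeric(), mean_prob = numeric(),
                                  pass_min_area = logical(), pass_prob = logical(),
                                  dropped = logical(), kept = logical()),
                labels = lab))
  area <- tabulate(lab[lab > 0], nbins = n)
  mean_prob <- if (is.null(prob_image)) rep(NA_real_, n) else
    as.numeric(rowsum(prob_image[lab > 0], lab[lab > 0])) / area
  rois <- data.frame(id = seq_len(n), area_px = area,
                     area_mm2 = if (is.null(pixel_size_mm)) NA_real_ else
                       area * pixel_size_mm^2,
                     mean_prob = mean_prob,
                     pass_min_area = area >= min_area_px,
                     pass_prob = is.na(mean_prob) | mean_prob >= min_mean_prob,
                     dropped = seq_len(n) %in% drop_ids)
  rois$kept <- rois$pass_min_area & rois$pass_prob & !rois$dropped
  list(rois = rois, labels = lab)
}

#' Fraction of the colony area occupied by sectors
#'
#' @param rois data.frame from [extract_sector_rois()] (or a list holding
#'   it as `$rois`); only `kept` ROIs count.
#' @param colony_mask logical colony footprint.
#' @return scalar in `[0, 1]`.
#' @export
sector_area_fraction <- function(rois, colony_mask) {
  if (is.list(rois) && !is.data.frame(rois) && !is.null(rois$rois)) rois <- rois$rois
  ca <- sum(colony_mask)
  if (ca == 0) stop("colony mask is empty")
  if (nrow(rois) == 0) return(0)
  min(sum(rois$area_px[rois$kept]) / ca, 1)
}

#' Select a sector-free wedge from a sector-probability image
#'
#' Scans candidate wedges of the given angular width at 1-degree steps and
#' returns the wedge with the lowest mean sector probability over the
#' considered pixels (ties broken by the smallest start angle). This
#' automates the manual verification that the kymograph radial section
#' lacks sectoring; an explicit wedge in the configuration overrides it.
#'
#' @param prob_image sector-probability matrix.
#' @param center (row, col) colony centre.
#' @param wedge_width_deg wedge width, degrees, in (0, 360].
#' @param mask optional logical matrix restricting the scored pixels (e.g.
#'   the stained annulus); default: all pixels.
#' @param max_mean error ceiling: if every candidate's mean exceeds it, an
#'   error advises a manual wedge override.
#' @param step_deg scan step, degrees.
#' @return a [wedge()] with `sector_free = TRUE` and attribute
#'   `mean_probability`.
#' @export
select_sector_free_wedge <- function(prob_image, center, wedge_width_deg = 30,
                                     mask = NULL, max_mean = 1, step_deg = 1) {
  if (wedge_width_deg <= 0 || wedge_width_deg > 360)
    stop("wedge_width_deg must lie in (0, 360]")
  g <- radial_grids(nrow(prob_image), ncol(prob_image), center)
  keep <- if (is.null(mask)) rep(TRUE, length(prob_image)) else as.logical(mask)
  deg <- (floor(g$theta[keep] * 180 / pi) %% 360) + 1L
  sums <- rowsum(as.numeric(prob_image)[keep], deg)
  cnts <- tabulate(deg, nbins = 360)
  s360 <- numeric(360); s360[as.integer(rownames(sums))] <- sums
  width <- round(wedge_width_deg)
  starts <- seq(0, 359, by = step_deg)
  score <- vapply(starts, function(a) {
    idx <- ((a + seq_len(width) - 1) %% 360) + 1L
    tot <- sum(cnts[idx])
    if (tot == 0) Inf else sum(s360[idx]) / tot
  }, 0)
  best <- which.min(score)  # which.min takes the first (smallest start) on ties
  if (!is.finite(score[best]) || score[best] > max_mean)
    stop("no candidate wedge has mean sector probability <= ", max_mean,
         "; supply a manual wedge override")
  w <- wedge(theta_min = starts[best] * pi / 180,
             theta_max = (starts[best] + wedge_width_deg) * pi / 180,
             center_px = center, sector_free = TRUE)
  attr(w, "mean_probability") <- score[best]
  w
}
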