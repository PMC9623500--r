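#' Phase region of a kymograph
#'
#' A phase region is a radial band, expressed as fractions of the
#' instantaneous colony radius, optionally restricted to a time window.
#' The defaults encode the two death phases: Phase 1 along the rim
#' (`[0.85, 1] * R(t)`) and Phase 2 in the colony interior
#' (`[0.2, 0.8] * R(t)`); the two default bands are disjoint at every time.
#'
#' @param tag `"P1"`, `"P2"` or any label.
#' @param band length-2 radial band as fractions of R(t), `0 <= lo < hi <= 1`.
#' @param window optional fixed time window (h); `NULL` means the whole
#'   movie (windows are typically auto-detected downstream).
#' @return a `phase_region`.
#' @export
phase_region <- function(tag = c("P1", "P2"), band = NULL, window = NULL) {
  tag <- if (is.character(tag)) tag[1] else tag
  band <- band %||% switch(tag, P1 = c(0.85, 1), P2 = c(0.2, 0.8),
                           stop("band required for custom region tag"))
  if (band[1] < 0 || band[2] > 1 || band[1] >= band[2])
    stop("band fractions must satisfy 0 <= lo < hi <= 1")
  structure(list(tag = tag, band = band, window = window), class = "phase_region")
}

#' Boolean kymograph mask of a phase region
#'
#' Marks cells whose radial bin centre lies inside `band * R(t)` and whose
#' frame time lies inside the region window.
#'
#' @param kymo a kymograph.
#' @param region a [phase_region()].
#' @param radius_series_mm per-frame colony radius (mm); defaults to the
#'   radius stored in the kymograph.
#' @return logical matrix, same dimension as `kymo$values`.
#' @export
region_mask <- function(kymo, region, radius_series_mm = NULL) {
  R_t <- radius_series_mm %||% kymo$radius_mm
  if (is.null(R_t)) stop("radius series required (none stored in kymograph)")
  if (length(R_t) != ncol(kymo$values)) stop("radius series must cover all columns")
  rc <- kymo_bin_centers_mm(kymo)
  lo <- outer(rc, region$band[1] * R_t, `>=`)
  hi <- outer(rc, region$band[2] * R_t, `<=`)
  m <- lo & hi
  if (!is.null(region$window)) {
    tin <- kymo$frame_times_h >= region$window[1] & kymo$frame_times_h <= region$window[2]
    m <- m & matrix(tin, nrow(m), ncol(m), byrow = TRUE)
  }
  if (!any(m)) stop("phase region mask is empty")
  m
}

#' Region-mean time series of a kymograph
#'
#' Mean of the masked cells per column (frames with no masked cell give NA).
#'
#' @param kymo a kymograph.
#' @param mask logical matrix from [region_mask()].
#' @return numeric vector, one value per frame.
#' @export
region_mean_series <- function(kymo, mask) {
  v <- kymo$values
  v[!mask] <- NA
  colMeans(v, na.rm = TRUE)
}

#' Integrated death signal over a kymograph region
#'
#' Area-weighted sum of the baseline-subtracted, positive-part linear ratio
#' over the masked cells: `sum((ratio - baseline)_+ * r * dr * dt)`. The
#' annulus weight (proportional to the bin-centre radius) makes the
#' statistic approximate a whole-colony area integral. The baseline is the
#' phase-free ratio level of the radial band, estimated as the smaller of
#' the band's median ratio over the first and over the last
#' `n_baseline_frames` frames: rim death is already active at the first
#' acquisition, so its phase-free reference is the post-cessation level,
#' while interior death persists to the end, so its reference is pre-onset.
#'
#' @param ratio_kymo a linear-ratio kymograph (`ratio_linear`).
#' @param mask logical matrix from [region_mask()].
#' @param baseline explicit baseline; `NULL` to estimate as above.
#' @param n_baseline_frames frames used for the baseline estimate.
#' @return scalar, with attribute `baseline`.
#' @export
integrated_death <- function(ratio_kymo, mask, baseline = NULL,
                             n_baseline_frames = 4L) {
  if (!identical(ratio_kymo$channel, "ratio_linear"))
    stop("integrated_death requires a linear-ratio kymograph, not ",
         ratio_kymo$channel)
  v <- ratio_kymo$values
  if (is.null(baseline)) {
    rows <- which(rowSums(mask) > 0)
    nb <- min(n_baseline_frames, ncol(v))
    first <- median(v[rows, seq_len(nb)], na.rm = TRUE)
    last <- median(v[rows, ncol(v) - seq_len(nb) + 1], na.rm = TRUE)
    baseline <- min(first, last)
  }
  v[!is.finite(v)] <- baseline  # flagged-missing cells contribute nothing
  rc <- kymo_bin_centers_mm(ratio_kymo)
  dr <- diff(ratio_kymo$bin_edges_mm)
  dt <- c(diff(ratio_kymo$frame_times_h),
          tail(diff(ratio_kymo$frame_times_h), 1))
  w <- outer(rc * dr, dt)
  out <- sum(pmax(v - baseline, 0) * w * mask)
  attr(out, "baseline") <- baseline
  out
}

#' Detect a phase window in a region-mean ratio series
#'
#' The onset is the first time the series exceeds `baseline + k * sigma`
#' for at least `m` consecutive frames, and the end is the last time inside
#' such a run. The baseline is a low quantile of the series (robust to the
#' phase occupying most of the movie) and `sigma` is the robust
#' frame-to-frame noise scale, `mad(diff(series)) / sqrt(2)`; a series that
#' never exceeds the threshold yields the none-detected sentinel.
#'
#' @param series region-mean ratio per frame.
#' @param times_h frame times.
#' @param k threshold in noise sigmas.
#' @param m minimum run length, frames.
#' @param baseline_quantile quantile of the series used as the baseline.
#' @param range_fraction floor on the exceedance as a fraction of the
#'   series' dynamic range (95th percentile minus baseline): a detection
#'   must be a meaningful excursion relative to the series' own signal
#'   scale, not merely exceed the noise scale.
#' @return list with `onset_h`, `end_h`, `detected`, `threshold`.
#' @export
detect_phase_window <- function(series, times_h, k = 3, m = 3L,
                                baseline_quantile = 0.2,
                                range_fraction = 0.04) {
  stopifnot(length(series) == length(times_h))
  if (length(series) < m) stop("need at least m frames")
  ok <- is.finite(series)
  baseline <- as.numeric(quantile(series[ok], baseline_quantile))
  sigma <- mad(diff(series[ok])) / sqrt(2)
  q95 <- as.numeric(quantile(series[ok], 0.95))
  thr <- baseline + max(k * sigma, range_fraction * (q95 - baseline))
  above <- series > thr & ok
  r <- rle(above)
  good <- r$values & r$lengths >= m
  if (!any(good))
    return(list(onset_h = NA_real_, end_h = NA_real_, detected = FALSE,
                threshold = thr))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  list(onset_h = times_h[min(starts[good])],
       end_h = times_h[max(ends[good])],
       detected = TRUE, threshold = thr)
}

#' Ratio of integrated Phase-1 to Phase-2 death
#'
#' Returns `p1 / p2`. If the Phase-2 integral is below `tol` times the
#' Phase-1 integral (death "did not occur" at the measurement floor), the
#' ratio is reported as `Inf`.
#'
#' @param p1_integral,p2_integral integrated death values.
#' @param tol relative floor below which Phase 2 counts as absent.
#' @return scalar (possibly `Inf`).
#' @export
p1_p2_ratio <- function(p1_integral, p2_integral, tol = 0.02) {
  if (p1_integral < 0 || p2_integral < 0) stop("integrals must be >= 0")
  if (p2_integral <= tol * p1_integral) return(Inf)
  p1_integral / p2_integral
}

## least-absolute-deviations line fit (robust to single-frame dropouts)
lad_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  start <- coef(lm(y ~ x))
  obj <- function(p) sum(abs(y - p[1] - p[2] * x))
  optim(start, obj, method = "Nelder-Mead")$par
}

#' Track the Phase-2 death wave fronts
#'
#' For each frame after `t_from`, finds the innermost and outermost radii
#' at which the baseline-subtracted ratio crosses `level` times the running
#' peak of the wave signal, then fits robust (least-absolute-deviations)
#' lines radius-versus-time. The outward front speed is positive, the
#' inward speed negative, in mm/h.
#'
#' @param ratio_kymo a linear-ratio kymograph.
#' @param t_from time (h) after which the wave is tracked (typically the
#'   detected Phase-2 onset).
#' @param level crossing level as a fraction of the running peak.
#' @param band radial band searched, as fractions of R(t).
#' @return list with `times_h`, `inner_mm`, `outer_mm`,
#'   `outward_speed_mm_h`, `inward_speed_mm_h`.
#' @export
track_wave_front <- function(ratio_kymo, t_from, level = 0.5, band = c(0.2, 0.8)) {
  tt <- ratio_kymo$frame_times_h
  sel <- which(tt >= t_from)
  if (length(sel) < 2) stop("no frames after t_from")
  rc <- kymo_bin_centers_mm(ratio_kymo)
  R_t <- ratio_kymo$radius_mm
  pre <- ratio_kymo$values[, tt < t_from, drop = FALSE]
  baseline <- if (ncol(pre) > 0) median(pre, na.rm = TRUE) else 0
  inner <- outer_r <- rep(NA_real_, length(sel))
  peak <- 0
  for (j in seq_along(sel)) {
    kcol <- sel[j]
    rows <- which(rc >= band[1] * R_t[kcol] & rc <= band[2] * R_t[kcol])
    v <- ratio_kymo$values[rows, kcol] - baseline
    peak <- max(peak, max(v, na.rm = TRUE))
    cross <- which(v >= level * peak)
    if (length(cross) > 0) {
      inner[j] <- rc[rows[min(cross)]]
      outer_r[j] <- rc[rows[max(cross)]]
    }
  }
  if (mean(is.na(inner)) > 0.5)
    stop("wave front not detectable in at least half of the frames")
  fi <- lad_fit(tt[sel], inner)
  fo <- lad_fit(tt[sel], outer_r)
  list(times_h = tt[sel], inner_mm = inner, outer_mm = outer_r,
       outward_speed_mm_h = fo[2], inward_speed_mm_h = fi[2])
}

#' Welch two-sample comparison of per-colony statistics
#'
#' Two-tailed Student's t test with unequal sample variances
#' (Welch-Satterthwaite degrees of freedom), per-group mean/SD/SEM, fold
#' change of means, and the significance star string
#' (`*`, `**`, `***`, `****` at p < 0.05, 0.01, 0.005, 0.0005).
#'
#' @param group_a,group_b numeric vectors (n >= 2 each).
#' @param alpha_levels significance thresholds for the star mapping.
#' @return a `strain_comparison` list.
#' @export
compare_strains <- function(group_a, group_b,
                            alpha_levels = c(0.05, 0.01, 0.005, 0.0005)) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("need at least two replicates per group")
  if (sd(group_a) == 0 && sd(group_b) == 0 && mean(group_a) == mean(group_b)) {
    tstat <- 0; p <- 1; df <- length(group_a) + length(group_b) - 2
  } else {
    ht <- t.test(group_a, group_b, var.equal = FALSE)
    tstat <- unname(ht$statistic); p <- ht$p.value; df <- unname(ht$parameter)
  }
  summ <- function(x) list(mean = mean(x), sd = sd(x),
                           sem = sd(x) / sqrt(length(x)), n = length(x))
  structure(list(group_a = summ(group_a), group_b = summ(group_b),
                 fold_change = mean(group_a) / mean(group_b),
                 t_statistic = tstat, df = df, p_value = p,
                 stars = significance_stars(p, alpha_levels)),
            class = "strain_comparison")
}

#' Significance star string for a p value
#' @param p p value.
#' @param alpha_levels decreasing thresholds mapped to `*`, `**`, ....
#' @return character: `""`, `"*"`, `"**"`, `"***"` or `"****"`.
#' @export
significance_stars <- function(p, alpha_levels = c(0.05, 0.01, 0.005, 0.0005)) {
  strrep("*", sum(p < alpha_levels))
}

#' @export
print.strain_comparison <- function(x, ...) {
  cat(sprintf("Welch t: fold = %.3g, t = %.3g (df = %.3g), p = %.3g %s\n",
              x$fold_change, x$t_statistic, x$df, x$p_value, x$stars))
  invisible(x)
}
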