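#' Default pipeline configuration
#'
#' All tunable parameters of the analysis stages with their documented
#' defaults. The configuration round-trips losslessly through YAML.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    input = list(preset = "wt_2740_80", seed = 0L, movie_dir = NULL),
    registration = list(jump_threshold_px = 3, downsample = 2L),
    projection = list(rolling_ball_radius_px = 1000L, window_h = NULL),
    kymograph = list(bin_width_px = 1, alpha = 0.1, wedge_width_deg = 30,
                     wedge_theta_min_deg = NULL),
    phases = list(p1_band = c(0.85, 1), p2_band = c(0.2, 0.8),
                  k = 3, m = 3L, n_baseline_frames = 4L, wave_level = 0.35),
    segmentation = list(n_trees = 100L, seed = 0L, scales = .default_scales,
                        min_area_fraction = 0.001, min_mean_prob = 0.5,
                        window_h = c(8, 38),
                        stain_alpha = 0.25, n_train = 4L, drop_ids = integer()),
    comparison = list(alpha_levels = c(0.05, 0.01, 0.005, 0.0005)),
    output = list(dir = NULL, log = "info"))
}

#' Validate a pipeline configuration
#'
#' Fills defaults, rejects unknown keys by name and checks value ranges.
#' `raw` may be a nested list or the path of a YAML file; an empty file or
#' `NULL` yields the full default configuration.
#'
#' @param raw list, YAML file path, or NULL.
#' @return validated configuration list.
#' @export
validate_config <- function(raw = NULL) {
  if (is.character(raw)) raw <- yaml::read_yaml(raw)
  if (is.null(raw)) raw <- list()
  cfg <- merge_config(default_config(), raw, path = "config")
  with(cfg, {
    if (!is.null(input$preset) && !input$preset %in% .preset_names)
      stop("config: unknown preset '", input$preset, "'")
    if (kymograph$alpha <= 0 || kymograph$alpha >= 1)
      stop("config: kymograph$alpha must lie in (0, 1)")
    if (kymograph$wedge_width_deg <= 0 || kymograph$wedge_width_deg > 360)
      stop("config: kymograph$wedge_width_deg must lie in (0, 360]")
    if (any(phases$p1_band < 0) || any(phases$p1_band > 1) ||
        any(phases$p2_band < 0) || any(phases$p2_band > 1))
      stop("config: phase bands must lie in [0, 1]")
    if (segmentation$min_area_fraction < 0 || segmentation$min_area_fraction > 1)
      stop("config: segmentation$min_area_fraction must lie in [0, 1]")
  })
  cfg
}

merge_config <- function(def, raw, path = "config") {
  if (!is.list(raw)) stop(path, " must be a mapping")
  bad <- setdiff(names(raw), names(def))
  if (length(bad)) stop("unknown configuration key: ", path, "$", bad[1])
  for (nm in names(raw)) {
    if (is.list(def[[nm]]) && !is.null(names(def[[nm]]))) {
      def[[nm]] <- merge_config(def[[nm]], as.list(raw[[nm]]),
                                paste0(path, "$", nm))
    } else def[[nm]] <- raw[[nm]]
  }
  def
}

## Pseudo sector-probability image from a dead-channel projection: within
## the stained footprint, dark regions (suppressed death) score high.
sector_probability_proxy <- function(dead_projection, stained_mask) {
  v <- dead_projection[stained_mask]
  q <- quantile(v, c(0.05, 0.95))
  if (q[2] <= q[1]) q[2] <- q[1] + 1e-9
  p <- 1 - (dead_projection - q[1]) / (q[2] - q[1])
  p <- pmin(pmax(p, 0), 1)
  p[!stained_mask] <- 0
  p
}

#' End-to-end phase quantification of one colony movie
#'
#' Runs the full measurement chain the way the headline statistics are
#' produced: translation registration with jump removal, centroid tracking,
#' automatic selection of a sector-free wedge (from the dead-channel
#' time projection; a manual wedge in the configuration overrides it),
#' live/dead kymographs, linear-ratio kymograph, Phase-1/Phase-2 window
#' detection, integrated death per phase, their ratio, wave-front speeds
#' and the final colony radius.
#'
#' @param stack a [movie_stack()].
#' @param config configuration from [validate_config()].
#' @return a `phase_summary` list.
#' @export
analyze_colony_movie <- function(stack, config = validate_config()) {
  reg <- register_translation_stack(stack,
                                    jump_threshold_px = config$registration$jump_threshold_px,
                                    downsample = config$registration$downsample)$stack
  tr <- track_centroids(reg, alpha = config$kymograph$alpha)
  Tn <- n_frames(reg)

  ## sector-free wedge: manual override or automatic scan of the projection
  kcfg <- config$kymograph
  if (!is.null(kcfg$wedge_theta_min_deg)) {
    wd <- wedge(kcfg$wedge_theta_min_deg * pi / 180,
                (kcfg$wedge_theta_min_deg + kcfg$wedge_width_deg) * pi / 180)
  } else {
    t_hi <- min(max(stack$frame_times_h),
                config$segmentation$window_h[2] %||% Inf)
    proj <- max_time_projection(reg, "dead",
                                c(min(stack$frame_times_h), t_hi))
    stained <- colony_mask_from_image(proj$image, config$segmentation$stain_alpha)
    ctr <- tr$centers[Tn, ]
    if (!any(stained)) {
      wd <- wedge(0, kcfg$wedge_width_deg * pi / 180)
    } else {
      prob <- sector_probability_proxy(proj$image, stained)
      wd <- select_sector_free_wedge(prob, ctr, kcfg$wedge_width_deg,
                                     mask = stained, max_mean = 1)
    }
  }

  ky <- build_kymographs(reg, wd, bin_width_px = kcfg$bin_width_px,
                         alpha = kcfg$alpha, tracking = tr)
  ratio <- ratio_kymograph(ky$dead, ky$live)

  pcfg <- config$phases
  summarize_phase <- function(band, window = NULL) {
    reg_full <- phase_region("custom", band = band)
    msk <- region_mask(ratio, reg_full)
    series <- region_mean_series(ratio, msk)
    ## phase-free reference level of the band: the smaller of its mean ratio
    ## at the start and at the end of the movie (see integrated_death docs)
    nb <- pcfg$n_baseline_frames
    baseline <- min(median(head(series, nb), na.rm = TRUE),
                    median(tail(series, nb), na.rm = TRUE))
    win <- detect_phase_window(series, ratio$frame_times_h,
                               k = pcfg$k, m = pcfg$m)
    integral <- 0
    if (win$detected) {
      reg_win <- phase_region("custom", band = band,
                              window = window %||% c(win$onset_h, win$end_h))
      mw <- region_mask(ratio, reg_win)
      integral <- as.numeric(integrated_death(ratio, mw, baseline = baseline))
    }
    list(window = win, series = series, integral = integral, baseline = baseline)
  }
  p1 <- summarize_phase(pcfg$p1_band)
  p2 <- summarize_phase(pcfg$p2_band)
  ## Phase 2 is operationally the late death phase: an interior signal whose
  ## onset does not follow the cessation of rim death is rim-death bleed-over
  ## (or drift), not a second phase
  if (p2$window$detected && p1$window$detected &&
      p2$window$onset_h <= p1$window$end_h) {
    p2$window$detected <- FALSE
    p2$window$onset_h <- p2$window$end_h <- NA_real_
    p2$integral <- 0
  }

  total_mask <- region_mask(ratio, phase_region("custom", band = c(0, 1)))
  total_series <- region_mean_series(ratio, total_mask)
  nb <- pcfg$n_baseline_frames
  total_baseline <- min(median(head(total_series, nb), na.rm = TRUE),
                        median(tail(total_series, nb), na.rm = TRUE))
  total_integral <- as.numeric(integrated_death(ratio, total_mask,
                                                baseline = total_baseline))

  fronts <- NULL
  if (p2$window$detected) {
    fronts <- tryCatch(
      track_wave_front(ratio, t_from = p2$window$onset_h,
                       level = pcfg$wave_level, band = pcfg$p2_band),
      error = function(e) NULL)
  }

  structure(list(
    wedge = wd,
    kymographs = list(live = ky$live, dead = ky$dead, ratio = ratio),
    centers_px = ky$centers,
    radius_mm = ky$radius_mm,
    final_radius_mm = ky$radius_mm[Tn],
    p1 = p1, p2 = p2,
    p1_p2_ratio = p1_p2_ratio(p1$integral, p2$integral),
    total_integral = total_integral,
    fronts = fronts), class = "phase_summary")
}

#' @export
print.phase_summary <- function(x, ...) {
  fmt_win <- function(w) if (w$window$detected)
    sprintf("[%.3g, %.3g] h, integral %.4g", w$window$onset_h, w$window$end_h,
            w$integral) else "not detected"
  cat("phase_summary\n",
      sprintf("  final radius: %.3g mm\n", x$final_radius_mm),
      "  P1: ", fmt_win(x$p1), "\n",
      "  P2: ", fmt_win(x$p2), "\n",
      sprintf("  P1:P2 integrated death ratio: %.3g\n", x$p1_p2_ratio),
      if (!is.null(x$fronts))
        sprintf("  P2 front speeds: outward %+.3g, inward %+.3g mm/h\n",
                x$fronts$outward_speed_mm_h, x$fronts$inward_speed_mm_h),
      sep = "")
  invisible(x)
}

#' Training labels for the sector classifier from ground truth
#'
#' Builds a label mask (1 = sector, 2 = non-sector, 0 = unlabeled) for the
#' final frame of the projection window: sector pixels are the eroded true
#' sector wedges, non-sector pixels the true colony footprint away from the
#' (dilated) wedges; the uncertain boundary band stays unlabeled.
#'
#' @param truth a `ground_truth`.
#' @param t_h time (h) at which the labels are realized (projection window
#'   end).
#' @param margin_px boundary band half-width left unlabeled.
#' @return integer matrix.
#' @export
make_training_labels <- function(truth, t_h = 38, margin_px = 3L) {
  frame <- max(which(truth$frame_times_h <= t_h))
  sec <- ground_truth_sector_mask(truth, frame)
  col <- ground_truth_colony_mask(truth, frame)
  br <- EBImage::makeBrush(2L * margin_px + 1L, "disc")
  sec_in <- as.matrix(EBImage::erode(matrix(as.numeric(sec), nrow(sec)), br)) > 0
  sec_out <- as.matrix(EBImage::dilate(matrix(as.numeric(sec), nrow(sec)), br)) > 0
  lab <- matrix(0L, nrow(sec), ncol(sec))
  lab[col & !sec_out] <- 2L
  lab[sec_in] <- 1L
  lab
}

#' Dead-channel time projection for sector segmentation
#'
#' Registers the movie, projects the dead channel over the segmentation
#' window (by default the first 38 h of growth) and applies rolling-ball
#' background subtraction.
#'
#' @param stack a [movie_stack()].
#' @param config validated configuration.
#' @return list with `projection` (matrix), `colony_mask` (live-channel
#'   footprint at the window end), `stained_mask` (dead-channel stained
#'   footprint).
#' @export
segmentation_projection <- function(stack, config = validate_config()) {
  reg <- register_translation_stack(stack,
                                    jump_threshold_px = config$registration$jump_threshold_px,
                                    downsample = config$registration$downsample)$stack
  win <- c(min(stack$frame_times_h),
           min(config$segmentation$window_h[2], max(stack$frame_times_h)))
  pd <- max_time_projection(reg, "dead", win)$image
  pl <- max_time_projection(reg, "live", win)$image
  rb <- config$projection$rolling_ball_radius_px
  if (!is.null(rb) && rb >= 1) pd <- rolling_ball_subtract(pd, rb)
  colony <- colony_mask_from_image(pl, 0.1)
  ## radially closed stained footprint: sectors cut the stained annulus open
  ## to its boundary, so the support is the full disk out to the stained
  ## radial extent (where segmentation has signal to work with)
  raw <- colony_mask_from_image(pd, config$segmentation$stain_alpha)
  stained <- raw
  if (any(raw)) {
    idx <- which(raw, arr.ind = TRUE)
    ctr <- colMeans(which(colony, arr.ind = TRUE))
    rr <- sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2)
    g <- radial_grids(nrow(pd), ncol(pd), ctr)
    stained <- g$r <= quantile(rr, 0.995) + 2
  }
  list(projection = pd, colony_mask = colony, stained_mask = stained)
}

#' Segment sectors in a dead-channel projection
#'
#' The full segmentation path: sector-probability image from the trained
#' classifier (restricted to the stained colony footprint), Renyi-entropy
#' threshold of the probability histogram over that footprint, particle
#' size cutoff, and the colony-area fraction occupied by the kept ROIs.
#'
#' @param seg result of [segmentation_projection()].
#' @param classifier a [train_pixel_classifier()] model.
#' @param config validated configuration.
#' @return list with `probability`, `threshold`, `binary`, `rois`,
#'   `sector_fraction`.
#' @export
segment_sectors <- function(seg, classifier, config = validate_config()) {
  prob <- predict_probability(classifier, seg$projection, mask = seg$stained_mask)
  vals <- prob[seg$stained_mask]
  thr <- renyi_entropy_threshold(matrix(vals, nrow = 1))
  binary <- prob > as.numeric(thr)
  min_area <- ceiling(config$segmentation$min_area_fraction * sum(seg$colony_mask))
  rois <- extract_sector_rois(binary, min_area, seg$stained_mask,
                              prob_image = prob,
                              min_mean_prob = config$segmentation$min_mean_prob,
                              drop_ids = config$segmentation$drop_ids)
  list(probability = prob, threshold = as.numeric(thr), binary = binary,
       rois = rois,
       sector_fraction = sector_area_fraction(rois, seg$colony_mask))
}

#' Pixel-level recall and precision of a segmentation
#'
#' @param predicted logical matrix (kept-ROI pixels).
#' @param truth_mask logical ground-truth sector mask.
#' @return list with `recall`, `precision`.
#' @export
segmentation_metrics <- function(predicted, truth_mask) {
  tp <- sum(predicted & truth_mask)
  list(recall = if (sum(truth_mask) == 0) NA_real_ else tp / sum(truth_mask),
       precision = if (sum(predicted) == 0) NA_real_ else tp / sum(predicted))
}

roi_pixel_mask <- function(rois) {
  keep_ids <- rois$rois$id[rois$rois$kept]
  rois$labels %in% keep_ids & rois$labels > 0
}

#' Kept-ROI pixel mask from an [extract_sector_rois()] result
#' @param rois list from [extract_sector_rois()].
#' @return logical matrix.
#' @export
sector_pixel_mask <- function(rois) {
  matrix(roi_pixel_mask(rois), nrow(rois$labels), ncol(rois$labels))
}

#' Run the pipeline end to end for one configuration
#'
#' Stages: simulate (or load) the movie, write projections, kymographs and
#' the phase summary, and (optionally) the sector segmentation, into the
#' output directory together with a YAML run manifest recording the
#' configuration echo, seeds, per-file MD5 hashes and timestamps. A rerun
#' with an unchanged configuration reuses cached stage outputs (matched by
#' configuration hash) and marks them as cache hits in the manifest.
#'
#' @param config configuration (list, YAML path or NULL); must provide
#'   `output$dir`.
#' @param segment also run the segmentation stage (trains a classifier on
#'   `segmentation$n_train` extra seeds of the same preset).
#' @return the run manifest, invisibly.
#' @export
run_pipeline <- function(config, segment = FALSE) {
  cfg <- validate_config(config)
  out_dir <- cfg$output$dir
  if (is.null(out_dir)) stop("config: output$dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- config_hash(cfg)
  manifest_path <- file.path(out_dir, "manifest.yaml")
  old <- if (file.exists(manifest_path)) yaml::read_yaml(manifest_path) else NULL
  cache_ok <- !is.null(old) && identical(old$config_hash, cfg_hash) &&
    all(file.exists(file.path(out_dir, names(old$files %||% list())))) &&
    identical(unname(unlist(old$files)),
              unname(tools::md5sum(file.path(out_dir, names(old$files)))))
  if (cache_ok) {
    old$cache_hit <- TRUE
    yaml::write_yaml(old, manifest_path)
    return(invisible(old))
  }

  ## stage 1: simulate or load
  if (!is.null(cfg$input$movie_dir)) {
    stack <- read_movie(cfg$input$movie_dir)
    truth <- NULL
  } else {
    sim <- generate_movie(make_preset(cfg$input$preset), seed = cfg$input$seed)
    stack <- sim$stack; truth <- sim$truth
    write_ground_truth(truth, file.path(out_dir, "ground_truth"))
  }

  ## stage 2: phase quantification
  ps <- analyze_colony_movie(stack, cfg)
  write_kymograph_csv(ps$kymographs$ratio, file.path(out_dir, "kymograph_ratio.csv"))
  write_kymograph_csv(ps$kymographs$dead, file.path(out_dir, "kymograph_dead.csv"))
  write_kymograph_csv(ps$kymographs$live, file.path(out_dir, "kymograph_live.csv"))
  plot_kymograph_png(ps$kymographs$ratio, file.path(out_dir, "kymograph_ratio.png"),
                     log10 = TRUE)
  summary_df <- data.frame(
    preset = cfg$input$preset %||% NA, seed = cfg$input$seed %||% NA,
    final_radius_mm = ps$final_radius_mm,
    p1_onset_h = ps$p1$window$onset_h, p1_end_h = ps$p1$window$end_h,
    p2_onset_h = ps$p2$window$onset_h, p2_end_h = ps$p2$window$end_h,
    p1_integral = ps$p1$integral, p2_integral = ps$p2$integral,
    p1_p2_ratio = ps$p1_p2_ratio, total_integral = ps$total_integral,
    outward_speed_mm_h = ps$fronts$outward_speed_mm_h %||% NA,
    inward_speed_mm_h = ps$fronts$inward_speed_mm_h %||% NA)
  utils::write.csv(summary_df, file.path(out_dir, "phase_summary.csv"),
                   row.names = FALSE)

  ## stage 3 (optional): segmentation
  if (segment) {
    scfg <- cfg$segmentation
    preset <- make_preset(cfg$input$preset)
    train_seeds <- cfg$input$seed + 1000L + seq_len(scfg$n_train)
    imgs <- list(); labs <- list()
    for (s in train_seeds) {
      sim_t <- generate_movie(preset, seed = s)
      sp <- segmentation_projection(sim_t$stack, cfg)
      imgs[[length(imgs) + 1]] <- sp$projection
      labs[[length(labs) + 1]] <- make_training_labels(sim_t$truth,
                                                       t_h = scfg$window_h[2])
    }
    clf <- train_pixel_classifier(imgs, labs, n_trees = scfg$n_trees,
                                  seed = scfg$seed, scales = scfg$scales)
    seg <- segment_sectors(segmentation_projection(stack, cfg), clf, cfg)
    utils::write.csv(seg$rois$rois, file.path(out_dir, "sector_rois.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(sector_fraction = seg$sector_fraction,
                                threshold = seg$threshold),
                     file.path(out_dir, "sector_fraction.csv"), row.names = FALSE)
  }

  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.yaml")
  manifest <- list(config = cfg, config_hash = cfg_hash,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   cache_hit = FALSE,
                   files = as.list(setNames(unname(tools::md5sum(file.path(out_dir, files))),
                                            files)))
  yaml::write_yaml(manifest, manifest_path)
  invisible(manifest)
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(cfg, f)
  unname(tools::md5sum(f))
}
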