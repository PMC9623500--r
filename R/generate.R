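#' Phenomenological death-rate field
#'
#' Evaluates the generator's death-rate kernel at polar positions
#' `(r, theta)` (colony-centred, mm / radians) and time `t` (h). The field is
#' the sum of three components, each gated by its time window and multiplied
#' by `(1 - death_suppression)` inside any sector wedge nucleated before `t`:
#'
#' * Phase 1: a Gaussian rim band centred at
#'   `(1 - rim_band_fraction/2) * R(t)`, active on
#'   `[p1$onset_h, p1$end_h)`.
#' * Phase 2: two Gaussian fronts starting at
#'   `ring_radius_fraction * R(onset)` and travelling outward/inward at the
#'   preset speeds, active from `p2$onset_h`.
#' * Uniform: a constant rate across the colony from `uniform$onset_h`
#'   (used by the constitutive-killing preset).
#'
#' The rate is zero outside the instantaneous colony radius. Units are
#' counts per pixel per hour: the movie generator accumulates exactly this
#' field into the dead channel, so its space-time integral equals the total
#' noise-free dead-channel signal.
#'
#' @param params a `generator_params`.
#' @param r radii, mm (vector).
#' @param theta angles, rad (vector, recycled against `r`).
#' @param t a single time, h.
#' @param sectors optional pre-computed [realize_sectors()] table.
#' @return numeric vector of rates, same length as `r`.
#' @export
death_rate_field <- function(params, r, theta, t, sectors = NULL) {
  stopifnot(length(t) == 1, all(r >= 0))
  n <- max(length(r), length(theta))
  r <- rep_len(r, n); theta <- rep_len(theta, n)
  R_t <- colony_radius_mm(params, t)
  rate <- numeric(n)
  p1 <- params$p1
  if (p1$amplitude > 0 && t >= p1$onset_h && t < p1$end_h) {
    ctr <- (1 - p1$rim_band_fraction / 2) * R_t
    sig <- p1$band_sigma_frac * R_t
    sig0 <- p1$band_sigma_frac * params$radius_curve$r0_mm
    rate <- rate + p1$amplitude * (sig0 / sig) * exp(-(r - ctr)^2 / (2 * sig^2))
  }
  p2 <- params$p2
  if (p2$amplitude > 0 && t >= p2$onset_h) {
    r0 <- p2$ring_radius_fraction * colony_radius_mm(params, p2$onset_h)
    ro <- r0 + p2$outward_speed_mm_h * (t - p2$onset_h)
    ri <- max(r0 - p2$inward_speed_mm_h * (t - p2$onset_h), 0)
    sig <- p2$band_width_mm / 2.3548
    amp <- p2$amplitude * (1 + (p2$init_burst %||% 0) *
                             exp(-(t - p2$onset_h) / (p2$init_tau_h %||% 1)))
    rate <- rate + amp *
      (exp(-(r - ro)^2 / (2 * sig^2)) + exp(-(r - ri)^2 / (2 * sig^2)))
  }
  if (params$uniform$amplitude > 0 && t >= params$uniform$onset_h)
    rate <- rate + params$uniform$amplitude
  if (is.null(sectors)) sectors <- realize_sectors(params)
  if (nrow(sectors) > 0 && params$sectors$death_suppression > 0) {
    fac <- 1 - params$sectors$death_suppression
    for (i in seq_len(nrow(sectors))) {
      if (t < sectors$nucleation_time_h[i]) next
      inside <- angle_in_interval(theta, sectors$theta1[i],
                                  (sectors$theta2[i] - sectors$theta1[i]) %% (2 * pi) + sectors$theta1[i]) &
        r >= sectors$r_nucleation_mm[i]
      rate[inside] <- rate[inside] * fac
    }
  }
  rate[r > R_t] <- 0
  rate
}

#' Resolved founding-stain amplitude
#'
#' The static dead-stain signal in the pre-imaging colony core defaults to
#' the surface density the Phase-1 rim band deposits as it sweeps outward
#' (`amplitude * sqrt(2*pi) * band_sigma / band speed`), so the stained
#' interior is seamless for strains with rim death and absent without it.
#' An explicit `founding$amplitude` overrides the match.
#'
#' @param params a `generator_params`.
#' @return amplitude in counts.
#' @export
founding_amplitude <- function(params) {
  f <- params$founding
  if (!is.null(f$amplitude)) return(f$amplitude)
  p1 <- params$p1
  if (p1$amplitude <= 0) return(0)
  speed <- (1 - p1$rim_band_fraction / 2) *
    (colony_radius_mm(params, p1$end_h) - colony_radius_mm(params, p1$onset_h)) /
    (p1$end_h - p1$onset_h)
  if (speed <= 0) return(0)
  sig0 <- p1$band_sigma_frac * params$radius_curve$r0_mm
  p1$amplitude * sqrt(2 * pi) * sig0 / speed
}

## Final deposited Phase-1 trail surface density at radii r_mm (1-D midpoint
## quadrature over the movie's frame intervals, no sector suppression).
trail_profile <- function(params, r_mm) {
  times <- seq(params$t_start_h, params$t_end_h + 1e-9, by = params$dt_h)
  out <- numeric(length(r_mm))
  p1 <- params$p1
  if (p1$amplitude <= 0) return(out)
  sig0 <- p1$band_sigma_frac * params$radius_curve$r0_mm
  cc <- 1 - p1$rim_band_fraction / 2
  for (k in seq_along(times)[-1]) {
    tm <- (times[k - 1] + times[k]) / 2
    if (tm < p1$onset_h || tm >= p1$end_h) next
    R_m <- colony_radius_mm(params, tm)
    sig <- p1$band_sigma_frac * R_m
    t_a <- max(times[k - 1], p1$onset_h)
    t_b <- min(times[k], p1$end_h)
    R_a <- colony_radius_mm(params, t_a)
    R_b <- colony_radius_mm(params, t_b)
    dRdt <- (R_b - R_a) / max(t_b - t_a, 1e-9)
    if (dRdt > 1e-9) {
      out <- out + p1$amplitude * sig0 * sqrt(2 * pi) / (cc * dRdt) *
        pmax(pnorm((cc * R_b - r_mm) / sig) - pnorm((cc * R_a - r_mm) / sig), 0) *
        (r_mm <= R_m)
    } else {
      out <- out + p1$amplitude * (sig0 / sig) * (t_b - t_a) *
        exp(-(r_mm - cc * R_m)^2 / (2 * sig^2)) * (r_mm <= R_m)
    }
  }
  out
}

#' Generate a synthetic two-channel colony movie with ground truth
#'
#' Renders a seeded, fully deterministic time-lapse of a radially growing
#' colony. The live channel is the live-reporter intensity times colony
#' occupancy (antialiased rim edge), minus the locally accumulated death
#' signal. The dead
#' channel is the accumulated death signal (midpoint-rule integral of
#' [death_rate_field()]) plus a static founding-core stain and the camera
#' background. Stage drift is applied as identical integer-pixel shifts to
#' both channels, then Poisson shot noise and Gaussian read noise are added.
#'
#' @param params a `generator_params`.
#' @param seed integer; overrides `params$seed`.
#' @return list with elements `stack` (a [movie_stack()]) and `truth`
#'   (a `ground_truth` list: per-frame `center_px` (row, col) and
#'   `colony_radius_mm`, the realized `sectors` table, `phase_windows`,
#'   `true_integrated` death per component, `drift_px`, and a `params` echo).
#' @export
generate_movie <- function(params, seed = params$seed) {
  validate_params(params)
  params$seed <- as.integer(seed)
  n <- params$image_size_px
  px <- params$pixel_size_mm
  dt <- params$dt_h
  times <- seq(params$t_start_h, params$t_end_h + 1e-9, by = dt)
  Tn <- length(times)
  r1_px <- params$radius_curve$r1_mm / px
  if (r1_px + params$drift$max_px + 1 > n / 2)
    stop("image too small to contain the final colony radius plus drift; ",
         "need at least ", ceiling(2 * (r1_px + params$drift$max_px + 3)), " px")

  ctr0 <- c((n + 1) / 2, (n + 1) / 2)
  g <- radial_grids(n, n, ctr0)
  r_mm <- g$r * px

  sectors <- realize_sectors(params)
  sup <- params$sectors$death_suppression
  adv <- params$sectors$growth_advantage
  ## static per-sector wedge fields (smooth edges stand in for the optical PSF)
  wedge_smooth <- vector("list", nrow(sectors))
  if (nrow(sectors) > 0) {
    for (i in seq_len(nrow(sectors))) {
      wm <- angle_in_interval(g$theta, sectors$theta1[i],
                              (sectors$theta2[i] - sectors$theta1[i]) %% (2 * pi) + sectors$theta1[i]) &
        r_mm >= sectors$r_nucleation_mm[i]
      wedge_smooth[[i]] <- as.matrix(EBImage::gblur(matrix(as.numeric(wm), n, n), sigma = 1.2))
    }
  }

  f_amp <- founding_amplitude(params)
  founding <- matrix(0, n, n)
  if (f_amp > 0) {
    if (is.null(params$founding$amplitude)) {
      ## auto mode: exact complement of the rim band's final 1-D deposit
      ## profile (radial quadrature), so founding + accumulating trail tile
      ## the interior at a seamless, constant stain density
      c0 <- (1 - params$p1$rim_band_fraction / 2) * params$radius_curve$r0_mm
      sig0 <- params$p1$band_sigma_frac * params$radius_curve$r0_mm
      rg <- seq(0, c0 + 4 * sig0, by = px / 4)
      Tfin <- trail_profile(params, rg)
      comp <- pmax(f_amp - Tfin, 0)
      comp[rg > c0 + 3 * sig0] <- 0
      fr <- approx(rg, comp, xout = pmin(r_mm, max(rg)), rule = 2)$y
      fr[r_mm > max(rg)] <- 0
      founding <- matrix(fr, n, n)
    } else {
      fr_px <- params$founding$radius_fraction * params$radius_curve$r0_mm / px
      fd <- pmin(pmax(fr_px - g$r + 0.5, 0), 1)
      founding <- f_amp * as.matrix(EBImage::gblur(fd, sigma = 1.2))
    }
  }

  res <- with_seed(params$seed, {
    ## drift: integer random walk, reflected at +/- max_px, zero at frame 1
    steps <- matrix(round(rnorm(2 * (Tn - 1), sd = params$drift$step_sd_px)), ncol = 2)
    drift <- rbind(c(0, 0), apply(steps, 2, cumsum))
    mx <- params$drift$max_px
    drift <- apply(drift, 2, function(v) {
      v <- v %% (4 * mx)
      v[v > 2 * mx] <- v[v > 2 * mx] - 4 * mx
      ifelse(abs(v) > mx, sign(v) * (2 * mx - abs(v)), v)
    })
    if (Tn == 1) drift <- matrix(0, 1, 2)

    cumD <- matrix(0, n, n)
    frames_live <- vector("list", Tn)
    frames_dead <- vector("list", Tn)
    true_int <- c(p1 = 0, p2 = 0, uniform = 0)
    gain <- params$noise$poisson_gain
    read_sd <- params$noise$read_sd
    bg <- params$noise$background

    for (k in seq_len(Tn)) {
      tk <- times[k]
      if (k > 1) {
        tm <- (times[k - 1] + tk) / 2
        R_m <- colony_radius_mm(params, tm)
        ## bounding box around the colony keeps early frames cheap
        half <- min(ceiling(R_m / px) + 6, floor((n - 1) / 2))
        ix <- seq(floor(ctr0[1]) - half, ceiling(ctr0[1]) + half)
        rs <- r_mm[ix, ix]
        inside <- rs <= R_m
        sfac <- matrix(1, length(ix), length(ix))
        if (nrow(sectors) > 0 && sup > 0) {
          for (i in seq_len(nrow(sectors)))
            if (tm >= sectors$nucleation_time_h[i])
              sfac <- sfac * (1 - sup * wedge_smooth[[i]][ix, ix])
        }
        add_comp <- function(base_rate, nm) add_comp_abs(base_rate * dt, nm)
        add_comp_abs <- function(increment, nm) {
          inc <- increment * sfac * inside
          cumD[ix, ix] <<- cumD[ix, ix] + inc
          true_int[nm] <<- true_int[nm] + sum(inc)
        }
        p1 <- params$p1
        if (p1$amplitude > 0 && tm >= p1$onset_h && tm < p1$end_h) {
          ## exact time integral of the narrow moving band over the frame
          ## interval (CDF difference); midpoint sampling would alias when
          ## the band advances further than its own width per frame
          cc <- 1 - p1$rim_band_fraction / 2
          sig <- p1$band_sigma_frac * R_m
          sig0 <- p1$band_sigma_frac * params$radius_curve$r0_mm
          t_a <- max(times[k - 1], p1$onset_h)
          t_b <- min(tk, p1$end_h)
          R_a <- colony_radius_mm(params, t_a)
          R_b <- colony_radius_mm(params, t_b)
          dRdt <- (R_b - R_a) / max(t_b - t_a, 1e-9)
          ## evaluate only on the narrow annulus the band touches this frame
          ring <- which(rs >= cc * R_a - 6 * sig & rs <= cc * R_b + 6 * sig)
          inc1 <- matrix(0, length(ix), length(ix))
          if (length(ring)) {
            rr <- rs[ring]
            inc1[ring] <- if (dRdt > 1e-9) {
              p1$amplitude * sig0 * sqrt(2 * pi) / (cc * dRdt) *
                pmax(pnorm((cc * R_b - rr) / sig) - pnorm((cc * R_a - rr) / sig), 0)
            } else {
              p1$amplitude * (sig0 / sig) * (t_b - t_a) *
                exp(-(rr - cc * R_m)^2 / (2 * sig^2))
            }
          }
          add_comp_abs(inc1, "p1")
        }
        p2 <- params$p2
        if (p2$amplitude > 0 && tm >= p2$onset_h) {
          r0 <- p2$ring_radius_fraction * colony_radius_mm(params, p2$onset_h)
          ro <- r0 + p2$outward_speed_mm_h * (tm - p2$onset_h)
          ri <- max(r0 - p2$inward_speed_mm_h * (tm - p2$onset_h), 0)
          sig <- p2$band_width_mm / 2.3548
          ampm <- p2$amplitude * (1 + (p2$init_burst %||% 0) *
                                    exp(-(tm - p2$onset_h) / (p2$init_tau_h %||% 1)))
          add_comp(ampm * (exp(-(rs - ro)^2 / (2 * sig^2)) +
                             exp(-(rs - ri)^2 / (2 * sig^2))), "p2")
        }
        if (params$uniform$amplitude > 0 && tm >= params$uniform$onset_h)
          add_comp(matrix(params$uniform$amplitude, length(ix), length(ix)), "uniform")
      }

      R_k <- colony_radius_mm(params, tk)
      ## compose the frame on the colony's bounding box; outside it the live
      ## channel is exactly zero and the dead channel exactly background
      hb <- min(ceiling(R_k / px * max(adv, 1)) + 3L, floor((n - 1) / 2))
      jx <- seq(floor(ctr0[1]) - hb, ceiling(ctr0[1]) + hb)
      R_eff <- matrix(R_k / px, length(jx), length(jx))
      lfac <- 1
      if (nrow(sectors) > 0) {
        for (i in seq_len(nrow(sectors))) {
          if (tk < sectors$nucleation_time_h[i]) next
          if (adv != 1) R_eff <- R_eff * (1 + (adv - 1) * wedge_smooth[[i]][jx, jx])
          if (!isTRUE(params$sectors$live_reporter))
            lfac <- lfac * (1 - 0.4 * wedge_smooth[[i]][jx, jx])
        }
      }
      occ <- pmin(pmax(R_eff - g$r[jx, jx] + 0.5, 0), 1)
      ## founding-core cells are dead too: they deplete the live reporter
      ## exactly like in-movie death, keeping the interior ratio seamless
      lv <- pmax(params$live_intensity * occ * lfac - cumD[jx, jx] - founding[jx, jx], 0)
      dd <- cumD[jx, jx] + founding[jx, jx] + bg
      if (gain > 0) {
        idx <- which(lv > 0)
        lv[idx] <- rpois(length(idx), lv[idx] * gain) / gain
        dd[] <- rpois(length(dd), dd * gain) / gain
      }
      if (read_sd > 0) {
        lv <- pmax(lv + rnorm(length(lv), sd = read_sd), 0)
        dd <- pmax(dd + rnorm(length(dd), sd = read_sd), 0)
      }
      live0 <- matrix(0, n, n); dead0 <- matrix(bg, n, n)
      live0[jx, jx] <- lv
      dead0[jx, jx] <- dd
      dy <- drift[k, 1]; dx <- drift[k, 2]
      if (dy != 0 || dx != 0) {
        live0 <- shift_matrix(live0, dy, dx)
        dead0 <- shift_matrix(dead0, dy, dx, fill = bg)
      }
      frames_live[[k]] <- live0
      frames_dead[[k]] <- dead0
    }
    list(frames_live = frames_live, frames_dead = frames_dead,
         drift = drift, true_int = true_int)
  })

  stack <- movie_stack(res$frames_live, res$frames_dead, times, px)
  pw <- list()
  if (params$p1$amplitude > 0) pw$p1 <- c(params$p1$onset_h, params$p1$end_h)
  if (params$p2$amplitude > 0) pw$p2 <- c(params$p2$onset_h, params$t_end_h)
  if (params$uniform$amplitude > 0) pw$uniform <- c(params$uniform$onset_h, params$t_end_h)
  truth <- structure(list(
    center_px = sweep(res$drift, 2, ctr0, `+`),
    colony_radius_mm = colony_radius_mm(params, times),
    frame_times_h = times,
    sectors = sectors,
    phase_windows = pw,
    true_integrated = as.list(res$true_int),
    drift_px = res$drift,
    params = params), class = "ground_truth")
  list(stack = stack, truth = truth)
}

#' Ground-truth sector mask for one frame
#'
#' Realizes the true sector mask (wedge intersected with the colony disk and
#' the nucleation radius, in image coordinates including drift) for a given
#' frame of a generated movie.
#'
#' @param truth a `ground_truth` from [generate_movie()].
#' @param frame frame index.
#' @return logical matrix.
#' @export
ground_truth_sector_mask <- function(truth, frame) {
  p <- truth$params
  n <- p$image_size_px
  g <- radial_grids(n, n, truth$center_px[frame, ])
  r_mm <- g$r * p$pixel_size_mm
  out <- matrix(FALSE, n, n)
  tk <- truth$frame_times_h[frame]
  R_k <- truth$colony_radius_mm[frame]
  sec <- truth$sectors
  for (i in seq_len(nrow(sec))) {
    if (tk < sec$nucleation_time_h[i]) next
    out <- out | (angle_in_interval(g$theta, sec$theta1[i],
                                    (sec$theta2[i] - sec$theta1[i]) %% (2 * pi) + sec$theta1[i]) &
                    r_mm >= sec$r_nucleation_mm[i] & r_mm <= R_k)
  }
  out
}

#' Ground-truth colony mask for one frame
#' @inheritParams ground_truth_sector_mask
#' @return logical matrix, TRUE inside the true colony disk.
#' @export
ground_truth_colony_mask <- function(truth, frame) {
  p <- truth$params
  n <- p$image_size_px
  g <- radial_grids(n, n, truth$center_px[frame, ])
  g$r * p$pixel_size_mm <= truth$colony_radius_mm[frame]
}

#' Write ground truth as plain-text tables (plus final-frame masks)
#'
#' @param truth a `ground_truth`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(frame = seq_along(truth$frame_times_h),
                              time_h = truth$frame_times_h,
                              center_row = truth$center_px[, 1],
                              center_col = truth$center_px[, 2],
                              radius_mm = truth$colony_radius_mm,
                              drift_row = truth$drift_px[, 1],
                              drift_col = truth$drift_px[, 2]),
                   file.path(dir, "frames.csv"), row.names = FALSE)
  utils::write.csv(truth$sectors, file.path(dir, "sectors.csv"), row.names = FALSE)
  utils::write.csv(data.frame(component = names(truth$true_integrated),
                              integrated_death = unlist(truth$true_integrated)),
                   file.path(dir, "integrated_death.csv"), row.names = FALSE)
  last <- length(truth$frame_times_h)
  sm <- ground_truth_sector_mask(truth, last)
  tiff::writeTIFF(matrix(as.numeric(sm), nrow(sm)),
                  file.path(dir, "sector_mask_final.tif"))
  invisible(dir)
}
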