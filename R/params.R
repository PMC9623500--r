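## Amplitude constants shared by the strain presets. Units are intensity
## counts per hour (death-rate fields) or counts (static founding stain).
## The wild-type pair .P1_AMP/.P2_AMP is calibrated once, at design time,
## so that the ratio-metric pipeline measures a Phase-1:Phase-2 integrated
## death ratio of 10 on noise-free default movies -- the fold relation the
## presets are defined to encode. See the methods vignette.
.P1_AMP <- 2700
.P2_AMP <- 3.2
.T6SS_AMP <- 2

#' Construct generator parameters for a synthetic colony movie
#'
#' Returns the full parameter set of the synthetic two-channel colony movie
#' generator. All arguments have defaults describing the reference wild-type
#' phenotype: a colony growing linearly from 0.5 to 3 mm radius between 8 and
#' 56 h, rim-band Phase-1 death between 8 and 40 h, an interior Phase-2 death
#' ring appearing at 44 h and propagating inward and outward, and rim
#' sectors in which death is suppressed.
#'
#' @param image_size_px side of the square image, px.
#' @param pixel_size_mm physical pixel size, mm/px.
#' @param t_start_h,t_end_h,dt_h movie time span and frame interval, hours.
#' @param radius_curve list with `r0_mm`, `r1_mm` (initial/final colony
#'   radius), `law` (`"linear"` or `"logistic"`) and `t_sat_h`, the time at
#'   which expansion saturates at the final radius (colonies stop expanding
#'   before the movie ends; the radius is constant afterwards).
#' @param live_intensity peak live-channel intensity, counts.
#' @param p1 Phase-1 rim death: `onset_h`, `end_h`, `rim_band_fraction`
#'   (positions the band: a Gaussian centred at
#'   `(1 - rim_band_fraction/2) * R(t)`), `band_sigma_frac` (radial sigma
#'   of the band as a fraction of `R(t)`; the kernel amplitude is scaled by
#'   `sigma(t_start)/sigma(t)` so the deposited stain surface density stays
#'   constant along the trail), `amplitude` (peak rate at the first frame).
#' @param p2 Phase-2 ring death: `onset_h`, `ring_radius_fraction` (starting
#'   radius as a fraction of `R(onset)`), `outward_speed_mm_h`,
#'   `inward_speed_mm_h` (both positive; the inward front moves to smaller
#'   radii), `band_width_mm` (FWHM of each front), `amplitude`, and an
#'   initiation burst (`init_burst`, `init_tau_h`): the ring appears with a
#'   transient `(1 + init_burst * exp(-(t - onset)/init_tau_h))` rate factor,
#'   making the initiation a sharp step.
#' @param uniform spatially uniform death (constitutive killing):
#'   `onset_h`, `amplitude`.
#' @param founding static dead-stain signal laid down before imaging starts
#'   in the colony core: `radius_fraction` (of the initial radius),
#'   `amplitude` (counts; `NULL` auto-matches the Phase-1 trail stain
#'   density, so the stained interior is seamless for strains with rim
#'   death and absent for strains without it).
#' @param sectors clonal rim sectors: `count`, `nucleation_time_h`,
#'   `angular_width_deg`, `death_suppression` in `[0, 1]` (1 = no death
#'   inside the wedge), `growth_advantage` (local radial bulge factor),
#'   `live_reporter` (FALSE dims the live channel inside sectors),
#'   `min_gap_deg` minimum angular gap between sectors.
#' @param noise `poisson_gain` (0 disables shot noise), `read_sd` (additive
#'   Gaussian read noise sd, counts; 0 disables), `background` (counts,
#'   dead channel).
#' @param drift per-frame integer random-walk stage drift: `step_sd_px`,
#'   `max_px` (reflecting bound).
#' @param seed integer RNG seed controlling sector placement, drift and noise.
#' @return a list of class `generator_params`.
#' @seealso [make_preset()] for per-strain presets.
#' @export
generator_params <- function(
    image_size_px = 512L,
    pixel_size_mm = 0.012,
    t_start_h = 8, t_end_h = 56, dt_h = 0.5,
    radius_curve = list(r0_mm = 0.5, r1_mm = 3.0, law = "linear", t_sat_h = 43.45),
    live_intensity = 1000,
    p1 = list(onset_h = 8, end_h = 40, rim_band_fraction = 0.211,
              band_sigma_frac = 0.0095, amplitude = .P1_AMP),
    p2 = list(onset_h = 44, ring_radius_fraction = 0.35, outward_speed_mm_h = 0.04,
              inward_speed_mm_h = 0.025, band_width_mm = 0.12, amplitude = .P2_AMP,
              init_burst = 3, init_tau_h = 0.5),
    uniform = list(onset_h = 10, amplitude = 0),
    founding = list(radius_fraction = 0.8, amplitude = NULL),
    sectors = list(count = 2L, nucleation_time_h = 9, angular_width_deg = 30,
                   death_suppression = 0.97, growth_advantage = 1.0,
                   live_reporter = TRUE, min_gap_deg = 32),
    noise = list(poisson_gain = 10, read_sd = 0, background = 20),
    drift = list(step_sd_px = 0.4, max_px = 5),
    seed = 0L) {
  p <- list(image_size_px = as.integer(image_size_px), pixel_size_mm = pixel_size_mm,
            t_start_h = t_start_h, t_end_h = t_end_h, dt_h = dt_h,
            radius_curve = radius_curve, live_intensity = live_intensity,
            p1 = p1, p2 = p2, uniform = uniform,
            founding = founding, sectors = sectors, noise = noise, drift = drift,
            seed = as.integer(seed))
  validate_params(p)
  structure(p, class = "generator_params")
}

validate_params <- function(p) {
  with(p, {
    if (t_start_h >= t_end_h) stop("t_start_h must be before t_end_h")
    if (dt_h <= 0) stop("dt_h must be positive")
    if (pixel_size_mm <= 0) stop("pixel_size_mm must be positive")
    if (radius_curve$r0_mm <= 0 || radius_curve$r1_mm < radius_curve$r0_mm)
      stop("radius curve must be positive and non-decreasing")
    if (!radius_curve$law %in% c("linear", "logistic"))
      stop("radius law must be 'linear' or 'logistic'")
    for (a in c(p1$amplitude, p2$amplitude, uniform$amplitude,
                if (!is.null(founding$amplitude)) founding$amplitude))
      if (a < 0) stop("amplitudes must be non-negative")
    if (p1$rim_band_fraction <= 0 || p1$rim_band_fraction > 1)
      stop("rim_band_fraction must lie in (0, 1]")
    if (sectors$death_suppression < 0 || sectors$death_suppression > 1)
      stop("death_suppression must lie in [0, 1]")
    if (live_intensity <= 0) stop("live_intensity must be positive")
  })
  invisible(p)
}

.preset_names <- c("wt_2740_80", "delta8", "delta_vask", "delta9",
                   "luxo_a97e", "c6706_vector", "t6ss_on")

#' Strain presets for the synthetic movie generator
#'
#' Each preset encodes the documented phenotype of one strain as generator
#' parameters; presets differ from the wild type only in death amplitudes,
#' onsets and sector geometry:
#'
#' * `wt_2740_80` -- reference strain: Phase-1 rim death 8--40 h, Phase-2
#'   interior ring from 44 h, final radius 3 mm, 10:1 ratio-metric
#'   P1:P2 integrated death, two 30-degree sectors.
#' * `delta8` -- T6SS effector-less: Phase-1 death 4-fold lower, no Phase-2
#'   death, 2.5-fold larger total sector angle.
#' * `delta_vask` -- injection-apparatus mutant: death as wild type
#'   (no Phase-2 defect), 2.5-fold larger total sector angle.
#' * `delta9` -- `delta8` plus `delta_vask`: Phase-1 death as `delta8`,
#'   no Phase-2 death, half the wild-type sector angle.
#' * `luxo_a97e` -- low-cell-density-locked quorum-sensing mutant: no
#'   Phase-1 death, normal Phase-2 death, no sectors.
#' * `c6706_vector` -- naturally T6SS-silent strain with empty vector: no
#'   Phase-1 death, 10-fold weaker Phase-2 death, no sectors.
#' * `t6ss_on` -- constitutive T6SS expression in the `c6706_vector`
#'   background: additional strong spatially uniform death from 10 h,
#'   sectors as wild type.
#'
#' @param strain one of the preset names above.
#' @param ... named overrides applied on top of the preset; sub-lists (e.g.
#'   `p1`) are merged element-wise, so `make_preset("wt_2740_80",
#'   p1 = list(amplitude = 0))` keeps the other Phase-1 fields.
#' @return a `generator_params` object.
#' @export
make_preset <- function(strain, ...) {
  if (length(strain) != 1 || !strain %in% .preset_names)
    stop("unknown strain preset '", paste(strain, collapse = ","),
         "'; valid presets: ", paste(.preset_names, collapse = ", "))
  p <- generator_params()
  mod <- switch(strain,
    wt_2740_80 = list(),
    delta8 = list(p1 = list(amplitude = .P1_AMP / 4),
                  p2 = list(amplitude = 0),
                  sectors = list(count = 5L)),
    delta_vask = list(sectors = list(count = 5L)),
    delta9 = list(p1 = list(amplitude = .P1_AMP / 4),
                  p2 = list(amplitude = 0),
                  sectors = list(count = 1L)),
    luxo_a97e = list(p1 = list(amplitude = 0),
                     sectors = list(count = 0L)),
    c6706_vector = list(p1 = list(amplitude = 0),
                        p2 = list(amplitude = .P2_AMP / 10),
                        sectors = list(count = 0L)),
    t6ss_on = list(p1 = list(amplitude = 0),
                   p2 = list(amplitude = .P2_AMP / 10),
                   uniform = list(amplitude = .T6SS_AMP)))
  p <- merge_params(p, mod)
  p <- merge_params(p, list(...))
  validate_params(p)
  structure(p, class = "generator_params")
}

## Element-wise merge: scalar fields are replaced, sub-lists merged.
merge_params <- function(p, mod) {
  for (nm in names(mod)) {
    if (!nm %in% names(p)) stop("unknown generator parameter: ", nm)
    if (is.list(p[[nm]]) && is.list(mod[[nm]])) {
      bad <- setdiff(names(mod[[nm]]), names(p[[nm]]))
      if (length(bad)) stop("unknown generator parameter: ", nm, "$", bad[1])
      p[[nm]][names(mod[[nm]])] <- mod[[nm]]
    } else p[[nm]] <- mod[[nm]]
  }
  p
}

#' Colony radius at given times
#'
#' Evaluates the preset growth law. The linear law interpolates between the
#' initial and final radius over the movie span; the logistic law starts at
#' the initial radius and saturates at 99% of the final radius at the last
#' frame.
#'
#' @param params a `generator_params`.
#' @param t_h times in hours (vectorised).
#' @return radii in mm.
#' @export
colony_radius_mm <- function(params, t_h) {
  rc <- params$radius_curve
  t0 <- params$t_start_h
  ts <- rc$t_sat_h %||% params$t_end_h
  tt <- pmin(pmax(t_h, t0), ts)
  if (rc$law == "linear") {
    rc$r0_mm + (rc$r1_mm - rc$r0_mm) * (tt - t0) / (ts - t0)
  } else {
    ## logistic: saturates at 99% of the final radius at t_sat
    K <- rc$r1_mm * 1.01
    k <- log((K / rc$r0_mm - 1) / (K / rc$r1_mm - 1)) / (ts - t0)
    K / (1 + (K / rc$r0_mm - 1) * exp(-k * (tt - t0)))
  }
}

## Inverse of the growth law: time at which the rim first reached radius r_mm.
## Times before the movie start are clamped to t_start_h.
colonization_time_h <- function(params, r_mm) {
  rc <- params$radius_curve
  t0 <- params$t_start_h
  ts <- rc$t_sat_h %||% params$t_end_h
  r <- pmin(pmax(r_mm, rc$r0_mm), rc$r1_mm)
  if (rc$law == "linear") {
    t0 + (r - rc$r0_mm) / (rc$r1_mm - rc$r0_mm) * (ts - t0)
  } else {
    K <- rc$r1_mm * 1.01
    k <- log((K / rc$r0_mm - 1) / (K / rc$r1_mm - 1)) / (ts - t0)
    t0 + log((K / rc$r0_mm - 1) / (K / r - 1)) / k
  }
}

#' Realized sector geometry for a parameter set
#'
#' Sector nucleation angles are drawn from the seeded generator RNG,
#' uniformly on the circle subject to a minimum angular gap, so the same
#' `generator_params` always yield the same sectors. Sectors nucleate at the
#' rim: each wedge occupies radii beyond the colony radius at its nucleation
#' time.
#'
#' @param params a `generator_params`.
#' @return data.frame with columns `id`, `theta1`, `theta2` (rad),
#'   `nucleation_time_h`, `r_nucleation_mm`; zero rows if the preset has no
#'   sectors.
#' @export
realize_sectors <- function(params) {
  s <- params$sectors
  n <- as.integer(s$count)
  if (n == 0L)
    return(data.frame(id = integer(), theta1 = numeric(), theta2 = numeric(),
                      nucleation_time_h = numeric(), r_nucleation_mm = numeric()))
  w <- s$angular_width_deg * pi / 180
  gap <- s$min_gap_deg * pi / 180
  if (n * (w + gap) > 2 * pi)
    stop("sector geometry does not fit on the circle; reduce count/width/gap")
  ## constructive placement: a uniform start angle plus Dirichlet-distributed
  ## slack between consecutive sectors guarantees the minimum gap in one draw
  centers <- with_seed(params$seed + 7L, {
    slack <- 2 * pi - n * (w + gap)
    extra <- rexp(n)
    extra <- slack * extra / sum(extra)
    start <- runif(1, 0, 2 * pi)
    pos <- start + cumsum(c(0, (w + gap + extra)[-n]))
    (pos + w / 2) %% (2 * pi)
  })
  r_nuc <- colony_radius_mm(params, s$nucleation_time_h)
  data.frame(id = seq_len(n),
             theta1 = (centers - w / 2) %% (2 * pi),
             theta2 = (centers + w / 2) %% (2 * pi),
             nucleation_time_h = s$nucleation_time_h,
             r_nucleation_mm = r_nuc)
}
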