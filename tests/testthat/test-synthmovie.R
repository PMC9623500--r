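test_that("presets encode the documented strain phenotypes", {
  wt <- make_preset("wt_2740_80")
  expect_equal(wt$p1$onset_h, 8)
  expect_equal(wt$p1$end_h, 40)
  expect_equal(wt$p2$onset_h, 44)
  expect_equal(wt$radius_curve$r1_mm, 3)

  d8 <- make_preset("delta8")
  expect_equal(d8$p2$amplitude, 0)
  expect_equal(d8$p1$amplitude, wt$p1$amplitude / 4)
  # sector angular budget: 2.5x the wild type for delta8/delta-vasK, 0.5x for delta9
  ang <- function(p) p$sectors$count * p$sectors$angular_width_deg
  expect_equal(ang(d8) / ang(wt), 2.5)
  expect_equal(ang(make_preset("delta_vask")) / ang(wt), 2.5)
  expect_equal(ang(make_preset("delta9")) / ang(wt), 0.5)
  expect_equal(make_preset("luxo_a97e")$p1$amplitude, 0)
  expect_equal(make_preset("c6706_vector")$p2$amplitude, wt$p2$amplitude / 10)
  expect_gt(make_preset("t6ss_on")$uniform$amplitude, 0)

  expect_error(make_preset("no_such_strain"), "valid presets")
  expect_error(make_preset("wt_2740_80", p1 = list(amplitude = -1)), "non-negative")
  expect_error(make_preset("wt_2740_80", bogus_key = 1), "unknown generator parameter")
})

test_that("death-rate field realizes the phase geometry", {
  p <- tiny_noise_free(sectors = list(count = 0L))
  # silent before either phase is active
  expect_equal(death_rate_field(p, seq(0, 3, 0.1), 0, t = 5), rep(0, 31))
  # at 20 h the maximum over a dense radial grid sits in the outer rim band
  r <- seq(0, colony_radius_mm(p, 20), by = 0.002)
  rate <- death_rate_field(p, r, 0, t = 20)
  r_peak <- r[which.max(rate)]
  expect_gt(r_peak, 0.8 * colony_radius_mm(p, 20))
  expect_lt(r_peak, colony_radius_mm(p, 20))
  # zero outside the instantaneous colony radius
  expect_equal(death_rate_field(p, colony_radius_mm(p, 20) + 0.05, 0, t = 20), 0)

  # full suppression inside a sector wedge, untouched outside
  ps <- tiny_noise_free(sectors = list(count = 1L, death_suppression = 1))
  sec <- realize_sectors(ps)
  th_in <- (sec$theta1[1] + 0.1) %% (2 * pi)
  r_in <- sec$r_nucleation_mm[1] + 0.3
  expect_equal(death_rate_field(ps, r_in, th_in, t = 20), 0)
  th_out <- (sec$theta2[1] + 0.5) %% (2 * pi)
  expect_gt(death_rate_field(ps, r_in, th_out, t = 20), 0)
})

test_that("movie generation is deterministic and respects its contracts", {
  a <- generate_movie(tiny_preset(), seed = 7)
  b <- generate_movie(tiny_preset(), seed = 7)
  expect_identical(a$stack, b$stack)
  expect_identical(a$truth$drift_px, b$truth$drift_px)
  c2 <- generate_movie(tiny_preset(), seed = 8)
  expect_false(identical(a$stack$frames_dead, c2$stack$frames_dead))

  # ground-truth radius equals the growth law exactly, and is non-decreasing
  p <- tiny_preset()
  expect_equal(a$truth$colony_radius_mm,
               colony_radius_mm(p, a$stack$frame_times_h))
  expect_true(all(diff(a$truth$colony_radius_mm) >= 0))

  # image too small for the colony -> explicit error
  expect_error(generate_movie(tiny_preset(image_size_px = 100L), seed = 0),
               "image too small")
})

test_that("noise-free dead channel is cumulative and matches the field integral", {
  sim <- tiny_movie_nf()
  dead <- sim$stack$frames_dead
  # per-pixel monotone accumulation (conservation)
  for (k in c(10, 25, 40)) {
    expect_true(all(dead[[k + 1]] - dead[[k]] >= -1e-9))
  }
  # total added dead signal equals the dense space-time quadrature of the
  # rate field within 1%
  p <- tiny_noise_free()
  sec <- realize_sectors(p)
  times <- sim$stack$frame_times_h
  n <- p$image_size_px
  ctr <- c((n + 1) / 2, (n + 1) / 2)
  gy <- (seq_len(n) - ctr[1]) * p$pixel_size_mm
  r <- sqrt(outer(gy^2, gy^2, `+`))
  th <- atan2(matrix(gy, n, n), matrix(gy, n, n, byrow = TRUE))
  fine <- seq(min(times), max(times), by = p$dt_h / 8)
  integral <- 0
  for (i in seq_along(fine)[-1]) {
    tm <- (fine[i - 1] + fine[i]) / 2
    integral <- integral +
      sum(death_rate_field(p, as.numeric(r), as.numeric(th), tm, sectors = sec)) *
      (fine[i] - fine[i - 1])
  }
  total_added <- sum(dead[[length(dead)]] - dead[[1]])
  expect_lt(abs(total_added - integral) / integral, 0.01)
})

test_that("generator phenotype scales monotonically with rim-death amplitude", {
  base <- tiny_noise_free()
  amps <- c(0.5, 1, 2) * base$p1$amplitude
  ints <- vapply(amps, function(a) {
    sim <- generate_movie(tiny_noise_free(p1 = list(amplitude = a)), seed = 3)
    sim$truth$true_integrated$p1
  }, 0)
  expect_true(all(diff(ints) > 0))
})

test_that("silent generator yields a pure background dead channel", {
  p <- tiny_noise_free(p1 = list(amplitude = 0), p2 = list(amplitude = 0),
                       sectors = list(count = 0L))
  sim <- generate_movie(p, seed = 0)
  for (k in c(1, 20, 49))
    expect_equal(sim$stack$frames_dead[[k]],
                 matrix(20, p$image_size_px, p$image_size_px))
})

test_that("sector placement respects widths and minimum gaps", {
  for (s in 0:4) {
    p <- tiny_preset("delta8", seed = s)
    sec <- realize_sectors(p)
    expect_equal(nrow(sec), 5)
    w <- (sec$theta2 - sec$theta1) %% (2 * pi)
    expect_equal(w, rep(30 * pi / 180, 5), tolerance = 1e-9)
    ctrs <- sort((sec$theta1 + w / 2) %% (2 * pi))
    gaps <- diff(c(ctrs, ctrs[1] + 2 * pi)) - 30 * pi / 180
    expect_true(all(gaps >= 32 * pi / 180 - 1e-9))
  }
})

test_that("ground-truth sector masks lie inside the colony mask", {
  sim <- tiny_movie()
  k <- n_frames(sim$stack)
  sm <- ground_truth_sector_mask(sim$truth, k)
  cm <- ground_truth_colony_mask(sim$truth, k)
  expect_gt(sum(sm), 0)
  expect_true(all(cm[sm]))
})

test_that("movies round-trip through TIFF + YAML on disk", {
  sim <- tiny_movie()
  dir <- withr::local_tempdir()
  write_movie(sim$stack, dir, extra = list(seed = 1))
  back <- read_movie(dir)
  expect_equal(back$frame_times_h, sim$stack$frame_times_h)
  expect_equal(back$pixel_size_mm, sim$stack$pixel_size_mm)
  expect_equal(back$frames_dead[[5]], sim$stack$frames_dead[[5]], tolerance = 1e-4)
  write_ground_truth(sim$truth, file.path(dir, "gt"))
  expect_true(file.exists(file.path(dir, "gt", "frames.csv")))
  expect_true(file.exists(file.path(dir, "gt", "sectors.csv")))
})
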