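mk_kymo <- function(vals, times = seq_len(ncol(vals)), bw_mm = 0.1,
                    channel = "ratio_linear", radius = NULL) {
  colonykym:::new_kymograph(vals, seq(0, nrow(vals)) * bw_mm, times, channel,
                            wedge(), bw_mm,
                            radius_mm = radius %||% rep(nrow(vals) * bw_mm, ncol(vals)))
}

test_that("region masks realize radial bands against hand counts", {
  # 10-bin toy kymograph, radius growing 0.4 -> 1.0 mm over 5 frames
  vals <- matrix(1, 10, 5)
  radius <- seq(0.4, 1.0, length.out = 5)
  ky <- mk_kymo(vals, radius = radius)
  m <- region_mask(ky, phase_region("custom", band = c(0.5, 1)), radius)
  # hand-computed per-column counts: bins with centre in [0.5, 1]*R(t)
  rc <- seq(0.05, 0.95, by = 0.1)
  expected <- vapply(radius, function(R) sum(rc >= 0.5 * R & rc <= R), 0L)
  expect_equal(colSums(m), as.numeric(expected))

  # default P1 and P2 bands are disjoint at every time
  m1 <- region_mask(ky, phase_region("P1"), radius)
  m2 <- region_mask(ky, phase_region("P2"), radius)
  expect_equal(sum(m1 & m2), 0)

  # window restriction and empty-mask error
  mw <- region_mask(ky, phase_region("custom", band = c(0.5, 1), window = c(2, 3)),
                    radius)
  expect_equal(sum(colSums(mw) > 0), 2)
  expect_error(region_mask(ky, phase_region("custom", band = c(0.98, 0.99),
                                            window = c(99, 100)), radius))
  expect_error(phase_region("custom", band = c(0.9, 0.2)), "band")
})

test_that("integrated death equals the double-loop summation oracle", {
  withr::with_seed(30, {
    vals <- matrix(runif(36, 0.5, 2), 6)
    ky <- mk_kymo(vals, times = seq(2, 12, by = 2))
    mask <- matrix(c(rep(FALSE, 12), rep(TRUE, 24)), 6)
    b <- 0.8
    out <- integrated_death(ky, mask, baseline = b)
    # independent double loop
    rc <- (seq_len(6) - 0.5) * 0.1
    dts <- c(diff(seq(2, 12, by = 2)), 2)
    oracle <- 0
    for (i in 1:6) for (j in 1:6) if (mask[i, j])
      oracle <- oracle + max(vals[i, j] - b, 0) * rc[i] * 0.1 * dts[j]
    expect_equal(as.numeric(out), oracle)
  })

  # ratio == baseline -> 0; baseline + 1 on mask of weight W -> W
  vals2 <- matrix(1.5, 4, 4)
  ky2 <- mk_kymo(vals2)
  mask2 <- matrix(TRUE, 4, 4)
  expect_equal(as.numeric(integrated_death(ky2, mask2, baseline = 1.5)), 0)
  rc2 <- (seq_len(4) - 0.5) * 0.1
  W <- sum(outer(rc2 * 0.1, rep(1, 4)))
  expect_equal(as.numeric(integrated_death(ky2, mask2, baseline = 0.5)), W)

  lg <- mk_kymo(vals2, channel = "ratio_log10")
  expect_error(integrated_death(lg, mask2), "linear-ratio")
})

test_that("integrated death scales linearly with the dead channel", {
  sim <- tiny_movie_nf()
  scaled <- sim$stack
  scaled$frames_dead <- lapply(scaled$frames_dead, function(m) 3 * m)
  ps1 <- analyze_colony_movie(sim$stack)
  ps2 <- analyze_colony_movie(scaled)
  expect_equal(ps2$p1$integral / ps1$p1$integral, 3, tolerance = 0.01)
})

test_that("phase-window detection finds steps and ignores flat noise", {
  tt <- seq(8, 56, by = 0.5)
  clean <- ifelse(tt >= 30, 1, 0.02)
  w <- detect_phase_window(clean, tt)
  expect_true(w$detected)
  expect_equal(w$onset_h, 30)
  expect_equal(w$end_h, 56)

  withr::with_seed(42, {
    hits <- vapply(1:20, function(i) {
      flat <- rnorm(length(tt), 1, 0.01)
      detect_phase_window(flat, tt)$detected
    }, NA)
    expect_lte(mean(hits), 0.1)
  })

  # sentinel shape when nothing exceeds the threshold
  none <- detect_phase_window(rep(c(1, 1.0001), 20), seq_len(40))
  expect_false(none$detected)
  expect_true(is.na(none$onset_h))
  expect_error(detect_phase_window(c(1, 2), c(1, 2), m = 3), "m frames")
})

test_that("phase ratio handles equality, absence and bad input", {
  expect_equal(p1_p2_ratio(2, 2), 1)
  expect_equal(p1_p2_ratio(5, 0.5), 10)
  expect_identical(p1_p2_ratio(3, 0), Inf)
  expect_identical(p1_p2_ratio(3, 0.01), Inf)  # below the relative floor
  expect_error(p1_p2_ratio(-1, 2), ">= 0")
})

test_that("wave-front speeds recover constructed moving fronts within 5%", {
  # synthetic ratio kymograph with two Gaussian fronts r(t) = r0 +/- v t
  nb <- 120; times <- seq(44, 56, by = 0.5)
  rc <- (seq_len(nb) - 0.5) * 0.02
  v_out <- 0.05; v_in <- 0.03; r0 <- 1.1
  vals <- sapply(times, function(t) {
    ro <- r0 + v_out * (t - 44); ri <- r0 - v_in * (t - 44)
    0.1 + 1.0 * (exp(-(rc - ro)^2 / (2 * 0.04^2)) + exp(-(rc - ri)^2 / (2 * 0.04^2)))
  })
  ky <- mk_kymo(vals, times = times, bw_mm = 0.02,
                radius = rep(2.4, length(times)))
  fr <- track_wave_front(ky, t_from = 44, level = 0.5, band = c(0.1, 0.95))
  expect_lt(abs(fr$outward_speed_mm_h - v_out), 0.05 * v_out + 0.003)
  expect_lt(abs(fr$inward_speed_mm_h - (-v_in)), 0.05 * v_in + 0.003)

  # stationary band: both speeds ~ 0
  vals2 <- sapply(times, function(t) 0.1 + exp(-(rc - r0)^2 / (2 * 0.05^2)))
  ky2 <- mk_kymo(vals2, times = times, bw_mm = 0.02,
                 radius = rep(2.4, length(times)))
  fr2 <- track_wave_front(ky2, t_from = 44, level = 0.5, band = c(0.1, 0.95))
  expect_lt(abs(fr2$outward_speed_mm_h), 0.004)
  expect_lt(abs(fr2$inward_speed_mm_h), 0.004)
})

test_that("Welch comparison matches the closed-form computation", {
  a <- c(1, 2, 3); b <- c(11, 12, 13)
  cmp <- compare_strains(a, b)
  # hand computation: means 2 and 12, each variance 1, n = 3
  # t = (2 - 12) / sqrt(1/3 + 1/3) = -12.247449, df = 4
  expect_equal(cmp$t_statistic, -10 / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(cmp$df, 4, tolerance = 1e-9)
  expect_equal(cmp$p_value, 2 * pt(-abs(-10 / sqrt(2 / 3)), 4), tolerance = 1e-12)
  expect_equal(cmp$fold_change, 2 / 12)
  expect_equal(cmp$group_a$sem, sd(a) / sqrt(3))

  same <- compare_strains(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$fold_change, 1)
  expect_equal(same$p_value, 1)

  degen <- compare_strains(c(2, 2), c(2, 2))
  expect_equal(degen$p_value, 1)
  expect_error(compare_strains(1, c(1, 2)), "two replicates")
})

test_that("significance stars follow the published thresholds", {
  expect_equal(significance_stars(0.2), "")
  expect_equal(significance_stars(0.03), "*")
  expect_equal(significance_stars(0.009), "**")
  expect_equal(significance_stars(0.004), "***")
  expect_equal(significance_stars(0.0004), "****")
  expect_equal(compare_strains(c(1, 2, 3), c(11, 12, 13))$stars, "****")
})
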