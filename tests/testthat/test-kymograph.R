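test_that("iterative centroid finds symmetric and offset colonies", {
  d <- disk_image(101, 30) * 100
  expect_equal(locate_centroid(d), c(51, 51), tolerance = 0.1)

  # off-centre Gaussian blob: closed-form weighted centroid is its centre
  g <- outer(dnorm(seq_len(101), 37, 6), dnorm(seq_len(101), 63, 6))
  est <- locate_centroid(g, init = c(50, 50), support_radius_px = 30, tol_px = 0.1)
  expect_equal(est, c(37, 63), tolerance = 0.5)

  expect_error(locate_centroid(matrix(0, 10, 10)), "all-zero")
})

test_that("translation registration removes jumps but keeps slow drift", {
  base <- as.matrix(EBImage::gblur(disk_image(96, 25) * 100, 2))
  frames <- list(base, base, shift_matrix(base, 6, 0), shift_matrix(base, 6, 0))
  st <- movie_stack(frames, frames, 1:4, 0.01)
  reg <- register_translation_stack(st, jump_threshold_px = 3)
  expect_equal(reg$corrections[3, ], c(6, 0))
  resid <- estimate_translation(base, reg$stack$frames_live[[3]])
  expect_lt(max(abs(resid)), 0.5)

  # sub-threshold drift is left intact
  fr2 <- list(base, shift_matrix(base, 1, 0), shift_matrix(base, 2, 0))
  st2 <- movie_stack(fr2, fr2, 1:3, 0.01)
  reg2 <- register_translation_stack(st2, jump_threshold_px = 3)
  expect_true(all(reg2$corrections == 0))
  expect_identical(reg2$stack$frames_live[[3]], fr2[[3]])
})

test_that("colony radius detection matches a binary disk and rejects blanks", {
  d <- disk_image(101, 30) * 100
  r <- detect_colony_radius(d, c(51, 51), alpha = 0.5)
  expect_lt(abs(r - 30), 1.5)
  expect_equal(detect_colony_radius(d, c(51, 51), alpha = 0.5,
                                    pixel_size_mm = 0.01), r * 0.01)
  expect_error(detect_colony_radius(matrix(0, 20, 20), c(10, 10)), "all-zero")
  expect_error(detect_colony_radius(d, c(51, 51), alpha = 1.5), "alpha")
})

test_that("circumferential averaging equals the per-pixel loop oracle", {
  withr::with_seed(4, {
    # piecewise-constant radial field on a 64x64 grid
    ctr <- c(32.5, 32.5)
    g <- radial <- outer((seq_len(64) - ctr[1])^2, (seq_len(64) - ctr[2])^2, `+`)
    radial <- sqrt(radial)
    img <- ifelse(radial < 10, 5, ifelse(radial < 20, 2, 7)) + 0 * g
    w <- wedge(center_px = ctr)
    prof <- circumferential_average(img, w, n_bins = 28)
    oracle <- oracle_circumferential(img, ctr, 0, 2 * pi, 1, 28)
    expect_equal(as.numeric(prof), oracle)
    # interior bins reproduce the radial field exactly
    expect_equal(as.numeric(prof[3:8]), rep(5, 6))
    expect_equal(as.numeric(prof[13:18]), rep(2, 6))

    # narrow wedge against the loop oracle
    w2 <- wedge(0.4, 1.5, center_px = ctr)
    img2 <- matrix(runif(64 * 64), 64)
    prof2 <- circumferential_average(img2, w2, n_bins = 25)
    oracle2 <- oracle_circumferential(img2, ctr, 0.4, 1.5, 1, 25)
    filled <- which(!is.na(oracle2))
    expect_equal(as.numeric(prof2[filled]), oracle2[filled])

    # reflex wedge (> pi) as well
    w3 <- wedge(2.5, 1.2, center_px = ctr)
    prof3 <- circumferential_average(img2, w3, n_bins = 25)
    oracle3 <- oracle_circumferential(img2, ctr, 2.5, 1.2, 1, 25)
    filled3 <- which(!is.na(oracle3))
    expect_equal(as.numeric(prof3[filled3]), oracle3[filled3])
  })
})

test_that("quadrant-dependent images average to the selected quadrant only", {
  ctr <- c(32.5, 32.5)
  g <- radial_grids(64, 64, ctr)
  img <- matrix(1, 64, 64)
  q1 <- angle_in_interval(g$theta, 0, pi / 2)
  img[q1] <- 9
  prof <- circumferential_average(img, wedge(0.1, pi / 2 - 0.1, center_px = ctr),
                                  n_bins = 25)
  expect_equal(as.numeric(prof[5:25]), rep(9, 21))
})

test_that("wedge averages combine across disjoint wedges by pixel counts", {
  img <- matrix(runif(64 * 64), 64)
  ctr <- c(32.5, 32.5)
  wa <- wedge(0, 1, center_px = ctr); wb <- wedge(1, 2, center_px = ctr)
  wu <- wedge(0, 2, center_px = ctr)
  pa <- circumferential_average(img, wa, n_bins = 25)
  pb <- circumferential_average(img, wb, n_bins = 25)
  pu <- circumferential_average(img, wu, n_bins = 25)
  ca <- attr(pa, "counts"); cb <- attr(pb, "counts")
  comb <- (pa * ca + pb * cb) / (ca + cb)
  ok <- ca + cb > 0 & ca > 0 & cb > 0
  expect_equal(as.numeric(comb[ok]), as.numeric(pu[ok]), tolerance = 1e-12)
})

test_that("kymographs equal column-wise circumferential averages", {
  sim <- tiny_movie_nf()
  st <- sim$stack
  tr <- track_centroids(st)
  ky <- build_kymographs(st, wedge(0.3, 0.8), tracking = tr)
  for (k in c(5, 30)) {
    wk <- wedge(0.3, 0.8, center_px = tr$centers[k, ])
    prof <- circumferential_average(st$frames_dead[[k]], wk,
                                    n_bins = nrow(ky$dead$values))
    keep <- which((seq_len(nrow(ky$dead$values)) - 0.5) <= tr$radius_px[k] - 2)
    expect_equal(ky$dead$values[keep, k], as.numeric(prof)[keep])
  }
  expect_equal(ncol(ky$live$values), n_frames(st))
  expect_true(all(diff(ky$live$bin_edges_mm) > 0))
})

test_that("full-circle kymographs are invariant to 90-degree rotation", {
  sim <- tiny_movie_nf()
  st <- sim$stack
  rot <- st
  rot$frames_live <- lapply(st$frames_live, function(m) t(m)[ncol(m):1, ])
  rot$frames_dead <- lapply(st$frames_dead, function(m) t(m)[ncol(m):1, ])
  k1 <- build_kymographs(st)
  k2 <- build_kymographs(rot)
  v1 <- k1$dead$values; v2 <- k2$dead$values
  ok <- is.finite(v1) & is.finite(v2)
  rms <- sqrt(mean((v1[ok] - v2[ok])^2)) / mean(v1[ok])
  expect_lt(rms, 0.01)
})

test_that("centroid tracking follows the true drifting centre", {
  sim <- tiny_movie()
  tr <- track_centroids(sim$stack)
  err <- tr$centers - sim$truth$center_px
  expect_lt(max(abs(err)), 0.5)
})

test_that("detected radius matches the ground truth within one bin", {
  sim <- tiny_movie()
  tr <- track_centroids(sim$stack)
  err <- tr$radius_px - sim$truth$colony_radius_mm / sim$stack$pixel_size_mm
  expect_lt(max(abs(err)), 1 + 1e-9)
})

test_that("ratio kymographs follow element-wise division with the floor", {
  v <- matrix(runif(25, 1, 2), 5)
  mk <- function(vals, ch) colonykym:::new_kymograph(
    vals, seq(0, 5) * 0.01, 1:5, ch, wedge(), 0.01, radius_mm = rep(0.05, 5))
  live <- mk(v, "live"); dead <- mk(2 * v, "dead")
  lin <- ratio_kymograph(dead, live, floor = 0.5)
  expect_equal(lin$values, (2 * v) / pmax(v, 0.5))
  expect_equal(lin$channel, "ratio_linear")
  lg <- ratio_kymograph(mk(10 * v, "dead"), live, log10 = TRUE, floor = 0.5)
  expect_equal(lg$values, matrix(1, 5, 5), tolerance = 1e-9)
  same <- ratio_kymograph(mk(v, "dead"), live, floor = 0.5)
  expect_equal(same$values, matrix(1, 5, 5))
  bad <- mk(v, "dead"); bad$frame_times_h <- 2:6
  expect_error(ratio_kymograph(bad, live), "axes")
})

test_that("kymograph CSV export round-trips shape and axes", {
  sim <- tiny_movie_nf()
  ky <- build_kymographs(sim$stack, wedge(0, pi / 3))
  f <- withr::local_tempfile(fileext = ".csv")
  write_kymograph_csv(ky$dead, f)
  back <- utils::read.csv(f, check.names = FALSE)
  expect_equal(nrow(back), nrow(ky$dead$values))
  expect_equal(ncol(back), ncol(ky$dead$values) + 2)
})
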