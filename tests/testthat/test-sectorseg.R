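test_that("feature stack behaves on degenerate and analytic inputs", {
  const <- matrix(4, 24, 24)
  st <- compute_feature_stack(const, scales = c(1, 2))
  expect_equal(st[, , "gauss_s1"], const, tolerance = 1e-6)
  expect_true(max(abs(st[, , "gradmag_s2"])) < 1e-6)
  expect_true(max(abs(st[, , "laplace_s1"])) < 1e-6)
  expect_true(max(abs(st[10:15, 10:15, "var_s2"])) < 1e-4)

  # DoG is by definition blur(s) - blur(2s)
  img <- matrix(withr::with_seed(5, runif(40 * 40)), 40)
  st2 <- compute_feature_stack(img, scales = 2)
  g2 <- as.matrix(EBImage::gblur(img, 2)); g4 <- as.matrix(EBImage::gblur(img, 4))
  expect_equal(st2[, , "dog_s2"], g2 - g4)

  # gradient magnitude of a linear ramp is the constant slope
  ramp <- matrix(rep(seq_len(32) * 1.5, each = 32), 32, byrow = FALSE)
  st3 <- compute_feature_stack(ramp, scales = 1)
  interior <- st3[8:24, 8:24, "gradmag_s1"]
  expect_equal(as.numeric(interior), rep(1.5, length(interior)), tolerance = 0.02)

  expect_error(compute_feature_stack(img, scales = c(1, -2)), "positive")
  expect_error(compute_feature_stack(img, scales = numeric()), "non-empty")
})

test_that("Renyi entropy threshold matches exhaustive per-order search", {
  withr::with_seed(11, {
    img <- matrix(c(rnorm(600, 60, 12), rnorm(424, 190, 18)), 32)
    img <- pmin(pmax(img, 0), 255)
    thr <- renyi_entropy_threshold(img)
    per <- attr(thr, "per_order")
    v <- as.numeric(img); lo <- min(v); hi <- max(v)
    bin <- pmin(floor((v - lo) / (hi - lo) * 256), 255)
    p <- tabulate(bin + 1, 256) / length(v)
    expect_equal(unname(per["alpha_0.5"]), oracle_renyi_order(p, 0.5))
    expect_equal(unname(per["alpha_1"]), oracle_renyi_order(p, 1))   # Kapur
    expect_equal(unname(per["alpha_2"]), oracle_renyi_order(p, 2))
    # combined threshold separates the two modes
    expect_gt(thr, 60); expect_lt(thr, 190)
  })
  # two-delta histogram: threshold strictly between the spikes
  img2 <- matrix(c(rep(10, 500), rep(200, 500)), 25)
  t2 <- renyi_entropy_threshold(img2)
  expect_gt(t2, 10); expect_lt(t2, 200)
  expect_error(renyi_entropy_threshold(matrix(3, 5, 5)), "constant")
})

test_that("threshold always lies strictly inside the intensity range", {
  withr::with_seed(12, {
    for (i in 1:5) {
      img <- matrix(sample(0:255, 400, replace = TRUE, prob = runif(256)), 20)
      if (min(img) == max(img)) next
      thr <- as.numeric(renyi_entropy_threshold(img))
      expect_gt(thr, min(img)); expect_lt(thr, max(img))
    }
  })
})

test_that("pixel classifier separates texture classes and is deterministic", {
  withr::with_seed(21, {
    smooth <- as.matrix(EBImage::gblur(matrix(runif(64 * 64), 64), 4)) * 10 + 5
    speckle <- matrix(rpois(64 * 64, 8), 64)
    img <- cbind(smooth, speckle)
    lab <- cbind(matrix(1L, 64, 64), matrix(2L, 64, 64))
    # train on 500 px per class
    keep <- matrix(0L, 64, 128)
    idx1 <- sample(which(lab == 1), 500); idx2 <- sample(which(lab == 2), 500)
    keep[idx1] <- 1L; keep[idx2] <- 2L
    clf <- train_pixel_classifier(list(img), list(keep), n_trees = 60, seed = 2,
                                  scales = c(1, 2, 4))
    expect_gte(clf$oob_accuracy, 0.95)

    pr <- predict_probability(clf, img)
    expect_true(all(pr >= 0 & pr <= 1))
    # resubstitution: argmax reproduces >= 99% of the labeled pixels
    hard <- (pr < 0.5) + 1L
    acc <- mean(hard[keep > 0] == keep[keep > 0])
    expect_gte(acc, 0.99)

    # determinism
    clf2 <- train_pixel_classifier(list(img), list(keep), n_trees = 60, seed = 2,
                                   scales = c(1, 2, 4))
    expect_equal(predict_probability(clf2, img), pr)

    # constant image -> spatially constant probability
    pc <- predict_probability(clf, matrix(5, 32, 32))
    expect_equal(max(pc) - min(pc), 0)

    expect_error(train_pixel_classifier(list(img), list((keep > 0) * 1L)),
                 "both classes")
    clf3 <- clf; clf3$scales <- c(1, 2)
    expect_error(predict_probability(clf3, img), "scales")
  })
})

test_that("ROI extraction matches flood-fill areas and applies filters", {
  binary <- matrix(FALSE, 40, 40)
  binary[3:8, 3:8] <- TRUE            # 36 px
  binary[15:34, 10:24] <- TRUE        # 300 px
  binary[39, 39] <- TRUE              # 1 px
  colony <- matrix(TRUE, 40, 40)
  rois <- extract_sector_rois(binary, min_area_px = 100, colony)
  expect_equal(sort(rois$rois$area_px), oracle_component_areas(binary))
  expect_equal(sum(rois$rois$kept), 1)
  expect_equal(rois$rois$area_px[rois$rois$kept], 300)

  # 8-connectivity: a diagonal chain is one component
  diagb <- matrix(FALSE, 10, 10); for (i in 1:6) diagb[i, i] <- TRUE
  r2 <- extract_sector_rois(diagb, 1, matrix(TRUE, 10, 10))
  expect_equal(nrow(r2$rois), 1)
  expect_equal(r2$rois$area_px, 6)

  # empty input is valid; colony mask restricts components
  r3 <- extract_sector_rois(matrix(FALSE, 5, 5), 1, matrix(TRUE, 5, 5))
  expect_equal(nrow(r3$rois), 0)
  colony2 <- matrix(TRUE, 40, 40); colony2[, 1:9] <- FALSE
  r4 <- extract_sector_rois(binary, 10, colony2)
  expect_equal(max(r4$rois$area_px), 300)
  expect_false(36 %in% r4$rois$area_px)

  # probability filter rejects low-confidence components
  prob <- matrix(0.1, 40, 40); prob[15:34, 10:24] <- 0.9
  r5 <- extract_sector_rois(binary, 10, colony, prob_image = prob,
                            min_mean_prob = 0.5)
  expect_equal(r5$rois$area_px[r5$rois$kept], 300)
  # curation drop-list
  keep_id <- r5$rois$id[r5$rois$kept]
  r6 <- extract_sector_rois(binary, 10, colony, prob_image = prob,
                            drop_ids = keep_id)
  expect_equal(sum(r6$rois$kept), 0)
})

test_that("sector area fraction is a ratio with additive structure", {
  colony <- disk_image(60, 25) > 0
  half <- colony & (row(colony) <= 30)
  rois <- extract_sector_rois(half, 1, colony)
  expect_equal(sector_area_fraction(rois, colony), sum(half) / sum(colony))
  expect_equal(sector_area_fraction(extract_sector_rois(matrix(FALSE, 60, 60), 1, colony),
                                    colony), 0)
  # additivity over disjoint ROI sets
  q1 <- colony & (row(colony) <= 30) & (col(colony) <= 30)
  q2 <- colony & (row(colony) > 30) & (col(colony) > 30)
  f1 <- sector_area_fraction(extract_sector_rois(q1, 1, colony), colony)
  f2 <- sector_area_fraction(extract_sector_rois(q2, 1, colony), colony)
  fu <- sector_area_fraction(extract_sector_rois(q1 | q2, 1, colony), colony)
  expect_equal(fu, f1 + f2)
  expect_error(sector_area_fraction(rois, matrix(FALSE, 60, 60)), "empty")
})

test_that("sector-free wedge selection avoids the high-probability wedge", {
  n <- 101; ctr <- c(51, 51)
  # zero probability everywhere: first wedge wins the tie-break
  w0 <- select_sector_free_wedge(matrix(0, n, n), ctr, 30)
  expect_equal(w0$theta_min, 0)
  expect_true(w0$sector_free)

  # one hot wedge: the selected wedge must not overlap it
  g <- radial_grids(n, n, ctr)
  hot <- angle_in_interval(g$theta, 0.5, 1.5) & g$r <= 45
  prob <- matrix(0, n, n); prob[hot] <- 1
  ws <- select_sector_free_wedge(prob, ctr, 45, mask = g$r <= 45)
  mid <- seq(ws$theta_min, ws$theta_min + 45 * pi / 180, length.out = 20)
  overlap <- any(((mid - 0.5) %% (2 * pi)) <= 1.0)
  expect_false(overlap)
  expect_lt(attr(ws, "mean_probability"), 0.01)

  expect_error(select_sector_free_wedge(matrix(1, n, n), ctr, 30, max_mean = 0.5),
               "manual wedge")
  expect_error(select_sector_free_wedge(matrix(0, n, n), ctr, 0), "wedge_width")
})

test_that("automatic wedge avoids true sectors on generated movies", {
  for (s in 0:2) {
    sim <- generate_movie(tiny_preset(), seed = s)
    reg <- register_translation_stack(sim$stack, downsample = 2)$stack
    proj <- max_time_projection(reg, "dead", c(8, 38))
    stained <- colony_mask_from_image(proj$image, 0.25)
    prob <- colonykym:::sector_probability_proxy(proj$image, stained)
    ctr <- sim$truth$center_px[n_frames(sim$stack), ]
    wd <- select_sector_free_wedge(prob, ctr, 30, mask = stained)
    # wedge must not intersect any true sector interval
    sec <- sim$truth$sectors
    th <- seq(wd$theta_min + 0.02, wd$theta_min + 30 * pi / 180 - 0.02,
              length.out = 30)
    for (i in seq_len(nrow(sec))) {
      w_sec <- (sec$theta2[i] - sec$theta1[i]) %% (2 * pi)
      expect_false(any(((th - sec$theta1[i]) %% (2 * pi)) <= w_sec),
                   info = sprintf("seed %d sector %d", s, i))
    }
  }
})
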