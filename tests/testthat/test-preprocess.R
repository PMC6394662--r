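test_that("channel selection takes the highest-standard-deviation channel", {
  # blue-stained colonies on a light dish: green carries the most contrast
  img <- make_flat_plate(64, 64, bg_rgb = c(232, 230, 235),
                         colony_rgb = c(120, 40, 180),
                         centers = rbind(c(20, 20), c(44, 40)),
                         radii = c(6, 7))
  expect_equal(attr(select_channel(img), "channel_origin"), "G")

  # identical channels: tie broken toward R
  flat <- make_flat_plate(16, 16, bg_rgb = c(90, 90, 90), colony_rgb = c(90, 90, 90))
  expect_equal(attr(select_channel(flat), "channel_origin"), "R")

  # constructed per-channel standard deviations; oracle is sd() itself
  set.seed(1)
  px <- array(0, dim = c(32, 32, 3))
  px[, , 1] <- pmin(pmax(round(rnorm(1024, 128, 5)), 0), 255)
  px[, , 2] <- pmin(pmax(round(rnorm(1024, 128, 40)), 0), 255)
  px[, , 3] <- pmin(pmax(round(rnorm(1024, 128, 12)), 0), 255)
  sds <- apply(px, 3, sd)
  expect_equal(which.max(sds), 2L)
  expect_equal(attr(select_channel(plate_image(px)), "channel_origin"), "G")
})

test_that("calibration polynomials match their printed constants", {
  expect_identical(default_sigma(0), 1.3)
  expect_equal(default_sigma(600), 1.9e-6 * 600^2 + 6.3e-4 * 600 + 1.3)
  expect_equal(default_sigma(600), 2.362, tolerance = 1e-9)
  expect_equal(default_sigma(1200), 4.792, tolerance = 1e-9)
  expect_error(default_sigma(-1), class = "colonysizer_validation_error")

  expect_identical(default_rolling_radius(1000), 25L)
  expect_identical(default_rolling_radius(600), 15L)
  expect_identical(default_rolling_radius(10), 1L)  # clamped to >= 1
  expect_error(default_rolling_radius(0), class = "colonysizer_validation_error")

  # monotone in resolution
  grid <- seq(50, 2400, by = 50)
  expect_true(all(diff(vapply(grid, default_sigma, numeric(1))) > 0))
})

test_that("gaussian blur is an identity at sigma 0 and on constants", {
  set.seed(7)
  img <- matrix(runif(40 * 30, 0, 255), 40, 30)
  expect_identical(gaussian_blur(img, 0), img)
  const <- matrix(42, 25, 25)
  expect_equal(gaussian_blur(const, 3), const, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("blurring an impulse reproduces the discrete kernel centre weight", {
  sigma <- 2
  n <- 41
  img <- matrix(0, n, n)
  img[21, 21] <- 1
  out <- gaussian_blur(img, sigma)
  r <- ceiling(3.5 * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  expect_equal(out[21, 21], k[r + 1]^2, tolerance = 1e-12)
  # and the full response is the separable outer product
  expect_equal(out[(21 - r):(21 + r), (21 - r):(21 + r)], outer(k, k),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("gaussian blur conserves total intensity with reflective borders", {
  set.seed(11)
  for (sigma in c(0.8, 2, 5)) {
    img <- matrix(runif(50 * 37, 0, 255), 50, 37)
    out <- gaussian_blur(img, sigma)
    expect_lt(abs(sum(out) - sum(img)) / sum(img), 1e-6)
  }
})

test_that("rolling-ball subtraction flattens backgrounds and keeps colonies", {
  # flat image: background fully removed
  expect_true(all(subtract_background(matrix(57, 30, 30), 5) == 0))

  # gentle gradient + small bright disc, checked against a brute-force
  # grayscale opening oracle
  h <- 50; w <- 50; radius <- 8
  gradient <- matrix(rep(seq(0, 10, length.out = w), each = h), h, w)
  disk <- make_disk_mask(h, w, c(25, 25), 3) * 100
  img <- gradient + disk
  out <- subtract_background(img, radius)
  oracle <- img - brute_opening(img, radius)
  expect_lt(max(abs(out - oracle)), 3)           # brush rasterisation slack
  expect_gt(max(out), 90)                        # disc amplitude kept (>90%)
  expect_lt(max(out[disk == 0]), 0.05 * 10 + 3)  # off-disc residual small

  # an object wider than the ball is swallowed into the background
  # estimate: its peak is visibly reduced (the under-sized-ball failure mode)
  big <- make_disk_mask(60, 60, c(30, 30), 12) * 100
  out_big <- subtract_background(big, 4)
  expect_lt(out_big[30, 30], big[30, 30])
  expect_lt(out_big[30, 30], 10)

  # bounds: 0 <= output <= input
  set.seed(3)
  noisy <- matrix(runif(40 * 40, 0, 255), 40, 40)
  out_n <- subtract_background(noisy, 6)
  expect_true(all(out_n >= 0) && all(out_n <= noisy + 1e-9))
})

test_that("thresholding separates modes and the auto cut lands between them", {
  expect_true(all(binarize(matrix(0, 10, 10), 10) == 0L))

  img <- matrix(c(0, 255), 20, 20)
  m <- binarize(img, 128)
  expect_identical(matrix(as.integer(m), 20, 20),
                   matrix(as.integer(img == 255), 20, 20))

  # bimodal image, equal weights at 30 and 200: hand-run intermeans
  bi <- matrix(rep(c(30, 200), each = 200), 20, 20)
  t_hand <- mean(bi)
  repeat {
    t_new <- (mean(bi[bi <= t_hand]) + mean(bi[bi > t_hand])) / 2
    if (abs(t_new - t_hand) < 0.5) break
    t_hand <- t_new
  }
  m_auto <- binarize(bi, "auto")
  thr <- attr(m_auto, "threshold")
  expect_equal(thr, t_hand, tolerance = 0.5)
  expect_gt(thr, 30); expect_lt(thr, 200)
  expect_identical(matrix(as.integer(m_auto), 20, 20),
                   matrix(as.integer(bi == 200), 20, 20))
})

test_that("raising the threshold never adds foreground", {
  set.seed(5)
  img <- matrix(runif(30 * 30, 0, 255), 30, 30)
  cuts <- sort(runif(6, 0, 255))
  masks <- lapply(cuts, function(t) binarize(img, t))
  for (i in seq_len(length(cuts) - 1)) {
    expect_true(all(masks[[i + 1]] <= masks[[i]]))
  }
})

test_that("ROI masking clears the rim and leaves the interior untouched", {
  h <- 400; w <- 400
  full <- matrix(1L, h, w)
  out0 <- apply_roi(full, roi_margin = 0)
  dist2 <- (row(full) - 200.5)^2 + (col(full) - 200.5)^2
  expect_identical(matrix(as.integer(out0), h, w),
                   matrix(as.integer(dist2 <= 200^2), h, w))

  # blob centred on the dish rim (radius 200) disappears with a 5% margin
  rim_blob <- make_disk_mask(h, w, c(200.5 + 199, 200.5), 4)
  expect_true(all(apply_roi(rim_blob, roi_margin = 0.05) == 0L))

  # mask well inside half the dish radius is unchanged at a 20% margin
  inner <- make_disk_mask(h, w, c(230, 180), 25)
  expect_identical(matrix(as.integer(apply_roi(inner, roi_margin = 0.2)), h, w),
                   matrix(as.integer(inner), h, w))

  # subset property
  set.seed(9)
  rand <- matrix(rbinom(h * w, 1, 0.3), h, w)
  out <- apply_roi(rand, roi_margin = 0.1)
  expect_true(all(out <= rand))
})

test_that("polarity normalisation inverts dark-colony channels only", {
  dark_on_light <- matrix(230, 40, 40)
  dark_on_light[15:20, 15:20] <- 60
  res <- normalize_polarity(dark_on_light)
  expect_true(res$inverted)
  expect_equal(res$pixels[1, 1], 25)

  light_on_dark <- 255 - dark_on_light
  res2 <- normalize_polarity(light_on_dark)
  expect_false(res2$inverted)
  expect_equal(res2$pixels[1, 1], 25)
})

test_that("pipeline parameters validate their ranges", {
  expect_error(pipeline_params(sigma = -1), class = "colonysizer_validation_error")
  expect_error(pipeline_params(roi_margin = 1), class = "colonysizer_validation_error")
  expect_error(pipeline_params(circ_min = 0.9, circ_max = 0.5),
               class = "colonysizer_validation_error")
  expect_error(pipeline_params(min_area = 50, max_area = 10),
               class = "colonysizer_validation_error")
  p <- resolve_pipeline_params(pipeline_params(), dpi = 800)
  expect_equal(p$sigma, default_sigma(800))
  expect_equal(p$rolling_radius, default_rolling_radius(800))
  expect_equal(p$min_area, 20 * (800 / 600)^2)
  expect_warning(resolve_pipeline_params(pipeline_params(), dpi = NA),
                 "600 DPI")
})
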