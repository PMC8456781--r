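# Image normalization, profile extraction and prominence-based spot counting.

test_that("normalize_image maps background to 0 and in-mask max to 65535", {
  set.seed(2)
  img <- matrix(100, 40, 40)             # flat background floor
  img[15:25, 15:25] <- sample(2000:30000, 121)
  img[20, 20] <- 30000                   # in-mask maximum
  mask <- matrix(FALSE, 40, 40)
  mask[15:25, 15:25] <- TRUE

  out <- normalize_image(img, mask)
  expect_identical(out, {
    o <- pmin(pmax(round((img - 100) * 65535 / (30000 - 100)), 0), 65535)
    storage.mode(o) <- "integer"
    o
  })
  expect_equal(max(out[mask]), 65535)

  # identity: already spanning the full range over zero background
  img2 <- matrix(0, 20, 20)
  img2[10, 10] <- 65535
  mask2 <- matrix(FALSE, 20, 20); mask2[8:12, 8:12] <- TRUE
  expect_equal(unname(normalize_image(img2, mask2)[10, 10]), 65535)
  expect_true(all(normalize_image(img2, mask2) == img2))

  # scale invariance: halving every intensity does not change the output
  expect_identical(normalize_image(img / 2, mask), normalize_image(img, mask))

  expect_error(normalize_image(matrix(5, 4, 4), matrix(TRUE, 4, 4)),
               "undefined scale")
  expect_error(normalize_image(img, mask[1:10, 1:10]), "shape")
})

test_that("extract_profile reproduces raw pixels on axis-aligned lines", {
  set.seed(3)
  img <- matrix(sample(0:1000, 50 * 50, replace = TRUE), 50, 50)
  # constant image: every sample equals the constant
  flat <- matrix(777, 50, 50)
  p <- extract_profile(flat, cbind(c(5, 30), c(10, 10)), 0.1)
  expect_true(all(p$intensities == 777))
  # horizontal polyline on an integer pixel row samples raw values
  p2 <- extract_profile(img, cbind(c(5, 30), c(10, 10)), 0.1)
  expect_equal(p2$intensities, img[11, 6:31])
  expect_equal(p2$arc_positions, (0:25) * 0.1)
})

test_that("extract_profile matches analytic bilinear values on a gradient", {
  # linear image I(x, y) = 3x + 7y: bilinear interpolation is exact
  xg <- matrix(rep(0:39, each = 40), 40)
  yg <- matrix(rep(0:39, times = 40), 40)
  img <- 3 * xg + 7 * yg
  pl <- cbind(c(2.3, 30.7), c(4.1, 28.9))
  p <- extract_profile(img, pl, 0.05)
  total <- sqrt(sum((pl[2, ] - pl[1, ])^2))
  s <- seq(0, total, length.out = length(p$intensities))
  u <- (pl[2, ] - pl[1, ]) / total
  expected <- 3 * (pl[1, 1] + s * u[1]) + 7 * (pl[1, 2] + s * u[2])
  expect_equal(p$intensities, round(expected), tolerance = 1e-12)
})

test_that("extract_profile is equivariant to joint translation", {
  set.seed(4)
  img <- matrix(sample(0:500, 60 * 60, replace = TRUE), 60, 60)
  big <- matrix(0L, 70, 70)
  big[6:65, 9:68] <- img  # translate by (dx = 8, dy = 5)
  pl <- cbind(c(10.5, 40.2), c(20.1, 35.8))
  pl_t <- pl + matrix(rep(c(8, 5), each = 2), ncol = 2)
  p1 <- extract_profile(img, pl, 0.1)
  p2 <- extract_profile(big, pl_t, 0.1)
  expect_equal(p1$intensities, p2$intensities)
  expect_error(extract_profile(img, cbind(c(1, 1.5), c(1, 1)), 0.1), "arc length")
})

test_that("find_maxima matches the exhaustive flood-fill oracle", {
  # ridge case: two maxima joined by a saddle shallower than the prominence
  img <- matrix(0, 9, 9)
  img[3, 3] <- 1000
  img[3, 7] <- 900
  img[3, 4:6] <- 850   # saddle dips by 50 < prominence
  expect_equal(nrow(find_maxima(img, 100)), 1)
  expect_equal(oracle_find_maxima_count(img, 100), 1)
  img[3, 4:6] <- 500   # saddle dips by 400 >= prominence
  expect_equal(nrow(find_maxima(img, 100)), 2)
  expect_equal(oracle_find_maxima_count(img, 100), 2)

  # randomized property check on small integer images
  set.seed(5)
  for (i in 1:25) {
    im <- matrix(sample(0:12, 64, replace = TRUE), 8, 8)
    prom <- sample(1:6, 1)
    expect_equal(nrow(find_maxima(im, prom)),
                 oracle_find_maxima_count(im, prom),
                 info = sprintf("case %d prom %d", i, prom))
  }
})

test_that("spot counting masks intracellular spots and validates inputs", {
  h <- 64; w <- 64
  cell <- gaussian_spot_image(h, w, data.frame(x = 32, y = 32, amplitude = 0), 1)
  factin <- matrix(0, h, w)
  factin[20:45, 20:45] <- 30000  # square "cell"
  outside <- data.frame(x = c(8, 55, 10), y = c(8, 10, 55),
                        amplitude = 20000)
  inside <- data.frame(x = c(30, 40), y = c(30, 35), amplitude = 20000)
  img <- gaussian_spot_image(h, w, rbind(outside, inside), 1.5)

  n <- count_myo10_spots(img, factin, prominence = 2000)
  expect_equal(as.integer(n), 3)

  # adding a spot inside the mask leaves the count unchanged
  img2 <- img + gaussian_spot_image(h, w, data.frame(x = 25, y = 40,
                                                     amplitude = 20000), 1.5)
  expect_equal(as.integer(count_myo10_spots(img2, factin, prominence = 2000)), 3)

  # adding an isolated supra-prominence spot outside increases it by one
  img3 <- img + gaussian_spot_image(h, w, data.frame(x = 55, y = 55,
                                                     amplitude = 20000), 1.5)
  expect_equal(as.integer(count_myo10_spots(img3, factin, prominence = 2000)), 4)

  # blank MYO10 channel gives zero spots, not an error
  expect_equal(as.integer(count_myo10_spots(matrix(0, h, w), factin,
                                            prominence = 2000)), 0)
  # but an empty cell mask is an error distinct from zero
  expect_error(count_myo10_spots(img, matrix(0, h, w), prominence = 2000,
                                 mask_threshold = 100), "empty cell mask")
  expect_error(count_myo10_spots(img, factin[1:10, ], prominence = 2000),
               "shape")
})

test_that("background subtraction flattens a smooth gradient", {
  xg <- matrix(rep(0:63, each = 64), 64)
  bg <- 2000 + 30 * xg
  spots <- gaussian_spot_image(64, 64, data.frame(x = 20, y = 20,
                                                  amplitude = 10000), 1.5)
  out <- subtract_background(bg + spots, radius = 10)
  # the gradient is largely removed; the spot survives
  expect_lt(median(out), 500)
  expect_gt(max(out), 8000)
})
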