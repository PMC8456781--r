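# 40-bin reduction, map averaging, enrichment and tip positivity.

rec_of <- function(x, pixel_size = 0.08, id = "f", ch = "c") {
  profile_record(x, (seq_along(x) - 1) * pixel_size, pixel_size,
                 filopodium_id = id, channel = ch)
}

test_that("bin_profile obeys its assignment rule", {
  # identity for a 40-sample profile
  x <- sample(0:65535, 40)
  expect_identical(bin_profile(rec_of(x))$bin_values, as.numeric(x))

  # 80 samples: bin k is the median of samples (2k-1, 2k)
  y <- sample(0:65535, 80)
  b <- bin_profile(rec_of(y))
  expect_equal(b$bin_values,
               vapply(1:40, function(k) median(y[c(2 * k - 1, 2 * k)]),
                      numeric(1)))
  expect_false(b$upsampled)

  # constant profiles of any length give constant bins
  for (n in c(7, 40, 101)) {
    expect_true(all(bin_profile(rec_of(rep(123, n)))$bin_values == 123))
  }

  # random lengths against the brute-force oracle
  set.seed(6)
  for (n in c(41, 55, 160, 397)) {
    z <- sample(0:65535, n, replace = TRUE)
    expect_equal(bin_profile(rec_of(z))$bin_values, oracle_bin(z),
                 info = paste("n =", n))
  }

  # short profiles are upsampled and flagged, still 40 bins
  short <- bin_profile(rec_of(c(10, 20, 30)))
  expect_length(short$bin_values, 40)
  expect_true(short$upsampled)
  expect_true(all(short$bin_values %in% c(10, 20, 30)))
  expect_identical(short$bin_values[1], 10)
  expect_identical(short$bin_values[40], 30)

  expect_error(bin_profile(rec_of(1:40), n_bins = 0), "n_bins")
})

test_that("build_map averages binned profiles per group", {
  a <- bin_profile(rec_of(rep(100, 40), ch = "g1"))
  b <- bin_profile(rec_of(rep(300, 40), ch = "g1"))
  m1 <- build_map(list(a))
  expect_equal(m1$mean, a$bin_values)
  expect_equal(unique(m1$n), 1)
  m2 <- build_map(list(a, b))
  expect_true(all(m2$mean == 200))
  expect_equal(unique(m2$n), 2)
  expect_error(build_map(list()), "no profiles")
  expect_error(build_map(list(a, b), group_by = "x"), "one label per profile")
  mm <- map_matrix(m2)
  expect_equal(dim(mm), c(1L, 40L))
})

test_that("averaged maps of tip-enriched scenes decay from tip to base", {
  law <- channel_law("tip", "tip_exponential", amplitude = 30000,
                     decay_length = 1, body_fraction = 0)
  cfg <- scene_config(image_size = c(256L, 256L), pixel_size = 0.08,
                      cell_radius = 2, filopodium_length_range = c(3, 6),
                      n_filopodia = 25, channel_models = list(law),
                      noise = list(poisson_scale = 2, read_sd = 30), seed = 21)
  sc <- make_scene(cfg)
  binned <- lapply(seq_along(sc$polylines), function(i) {
    bin_profile(extract_profile(sc$images[["tip"]], sc$polylines[[i]],
                                cfg$pixel_size, channel = "tip"))
  })
  m <- build_map(binned)
  expect_gt(m$mean[m$bin == 1], m$mean[m$bin == 40])
  # the mean binned profile should decay roughly monotonically: compare
  # quarters of the map
  q <- tapply(m$mean, cut(m$bin, c(0, 10, 20, 30, 40)), mean)
  expect_true(all(diff(q) < 0))
})

test_that("enrichment ratio follows its definition and scale invariance", {
  expect_equal(enrichment_ratio(bin_profile(rec_of(rep(70, 40)))), 1.0)
  x <- c(rep(200, 6), rep(100, 34))
  expect_equal(enrichment_ratio(bin_profile(rec_of(x))), 2.0)

  set.seed(7)
  z <- sample(1000:20000, 40)
  bz <- bin_profile(rec_of(z))
  expect_equal(enrichment_ratio(bz), mean(z[1:6]) / mean(z[7:40]))
  # invariance under intensity scaling c > 0
  for (cc in c(0.25, 3)) {
    expect_equal(enrichment_ratio(bin_profile(rec_of(z * cc))),
                 enrichment_ratio(bz))
  }
  zero_shaft <- bin_profile(rec_of(c(rep(10, 6), rep(0, 34))))
  expect_error(enrichment_ratio(zero_shaft), "shaft mean is 0")
})

test_that("tip positivity flips exactly at the 5000 boundary", {
  at <- bin_profile(rec_of(c(rep(5000, 6), rep(0, 34))))
  below <- bin_profile(rec_of(c(rep(4999, 6), rep(0, 34))))
  expect_true(classify_tip_positive(at))
  expect_false(classify_tip_positive(below))
  expect_equal(percent_positive(list(at, below)), 50)
  expect_error(percent_positive(list()), "no profiles")
})

test_that("filopodium length is the traced arc length in micrometres", {
  img <- matrix(1000, 120, 120)
  p <- extract_profile(img, cbind(c(5, 105), c(10, 10)), 0.08)
  expect_equal(filopodium_length(p), 8.0)
  # L-shaped polyline: sum of the two segment lengths
  pl <- cbind(c(5, 5, 35), c(5, 45, 45))
  expect_equal(polyline_length(pl, 0.1), (40 + 30) * 0.1)
  p2 <- extract_profile(img, pl, 0.1)
  expect_equal(filopodium_length(p2), 7, tolerance = 1e-9)
  # 2-sample degenerate record still has positive length
  r <- profile_record(c(1, 2), c(0, 0.16), 0.08)
  expect_gt(filopodium_length(r), 0)
})

test_that("percent positive recovers the generator's positive fraction", {
  # 10 scenes x 40 filopodia, active channel positive in 25% of filopodia
  n_pos <- 0; n_tot <- 0
  for (s in 1:10) {
    law <- channel_law("act", "tip_exponential", amplitude = 30000,
                       decay_length = 1, tip_positive_fraction = 0.25,
                       body_fraction = 0)
    cfg <- scene_config(image_size = c(400L, 400L), pixel_size = 0.08,
                        cell_radius = 6, filopodium_length_range = c(2, 8),
                        n_filopodia = 40, channel_models = list(law),
                        noise = list(poisson_scale = 2, read_sd = 30),
                        seed = 100 + s)
    sc <- make_scene(cfg)
    pos <- vapply(seq_along(sc$polylines), function(i) {
      classify_tip_positive(bin_profile(extract_profile(
        sc$images[["act"]], sc$polylines[[i]], cfg$pixel_size)))
    }, logical(1))
    # the classifier must agree with the stored ground truth per filopodium
    expect_equal(pos, unname(sc$ground_truth_positive[, "act"]))
    n_pos <- n_pos + sum(pos); n_tot <- n_tot + length(pos)
  }
  se <- sqrt(0.25 * 0.75 / n_tot)
  expect_lt(abs(n_pos / n_tot - 0.25), 3 * se)
})
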