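# Synthetic-data generator: determinism, ground truth, closed-form renders.

small_scene_config <- function(..., noise = list(poisson_scale = 0, read_sd = 0)) {
  scene_config(image_size = c(160L, 160L), pixel_size = 0.08, cell_radius = 2,
               filopodium_length_range = c(1.5, 3), noise = noise, ...)
}

test_that("a scene with no filopodia has only the cell body", {
  sc <- make_scene(small_scene_config(n_filopodia = 0, seed = 5))
  expect_length(sc$polylines, 0)
  expect_equal(nrow(sc$ground_truth_positive), 0)
  # nothing outside the body disk in a noise-free render
  img <- sc$images[["MYO10"]]
  ctr <- sc$cell_center_px
  far <- img[1:10, 1:10]
  expect_true(all(far == 0))
  expect_gt(max(img), 0)
})

test_that("scenes are deterministic given the seed", {
  cfg <- small_scene_config(n_filopodia = 6, seed = 42,
                            noise = list(poisson_scale = 4, read_sd = 60))
  s1 <- make_scene(cfg)
  s2 <- make_scene(cfg)
  expect_identical(s1$images, s2$images)
  expect_identical(s1$polylines, s2$polylines)
  s3 <- make_scene(small_scene_config(n_filopodia = 6, seed = 43,
                                      noise = list(poisson_scale = 4, read_sd = 60)))
  expect_false(identical(s1$images, s3$images))
})

test_that("noise-free render matches the per-pixel closed-form oracle", {
  law <- channel_law("tip", "tip_exponential", amplitude = 20000,
                     decay_length = 1)
  cfg <- scene_config(image_size = c(96L, 96L), pixel_size = 0.08,
                      cell_radius = 1.2, filopodium_length_range = c(1, 2),
                      n_filopodia = 3, channel_models = list(law),
                      noise = list(poisson_scale = 0, read_sd = 0), seed = 9)
  sc <- make_scene(cfg)
  expect_equal(unname(sc$images[["tip"]]),
               unname(oracle_render_channel(sc, law)), tolerance = 0)
})

test_that("scene geometry invariants hold: tip outside, base on the rim", {
  sc <- make_scene(small_scene_config(n_filopodia = 12, seed = 11))
  ctr <- sc$cell_center_px
  for (pl in sc$polylines) {
    d_tip <- sqrt(sum((pl[1, ] - ctr)^2))
    d_base <- sqrt(sum((pl[2, ] - ctr)^2))
    expect_gt(d_tip, sc$cell_radius_px)
    expect_equal(d_base, sc$cell_radius_px, tolerance = 1e-9)
  }
  for (img in sc$images) {
    expect_true(all(img >= 0 & img <= 65535))
  }
})

test_that("image too small for the cell plus filopodia is rejected", {
  expect_error(scene_config(image_size = c(64L, 64L), pixel_size = 0.08,
                            cell_radius = 8, filopodium_length_range = c(2, 8)),
               "too small")
})

test_that("gold particle distances follow the requested law", {
  expect_length(make_gold_particles(0, "uniform", seed = 1)$distances, 0)
  expect_error(make_gold_particles(-1, "uniform"), "non-negative")

  u <- make_gold_particles(1e5, "uniform", filo_length = 2000, seed = 2)
  se_u <- 2000 / sqrt(12) / sqrt(1e5)
  expect_lt(abs(mean(u$distances) - 1000), 3 * se_u)

  g <- make_gold_particles(1e5, "tip_exponential", scale = 200,
                           filo_length = 2e5, seed = 3)
  se_g <- 200 / sqrt(1e5)
  expect_lt(abs(mean(g$distances) - 200), 3 * se_g)
  expect_true(all(g$distances >= 0 & g$distances <= 2e5))
})

test_that("titrations follow the depletion model exactly when noise-free", {
  t0 <- make_titration(A0 = 2e-8, Kd = 1e-6, F_free = 800, F_bound = 900,
                       noise_sd = 0)
  # appending L0 = 0 must give exactly F_free
  expect_equal(unname(800 + (900 - 800) *
                        complex_concentration(2e-8, 0, 1e-6) / 2e-8), 800)
  # saturation: tiny Kd, L0 >> A0 -> F_bound
  sat <- 800 + (900 - 800) * complex_concentration(2e-8, 1e-3, 1e-12) / 2e-8
  expect_equal(sat, 900, tolerance = 1e-6)
  # half-occupancy point: L0 = Kd >> A0, checked against the bisection root
  al <- complex_concentration(2e-8, 1e-5, 1e-5)
  expect_equal(al, oracle_complex_root(2e-8, 1e-5, 1e-5), tolerance = 1e-10)
  expect_equal(al / 2e-8, 0.5, tolerance = 1e-2)
  expect_error(make_titration(Kd = 1e-6, F_free = 800, F_bound = 800),
               "degenerate")
  expect_identical(t0$signal,
                   make_titration(A0 = 2e-8, Kd = 1e-6, F_free = 800,
                                  F_bound = 900, noise_sd = 0)$signal)
})

test_that("flow populations have log-normal structure and are seeded", {
  f0 <- make_flow_population(50, list(F = c(5, 0)), seed = 1)
  expect_true(all(f0$intensity == exp(5)))
  f1 <- make_flow_population(200, list(F = c(5, 0.5)), seed = 2)
  f2 <- make_flow_population(200, list(F = c(5, 0.5)), seed = 2)
  expect_identical(f1, f2)
  expect_true(all(f1$intensity >= 0))
})

test_that("time-lapse lifetimes follow the discretized exponential", {
  expect_error(make_timelapse(10, 20, interval = 0), "interval")
  tl1 <- make_timelapse(100, 20, interval = 5, n_frames = 50, seed = 7)
  tl2 <- make_timelapse(100, 20, interval = 5, n_frames = 50, seed = 7)
  expect_identical(tl1$spots, tl2$spots)
  # per-frame displacement bounded
  for (id in unique(tl1$spots$spot_id)) {
    tr <- tl1$spots[tl1$spots$spot_id == id, ]
    if (nrow(tr) > 1) {
      steps <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
      expect_true(all(steps <= 0.2 + 1e-12))
    }
  }
  # mean observed track length vs direct-summation expectation, long movie so
  # truncation is negligible
  tl <- make_timelapse(1e4, mean_lifetime = 5, interval = 5,
                       n_frames = 2000, seed = 8)
  expect_mean <- sum(exp(-(0:999) * 5 / 5))
  obs <- tl$ground_truth$observed_frames
  se <- sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - expect_mean), 3 * se)
})
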