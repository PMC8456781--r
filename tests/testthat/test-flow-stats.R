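# Activity indices, ddCt expression and resampling statistics.

test_that("the fibronectin-binding activity index follows its formula", {
  expect_equal(activity_index_fn(100, 100, 400), 0)
  expect_equal(activity_index_fn(300, 100, 400), 0.5)
  # common-gain invariance: scaling every channel leaves AI unchanged
  expect_equal(activity_index_fn(600, 200, 800), activity_index_fn(300, 100, 400))
  expect_error(activity_index_fn(300, 100, 0), "F_PB1")
})

test_that("the antibody-based activity index follows its formula", {
  expect_equal(activity_index_9eg7(100, 1700, 100), 0)
  expect_equal(activity_index_9eg7(1700, 1700, 100), 1)
  expect_equal(activity_index_9eg7(900, 1700, 100), 0.5)
  expect_equal(activity_index_9eg7(1800, 3400, 200),
               activity_index_9eg7(900, 1700, 100))
  expect_error(activity_index_9eg7(900, 100, 100), "background")
})

test_that("flow summaries and rectangular gating work on generated tables", {
  fl <- make_flow_population(500, list(F = c(6, 0.4), F_PB1 = c(7, 0.3)),
                             seed = 20)
  s <- flow_summaries(fl)
  expect_named(s, c("F", "F_PB1"))
  expect_equal(s[["F"]], mean(fl$intensity[fl$stain == "F"]))
  gated <- rectangular_gate(fl, list(F = c(0, exp(6))))
  kept <- unique(gated$cell_id)
  expect_true(all(fl$intensity[fl$stain == "F" & fl$cell_id %in% kept] <= exp(6)))
  expect_lt(length(kept), 500)
})

test_that("ddCt expression matches direct arithmetic and its invariances", {
  ct <- data.frame(gene = rep(c("G", "GAPDH"), 2),
                   sample = rep(c("s", "c"), each = 2),
                   ct = c(24, 18, 26, 18))
  expect_equal(relative_expression_ddct(ct, "G", "s", "c"), 4.0)
  # all equal -> 1
  ct1 <- data.frame(gene = rep(c("G", "GAPDH"), 2),
                    sample = rep(c("s", "c"), each = 2), ct = 20)
  expect_equal(relative_expression_ddct(ct1, "G", "s", "c"), 1.0)
  # one cycle lower in the sample, reference unchanged -> 2
  ct2 <- ct1; ct2$ct[ct2$gene == "G" & ct2$sample == "s"] <- 19
  expect_equal(relative_expression_ddct(ct2, "G", "s", "c"), 2.0)
  # adding a constant to every Ct changes nothing
  ct3 <- ct; ct3$ct <- ct3$ct + 3.7
  expect_equal(relative_expression_ddct(ct3, "G", "s", "c"), 4.0)
  expect_error(relative_expression_ddct(ct[-1, ], "G", "s", "c"),
               "gene 'G' in sample 's'")
})

test_that("randomization test matches exhaustive enumeration", {
  r <- randomization_test(c(1, 2, 3), c(101, 102, 103), exact = TRUE)
  expect_equal(r$p, 2 / 20)

  # Monte-Carlo agrees with the exact oracle on random small groups
  set.seed(21)
  for (i in 1:5) {
    a <- round(runif(sample(3:5, 1), 0, 10), 1)
    b <- round(runif(sample(3:5, 1), 0, 10), 1)
    exact_p <- {
      pooled <- c(a, b)
      ix <- combn(length(pooled), length(a))
      s_obs <- mean(a) - mean(b)
      s_null <- apply(ix, 2, function(k) mean(pooled[k]) - mean(pooled[-k]))
      mean(abs(s_null) >= abs(s_obs) - 1e-12)
    }
    expect_equal(randomization_test(a, b, exact = TRUE)$p, exact_p)
    mc <- randomization_test(a, b, n_resamples = 4000, seed = i)$p
    expect_lt(abs(mc - exact_p), 0.05)
  }

  # identical multisets give p = 1
  x <- c(2, 4, 6)
  expect_equal(randomization_test(x, x, exact = TRUE)$p, 1)
  expect_equal(randomization_test(x, x, n_resamples = 99, seed = 1)$p, 1)
  expect_error(randomization_test(1, c(1, 2)), "n >= 2")
  expect_error(randomization_test(x, x, n_resamples = 0), "n_resamples")
})

test_that("effect size gives exact answers on constant groups", {
  r0 <- effect_size(c(5, 5, 5), c(3, 3, 3), n_boot = 50, seed = 2)
  expect_equal(r0$difference, 2)
  expect_equal(r0$ci, c(2, 2))
  r1 <- effect_size(c(1, 2, 3), c(1, 2, 3), n_boot = 200, seed = 3)
  expect_equal(r1$difference, 0)
  expect_lte(r1$ci[1], 0)
  expect_gte(r1$ci[2], 0)
})

test_that("bootstrap CI coverage is near nominal for a known difference", {
  set.seed(22)
  hits <- 0
  n_sim <- 200
  for (i in seq_len(n_sim)) {
    a <- rnorm(50, 1, 1)
    b <- rnorm(50, 0, 1)
    ci <- effect_size(a, b, n_boot = 200, seed = i)$ci
    if (ci[1] <= 1 && 1 <= ci[2]) hits <- hits + 1
  }
  se <- sqrt(0.95 * 0.05 / n_sim)
  expect_lt(abs(hits / n_sim - 0.95), 3 * se + 0.01)
})

test_that("tukey_summary uses type-7 quartiles and 1.5 IQR whiskers", {
  s <- tukey_summary(1:7)
  expect_equal(s$median, 4)
  expect_equal(s$q1, 2.5)
  expect_equal(s$q3, 5.5)
  expect_length(s$outliers, 0)
  expect_equal(s$whisker_low, 1)
  expect_equal(s$whisker_high, 7)

  s1 <- tukey_summary(42)
  expect_equal(s1$median, 42)
  expect_equal(s1$q1, 42)
  expect_equal(s1$whisker_high, 42)

  # an extreme point becomes an outlier and leaves the whisker unchanged
  x <- 1:7
  iqr <- 3
  s2 <- tukey_summary(c(x, 5.5 + 10 * iqr))
  expect_true((5.5 + 10 * iqr) %in% s2$outliers)
  expect_equal(s2$whisker_high, 7)
})
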