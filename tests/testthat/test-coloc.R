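test_that("Pearson correlation behaves on constructed channels", {
  m <- matrix(runif(64 * 64, 0, 100), 64)
  expect_equal(pearson_coefficient(image_pair(m, m)), 1)
  expect_equal(pearson_coefficient(image_pair(m, max(m) - m)), -1)
  set.seed(61)
  a <- matrix(runif(256 * 256), 256)
  b <- matrix(runif(256 * 256), 256)
  expect_lt(abs(pearson_coefficient(image_pair(a, b))), 0.05)
  expect_error(pearson_coefficient(image_pair(m, m * 0)), "variance")
})

test_that("intensity-ratio coefficients follow their worked arithmetic", {
  # identical channels
  m <- matrix(runif(16, 1, 10), 4)
  expect_equal(manders_coefficients(image_pair(m, m)),
               tibble::tibble(m1 = 1, m2 = 1))
  # scaling identity: ch2 = 2 ch1 -> (2, 0.5)
  expect_equal(manders_coefficients(image_pair(m, 2 * m)),
               tibble::tibble(m1 = 2, m2 = 0.5))
  # 2x2 worked case: s1 = 1..4, s2 = 4..1 -> cross 20, norms 30
  got <- manders_coefficients(image_pair(matrix(1:4, 2), matrix(4:1, 2)))
  expect_equal(got$m1, 2 / 3)
  expect_equal(got$m2, 2 / 3)
  expect_error(manders_coefficients(image_pair(m, m * 0)), "all-zero")
})

test_that("coefficient scaling laws hold exactly", {
  set.seed(63)
  s1 <- matrix(runif(900, 0, 50), 30)
  s2 <- matrix(runif(900, 0, 50), 30)
  base <- manders_coefficients(image_pair(s1, s2))
  for (a in c(0.5, 3)) {
    scaled1 <- manders_coefficients(image_pair(a * s1, s2))
    expect_equal(scaled1$m1, base$m1 / a, tolerance = 1e-12)
    scaled2 <- manders_coefficients(image_pair(s1, a * s2))
    expect_equal(scaled2$m2, base$m2 / a, tolerance = 1e-12)
  }
})

test_that("automatic thresholds land at a constructed noise/signal boundary", {
  # correlated signal on top of an uncorrelated low-intensity noise floor
  set.seed(65)
  n <- 128
  sig <- matrix(0, n, n)
  idx <- sample.int(n * n, 2000)
  sig[idx] <- runif(2000, 100, 1000)
  noise1 <- matrix(sample(0:40, n * n, replace = TRUE), n)
  noise2 <- matrix(sample(0:40, n * n, replace = TRUE), n)
  pair <- image_pair(sig + noise1, sig + noise2)
  thr <- costes_thresholds(pair)
  # thresholds must sit near the top of the uncorrelated floor
  expect_gt(thr$threshold_ch1, 20)
  expect_lt(thr$threshold_ch1, 120)
  # stop-rule post-condition: below-threshold correlation is <= 0
  expect_lte(thr$below_r, 0)
  expect_lte(pearson_coefficient(pair, "below",
                                 c(thr$threshold_ch1, thr$threshold_ch2)),
             0)
})

test_that("independent channels collapse thresholds with a warning", {
  set.seed(67)
  a <- matrix(runif(64 * 64, 0, 100), 64)
  b <- matrix(runif(64 * 64, 0, 100), 64)
  expect_warning(thr <- costes_thresholds(image_pair(a, b)),
                 "minimum|non-positive")
  expect_lte(thr$threshold_ch1, min(a) + 1)
})

test_that("stop rule holds on simulated pairs with partial colocalization", {
  pair <- simulate_image_pair(coloc_fraction = 0.5, seed = 69)
  thr <- costes_thresholds(pair)
  expect_lte(thr$below_r, 0)
})

test_that("overlap statistics on identical channels are unity", {
  m <- matrix(runif(900, 0, 200), 30)
  pair <- image_pair(m, m)
  ov <- overlap_and_counts(pair, c(50, 50))
  expect_equal(ov$stats$overlap_r_above, 1)
  expect_equal(ov$stats$k1, 1)
  expect_equal(ov$stats$k2, 1)
  # mask equals the above-threshold set (ratio of identical pixels is 1)
  expect_equal(sum(ov$mask), sum(m > 50))
  expect_equal(ov$stats$n_coloc_pixels, ov$stats$n_ch1_above)
})

test_that("overlap R is bounded by Cauchy-Schwarz over random pairs", {
  set.seed(71)
  for (i in 1:5) {
    a <- matrix(runif(400, 0, 100), 20)
    b <- matrix(runif(400, 0, 100), 20)
    ov <- overlap_and_counts(image_pair(a, b), c(30, 30))
    expect_gte(ov$stats$overlap_r_above, 0)
    expect_lte(ov$stats$overlap_r_above, 1 + 1e-12)
  }
})

test_that("disjoint puncta yield almost no colocalized pixels", {
  # well-separated spots, half-amplitude thresholds: only cores count
  pair <- simulate_image_pair(n_puncta = 30, coloc_fraction = 0,
                              min_separation = 12, seed = 73)
  ov <- overlap_and_counts(pair, c(4000, 4000))
  n_above <- min(ov$stats$n_ch1_above, ov$stats$n_ch2_above)
  expect_lt(ov$stats$n_coloc_pixels, 0.01 * n_above)
})

test_that("fully colocalized noiseless pairs are exactly identical", {
  pair <- simulate_image_pair(coloc_fraction = 1, background = 0,
                              noise_sd = 0, seed = 75)
  expect_identical(pair$ch1, pair$ch2)
  rep <- suppressWarnings(coloc_report(pair)) # identical channels never decorrelate
  expect_equal(rep$stats$pearson, 1)
  expect_equal(rep$stats$m1, 1)
  expect_equal(rep$stats$m2, 1)
  expect_equal(rep$stats$overlap_r_above, 1)
  # set identity: colocalized pixels = above-threshold pixels in each channel
  expect_equal(rep$stats$n_coloc_pixels, rep$stats$n_ch1_above)
  expect_equal(rep$stats$n_coloc_pixels, rep$stats$n_ch2_above)
})

test_that("Pearson and colocalized counts rise with the true fraction", {
  stats <- purrr::map_dfr(c(0, 0.25, 0.5, 0.75, 1), function(f) {
    pair <- simulate_image_pair(coloc_fraction = f, seed = 77)
    tibble::tibble(fraction = f,
                   pearson = pearson_coefficient(pair))
  })
  expect_true(all(diff(stats$pearson) > 0))
})

test_that("the colocalization mask is invariant under joint rescaling", {
  pair <- simulate_image_pair(coloc_fraction = 0.5, seed = 79)
  thr <- costes_thresholds(pair)
  ov <- overlap_and_counts(pair, thr)
  sc <- image_pair(pair$ch1 * 3, pair$ch2 * 3)
  ov_sc <- overlap_and_counts(
    sc, c(thr$threshold_ch1 * 3, thr$threshold_ch2 * 3)
  )
  expect_identical(ov$mask, ov_sc$mask)
})

test_that("the full report covers the expected statistic set", {
  pair <- simulate_image_pair(coloc_fraction = 0.5, seed = 81)
  rep <- coloc_report(pair)
  expect_setequal(
    names(rep$stats),
    c("pearson", "m1", "m2", "threshold_ch1", "threshold_ch2", "slope",
      "intercept", "overlap_r_above", "overlap_r_below", "k1", "k2",
      "n_coloc_pixels", "n_ch1_above", "n_ch2_above")
  )
  td <- tidy(rep)
  expect_named(td, c("statistic", "value"))
  expect_true(is.matrix(rep$mask))
})
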