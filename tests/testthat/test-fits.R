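test_that("Hill fit is exact on noiseless self-generated data", {
  dr <- simulate_dose_response(pmax = 0.5, k05 = 10, n_hill = 2,
                               concentrations = c(0, 2, 5, 10, 20, 50),
                               replicates = 1, noise_sd = 0)
  fit <- fit_hill(dr)
  expect_equal(fit$pmax, 0.5, tolerance = 1e-8)
  expect_equal(fit$k05, 10, tolerance = 1e-7)
  expect_equal(fit$n_hill, 2, tolerance = 1e-7)
  # half-activation identity on the fitted curve
  expect_equal(predict(fit, fit$k05), fit$pmax / 2, tolerance = 1e-12)
  expect_gt(fit$r_squared, 1 - 1e-10)
})

test_that("Hill fit recovers the published parameter set within 2 s.e.", {
  dr <- simulate_dose_response(seed = 1) # 0.411 / 22 / 2.5, sigma 0.02, 11 reps
  fit <- fit_hill(dr)
  expect_lt(abs(fit$k05 - 22), 2 * fit$se[["k05"]])
  expect_lt(abs(fit$pmax - 0.411), 2 * fit$se[["pmax"]])
  expect_lt(abs(fit$n_hill - 2.5), 2 * fit$se[["n_hill"]])
  expect_gt(fit$r_squared, 0.9)
})

test_that("Hill fit input contract is enforced", {
  bad <- tibble::tibble(concentration = c(0, 10, 20), po = c(0, 0.1, 0.2))
  expect_error(fit_hill(bad), "4 distinct")
})

test_that("GHK fit is exact on noiseless data and Erev is the curve root", {
  r_true <- perm_ratio_for_reversal(83)
  p_true <- p_na_for_conductance(6.6, r_true)
  iv <- simulate_iv(p_true, r_true, voltages = seq(-120, 100, by = 20),
                    noise_sd = 0)
  fit <- fit_ghk(iv)
  expect_equal(fit$p_na, p_true, tolerance = 1e-6)
  expect_equal(fit$perm_ratio, r_true, tolerance = 1e-6)
  expect_equal(fit$erev, 83, tolerance = 1e-4)
  # Erev equals the root of the fitted current
  root <- uniroot(function(v) predict(fit, v), c(0, 200), tol = 1e-9)$root
  expect_equal(fit$erev, root, tolerance = 0.01)
  # fitted curve rectifies inward
  expect_gt(abs(predict(fit, -100)), abs(predict(fit, 100)))
})

test_that("GHK fit recovers reversal and conductance within 2 s.e.", {
  r_true <- perm_ratio_for_reversal(83)
  p_true <- p_na_for_conductance(6.6, r_true)
  iv <- simulate_iv(p_true, r_true, seed = 1) # 10 voltages, sigma 0.05 pA
  fit <- suppressWarnings(fit_ghk(iv)) # currents never bracket +83 mV
  expect_lt(abs(fit$erev - 83), 2 * fit$erev_se)
  g <- slope_conductance(fit)
  expect_lt(abs(g$conductance_pS - 6.6), 2 * g$std.error)
})

test_that("slope conductance of an ohmic curve equals its conductance", {
  # near-symmetric permeation approximates an ohmic I-V through 0
  fit <- list(p_na = 1, perm_ratio = 1, na_in = 100, li_out = 100,
              temperature = 295.15,
              vcov = diag(c(1e-12, 1e-12)),
              data = tibble::tibble(voltage_mV = c(-120, -40),
                                    current_pA = c(-1, 1)))
  class(fit) <- "ghk_fit"
  g1 <- slope_conductance(fit, -120, -40)
  g2 <- slope_conductance(fit, -60, -20)
  # symmetric-solution GHK is exactly linear: same slope on any window
  expect_equal(g1$conductance_pS, g2$conductance_pS, tolerance = 1e-9)

  # rectifying curve: narrowing the window toward 0 shifts the slope down
  r_true <- perm_ratio_for_reversal(83)
  p_true <- p_na_for_conductance(6.6, r_true)
  iv <- simulate_iv(p_true, r_true, voltages = seq(-140, 60, 20),
                    noise_sd = 0)
  fitr <- suppressWarnings(fit_ghk(iv)) # sweep tops out below +83 mV
  g_wide <- slope_conductance(fitr, -120, -40)$conductance_pS
  g_mid <- slope_conductance(fitr, -100, -20)$conductance_pS
  g_hi <- slope_conductance(fitr, -80, 0)$conductance_pS
  expect_gt(g_wide, g_mid)
  expect_gt(g_mid, g_hi)
  expect_equal(g_wide, 6.6, tolerance = 1e-6)
})

test_that("linear rate fit matches OLS identities", {
  # exact line: zero residuals, vanishing p
  d <- tibble::tibble(concentration = c(5, 10, 20, 40),
                      rate = 2e-4 * c(5, 10, 20, 40) + 1e-3)
  fit <- suppressWarnings(linear_rate_fit(d)) # exact line
  expect_equal(fit$slope, 2e-4, tolerance = 1e-12)
  expect_equal(fit$intercept, 1e-3, tolerance = 1e-12)
  expect_lt(fit$p_value, 1e-10)

  # reciprocal mean closed times of the worked scheme: slope = k1, through 0
  sj <- sojourn_means(coo_scheme(0.001, 0.01, 0.0005, 0.005), c(10, 20, 50))
  fit2 <- suppressWarnings(linear_rate_fit(tibble::tibble(
    concentration = sj$concentration, rate = 1 / sj$mean_closed
  ))) # exact line
  expect_equal(fit2$slope, 0.001, tolerance = 1e-10)
  expect_equal(fit2$intercept, 0, tolerance = 1e-12)

  expect_error(linear_rate_fit(d[1:2, ]), "3 points")
  expect_error(linear_rate_fit(
    tibble::tibble(concentration = c(1, 1, 1), rate = c(1, 2, 3))
  ), "singular")
})

test_that("opening-rate slope vs concentration is recovered within 2 s.e.", {
  # generative truth: the measured opening-rate slope and its printed
  # uncertainty used as the noise scale of the synthetic rates
  slope_true <- 7.97e-6
  se_printed <- 1.63e-6
  L <- c(0, 10, 20, 30, 50)
  sigma <- se_printed * sqrt(sum((L - mean(L))^2))
  set.seed(1)
  d <- tibble::tibble(concentration = L,
                      rate = slope_true * L + rnorm(length(L), 0, sigma))
  fit <- linear_rate_fit(d)
  expect_lt(abs(fit$slope - slope_true), 2 * fit$slope_se)
})

test_that("tidiers return the advertised shapes", {
  dr <- simulate_dose_response(seed = 2)
  hf <- fit_hill(dr)
  td <- tidy(hf)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(nrow(td), 3L)
  expect_named(glance(hf), c("r.squared", "rss", "nobs"))

  r_true <- perm_ratio_for_reversal(83)
  iv <- simulate_iv(p_na_for_conductance(6.6, r_true), r_true,
                    voltages = seq(-120, 100, 20), noise_sd = 0.02,
                    seed = 3)
  gf <- suppressWarnings(fit_ghk(iv)) # near-zero current at the top voltage
  expect_equal(tidy(gf)$term, c("p_na", "perm_ratio", "erev_mV"))
})
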