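test_that("dwell summary computes censored-excluded means", {
  # interior open events of 10 and 30 ms -> mean 20 ms
  ev <- event_list(
    level = c(0, 1, 0, 1, 0),
    start_ms = c(0, 40, 50, 70, 100),
    duration_ms = c(40, 10, 20, 30, 25),
    total_time = 125
  )
  dw <- dwell_summary(ev)
  expect_equal(dw$mean_open, 20)
  expect_equal(dw$mean_closed, 20) # only the middle closed sojourn survives
  expect_equal(dw$n_open_events, 2L)
  expect_equal(dw$n_closed_events, 1L) # first/last excluded as censored
})

test_that("multi-channel records are rejected for dwell analysis", {
  ev <- event_list(c(0, 2, 0), c(0, 10, 20), c(10, 10, 10), 30)
  expect_error(dwell_summary(ev), "burst")
})

test_that("knockout-phenotype mean open time is recovered within 2 s.e.", {
  # closing rate set to the reciprocal of the 41.1 ms knockout mean open time
  sch <- co_scheme(0.001, 1 / 41.1)
  sim <- simulate_patch(sch, L = 20, duration_ms = 2e5, unit_current = -0.5,
                        noise_sd = 0.05, filter_cutoff = 1000, seed = 1)
  dw <- dwell_summary(idealize(sim$trace, unit_current = -0.5))
  expect_gt(dw$n_open_events, 2000)
  se <- dw$sd_open / sqrt(dw$n_open_events)
  expect_lt(abs(dw$mean_open - 41.1), 2 * se)
})

test_that("one-component fit returns the sample-mean tau", {
  set.seed(2)
  d <- rexp(500, 1 / 25)
  fit <- fit_exponential_mixture(d, 1)
  expect_equal(fit$components$tau, mean(d), tolerance = 1e-12)
  expect_true(fit$converged)
})

test_that("two-exponential mixtures are recovered within 10%", {
  set.seed(3)
  d <- c(rexp(2500, 1 / 10), rexp(2500, 1 / 200))
  fit <- fit_exponential_mixture(d, 2, seed = 4)
  expect_true(fit$converged)
  expect_lt(abs(fit$components$tau[1] - 10) / 10, 0.10)
  expect_lt(abs(fit$components$tau[2] - 200) / 200, 0.10)
  expect_equal(sum(fit$components$weight), 1, tolerance = 1e-9)
  expect_equal(fit$components$weight[1], 0.5, tolerance = 0.05)
})

test_that("sequential-scheme open times reject a single exponential", {
  sch <- coo_scheme(0.001, 0.01, 0.0005, 0.005)
  p <- sample_path(sch, 20, 8e5, seed = 7)
  ev <- superpose_paths(p)
  open_d <- ev$duration_ms[ev$level == 1L]
  open_d <- open_d[-c(1, length(open_d))]
  f1 <- fit_exponential_mixture(open_d, 1)
  f2 <- fit_exponential_mixture(open_d, 2, seed = 8)
  # mixture never fits worse, and the likelihood ratio is decisive at 1%
  expect_gte(f2$log_likelihood, f1$log_likelihood)
  lrt <- 2 * (f2$log_likelihood - f1$log_likelihood)
  expect_gt(lrt, qchisq(0.99, df = 2))
})

test_that("degenerate and undersized duration sets are rejected", {
  expect_error(fit_exponential_mixture(rep(5, 100), 2), "degenerate")
  expect_error(fit_exponential_mixture(rexp(10), 2), "50")
})

test_that("titration closed forms invert exactly on noiseless means", {
  # worked scheme: mean_open = 100 + 10 L, mean_closed = 1/(0.001 L)
  tit <- tibble::tibble(
    concentration = c(10, 20, 50),
    mean_open = c(200, 300, 600),
    mean_closed = c(100, 50, 20)
  )
  est <- suppressWarnings(recover_rates_from_titration(tit)) # exact fit
  expect_equal(est$estimate[est$term == "k1"], 0.001, tolerance = 1e-10)
  expect_equal(est$estimate[est$term == "k_1"], 0.01, tolerance = 1e-10)
  expect_equal(est$estimate[est$term == "k2_over_k_2"], 0.1,
               tolerance = 1e-10)
  expect_error(recover_rates_from_titration(tit[1:2, ]), "3 distinct")
})

test_that("rates are recovered from a simulated titration within 2 s.e.", {
  sch <- coo_scheme(0.001, 0.01, 0.0005, 0.005)
  set.seed(51)
  summaries <- purrr::map_dfr(c(10, 20, 50), function(L) {
    p <- sample_path(sch, L, 3e5)
    dplyr::mutate(dwell_summary(superpose_paths(p)), concentration = L)
  })
  est <- recover_rates_from_titration(summaries)
  for (i in seq_len(nrow(est))) {
    truth <- c(k1 = 0.001, k_1 = 0.01, k2_over_k_2 = 0.1)[[est$term[i]]]
    expect_lt(abs(est$estimate[i] - truth), 3 * est$std.error[i] + 0.1 * truth)
  }
})

test_that("dwell trends with concentration match the gating model", {
  # mean open grows, mean closed shrinks with ligand
  sch <- coo_scheme(0.001, 0.01, 0.0005, 0.005)
  sj <- sojourn_means(sch, c(10, 20, 50))
  expect_true(all(diff(sj$mean_open) > 0))
  expect_true(all(diff(sj$mean_closed) < 0))
  set.seed(53)
  emp <- purrr::map_dfr(c(10, 20, 50), function(L) {
    p <- sample_path(sch, L, 2e5)
    dplyr::mutate(dwell_summary(superpose_paths(p)), concentration = L)
  })
  expect_true(all(diff(emp$mean_open) > 0))
  expect_true(all(diff(emp$mean_closed) < 0))
})
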