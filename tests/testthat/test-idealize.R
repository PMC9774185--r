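test_that("baseline estimation finds the closed level", {
  tr0 <- pipgate:::new_ion_trace((0:99) * 0.25, rep(0, 100), list())
  expect_equal(estimate_baseline(tr0), 0)

  sim <- simulate_patch(co_scheme(0.0005, 0.02), L = 20, duration_ms = 1e5,
                        unit_current = -0.5, noise_sd = 0.1, seed = 23)
  # Po = 1/3: closed level dominates; baseline within noise_sd/2 of 0
  expect_lt(abs(estimate_baseline(sim$trace)), 0.05)
})

test_that("a noiseless square pulse idealizes to one event of the right length", {
  p <- make_path(c("closed", "open", "closed"), c(100, 50, 100))
  tr <- render_trace(p, unit_current = 1, noise_sd = 0, filter_cutoff = NULL)
  ev <- idealize(tr, unit_current = 1)
  open_ev <- ev[ev$level == 1L, ]
  expect_equal(nrow(open_ev), 1L)
  expect_lt(abs(open_ev$duration_ms - 50), 0.25) # one sample at 4 kHz
})

test_that("idealization on noiseless unfiltered traces is event-exact", {
  # fine sampling so that no latent sojourn falls below one sample
  sim <- simulate_patch(co_scheme(0.001, 0.01), L = 20, duration_ms = 5e4,
                        unit_current = -0.5, noise_sd = 0,
                        filter_cutoff = NULL, sampling_rate = 40000,
                        seed = 29)
  dt <- 1000 / 40000
  expect_gt(min(sim$events$duration_ms), dt) # precondition for exactness
  ev <- idealize(sim$trace, unit_current = -0.5)
  truth <- sim$events
  expect_equal(nrow(ev), nrow(truth))
  expect_equal(ev$level, truth$level)
  expect_true(all(abs(ev$duration_ms - truth$duration_ms) <= dt + 1e-9))
})

test_that("events below the filter dead time are missed, longer ones kept", {
  fc <- 100 # dead time 1.79 ms
  base <- c(200, 0.5, 200) # 0.5 ms opening: well under dead time
  tr <- render_trace(make_path(c("closed", "open", "closed"), base),
                     1, 0, fc, sampling_rate = 4000)
  ev <- idealize(tr, unit_current = 1)
  expect_true(all(ev$level == 0L))

  tr2 <- render_trace(make_path(c("closed", "open", "closed"),
                                c(200, 8, 200)), 1, 0, fc, 4000)
  ev2 <- idealize(tr2, unit_current = 1)
  expect_equal(sum(ev2$level == 1L), 1L)
})

test_that("dwell means recovered within 5% at low noise and high bandwidth", {
  sch <- coo_scheme(0.001, 0.01, 0.0005, 0.005)
  sim <- simulate_patch(sch, L = 20, duration_ms = 6e5, unit_current = -0.5,
                        noise_sd = 0.05, filter_cutoff = 1000, seed = 37)
  dw_est <- dwell_summary(idealize(sim$trace, unit_current = -0.5))
  dw_true <- dwell_summary(sim$events)
  expect_lt(abs(dw_est$mean_open - dw_true$mean_open) / dw_true$mean_open,
            0.05)
  expect_lt(abs(dw_est$mean_closed - dw_true$mean_closed) /
              dw_true$mean_closed, 0.05)
})

test_that("NPo follows the worked arithmetic and conserves the level average", {
  # 100 s record: 30 s at level 1, 10 s at level 2 -> NPo = 0.5
  ev <- event_list(c(0, 1, 2), c(0, 6e4, 9e4), c(6e4, 3e4, 1e4), 1e5)
  expect_equal(compute_npo(ev), 0.5)

  # conservation: NPo equals the time average of the level function
  set.seed(41)
  paths <- lapply(1:2, function(i) sample_path(co_scheme(0.002, 0.01), 20,
                                               3e4))
  ev2 <- superpose_paths(paths)
  expect_equal(compute_npo(ev2),
               sum(ev2$level * ev2$duration_ms) / 3e4, tolerance = 1e-12)

  # all closed and always open
  expect_equal(compute_npo(event_list(0L, 0, 100, 100)), 0)
  expect_equal(compute_npo(event_list(1L, 0, 100, 100)), 1)
  expect_error(compute_npo(event_list(integer(0), numeric(0), numeric(0),
                                      100)))
})

test_that("channel counting finds N from amplitude histogram peaks", {
  # three identical channels at Po ~ 0.3 each
  sch <- co_scheme(0.3 / 0.7 / 60 / 20, 1 / 60) # Po = 0.3, mean open 60 ms
  sim <- simulate_patch(sch, L = 20, duration_ms = 3e5, n_channels = 3,
                        unit_current = -0.5, noise_sd = 0.05,
                        filter_cutoff = 1000, seed = 43)
  expect_equal(estimate_channel_count(sim$trace, -0.5), 3L)

  sim1 <- simulate_patch(sch, L = 20, duration_ms = 3e5,
                         unit_current = -0.5, noise_sd = 0.05,
                         filter_cutoff = 1000, seed = 44)
  expect_equal(estimate_channel_count(sim1$trace, -0.5), 1L)
})

test_that("possible undercounting at low Po raises a warning", {
  sch <- co_scheme(0.05 / 0.95 / 100 / 20, 1 / 100) # Po = 0.05
  sim <- simulate_patch(sch, L = 20, duration_ms = 1e5, n_channels = 2,
                        unit_current = -0.5, noise_sd = 0.05,
                        filter_cutoff = 1000, seed = 47)
  expect_warning(estimate_channel_count(sim$trace, -0.5), "underestimate")
})

test_that("polarity mismatch between unit current and trace is an error", {
  p <- make_path(c("closed", "open", "closed"), c(100, 100, 100))
  tr <- render_trace(p, unit_current = -0.5, noise_sd = 0.02,
                     filter_cutoff = 500, seed = 3)
  expect_error(idealize(tr, unit_current = 0.5), "polarity")
  expect_error(idealize(tr, unit_current = 0), "non-zero")
})
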