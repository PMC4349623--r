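test_that("all simulators are deterministic under a fixed seed", {
  sched <- ref_schedule(10)
  m <- cam_one_set()
  s1 <- simulate_itc(sched, m, noise_sd_ucal = 0.2, seed = 42)
  s2 <- simulate_itc(sched, m, noise_sd_ucal = 0.2, seed = 42)
  expect_identical(s1, s2)

  d1 <- simulate_decay(ans_three_exp(), channels = 500, seed = 42)
  d2 <- simulate_decay(ans_three_exp(), channels = 500, seed = 42)
  expect_identical(d1, d2)

  q1 <- simulate_quench_series(100, 13.5, noise_frac = 0.02, seed = 42)
  q2 <- simulate_quench_series(100, 13.5, noise_frac = 0.02, seed = 42)
  expect_identical(q1, q2)

  k1 <- simulate_stopped_flow(1.41, duration_s = 3, noise_frac = 0.02,
                              seed = 42)
  k2 <- simulate_stopped_flow(1.41, duration_s = 3, noise_frac = 0.02,
                              seed = 42)
  expect_identical(k1, k2)

  p1 <- simulate_spectrum(list(c(480, 40, 1)), noise_frac = 0.02, seed = 42)
  p2 <- simulate_spectrum(list(c(480, 40, 1)), noise_frac = 0.02, seed = 42)
  expect_identical(p1, p2)

  # seeded simulators do not disturb the caller's RNG stream
  set.seed(1); before <- stats::runif(1)
  set.seed(1); invisible(simulate_itc(sched, m, seed = 99))
  expect_identical(stats::runif(1), before)
})

test_that("zero-noise ITC simulation reproduces the model heats exactly", {
  sched <- ref_schedule(15)
  m <- cam_one_set()
  sim <- simulate_itc(sched, m, noise_sd_ucal = 0, dilution_heat_ucal = -0.5,
                      seed = 1)
  expect_equal(dilution_correct(sim$sample, sim$blank)$heats_ucal,
               model_heats(sched, m), tolerance = 1e-12)
  expect_equal(sim$blank$heats_ucal, rep(-0.5, 15))
})

test_that("simulated CaM-like titration is sigmoidal with inflection near ratio 2", {
  sched <- ref_schedule(20)
  sim <- simulate_itc(sched, cam_one_set(), noise_sd_ucal = 0,
                      dilution_heat_ucal = 0, seed = 1)
  h <- sim$sample$heats_ucal
  expect_true(all(h < 0))  # exothermic
  # steepest change in the isotherm sits near molar ratio ~2
  infl <- sim$sample$molar_ratio[which.max(abs(diff(h)))]
  expect_gt(infl, 1.6); expect_lt(infl, 2.5)
  # early injections near-saturated, late ones near zero heat
  expect_gt(abs(h[1]), 10 * abs(h[20]))
})

test_that("ITC simulator rejects non-physical models", {
  expect_error(binding_model("one_set_of_sites", N = 2, K_a = -5, dH = -5),
               "non-physical")
  expect_error(titration_schedule(cell_conc_M = 30e-6,
                                  syringe_conc_M = 1e-3,
                                  injection_volumes_L = c(1e-5, -1e-5)))
})

test_that("decay expectation matches the model for a delta IRF", {
  m <- multiexp_model(alpha = c(1, 0.2), tau_ns = c(5, 20))
  sim <- simulate_decay(m, irf_fwhm_ns = 0, window_ns = 100, channels = 400,
                        peak_counts = 5000, expectation_only = TRUE)
  h <- decay_histogram(sim$expected, 100)
  expect_equal(sim$expected, model_decay(sim$model, h$time_ns),
               tolerance = 1e-8)
  expect_equal(max(sim$expected), 5000, tolerance = 1e-9)
})

test_that("Poisson replicate means converge to the expectation curve", {
  m <- multiexp_model(alpha = c(1, 0.3), tau_ns = c(3, 12))
  nrep <- 120
  acc <- 0
  for (s in seq_len(nrep)) {
    sim <- simulate_decay(m, irf_fwhm_ns = 1, window_ns = 60,
                          channels = 240, peak_counts = 2000, seed = s)
    acc <- acc + sim$decay$counts
  }
  expected <- simulate_decay(m, irf_fwhm_ns = 1, window_ns = 60,
                             channels = 240, peak_counts = 2000,
                             expectation_only = TRUE)$expected
  zbar <- (acc / nrep - expected) / sqrt(pmax(expected, 0.5) / nrep)
  # channelwise z-scores behave like standard normal draws
  expect_lt(abs(mean(zbar)), 0.2)
  expect_gt(stats::sd(zbar), 0.8); expect_lt(stats::sd(zbar), 1.25)
})

test_that("higher peak counts shrink lifetime errors (Poisson scaling)", {
  m <- multiexp_model(alpha = 1, tau_ns = 10)
  err_at <- function(pc) {
    es <- vapply(1:6, function(s) {
      sim <- simulate_decay(m, irf_fwhm_ns = 1, window_ns = 100,
                            channels = 500, peak_counts = pc, seed = s)
      f <- fit_decay(sim$decay, sim$irf, n_components = 1)
      abs(f$model$tau_ns - 10) / 10
    }, numeric(1))
    sqrt(mean(es^2))
  }
  expect_lt(err_at(1e6), err_at(1e4))
})

test_that("short windows and empty band lists trigger warnings", {
  m <- multiexp_model(alpha = 1, tau_ns = 50)
  expect_warning(simulate_decay(m, window_ns = 40, channels = 100,
                                expectation_only = TRUE), "truncation")
  expect_warning(simulate_spectrum(list(), seq(400, 500, 1)), "zero spectrum")
})

test_that("quench simulator follows the hyperbolic response law", {
  q <- seq(0, 0.3, length.out = 7)
  sr <- simulate_quench_series(100, 13.5, q_grid_M = q, noise_frac = 0)
  expect_equal(sr$response[, 1], 100 / (1 + 13.5 * q), tolerance = 1e-12)
  expect_equal(sr$reference[1] / sr$response[1, 1], 1)  # intercept exactly 1
  sr0 <- simulate_quench_series(100, 0, noise_frac = 0)
  expect_true(all(sr0$response == 100))
  expect_error(simulate_quench_series(100, 13.5, q_grid_M = c(-0.1, 0.1)))
})

test_that("stopped-flow simulator is exact at zero noise and flat at zero amplitude", {
  tr <- simulate_stopped_flow(2, amplitude = 1.5, offset = 0.2,
                              duration_s = 3, dt_s = 0.002, noise_frac = 0)
  expect_equal(tr$fluorescence, 0.2 + 1.5 * exp(-2 * tr$time_s),
               tolerance = 1e-12)
  flat <- suppressWarnings(
    simulate_stopped_flow(2, amplitude = 0, offset = 0.7, duration_s = 2,
                          noise_frac = 0))
  expect_true(all(flat$fluorescence == 0.7))
  expect_warning(simulate_stopped_flow(0.1, duration_s = 2, noise_frac = 0),
                 "identifiab")
})
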