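test_that("decay model evaluates the multi-exponential form", {
  m <- multiexp_model(alpha = c(2, 3), tau_ns = c(1, 5), baseline = 0.5)
  expect_equal(model_decay(m, 0), 0.5 + 5)
  expect_equal(model_decay(m, 1e6), 0.5, tolerance = 1e-12)
  m1 <- multiexp_model(alpha = 4, tau_ns = 2, baseline = 1)
  expect_equal(model_decay(m1, 2), 1 + 4 / exp(1))
})

test_that("fractional intensities and average lifetime follow their definitions", {
  m <- multiexp_model(alpha = c(0.2, 0.1), tau_ns = c(2, 10))
  fr <- fractional_intensities(m)
  expect_equal(fr$f, c(2 / 7, 5 / 7))
  expect_equal(sum(fr$f), 1, tolerance = 1e-12)
  expect_equal(sum(fr$B), 1, tolerance = 1e-12)

  m2 <- multiexp_model(alpha = c(1, 1), tau_ns = c(2, 10))
  expect_equal(amplitude_average_lifetime(m2), 104 / 12)
  # <tau> equals the intensity-weighted mean and is bounded by the taus
  set.seed(3)
  for (r in 1:20) {
    k <- sample(2:4, 1)
    m3 <- multiexp_model(alpha = stats::runif(k, 0.01, 1),
                         tau_ns = stats::runif(k, 0.1, 20))
    f3 <- fractional_intensities(m3)
    avt <- amplitude_average_lifetime(m3)
    expect_equal(avt, sum(f3$f * m3$tau_ns), tolerance = 1e-12)
    expect_gte(avt, min(m3$tau_ns))
    expect_lte(avt, max(m3$tau_ns))
    expect_equal(sum(f3$f), 1, tolerance = 1e-12)
  }
  expect_equal(fractional_intensities(multiexp_model(1, 7))$f, 1)
})

test_that("IRF convolution reduces to the direct model for a delta prompt", {
  m <- multiexp_model(alpha = c(800, 150), tau_ns = c(3, 15), baseline = 2)
  irf <- gaussian_irf(512, 100, fwhm_ns = 0, center_ns = 0)
  h <- decay_histogram(rep(1, 512), 100)
  conv <- convolve_irf(m, irf)
  expect_equal(conv, model_decay(m, h$time_ns), tolerance = 1e-9)

  # shrinking Gaussian width converges to the direct model
  sup_err <- vapply(c(2, 1, 0.25), function(wd) {
    irfw <- gaussian_irf(2048, 100, fwhm_ns = wd, center_ns = 0.2)
    hw <- decay_histogram(rep(1, 2048), 100)
    max(abs(convolve_irf(m, irfw) - model_decay(m, hw$time_ns))[100:2048])
  }, numeric(1))
  expect_true(all(diff(sup_err) < 0))

  # a shifted IRF shifts the expected peak by the same number of channels
  irfp <- gaussian_irf(1000, 100, fwhm_ns = 1, center_ns = 10)
  p0 <- which.max(convolve_irf(m, irfp))
  p5 <- which.max(convolve_irf(m, irfp, shift_ns = 5))
  expect_equal(p5 - p0, 5 / 0.1, tolerance = 1)
})

test_that("noiseless decays are recovered exactly and components sorted", {
  m <- multiexp_model(alpha = 1000, tau_ns = 20, baseline = 1)
  sim <- simulate_decay(m, irf_fwhm_ns = 0, window_ns = 200, channels = 1000,
                        peak_counts = 10000, expectation_only = TRUE)
  fit <- fit_decay(decay_histogram(round(sim$expected), 200), sim$irf,
                   n_components = 1, fit_shift = FALSE)
  expect_rel(fit$model$tau_ns, 20, 1e-3)
  expect_lt(fit$quality$chisq_red, 0.1)

  m2 <- multiexp_model(alpha = c(500, 500), tau_ns = c(30, 3), baseline = 0)
  sim2 <- simulate_decay(m2, irf_fwhm_ns = 1, window_ns = 200,
                         channels = 2000, peak_counts = 50000,
                         expectation_only = TRUE)
  fit2 <- fit_decay(decay_histogram(round(sim2$expected), 200), sim2$irf,
                    n_components = 2)
  expect_equal(order(fit2$model$tau_ns), 1:2)  # ascending tau
  expect_rel(sort(fit2$model$tau_ns), c(3, 30), 0.01)
})

test_that("tail fitting recovers lifetimes without an IRF", {
  m <- multiexp_model(alpha = c(900, 100), tau_ns = c(5, 25))
  sim <- simulate_decay(m, irf_fwhm_ns = 1, window_ns = 200, channels = 2000,
                        peak_counts = 20000, seed = 5)
  fit <- fit_decay(sim$decay, n_components = 2, mode = "tail")
  expect_rel(sort(fit$model$tau_ns), c(5, 25), 0.10)
})

test_that("chi-square acceptance is strict at 1.2", {
  expect_true(accept_fit(fit_quality(0.986)))
  expect_true(accept_fit(fit_quality(1.19)))
  expect_false(accept_fit(fit_quality(1.2)))
  expect_false(accept_fit(fit_quality(5)))
  expect_error(fit_quality(-0.1))
})

test_that("component-count selection finds the generating model order", {
  m1 <- multiexp_model(alpha = 1000, tau_ns = 12, baseline = 0)
  sim1 <- simulate_decay(m1, irf_fwhm_ns = 1, window_ns = 100,
                         channels = 1000, peak_counts = 10000, seed = 21)
  sel1 <- select_n_components(sim1$decay, sim1$irf, max_n = 2)
  expect_equal(sel1$n, 1L)
  expect_true(sel1$acceptable)

  m3 <- ans_three_exp()
  sim3 <- simulate_decay(m3, irf_fwhm_ns = 1, window_ns = 200,
                         channels = 1500, peak_counts = 10000, seed = 22)
  sel3 <- select_n_components(sim3$decay, sim3$irf, max_n = 3)
  expect_equal(sel3$n, 3L)
})

test_that("near-identical lifetimes are flagged degenerate", {
  m <- multiexp_model(alpha = c(500, 500), tau_ns = c(10, 10.5))
  sim <- simulate_decay(m, irf_fwhm_ns = 1, window_ns = 100, channels = 1000,
                        peak_counts = 10000, seed = 30)
  fit <- suppressWarnings(fit_decay(sim$decay, sim$irf, n_components = 2))
  # two tau within 1% of each other (or a collapsed pair) must be flagged
  expect_true(fit$degenerate ||
                abs(diff(fit$model$tau_ns)) / min(fit$model$tau_ns) > 0.01)
})

test_that("sub-resolution lifetimes carry the detection-limit flag", {
  m <- multiexp_model(alpha = c(3000), tau_ns = 0.3)
  sim <- simulate_decay(m, irf_fwhm_ns = 1, window_ns = 200, channels = 2000,
                        peak_counts = 10000, seed = 31)
  fit <- fit_decay(sim$decay, sim$irf, n_components = 1)
  # channel width 0.1 ns; anything below 0.2 ns is at the detection limit
  if (fit$model$tau_ns[1] < 0.2) expect_true(fit$at_detection_limit[1])
  expect_lt(fit$model$tau_ns[1], 1)  # dominated by the fast component
})

test_that("fits are stable under uniform count rescaling", {
  m <- multiexp_model(alpha = c(700, 300), tau_ns = c(4, 16))
  sim <- simulate_decay(m, irf_fwhm_ns = 1, window_ns = 150, channels = 1500,
                        peak_counts = 10000, expectation_only = TRUE)
  h1 <- decay_histogram(round(sim$expected), 150)
  h10 <- decay_histogram(round(sim$expected * 10), 150)
  f1 <- fit_decay(h1, sim$irf, n_components = 2)
  f10 <- fit_decay(h10, sim$irf, n_components = 2)
  expect_rel(f10$model$tau_ns, f1$model$tau_ns, 0.01)
})
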