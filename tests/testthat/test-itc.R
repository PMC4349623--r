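test_that("injection bookkeeping matches the displacement formulas", {
  sched <- titration_schedule(cell_volume_L = 1.4e-3, cell_conc_M = 30e-6,
                              syringe_conc_M = 1e-3,
                              injection_volumes_L = rep(10e-6, 10))
  c0 <- concentrations_after_injection(sched, 0)
  expect_equal(c0$M_t, 30e-6)
  expect_equal(c0$L_t, 0)

  # hand evaluation after 10 x 10 uL into 1.4 mL
  v <- 1e-4; V0 <- 1.4e-3
  c10 <- concentrations_after_injection(sched, 10)
  expect_equal(c10$M_t, 30e-6 * (1 - v / (2 * V0)) / (1 + v / (2 * V0)))
  expect_equal(c10$L_t, 1e-3 * (v / V0) / (1 + v / (2 * V0)))

  # first-order limit for tiny injections
  tiny <- titration_schedule(cell_conc_M = 30e-6, syringe_conc_M = 1e-3,
                             injection_volumes_L = rep(1e-9, 3))
  c1 <- concentrations_after_injection(tiny, 1)
  expect_equal(c1$L_t, 1e-3 * 1e-9 / 1.4e-3, tolerance = 1e-6)
  expect_error(concentrations_after_injection(sched, 11), "out of range")
})

test_that("identical-sites heat has the right limits", {
  expect_equal(total_heat_one_set(30e-6, 0, 2, 1e6, -5, 1.4e-3), 0)
  # saturation: Q -> N M dH V0 (in ucal)
  qsat <- total_heat_one_set(30e-6, 1, 2, 1e6, -5, 1.4e-3)
  expect_equal(qsat, 2 * 30e-6 * -5 * 1.4e-3 * 1e9, tolerance = 1e-3)
  expect_error(total_heat_one_set(30e-6, 1e-5, -1, 1e6, -5, 1.4e-3),
               "non-physical")
})

test_that("sequential free-ligand solver agrees with a brute-force oracle", {
  K1 <- 7.57e5; K2 <- 1.70e4
  # brute force: golden-section-free dense grid + local refinement
  brute <- function(M_t, L_t) {
    f <- function(L) L + M_t * (K1 * L + 2 * K1 * K2 * L^2) /
      (1 + K1 * L + K1 * K2 * L^2) - L_t
    grid <- seq(0, L_t, length.out = 20001)
    i <- which.min(abs(f(grid)))
    lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
    stats::uniroot(f, c(lo, hi), tol = 1e-18)$root
  }
  set.seed(42)
  for (rep in 1:5) {
    M_t <- stats::runif(1, 1e-6, 5e-5)
    L_t <- stats::runif(1, 1e-6, 2e-4)
    L <- free_ligand_sequential(M_t, L_t, K1, K2)
    expect_equal(L, brute(M_t, L_t), tolerance = 1e-9)
    # mass-balance residual
    P <- 1 + K1 * L + K1 * K2 * L^2
    res <- L + M_t * (K1 * L + 2 * K1 * K2 * L^2) / P - L_t
    expect_lt(abs(res), 1e-12 * L_t)
  }
  # reductions
  expect_equal(free_ligand_sequential(0, 1e-4, K1, K2), 1e-4)
  # K2 = 0 reduces to the single-site quadratic closed form
  M_t <- 3e-5; L_t <- 6e-5; K <- 5e5
  b <- M_t + 1 / K - L_t
  Lq <- (-b + sqrt(b^2 + 4 * L_t / K)) / 2
  expect_equal(free_ligand_sequential(M_t, L_t, K, 0), Lq,
               tolerance = 1e-10)
})

test_that("sequential heat limits and statistical-factor equivalence hold", {
  expect_equal(total_heat_sequential(3e-5, 0, 1e5, -5, 1e4, -3, 1.4e-3), 0)
  qsat <- total_heat_sequential(3e-5, 10, 1e5, -5, 1e4, -3, 1.4e-3)
  expect_equal(qsat, 3e-5 * 1.4e-3 * (-8) * 1e9, tolerance = 1e-3)

  # one-set (N = 2, k) == sequential (2k, k/2) with equal dH: the
  # independent oracle linking the two isotherm models, on a dense grid
  k <- 8.92e5; dH <- -5.02; V0 <- 1.4e-3
  M_grid <- seq(5e-6, 5e-5, length.out = 12)
  L_grid <- seq(1e-7, 2e-4, length.out = 15)
  for (M_t in M_grid) {
    Lf <- free_ligand_sequential(M_t, L_grid, 2 * k, k / 2)
    q_seq <- total_heat_sequential(M_t, Lf, 2 * k, dH, k / 2, dH, V0)
    q_one <- total_heat_one_set(M_t, L_grid, 2, k, dH, V0)
    expect_lt(max(abs(q_seq - q_one) / pmax(abs(q_one), 1e-9)), 1e-9)
  }
})

test_that("per-injection heats apply the displacement correction", {
  Q <- c(10, 18, 24)
  dV <- rep(0, 3)
  expect_equal(heat_per_injection(Q, dV, 1.4e-3), c(10, 8, 6))
  # constant Q -> dQ_i = (dV_i/V0) Q
  Qc <- rep(100, 4); dV <- rep(1e-5, 4)
  expect_equal(heat_per_injection(Qc, dV, 1.4e-3),
               c(100 + (1e-5 / 1.4e-3) * 50,
                 rep((1e-5 / 1.4e-3) * 100, 3)))
  expect_error(heat_per_injection(Q, rep(0, 2), 1.4e-3), "mismatch")
})

test_that("heat is conserved in the small-injection limit", {
  model <- cam_one_set()
  totals <- vapply(c(20, 80, 320), function(n) {
    sched <- titration_schedule(cell_conc_M = 30e-6, syringe_conc_M = 1e-3,
                                injection_volumes_L = rep(2e-4 / n, n))
    sum(model_heats(sched, model))
  }, numeric(1))
  # converges as injections shrink (volume-displacement term -> integral)
  expect_lt(abs(totals[3] - totals[2]), abs(totals[2] - totals[1]))
  expect_lt(abs(totals[3] - totals[2]) / abs(totals[3]), 0.01)
})

test_that("dilution correction subtracts the blank elementwise", {
  sched <- ref_schedule(10)
  tg <- thermogram(model_heats(sched, cam_one_set()), sched)
  zero <- thermogram(rep(0, 10), sched)
  expect_equal(dilution_correct(tg, zero)$heats_ucal, tg$heats_ucal)
  const <- thermogram(rep(-0.5, 10), sched)
  expect_equal(dilution_correct(tg, const)$heats_ucal, tg$heats_ucal + 0.5)
  expect_true(dilution_correct(tg, const)$corrected)
  other <- titration_schedule(cell_conc_M = 30e-6, syringe_conc_M = 1e-3,
                              injection_volumes_L = rep(5e-6, 10))
  expect_error(dilution_correct(tg, thermogram(rep(0, 10), other)),
               "schedules differ")
})

test_that("noiseless isotherm round trips recover the generating values", {
  sched <- ref_schedule(20)
  truth <- cam_one_set()
  tg <- thermogram(model_heats(sched, truth), sched)
  fit <- fit_isotherm(tg, "one_set_of_sites")
  expect_rel(fit$model$N, truth$N, 1e-4)
  expect_rel(fit$model$K_a, truth$K_a, 1e-4)
  expect_rel(fit$model$dH, truth$dH, 1e-4)

  truth2 <- cam1tnc_sequential()
  tg2 <- thermogram(model_heats(sched, truth2), sched)
  fit2 <- fit_isotherm(tg2, "sequential_two_site")
  expect_rel(fit2$model$K_a1, 7.57e5, 1e-4)
  expect_rel(fit2$model$K_a2, 1.70e4, 1e-4)
  expect_gte(fit2$model$K_a1, fit2$model$K_a2)

  # weak-binding regime (low c, incomplete saturation)
  weak_sched <- titration_schedule(cell_conc_M = 50e-6,
                                   syringe_conc_M = 5e-3,
                                   injection_volumes_L = rep(10e-6, 25))
  weak <- binding_model("one_set_of_sites", N = 5, K_a = 2.10e3, dH = -1.5)
  tg3 <- thermogram(model_heats(weak_sched, weak), weak_sched)
  fit3 <- suppressWarnings(fit_isotherm(tg3, "one_set_of_sites"))
  expect_rel(fit3$model$K_a, 2.10e3, 0.05)
})

test_that("isotherm confidence intervals roughly cover under noise", {
  sched <- ref_schedule(20)
  truth <- cam_one_set()
  mu <- model_heats(sched, truth)
  set.seed(11)
  hits <- 0L; nrep <- 40L
  for (r in seq_len(nrep)) {
    tg <- thermogram(mu + stats::rnorm(20, 0, 0.5), sched)
    fit <- suppressWarnings(fit_isotherm(tg, "one_set_of_sites"))
    ci <- fit$model$K_a + c(-1.96, 1.96) * fit$se["K_a"]
    if (truth$K_a >= ci[1] && truth$K_a <= ci[2]) hits <- hits + 1L
  }
  # ~95% nominal; allow wide binomial slack at 40 replicates
  expect_gte(hits / nrep, 0.80)
})

test_that("buffer ionization decomposition separates dH_b and n", {
  # two buffers, exact linear solve
  d <- buffer_ionization_decompose(dH_app = c(-5, -16), dH_i = c(0, -11))
  expect_equal(d$n, 1, tolerance = 1e-12)
  expect_equal(d$dH_b, -5, tolerance = 1e-12)
  # identical dH_app across buffers -> no protonation
  d0 <- buffer_ionization_decompose(dH_app = c(-5.0, -5.0, -5.0),
                                    dH_i = c(0, -4.9, -11.3))
  expect_equal(d0$n, 0, tolerance = 1e-12)
  expect_equal(d0$dH_b, -5.0, tolerance = 1e-12)
  # noisy three-buffer case matches closed-form OLS
  x <- c(0, -4.9, -11.3); y <- c(-5.1, -9.8, -16.4)
  d3 <- buffer_ionization_decompose(y, x)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(d3$n, beta, tolerance = 1e-12)
  expect_equal(d3$dH_b, mean(y) - beta * mean(x), tolerance = 1e-12)
  expect_error(buffer_ionization_decompose(c(-5, -6), c(1, 1)),
               "underdetermined")
})

test_that("thermodynamic linkage derives dG and dS consistently", {
  # published CaM/peptide affinity and enthalpy give dS of about +10
  ts <- thermo_derive(8.92e5, -5.02, 298.15)
  expect_equal(round(ts$dS_cal), 10)
  # identity dG = dH - T dS holds exactly
  expect_equal(ts$dG_kcal, ts$dH_kcal - ts$T_K * ts$dS_cal / 1000,
               tolerance = 1e-12)
  t1 <- thermo_derive(1, -3, 310)
  expect_equal(t1$dG_kcal, 0)
  expect_equal(t1$dS_cal, -3000 / 310)
  expect_error(thermo_derive(-1, 0, 298), "K_a")
})
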