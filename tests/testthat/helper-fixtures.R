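# Shared ground-truth fixtures, built in code.

# Reference CaM/peptide titration: 30 uM cell, 1 mM syringe, 10 uL shots.
ref_schedule <- function(n_inj = 20) {
  titration_schedule(cell_conc_M = 30e-6, syringe_conc_M = 1e-3,
                     injection_volumes_L = rep(10e-6, n_inj))
}

# Published fitted parameters used as simulation ground truth.
cam_one_set <- function() {
  binding_model("one_set_of_sites", N = 2.05, K_a = 8.92e5, dH = -5.02)
}
cam1tnc_sequential <- function() {
  binding_model("sequential_two_site", K_a1 = 7.57e5, dH1 = -4.99,
                K_a2 = 1.70e4, dH2 = -3.33)
}

# Bound-ANS decay components (fractional intensities 0.44/0.53 at 6.4 and
# 13.1 ns) plus the ~0.3 ns free-dye component carrying the remaining 3%
# of the intensity; amplitudes alpha_i are proportional to f_i / tau_i.
ans_three_exp <- function() {
  f <- c(0.03, 0.44, 0.53)
  tau <- c(0.3, 6.4, 13.1)
  multiexp_model(alpha = f / tau, tau_ns = tau)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / abs(expected)), tol)
}
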