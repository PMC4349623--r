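#' Simulation configuration with instrument defaults
#'
#' Collects the instrument descriptors and per-modality noise levels used by
#' the simulators. Defaults mirror a VP-ITC / TCSPC / stopped-flow bench:
#' 4000-channel, 200 ns decay window accumulated to 10,000 peak counts with
#' a 1 ns FWHM prompt; 0.2 ucal heat noise with a constant -0.5 ucal
#' dilution blank; 2 ms kinetic sampling.
#'
#' @param seed Integer seed; every simulator draws from one generator seeded
#'   here (no global state is consulted when a seed is passed explicitly).
#' @param heat_noise_ucal Gaussian per-injection heat noise SD, ucal.
#' @param dilution_heat_ucal Constant titrant-dilution heat per injection,
#'   ucal.
#' @param trace_noise_frac Stopped-flow noise SD as fraction of amplitude.
#' @param spectral_noise_frac Spectral noise SD as fraction of the peak.
#' @param channels,window_ns,peak_counts,irf_fwhm_ns TCSPC descriptors.
#' @param dt_s Kinetic sampling interval, s (2 or 5 ms typical).
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              heat_noise_ucal = 0.2,
                              dilution_heat_ucal = -0.5,
                              trace_noise_frac = 0.02,
                              spectral_noise_frac = 0.02,
                              channels = 4000L,
                              window_ns = 200,
                              peak_counts = 10000L,
                              irf_fwhm_ns = 1.0,
                              dt_s = 0.002) {
  stopifnot(heat_noise_ucal >= 0, trace_noise_frac >= 0,
            spectral_noise_frac >= 0, channels >= 2, window_ns > 0,
            peak_counts >= 1, irf_fwhm_ns >= 0, dt_s > 0)
  structure(as.list(environment()), class = "simulation_config")
}

# Local RNG: runs `expr` under a private seeded stream, leaving the caller's
# RNG state untouched.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate an ITC titration with matched dilution blank
#'
#' Per-injection heats are the exact model heats from the isotherm forward
#' model plus independent Gaussian noise; the matched blank contains only a
#' constant titrant-dilution heat per injection (plus noise). The raw sample
#' thermogram includes the same dilution heat, so that
#' [dilution_correct()]ing sample by blank recovers the model heats in
#' expectation.
#'
#' @param schedule A [titration_schedule()].
#' @param model A [binding_model()].
#' @param noise_sd_ucal Gaussian heat noise SD, ucal (0 = exact heats).
#' @param dilution_heat_ucal Constant dilution heat per injection, ucal.
#' @param seed Integer seed (NULL = use the current RNG state).
#' @return List with `sample` and `blank` [thermogram()]s and the
#'   ground-truth `model`.
#' @export
simulate_itc <- function(schedule, model, noise_sd_ucal = 0.2,
                         dilution_heat_ucal = -0.5, seed = NULL) {
  stopifnot(inherits(schedule, "titration_schedule"),
            inherits(model, "binding_model"), noise_sd_ucal >= 0)
  mu <- model_heats(schedule, model)
  n <- length(mu)
  .with_seed(seed, {
    eps_s <- stats::rnorm(n, 0, noise_sd_ucal)
    eps_b <- stats::rnorm(n, 0, noise_sd_ucal)
    list(sample = thermogram(mu + dilution_heat_ucal + eps_s, schedule),
         blank = thermogram(rep(dilution_heat_ucal, n) + eps_b, schedule),
         model = model)
  })
}

#' Gaussian prompt (IRF) histogram
#'
#' Narrow Gaussian instrument response centered, by default, 10% into the
#' time window (plausible for a pulsed-LED source), discretized on the same
#' channel grid as the decay.
#'
#' @param channels Channel count.
#' @param window_ns Window, ns.
#' @param fwhm_ns Prompt full width at half maximum, ns.
#' @param center_ns Prompt center, ns (default `0.1 * window_ns`).
#' @param peak_counts Counts in the maximum channel.
#' @return A [decay_histogram()].
#' @export
gaussian_irf <- function(channels, window_ns, fwhm_ns = 1.0,
                         center_ns = 0.1 * window_ns,
                         peak_counts = 10000) {
  stopifnot(channels >= 2, window_ns > 0, fwhm_ns >= 0)
  dt <- window_ns / channels
  t <- (seq_len(channels) - 0.5) * dt
  if (fwhm_ns == 0) {
    y <- numeric(channels)
    y[max(1, round(center_ns / dt + 0.5))] <- peak_counts
  } else {
    sd <- fwhm_ns / (2 * sqrt(2 * log(2)))
    y <- exp(-(t - center_ns)^2 / (2 * sd^2))
    y <- round(y / max(y) * peak_counts)
  }
  decay_histogram(y, window_ns)
}

#' Simulate a TCSPC decay histogram with its prompt
#'
#' Expected counts are the IRF-convolved decay model scaled so the maximum
#' expected channel equals `peak_counts`; observed counts are Poisson draws
#' (or the expectation itself with `expectation_only = TRUE`). The prompt is
#' returned alongside for reconvolution fitting.
#'
#' @param model A [multiexp_model()] (amplitudes set the component
#'   proportions; absolute scale is fixed by `peak_counts`).
#' @param irf_fwhm_ns Prompt FWHM, ns (0 gives a delta prompt in the first
#'   channel so the expectation equals the model on the channel grid).
#' @param window_ns Time window, ns.
#' @param channels Channel count.
#' @param peak_counts Target counts in the peak channel.
#' @param seed Integer seed.
#' @param expectation_only Skip the Poisson draw (noiseless mode).
#' @param irf_center_ns Prompt center; defaults to 10% into the window (or
#'   channel 1 for a delta prompt).
#' @return List with `decay` and `irf` [decay_histogram()]s, the scaled
#'   ground-truth `model`, and `expected` counts.
#' @export
simulate_decay <- function(model, irf_fwhm_ns = 1.0, window_ns = 200,
                           channels = 4000, peak_counts = 10000,
                           seed = NULL, expectation_only = FALSE,
                           irf_center_ns = NULL) {
  stopifnot(inherits(model, "multiexp_model"), channels >= 2,
            peak_counts >= 1)
  if (window_ns < max(model$tau_ns))
    warning("window shorter than the longest lifetime: truncation bias")
  dt <- window_ns / channels
  if (is.null(irf_center_ns))
    irf_center_ns <- if (irf_fwhm_ns == 0) 0.5 * dt else 0.1 * window_ns
  irf <- gaussian_irf(channels, window_ns, fwhm_ns = irf_fwhm_ns,
                      center_ns = irf_center_ns)
  shape <- convolve_irf(multiexp_model(model$alpha, model$tau_ns,
                                       baseline = 0), irf)
  scale <- (peak_counts - model$baseline) / max(shape)
  # FFT convolution can leave O(eps) negative values; expectations are counts
  expected <- pmax(shape * scale + model$baseline, 0)
  scaled <- multiexp_model(model$alpha * scale, model$tau_ns,
                           baseline = model$baseline)
  counts <- if (expectation_only) expected else
    .with_seed(seed, stats::rpois(channels, expected))
  list(decay = decay_histogram(counts, window_ns), irf = irf,
       model = scaled, expected = expected)
}

#' Simulate a Stern-Volmer quench series
#'
#' Responses follow `F = F0 / (1 + K_sv [Q])` (identically for lifetimes)
#' with multiplicative Gaussian noise.
#'
#' @param baseline Unquenched response(s) F0 or tau0 (> 0); a vector gives
#'   one response column per component.
#' @param K_sv Stern-Volmer constant(s), 1/M (recycled across components).
#' @param q_grid_M Quencher concentrations, M (non-negative, sorted;
#'   default 0-0.3 M in 7 steps).
#' @param noise_frac Multiplicative noise SD as a fraction of the response.
#' @param quencher Quencher label.
#' @param seed Integer seed.
#' @return A [quench_series()].
#' @export
simulate_quench_series <- function(baseline, K_sv,
                                   q_grid_M = seq(0, 0.3, length.out = 7),
                                   noise_frac = 0, quencher = "acrylamide",
                                   seed = NULL) {
  stopifnot(all(baseline > 0), all(K_sv >= 0), all(q_grid_M >= 0),
            !is.unsorted(q_grid_M), noise_frac >= 0)
  K_sv <- rep_len(K_sv, length(baseline))
  mu <- sapply(seq_along(baseline), function(j)
    baseline[j] / (1 + K_sv[j] * q_grid_M))
  mu <- matrix(mu, nrow = length(q_grid_M))
  resp <- .with_seed(seed,
    mu * matrix(stats::rnorm(length(mu), 1, noise_frac), nrow = nrow(mu)))
  quench_series(q_grid_M, resp, quencher = quencher, reference = baseline)
}

#' Simulate a stopped-flow dissociation trace
#'
#' `F(t) = offset + amplitude * exp(-k_off t)` on a uniform grid, with
#' additive Gaussian noise scaled to the amplitude.
#'
#' @param k_off Dissociation rate constant, 1/s (> 0).
#' @param amplitude Decay amplitude (0 gives a flat trace).
#' @param offset Fluorescence offset.
#' @param duration_s Trace length, s.
#' @param dt_s Sampling interval, s (2 or 5 ms typical).
#' @param noise_frac Noise SD as a fraction of `amplitude` (of `offset` when
#'   the amplitude is 0).
#' @param seed Integer seed.
#' @return A [stopped_flow_trace()].
#' @export
simulate_stopped_flow <- function(k_off, amplitude = 1, offset = 0.2,
                                  duration_s = 2, dt_s = 0.002,
                                  noise_frac = 0, seed = NULL) {
  stopifnot(k_off > 0, duration_s > 0, dt_s > 0, noise_frac >= 0)
  if (duration_s < 3 / k_off)
    warning("duration < 3/k_off: rate constant poorly identifiable")
  t <- seq(0, duration_s, by = dt_s)
  mu <- offset + amplitude * exp(-k_off * t)
  sd0 <- noise_frac * if (amplitude != 0) abs(amplitude) else abs(offset)
  y <- .with_seed(seed, mu + stats::rnorm(length(t), 0, sd0))
  stopped_flow_trace(t, y, meta = list(k_off_true = k_off))
}

#' Simulate an emission or CD spectrum
#'
#' Emission mode: a sum of Gaussian bands `amplitude * exp(-(l-center)^2 /
#' (2 width^2))` plus noise. CD mode: a mixture of synthetic helix and coil
#' basis curves, mixed so the resulting theta220/theta209 ratio equals
#' `target_ratio` exactly in the noiseless case; the pure helix basis is
#' calibrated to the canonical all-helix ratio 1.09.
#'
#' @param bands List of `c(center_nm, width_nm, amplitude)` triples
#'   (emission mode). An empty list yields a zero spectrum with a warning.
#' @param grid_nm Strictly increasing wavelength grid, nm.
#' @param noise_frac Noise SD as a fraction of the absolute peak signal.
#' @param kind `"emission"` or `"cd"`.
#' @param target_ratio CD mode: desired theta220/theta209 ratio.
#' @param scale Overall multiplicative scale.
#' @param seed Integer seed.
#' @return A [spectrum()].
#' @export
simulate_spectrum <- function(bands = list(), grid_nm = seq(400, 650, by = 1),
                              noise_frac = 0, kind = c("emission", "cd"),
                              target_ratio = 1.09, scale = 1, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(all(diff(grid_nm) > 0), noise_frac >= 0)
  if (kind == "emission") {
    if (length(bands) == 0) {
      warning("empty band list: returning a zero spectrum")
      mu <- numeric(length(grid_nm))
    } else {
      mu <- Reduce(`+`, lapply(bands, function(b)
        b[3] * exp(-(grid_nm - b[1])^2 / (2 * b[2]^2))))
    }
  } else {
    mu <- .cd_mixture(grid_nm, target_ratio)
  }
  mu <- mu * scale
  peak <- max(abs(mu), .Machine$double.eps)
  y <- .with_seed(seed, mu + stats::rnorm(length(mu), 0, noise_frac * peak))
  spectrum(grid_nm, y, kind = kind,
           meta = if (kind == "cd") list(target_ratio = target_ratio)
           else list())
}

# Synthetic far-UV CD bases. The helix basis is a positive ~193 nm band and
# two negative bands near 208 and 222 nm, with the 222-band amplitude solved
# so theta(220)/theta(209) = 1.09 exactly (the canonical all-helix value).
# The coil basis has a deep negative band at 198 nm and a weak positive
# shoulder, giving a small ratio.
.cd_gauss <- function(wl, c0, s) exp(-(wl - c0)^2 / (2 * s^2))
.cd_helix_basis <- function(grid_nm) {
  g193 <- function(wl) 2.0 * .cd_gauss(wl, 193, 6)
  g208 <- function(wl) -1.0 * .cd_gauss(wl, 208, 5.5)
  g222 <- function(wl) -.cd_gauss(wl, 222, 6.5)
  # solve amplitude a of the 222 band so that s(220) = 1.09 * s(209)
  r <- 1.09
  base220 <- g193(220) + g208(220); w220 <- -.cd_gauss(220, 222, 6.5)
  base209 <- g193(209) + g208(209); w209 <- -.cd_gauss(209, 222, 6.5)
  a <- (r * base209 - base220) / (w220 - r * w209)
  g193(grid_nm) + g208(grid_nm) + a * (-.cd_gauss(grid_nm, 222, 6.5))
}
.cd_coil_basis <- function(grid_nm) {
  -2.5 * .cd_gauss(grid_nm, 198, 7) + 0.15 * .cd_gauss(grid_nm, 218, 8)
}
.cd_mixture <- function(grid_nm, target_ratio) {
  h <- .cd_helix_basis(grid_nm)
  cl <- .cd_coil_basis(grid_nm)
  at <- function(y, x0) stats::approx(grid_nm, y, xout = x0)$y
  # solve w in s = w h + (1-w) c with s(220)/s(209) = target
  num <- target_ratio * at(cl, 209) - at(cl, 220)
  den <- (at(h, 220) - at(cl, 220)) - target_ratio * (at(h, 209) - at(cl, 209))
  w <- num / den
  w * h + (1 - w) * cl
}
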