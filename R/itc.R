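# Gas constant, cal/(mol K). All enthalpies are kcal/mol, heats ucal,
# concentrations M, volumes L, temperatures K.
.R_CAL <- 1.9872
.UCAL_PER_KCAL <- 1e9

#' Define an ITC titration schedule
#'
#' Describes a perfusion-cell titration: cell volume and pre-titration
#' macromolecule concentration, syringe (titrant) concentration, and the
#' sequence of injection volumes. Typical experiments inject 5--10 uL every
#' 2--3 minutes at 25 degrees C.
#'
#' @param cell_volume_L Active cell volume in litres (default 1.4e-3,
#'   a typical VP-ITC cell).
#' @param cell_conc_M Macromolecule concentration in the cell before the
#'   first injection, mol/L.
#' @param syringe_conc_M Titrant concentration in the syringe, mol/L.
#' @param injection_volumes_L Numeric vector of per-injection volumes, litres.
#' @param temperature_K Experiment temperature, kelvin (default 298.15).
#' @return An object of class `titration_schedule`.
#' @examples
#' titration_schedule(cell_conc_M = 30e-6, syringe_conc_M = 1e-3,
#'                    injection_volumes_L = rep(10e-6, 20))
#' @export
titration_schedule <- function(cell_volume_L = 1.4e-3,
                               cell_conc_M,
                               syringe_conc_M,
                               injection_volumes_L,
                               temperature_K = 298.15) {
  stopifnot(is.numeric(cell_volume_L), length(cell_volume_L) == 1L,
            cell_volume_L > 0,
            is.numeric(cell_conc_M), cell_conc_M > 0,
            is.numeric(syringe_conc_M), syringe_conc_M > 0,
            is.numeric(injection_volumes_L), length(injection_volumes_L) >= 1L,
            all(injection_volumes_L > 0),
            is.numeric(temperature_K), temperature_K > 0)
  if (sum(injection_volumes_L) > 0.2 * cell_volume_L)
    warning("cumulative injected volume exceeds 20% of the cell volume; ",
            "displacement correction becomes inaccurate")
  structure(list(cell_volume_L = cell_volume_L,
                 cell_conc_M = cell_conc_M,
                 syringe_conc_M = syringe_conc_M,
                 injection_volumes_L = as.numeric(injection_volumes_L),
                 temperature_K = temperature_K),
            class = "titration_schedule")
}

#' @export
print.titration_schedule <- function(x, ...) {
  cat("ITC titration schedule\n")
  cat(sprintf("  cell: %.4g mL at %.4g uM, syringe %.4g uM, T = %.2f K\n",
              x$cell_volume_L * 1e3, x$cell_conc_M * 1e6,
              x$syringe_conc_M * 1e6, x$temperature_K))
  cat(sprintf("  %d injections, total %.1f uL\n",
              length(x$injection_volumes_L),
              sum(x$injection_volumes_L) * 1e6))
  invisible(x)
}

#' Define a binding-isotherm parameter set
#'
#' Two isotherm models are supported: `"one_set_of_sites"` (N identical,
#' independent sites per macromolecule, parameters N, K_a, dH) and
#' `"sequential_two_site"` (ordered macroscopic steps with K_a1 >= K_a2 by
#' convention, parameters K_a1, dH1, K_a2, dH2).
#'
#' @param kind `"one_set_of_sites"` or `"sequential_two_site"`.
#' @param N Sites per macromolecule (one-set model).
#' @param K_a Association constant, 1/M (one-set model).
#' @param dH Binding enthalpy, kcal/mol of ligand (one-set model).
#' @param K_a1,K_a2 Macroscopic association constants, 1/M (sequential model).
#' @param dH1,dH2 Stepwise enthalpies, kcal/mol (sequential model).
#' @return An object of class `binding_model`.
#' @examples
#' binding_model("one_set_of_sites", N = 2.05, K_a = 8.92e5, dH = -5.02)
#' binding_model("sequential_two_site", K_a1 = 7.57e5, dH1 = -4.99,
#'               K_a2 = 1.70e4, dH2 = -3.33)
#' @export
binding_model <- function(kind = c("one_set_of_sites", "sequential_two_site"),
                          N = NULL, K_a = NULL, dH = NULL,
                          K_a1 = NULL, dH1 = NULL, K_a2 = NULL, dH2 = NULL) {
  kind <- match.arg(kind)
  if (kind == "one_set_of_sites") {
    if (is.null(N) || is.null(K_a) || is.null(dH))
      stop("one_set_of_sites requires N, K_a and dH")
    if (N <= 0 || K_a <= 0)
      stop("non-physical parameters: N and K_a must be > 0")
    out <- list(kind = kind, N = N, K_a = K_a, dH = dH)
  } else {
    if (is.null(K_a1) || is.null(dH1) || is.null(K_a2) || is.null(dH2))
      stop("sequential_two_site requires K_a1, dH1, K_a2 and dH2")
    if (K_a1 <= 0 || K_a2 <= 0)
      stop("non-physical parameters: association constants must be > 0")
    if (K_a1 < K_a2)
      stop("label convention violated: K_a1 must be >= K_a2")
    out <- list(kind = kind, K_a1 = K_a1, dH1 = dH1, K_a2 = K_a2, dH2 = dH2)
  }
  structure(out, class = "binding_model")
}

#' @export
print.binding_model <- function(x, ...) {
  if (x$kind == "one_set_of_sites") {
    cat(sprintf("Binding model: one set of sites\n  N = %.3g, K_a = %.3g 1/M, dH = %.3g kcal/mol\n",
                x$N, x$K_a, x$dH))
  } else {
    cat(sprintf("Binding model: sequential two-site\n  K_a1 = %.3g 1/M (dH1 = %.3g), K_a2 = %.3g 1/M (dH2 = %.3g kcal/mol)\n",
                x$K_a1, x$dH1, x$K_a2, x$dH2))
  }
  invisible(x)
}

#' Cell concentrations after the i-th injection
#'
#' MicroCal-style perfusion (overfill) bookkeeping: injecting displaces an
#' equal volume of the cell content. With `v` the cumulative injected volume
#' through injection `i` and `V0` the cell volume, the macromolecule and
#' titrant concentrations in the active volume are
#' `M_t = M0 (1 - v/2V0) / (1 + v/2V0)` and
#' `L_t = L_syr (v/V0) / (1 + v/2V0)`.
#'
#' @param schedule A [titration_schedule()].
#' @param i Injection index (1-based); `i = 0` returns the pre-titration state.
#' @return Named list with `M_t` and `L_t` (mol/L).
#' @export
concentrations_after_injection <- function(schedule, i) {
  stopifnot(inherits(schedule, "titration_schedule"))
  n <- length(schedule$injection_volumes_L)
  if (i < 0 || i > n) stop("injection index out of range: ", i)
  v <- if (i == 0) 0 else sum(schedule$injection_volumes_L[seq_len(i)])
  V0 <- schedule$cell_volume_L
  d <- 1 + v / (2 * V0)
  list(M_t = schedule$cell_conc_M * (1 - v / (2 * V0)) / d,
       L_t = schedule$syringe_conc_M * (v / V0) / d)
}

#' Total heat content for the identical-sites isotherm
#'
#' Closed-form root of the single-site-class binding quadratic. With
#' `X = 1 + L_t/(N M_t) + 1/(N K_a M_t)`, the heat content of the cell is
#' `Q = (N M_t dH V0 / 2) * (X - sqrt(X^2 - 4 L_t/(N M_t)))` (converted to
#' ucal). A numerically negative discriminant is clamped at zero.
#'
#' @param M_t Macromolecule concentration, M.
#' @param L_t Total ligand concentration, M. Vectorized over `M_t`/`L_t`.
#' @param N Sites per macromolecule.
#' @param K_a Association constant, 1/M.
#' @param dH Enthalpy, kcal/mol.
#' @param V0 Cell volume, L.
#' @return Heat content Q in ucal.
#' @export
total_heat_one_set <- function(M_t, L_t, N, K_a, dH, V0) {
  if (N <= 0 || K_a <= 0 || V0 <= 0)
    stop("non-physical parameters in total_heat_one_set")
  X <- 1 + L_t / (N * M_t) + 1 / (N * K_a * M_t)
  disc <- X^2 - 4 * L_t / (N * M_t)
  disc[disc < 0] <- 0
  (N * M_t * dH * V0 / 2) * (X - sqrt(disc)) * .UCAL_PER_KCAL
}

#' Free-ligand concentration for the sequential two-site model
#'
#' Solves the mass balance
#' `L_t = L + M_t (K1 L + 2 K1 K2 L^2) / (1 + K1 L + K1 K2 L^2)` for the free
#' ligand L by safeguarded bisection/Newton on `[0, L_t]`; the left-hand side
#' is strictly increasing in L so the root is unique. The returned root has
#' mass-balance residual below `1e-12 * max(L_t, 1e-12)`.
#'
#' @param M_t Macromolecule concentration, M.
#' @param L_t Total ligand concentration, M. Vectorized.
#' @param K_a1,K_a2 Macroscopic association constants, 1/M.
#' @return Free-ligand concentration, M.
#' @export
free_ligand_sequential <- function(M_t, L_t, K_a1, K_a2) {
  if (K_a1 <= 0 || K_a2 < 0) stop("association constants must be positive")
  n <- max(length(M_t), length(L_t))
  M_t <- rep_len(M_t, n); L_t <- rep_len(L_t, n)
  vapply(seq_len(n), function(j) {
    .free_ligand_seq_1(M_t[j], L_t[j], K_a1, K_a2)
  }, numeric(1))
}

.seq_bound <- function(L, M_t, K1, K2) {
  # ligand bound per litre at free ligand L
  P <- 1 + K1 * L + K1 * K2 * L^2
  M_t * (K1 * L + 2 * K1 * K2 * L^2) / P
}

.free_ligand_seq_1 <- function(M_t, L_t, K1, K2) {
  if (L_t <= 0) return(0)
  if (M_t <= 0) return(L_t)
  f <- function(L) L + .seq_bound(L, M_t, K1, K2) - L_t
  lo <- 0; hi <- L_t
  tol <- 1e-12 * max(L_t, 1e-12)
  # bisection to get close, then Newton polish
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol) { lo <- hi <- mid; break }
    if (fm > 0) hi <- mid else lo <- mid
    if (hi - lo < .Machine$double.eps * max(L_t, 1e-300)) break
  }
  L <- (lo + hi) / 2
  # Newton refinement with analytic derivative
  for (it in 1:50) {
    P <- 1 + K1 * L + K1 * K2 * L^2
    dP <- K1 + 2 * K1 * K2 * L
    num <- K1 * L + 2 * K1 * K2 * L^2
    dnum <- K1 + 4 * K1 * K2 * L
    fL <- L + M_t * num / P - L_t
    dfL <- 1 + M_t * (dnum * P - num * dP) / P^2
    step <- fL / dfL
    Lnew <- L - step
    if (Lnew < 0 || Lnew > L_t) break
    L <- Lnew
    if (abs(fL) < tol) break
  }
  if (abs(f(L)) > tol * 10)
    stop("free-ligand solver failed to reach residual tolerance")
  L
}

#' Total heat content for the sequential two-site isotherm
#'
#' With binding polynomial `P = 1 + K1 L + K1 K2 L^2` and species fractions
#' `F1 = K1 L / P`, `F2 = K1 K2 L^2 / P`, the cell heat content is
#' `Q = M_t V0 (F1 dH1 + F2 (dH1 + dH2))` in ucal.
#'
#' @param M_t Macromolecule concentration, M.
#' @param L_free Free-ligand concentration from [free_ligand_sequential()], M.
#' @param K_a1,K_a2 Macroscopic association constants, 1/M.
#' @param dH1,dH2 Stepwise enthalpies, kcal/mol.
#' @param V0 Cell volume, L.
#' @return Heat content Q in ucal.
#' @export
total_heat_sequential <- function(M_t, L_free, K_a1, dH1, K_a2, dH2, V0) {
  if (K_a1 <= 0 || K_a2 < 0 || V0 <= 0)
    stop("non-physical parameters in total_heat_sequential")
  P <- 1 + K_a1 * L_free + K_a1 * K_a2 * L_free^2
  F1 <- K_a1 * L_free / P
  F2 <- K_a1 * K_a2 * L_free^2 / P
  M_t * V0 * (F1 * dH1 + F2 * (dH1 + dH2)) * .UCAL_PER_KCAL
}

#' Per-injection heats from a total-heat series
#'
#' Converts the post-injection cell heat contents `Q_i` into observed
#' per-injection heats with the MicroCal displacement correction:
#' `dQ_i = Q_i - Q_(i-1) + (dV_i/V0) (Q_i + Q_(i-1))/2`, with `Q_0 = 0`.
#'
#' @param Q_series Heat contents after each injection, ucal.
#' @param injection_volumes_L Injection volumes, litres (same length).
#' @param V0 Cell volume, litres.
#' @return Per-injection heats, ucal.
#' @export
heat_per_injection <- function(Q_series, injection_volumes_L, V0) {
  if (length(Q_series) != length(injection_volumes_L))
    stop("Q_series and injection_volumes_L length mismatch")
  Qprev <- c(0, Q_series[-length(Q_series)])
  Q_series - Qprev + (injection_volumes_L / V0) * (Q_series + Qprev) / 2
}

#' Model per-injection heats for a schedule and binding model
#'
#' Forward model tying together the concentration bookkeeping, the isotherm
#' heat content, and the displacement correction; this is the curve the
#' fitter matches against the observed thermogram.
#'
#' @param schedule A [titration_schedule()].
#' @param model A [binding_model()].
#' @return Numeric vector of per-injection heats, ucal.
#' @export
model_heats <- function(schedule, model) {
  stopifnot(inherits(schedule, "titration_schedule"),
            inherits(model, "binding_model"))
  n <- length(schedule$injection_volumes_L)
  conc <- lapply(seq_len(n), concentrations_after_injection,
                 schedule = schedule)
  M_t <- vapply(conc, `[[`, numeric(1), "M_t")
  L_t <- vapply(conc, `[[`, numeric(1), "L_t")
  V0 <- schedule$cell_volume_L
  Q <- if (model$kind == "one_set_of_sites") {
    total_heat_one_set(M_t, L_t, model$N, model$K_a, model$dH, V0)
  } else {
    L_free <- free_ligand_sequential(M_t, L_t, model$K_a1, model$K_a2)
    total_heat_sequential(M_t, L_free, model$K_a1, model$dH1,
                          model$K_a2, model$dH2, V0)
  }
  heat_per_injection(Q, schedule$injection_volumes_L, V0)
}

#' Construct a thermogram object
#'
#' @param heats_ucal Per-injection heats, ucal.
#' @param schedule The [titration_schedule()] that produced them.
#' @param corrected Logical; has a dilution blank been subtracted?
#' @return An object of class `thermogram` with heats, post-injection molar
#'   ratios (titrant/macromolecule) and the schedule.
#' @export
thermogram <- function(heats_ucal, schedule, corrected = FALSE) {
  stopifnot(inherits(schedule, "titration_schedule"))
  n <- length(schedule$injection_volumes_L)
  if (length(heats_ucal) != n)
    stop("heats length (", length(heats_ucal),
         ") does not match number of injections (", n, ")")
  conc <- lapply(seq_len(n), concentrations_after_injection,
                 schedule = schedule)
  ratio <- vapply(conc, function(x) x$L_t / x$M_t, numeric(1))
  if (any(diff(ratio) <= 0)) stop("molar ratios are not strictly increasing")
  structure(list(heats_ucal = as.numeric(heats_ucal),
                 molar_ratio = ratio,
                 schedule = schedule,
                 corrected = corrected),
            class = "thermogram")
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("Thermogram: %d injections, molar ratio %.3g-%.3g%s\n",
              length(x$heats_ucal), min(x$molar_ratio), max(x$molar_ratio),
              if (isTRUE(x$corrected)) " (dilution-corrected)" else ""))
  invisible(x)
}

#' Subtract a titrant-dilution blank from a thermogram
#'
#' The blank is a titration run with buffer only in the cell; its heats are
#' subtracted injection-by-injection. Schedules must have matching injection
#' counts and volumes.
#'
#' @param tg Sample [thermogram()].
#' @param blank Blank [thermogram()].
#' @return Corrected `thermogram` (with `corrected = TRUE`).
#' @export
dilution_correct <- function(tg, blank) {
  stopifnot(inherits(tg, "thermogram"), inherits(blank, "thermogram"))
  if (length(tg$heats_ucal) != length(blank$heats_ucal))
    stop("sample and blank have different injection counts")
  if (!isTRUE(all.equal(tg$schedule$injection_volumes_L,
                        blank$schedule$injection_volumes_L)))
    stop("sample and blank injection schedules differ")
  out <- tg
  out$heats_ucal <- tg$heats_ucal - blank$heats_ucal
  out$corrected <- TRUE
  out
}

#' Fit a binding isotherm to a thermogram
#'
#' Weighted nonlinear least squares of the model per-injection heats against
#' the observed thermogram, by Levenberg-Marquardt in transformed coordinates
#' (log K to enforce positivity; for the sequential model `K_a2 = K_a1 * r`
#' with `r <= 1`, which breaks label switching). Multi-start over a log-spaced
#' grid of association constants guards against local minima.
#'
#' @param tg A [thermogram()] (dilution-corrected).
#' @param model_kind `"one_set_of_sites"` or `"sequential_two_site"`.
#' @param initial_guess Optional `binding_model` used as an extra start.
#' @param exclude_first Drop the first injection (common ITC practice for
#'   syringe-diffusion artifacts). Default `FALSE`.
#' @param weights Optional per-injection weights (default uniform).
#' @return List of class `isotherm_fit` with elements `model` (fitted
#'   [binding_model()]), `se` (asymptotic standard errors on the natural
#'   scale), `residuals`, `rss`, `converged`, and `thermo`
#'   (derived [thermo_derive()] state(s)).
#' @export
fit_isotherm <- function(tg, model_kind = c("one_set_of_sites",
                                            "sequential_two_site"),
                         initial_guess = NULL, exclude_first = FALSE,
                         weights = NULL) {
  stopifnot(inherits(tg, "thermogram"))
  model_kind <- match.arg(model_kind)
  sched <- tg$schedule
  keep <- seq_along(tg$heats_ucal)
  if (exclude_first) keep <- keep[-1]
  if (length(keep) < 6)
    stop("need at least 6 informative injections to fit an isotherm")
  y <- tg$heats_ucal
  w <- if (is.null(weights)) rep(1, length(y)) else weights
  sw <- sqrt(w[keep])

  if (max(abs(y[keep]) ) < .Machine$double.eps)
    warning("flat isotherm: heats are all ~0; fit is unidentifiable")

  dH0 <- y[which.max(abs(y[1:min(3, length(y))]))] /
    (sched$injection_volumes_L[1] * sched$syringe_conc_M * .UCAL_PER_KCAL)
  if (!is.finite(dH0) || dH0 == 0) dH0 <- -5

  if (model_kind == "one_set_of_sites") {
    resid_fn <- function(p) {
      m <- binding_model("one_set_of_sites", N = exp(p[1]),
                         K_a = exp(p[2]), dH = p[3])
      sw * (model_heats(sched, m)[keep] - y[keep])
    }
    starts <- lapply(c(3, 4, 5, 6, 7), function(lk)
      c(log(2), lk * log(10), dH0))
    # N start from the molar ratio at the half-heat point
    half <- tg$molar_ratio[which.min(abs(cumsum(y) - sum(y) / 2))]
    starts <- c(starts, lapply(c(4, 5, 6), function(lk)
      c(log(max(half, 0.1)), lk * log(10), dH0)))
    if (!is.null(initial_guess))
      starts <- c(list(c(log(initial_guess$N), log(initial_guess$K_a),
                         initial_guess$dH)), starts)
    lower <- c(log(1e-3), log(1e-2), -Inf)
    upper <- c(log(1e3), log(1e12), Inf)
  } else {
    resid_fn <- function(p) {
      K1 <- exp(p[1]); r <- exp(p[2])
      m <- binding_model("sequential_two_site", K_a1 = K1, dH1 = p[3],
                         K_a2 = K1 * r, dH2 = p[4])
      sw * (model_heats(sched, m)[keep] - y[keep])
    }
    starts <- list()
    for (lk in c(4, 5, 6)) for (lr in c(-1, -2))
      starts <- c(starts, list(c(lk * log(10), lr * log(10), dH0, dH0)))
    if (!is.null(initial_guess))
      starts <- c(list(c(log(initial_guess$K_a1),
                         log(initial_guess$K_a2 / initial_guess$K_a1),
                         initial_guess$dH1, initial_guess$dH2)), starts)
    lower <- c(log(1e-2), log(1e-10), -Inf, -Inf)
    upper <- c(log(1e12), 0, Inf, Inf)
  }

  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best_rss - 1e-12 * max(best_rss, 1)) {
      best <- fit; best_rss <- rss
    }
  }
  if (is.null(best)) stop("isotherm fit failed from every start")

  p <- best$par
  nres <- length(keep); npar <- length(p)
  sigma2 <- sum(best$fvec^2) / max(nres - npar, 1)
  cov <- tryCatch(sigma2 * solve(best$hessian), error = function(e)
    matrix(NA_real_, npar, npar))
  pse <- sqrt(pmax(diag(cov), 0))

  converged <- best$info %in% 1:4
  if (!converged)
    warning("isotherm fit did not formally converge; ",
            "best-so-far parameters returned (flagged unreliable)")

  T <- sched$temperature_K
  if (model_kind == "one_set_of_sites") {
    m <- binding_model("one_set_of_sites", N = exp(p[1]), K_a = exp(p[2]),
                       dH = p[3])
    se <- c(N = exp(p[1]) * pse[1], K_a = exp(p[2]) * pse[2], dH = pse[3])
    thermo <- thermo_derive(m$K_a, m$dH, T)
    cval <- m$K_a * sched$cell_conc_M * m$N
    if (cval < 1 || cval > 1000)
      warning(sprintf("c-value %.3g outside the well-determined 1-1000 range",
                      cval))
  } else {
    K1 <- exp(p[1]); K2 <- K1 * exp(p[2])
    m <- binding_model("sequential_two_site", K_a1 = K1, dH1 = p[3],
                       K_a2 = K2, dH2 = p[4])
    # delta-method SEs: Var(log K2) = Var(p1) + Var(p2) + 2 Cov
    vlk2 <- cov[1, 1] + cov[2, 2] + 2 * cov[1, 2]
    se <- c(K_a1 = K1 * pse[1], dH1 = pse[3],
            K_a2 = K2 * sqrt(max(vlk2, 0)), dH2 = pse[4])
    thermo <- list(site1 = thermo_derive(K1, m$dH1, T),
                   site2 = thermo_derive(K2, m$dH2, T))
  }

  structure(list(model = m, se = se,
                 residuals = best$fvec / sw,
                 rss = sum(best$fvec^2),
                 converged = converged,
                 thermo = thermo,
                 n_used = nres),
            class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat("Isotherm fit (", x$model$kind, ")\n", sep = "")
  print(x$model)
  cat(sprintf("  RSS = %.4g ucal^2 over %d injections; converged: %s\n",
              x$rss, x$n_used, x$converged))
  invisible(x)
}

#' Decompose apparent enthalpies into binding and buffer-ionization terms
#'
#' Binding-linked proton exchange makes the apparent calorimetric enthalpy
#' buffer-dependent: `dH_app = dH_b + n * dH_i`, with `dH_i` the buffer
#' protonation (ionization) enthalpy and `n` the number of protons taken up
#' (positive = protonation). Ordinary least squares of `dH_app` on `dH_i`
#' gives slope `n` and intercept `dH_b`.
#'
#' @param dH_app Apparent enthalpies per buffer, kcal/mol.
#' @param dH_i Buffer ionization enthalpies, kcal/mol (same length, at least
#'   two distinct values).
#' @return List with `dH_b`, `n`, standard errors (NA with 2 buffers), and
#'   `residuals`.
#' @export
buffer_ionization_decompose <- function(dH_app, dH_i) {
  stopifnot(length(dH_app) == length(dH_i), length(dH_app) >= 2)
  if (diff(range(dH_i)) < .Machine$double.eps)
    stop("all buffer ionization enthalpies are equal: n is underdetermined")
  fit <- stats::lm(dH_app ~ dH_i)
  co <- stats::coef(fit)
  se <- tryCatch(suppressWarnings(sqrt(diag(stats::vcov(fit)))),
                 error = function(e) rep(NA_real_, 2))
  if (length(dH_app) == 2) se <- rep(NA_real_, 2)
  list(dH_b = unname(co[1]), n = unname(co[2]),
       se_dH_b = unname(se[1]), se_n = unname(se[2]),
       residuals = unname(stats::residuals(fit)))
}

#' Derive free energy and entropy from an association constant and enthalpy
#'
#' `dG = -R T ln(K_a)` and `dS = (dH - dG)/T`, with R = 1.9872 cal/(mol K).
#' `dG`/`dH` are reported in kcal/mol and `dS` in cal/(mol K), the units
#' customary in binding calorimetry.
#'
#' @param K_a Association constant, 1/M (> 0).
#' @param dH Binding enthalpy, kcal/mol.
#' @param T Temperature, K.
#' @return List of class `thermo_state` with `dG_kcal`, `dH_kcal`,
#'   `dS_cal`, `T_K`.
#' @examples
#' thermo_derive(8.92e5, -5.02, 298.15)  # dS ~ +10 cal/(mol K)
#' @export
thermo_derive <- function(K_a, dH, T) {
  if (any(K_a <= 0)) stop("K_a must be > 0")
  if (any(T <= 0)) stop("T must be > 0 K")
  dG <- -.R_CAL * T * log(K_a) / 1000  # kcal/mol
  dS <- (dH - dG) * 1000 / T           # cal/(mol K)
  structure(list(dG_kcal = dG, dH_kcal = dH, dS_cal = dS, T_K = T),
            class = "thermo_state")
}

#' @export
print.thermo_state <- function(x, ...) {
  cat(sprintf("dG = %.3f kcal/mol, dH = %.3f kcal/mol, dS = %+.2f cal/(mol K) at %.2f K\n",
              x$dG_kcal, x$dH_kcal, x$dS_cal, x$T_K))
  invisible(x)
}
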