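#' Construct a quencher-titration series
#'
#' Holds quencher concentrations and the measured response: steady-state
#' fluorescence intensities, or one column per lifetime component for
#' lifetime-resolved quenching. The zero-quencher point supplies the
#' reference F0 (or tau0).
#'
#' @param quencher_M Quencher concentrations, mol/L (non-negative, sorted,
#'   including 0 unless `reference` is given).
#' @param response Numeric vector (intensity) or matrix/data.frame with one
#'   column per lifetime component (ns). All responses must be > 0.
#' @param quencher Quencher identity label (e.g. "acrylamide", "KI").
#' @param reference Optional explicit F0/tau0 value(s) if the series lacks a
#'   zero point.
#' @return Object of class `quench_series`.
#' @export
quench_series <- function(quencher_M, response, quencher = "acrylamide",
                          reference = NULL) {
  stopifnot(all(quencher_M >= 0), !is.unsorted(quencher_M))
  if (any(quencher_M < 0)) stop("negative quencher concentration")
  resp <- as.matrix(response)
  if (nrow(resp) != length(quencher_M))
    stop("response length does not match quencher grid")
  if (any(resp <= 0)) stop("responses must be positive")
  if (is.null(reference)) {
    if (quencher_M[1] != 0)
      stop("series must include [Q] = 0 or supply an explicit reference")
    reference <- resp[1, ]
  }
  structure(list(quencher_M = as.numeric(quencher_M), response = resp,
                 quencher = quencher, reference = as.numeric(reference)),
            class = "quench_series")
}

#' @export
print.quench_series <- function(x, ...) {
  cat(sprintf("Quench series (%s): %d levels, [Q] %.3g-%.3g M, %d response column(s)\n",
              x$quencher, length(x$quencher_M), min(x$quencher_M),
              max(x$quencher_M), ncol(x$response)))
  invisible(x)
}

.sv_fit_one <- function(q, ratio, intercept) {
  if (intercept == "fixed_at_1") {
    # F0/F - 1 = Ksv [Q]; slope through the origin
    y <- ratio - 1
    ksv <- sum(y * q) / sum(q^2)
    res <- y - ksv * q
    dof <- length(q) - 1
    se <- sqrt(sum(res^2) / max(dof, 1) / sum(q^2))
    icpt <- 1; icpt_se <- NA_real_
  } else {
    fit <- stats::lm(ratio ~ q)
    # vcov warns on exact (noiseless) data; zero-variance SEs are fine here
    co <- stats::coef(fit); vc <- suppressWarnings(stats::vcov(fit))
    ksv <- unname(co[2]); icpt <- unname(co[1])
    se <- sqrt(vc[2, 2]); icpt_se <- sqrt(vc[1, 1])
    res <- unname(stats::residuals(fit))
  }
  ss_tot <- sum((ratio - mean(ratio))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1
  list(K_sv = ksv, intercept = icpt, se = se, intercept_se = icpt_se,
       r_squared = r2, residuals = res)
}

#' Fit the linear Stern-Volmer relation
#'
#' Linear least squares of `F0/F` (or `tau0/tau`) against quencher
#' concentration: `F0/F = 1 + K_sv [Q]`. By default the intercept is fixed
#' at 1, as the relation dictates; `intercept = "free"` fits it as a
#' diagnostic. A clearly positive quadratic trend in the residuals triggers
#' an upward-curvature warning (static contribution or heterogeneity) but no
#' extended model is fitted.
#'
#' @param series A [quench_series()] with a single response column.
#' @param intercept `"fixed_at_1"` (default) or `"free"`.
#' @param tau0_ns Optional unquenched lifetime (ns) for deriving `k_q`.
#' @return Object of class `stern_volmer_result` with `K_sv` (1/M),
#'   `intercept`, `se`, `r_squared`, and `k_q` (1/(M s), when `tau0_ns` is
#'   given).
#' @export
stern_volmer_fit <- function(series, intercept = c("fixed_at_1", "free"),
                             tau0_ns = NULL) {
  stopifnot(inherits(series, "quench_series"))
  intercept <- match.arg(intercept)
  if (ncol(series$response) != 1)
    stop("use lifetime_stern_volmer() for multi-component series")
  if (length(series$quencher_M) < 3)
    stop("need at least 3 quencher levels")
  q <- series$quencher_M
  ratio <- series$reference[1] / series$response[, 1]
  out <- .sv_fit_one(q, ratio, intercept)
  # curvature diagnostic: significant positive quadratic term
  if (length(q) >= 4) {
    cf <- tryCatch(suppressWarnings(
      stats::coef(summary(stats::lm(ratio ~ q + I(q^2))))),
      error = function(e) NULL)
    if (!is.null(cf) && nrow(cf) == 3 && cf[3, 1] > 0 &&
        !is.nan(cf[3, 4]) && cf[3, 4] < 0.01)
      warning("upward curvature in the Stern-Volmer plot; ",
              "linear K_sv may be unreliable")
  }
  out$quencher <- series$quencher
  out$k_q <- if (!is.null(tau0_ns))
    quenching_rate_constant(out$K_sv, tau0_ns) else NA_real_
  out$tau0_ns <- if (is.null(tau0_ns)) NA_real_ else tau0_ns
  structure(out, class = "stern_volmer_result")
}

#' @export
print.stern_volmer_result <- function(x, ...) {
  cat(sprintf("Stern-Volmer fit (%s): K_sv = %.4g +/- %.2g 1/M (R^2 = %.4f)\n",
              x$quencher, x$K_sv, x$se, x$r_squared))
  if (is.finite(x$k_q))
    cat(sprintf("  k_q = %.3g 1/(M s) (tau0 = %.3g ns)\n", x$k_q, x$tau0_ns))
  invisible(x)
}

#' Bimolecular quenching rate constant
#'
#' `k_q = K_sv / tau0`, with tau0 converted from ns to s; the collisional
#' quenching rate constant in 1/(M s).
#'
#' @param K_sv Stern-Volmer constant, 1/M.
#' @param tau0_ns Unquenched lifetime, ns (> 0).
#' @return k_q in 1/(M s).
#' @examples
#' quenching_rate_constant(1.4, 6.4)    # ~2.2e8
#' quenching_rate_constant(0.25, 13.1)  # ~1.9e7
#' @export
quenching_rate_constant <- function(K_sv, tau0_ns) {
  if (any(tau0_ns <= 0)) stop("tau0 must be > 0")
  K_sv / (tau0_ns * 1e-9)
}

#' Per-component lifetime Stern-Volmer analysis
#'
#' Fits `tau0/tau = 1 + K_sv [Q]` independently for every lifetime component
#' tracked across the quencher grid. Components with missing values are
#' fitted on their available points and flagged partial.
#'
#' @param series A [quench_series()] whose response columns are per-component
#'   lifetimes (ns).
#' @param intercept Passed to the per-component linear fit.
#' @return List of `stern_volmer_result`, one per component; partial
#'   components carry `partial = TRUE`.
#' @export
lifetime_stern_volmer <- function(series,
                                  intercept = c("fixed_at_1", "free")) {
  stopifnot(inherits(series, "quench_series"))
  intercept <- match.arg(intercept)
  q_all <- series$quencher_M
  lapply(seq_len(ncol(series$response)), function(j) {
    tauj <- series$response[, j]
    ok <- is.finite(tauj)
    if (sum(ok) < 3)
      stop("component ", j, " has fewer than 3 usable quencher levels")
    out <- .sv_fit_one(q_all[ok], series$reference[j] / tauj[ok], intercept)
    out$quencher <- series$quencher
    out$k_q <- quenching_rate_constant(out$K_sv, series$reference[j])
    out$tau0_ns <- series$reference[j]
    out$partial <- !all(ok)
    structure(out, class = "stern_volmer_result")
  })
}

#' Classify quenching as dynamic or static
#'
#' Collisional (dynamic) quenching reduces intensity and lifetime together,
#' so the steady-state K_sv falls within the range of the per-component
#' lifetime K_sv values; a steady-state constant exceeding the largest
#' lifetime constant beyond the combined errors indicates a static
#' (ground-state complex) contribution.
#'
#' @param steady_state A `stern_volmer_result` from intensities.
#' @param lifetime_results List of `stern_volmer_result` from lifetimes.
#' @return `"dynamic"`, `"static_component"` or `"indeterminate"`.
#' @export
classify_quenching <- function(steady_state, lifetime_results) {
  stopifnot(inherits(steady_state, "stern_volmer_result"),
            length(lifetime_results) >= 1)
  k_ss <- steady_state$K_sv
  k_lt <- vapply(lifetime_results, `[[`, numeric(1), "K_sv")
  se_lt <- vapply(lifetime_results, function(x)
    if (is.finite(x$se)) x$se else 0, numeric(1))
  se_ss <- if (is.finite(steady_state$se)) steady_state$se else 0
  lo <- min(k_lt - se_lt) - se_ss
  hi <- max(k_lt + se_lt) + se_ss
  if (k_ss >= lo && k_ss <= hi) "dynamic"
  else if (k_ss > hi) "static_component"
  else "indeterminate"
}
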