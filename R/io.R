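# CSV schemas. Dialect is fixed: comma-separated, UTF-8, "." decimal, one
# header line. Units are embedded in the column names to prevent silent
# unit mistakes.
.schemas <- list(
  thermogram = c("injection_index", "volume_uL", "heat_ucal"),
  decay      = c("channel", "time_ns", "counts"),
  quench     = c("quencher_M"),           # + response or tau1_ns, tau2_ns, ...
  trace      = c("time_s", "fluorescence"),
  spectrum   = c("wavelength_nm", "signal")
)

.read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema mismatch in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  for (cn in names(df)) {
    if (!is.numeric(df[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cn]]))))
      stop("non-numeric cells in column '", cn, "' of ", path,
           " (data row(s) ", paste(utils::head(bad, 5), collapse = ", "), ")")
    }
  }
  df
}

#' Read a thermogram CSV
#'
#' Expects columns `injection_index, volume_uL, heat_ucal`. The schedule
#' concentrations are not stored in the CSV and must be supplied.
#'
#' @param path CSV file path.
#' @param cell_conc_M,syringe_conc_M,cell_volume_L,temperature_K Schedule
#'   parameters (see [titration_schedule()]).
#' @return A [thermogram()].
#' @export
read_thermogram <- function(path, cell_conc_M, syringe_conc_M,
                            cell_volume_L = 1.4e-3, temperature_K = 298.15) {
  df <- .read_csv_checked(path, .schemas$thermogram)
  ord <- order(df$injection_index)
  df <- df[ord, ]
  sched <- titration_schedule(cell_volume_L = cell_volume_L,
                              cell_conc_M = cell_conc_M,
                              syringe_conc_M = syringe_conc_M,
                              injection_volumes_L = df$volume_uL * 1e-6,
                              temperature_K = temperature_K)
  thermogram(df$heat_ucal, sched)
}

#' Write a thermogram CSV
#' @param tg A [thermogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_thermogram <- function(tg, path) {
  stopifnot(inherits(tg, "thermogram"))
  utils::write.csv(data.frame(
    injection_index = seq_along(tg$heats_ucal),
    volume_uL = tg$schedule$injection_volumes_L * 1e6,
    heat_ucal = tg$heats_ucal), path, row.names = FALSE)
  invisible(path)
}

#' Read a decay (or prompt) histogram CSV
#'
#' Expects columns `channel, time_ns, counts` on a uniform channel grid.
#' @param path CSV file path.
#' @return A [decay_histogram()].
#' @export
read_decay <- function(path) {
  df <- .read_csv_checked(path, .schemas$decay)
  df <- df[order(df$channel), ]
  if (anyDuplicated(df$channel)) stop("duplicated channel in ", path)
  dt <- stats::median(diff(df$time_ns))
  decay_histogram(df$counts, window_ns = dt * nrow(df))
}

#' Write a decay histogram CSV
#' @param hist A [decay_histogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_decay <- function(hist, path) {
  stopifnot(inherits(hist, "decay_histogram"))
  utils::write.csv(data.frame(channel = seq_along(hist$counts),
                              time_ns = hist$time_ns,
                              counts = hist$counts),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a quench-series CSV
#'
#' Expects `quencher_M` plus either a single `response` column or
#' per-component lifetime columns (`tau1_ns`, `tau2_ns`, ...).
#' @param path CSV file path.
#' @param quencher Quencher label.
#' @return A [quench_series()].
#' @export
read_quench <- function(path, quencher = "acrylamide") {
  df <- .read_csv_checked(path, .schemas$quench)
  resp_cols <- setdiff(names(df), "quencher_M")
  if (length(resp_cols) == 0) stop("no response column(s) in ", path)
  if (is.unsorted(df$quencher_M)) stop("quencher_M must be sorted in ", path)
  quench_series(df$quencher_M, df[resp_cols], quencher = quencher)
}

#' Read a stopped-flow trace CSV (`time_s, fluorescence`)
#' @param path CSV file path.
#' @return A [stopped_flow_trace()].
#' @export
read_trace <- function(path) {
  df <- .read_csv_checked(path, .schemas$trace)
  stopped_flow_trace(df$time_s, df$fluorescence)
}

#' Read a spectrum CSV (`wavelength_nm, signal`)
#' @param path CSV file path.
#' @param kind `"emission"` or `"cd"`.
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path, kind = c("emission", "cd")) {
  kind <- match.arg(kind)
  df <- .read_csv_checked(path, .schemas$spectrum)
  if (anyDuplicated(df$wavelength_nm))
    stop("duplicated wavelength in ", path)
  df <- df[order(df$wavelength_nm), ]
  spectrum(df$wavelength_nm, df$signal, kind = kind)
}

#' Write a spectrum CSV
#' @param spec A [spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum"))
  utils::write.csv(data.frame(wavelength_nm = spec$wavelength_nm,
                              signal = spec$signal),
                   path, row.names = FALSE)
  invisible(path)
}

# Round-trip-stable numeric formatting for reports.
.fmt_num <- function(x) signif(x, 10)

.report_sanitize <- function(x) {
  if (is.list(x)) {
    x <- x[order(names(x))]
    lapply(x, .report_sanitize)
  } else if (is.numeric(x)) .fmt_num(x) else x
}

#' Write an analysis report
#'
#' Deterministic serialization (sorted keys, fixed float precision) so that
#' reruns of the same analysis diff cleanly.
#'
#' @param report Named list of results (typically from [run_pipeline()]).
#' @param path Output path.
#' @param format `"json"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "markdown")) {
  format <- match.arg(format)
  rep_s <- .report_sanitize(report)
  if (format == "json") {
    jsonlite::write_json(rep_s, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  } else {
    lines <- c("# Analysis report", "")
    emit <- function(x, name, depth) {
      if (is.list(x)) {
        c(paste0(strrep("#", min(depth + 1, 6)), " ", name), "",
          unlist(lapply(names(x), function(nm) emit(x[[nm]], nm, depth + 1))))
      } else {
        paste0("- **", name, "**: ", paste(format(x, digits = 10),
                                           collapse = ", "))
      }
    }
    lines <- c(lines, unlist(lapply(names(rep_s), function(nm)
      emit(rep_s[[nm]], nm, 1))))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Run the full simulated-analysis pipeline
#'
#' Executes the requested stages on seeded synthetic data and assembles an
#' analysis report: ITC isotherm fit with derived dG/dS, TCSPC decay fit
#' with fractional intensities and average lifetime, Stern-Volmer fit with
#' k_q and dynamic/static classification, stopped-flow k_off, and spectral
#' summaries. Identical `config` (including `seed`) yields an identical
#' report. A stage failure halts with the partial report flagged.
#'
#' @param config List with `seed` and a `stages` character vector from
#'   `c("itc", "decay", "quench", "kinetics", "spectra")`; optional
#'   per-stage parameter lists override the defaults below.
#' @return Named list of class `analysis_report` with one entry per stage
#'   plus `provenance`.
#' @export
run_pipeline <- function(config = list()) {
  seed <- config$seed %||% 1L
  stages <- config$stages %||% c("itc", "decay", "quench", "kinetics",
                                 "spectra")
  valid <- c("itc", "decay", "quench", "kinetics", "spectra")
  bad <- setdiff(stages, valid)
  if (length(bad))
    stop("invalid stage name(s): ", paste(bad, collapse = ", "),
         "; valid stages are ", paste(valid, collapse = ", "))
  report <- list(provenance = list(
    seed = seed, stages = stages,
    package_version = as.character(utils::packageVersion("bindspec"))))
  for (st in stages) {
    res <- tryCatch(switch(st,
      itc = .stage_itc(config$itc, seed),
      decay = .stage_decay(config$decay, seed),
      quench = .stage_quench(config$quench, seed),
      kinetics = .stage_kinetics(config$kinetics, seed),
      spectra = .stage_spectra(config$spectra, seed)),
      error = function(e) e)
    if (inherits(res, "error")) {
      report$failed_stage <- list(stage = st, message = conditionMessage(res))
      class(report) <- "analysis_report"
      stop("pipeline stage '", st, "' failed: ", conditionMessage(res))
    }
    report[[st]] <- res
  }
  structure(report, class = "analysis_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage_itc <- function(pars, seed) {
  pars <- pars %||% list()
  truth <- pars$model %||% binding_model("one_set_of_sites", N = 2.05,
                                         K_a = 8.92e5, dH = -5.02)
  sched <- pars$schedule %||% titration_schedule(
    cell_conc_M = 30e-6, syringe_conc_M = 1e-3,
    injection_volumes_L = rep(10e-6, 20))
  sim <- simulate_itc(sched, truth, noise_sd_ucal = pars$noise %||% 0.2,
                      seed = seed + 101)
  tg <- dilution_correct(sim$sample, sim$blank)
  fit <- fit_isotherm(tg, truth$kind)
  list(truth = unclass(truth), fitted = unclass(fit$model),
       se = as.list(fit$se),
       thermo = if (truth$kind == "one_set_of_sites")
         unclass(fit$thermo) else lapply(fit$thermo, unclass))
}

.stage_decay <- function(pars, seed) {
  pars <- pars %||% list()
  truth <- pars$model %||% multiexp_model(
    alpha = c(0.1, 0.44 / 6.4, 0.53 / 13.1), tau_ns = c(0.3, 6.4, 13.1))
  sim <- simulate_decay(truth, channels = pars$channels %||% 1000,
                        window_ns = pars$window_ns %||% 200,
                        peak_counts = pars$peak_counts %||% 10000,
                        seed = seed + 202)
  fit <- fit_decay(sim$decay, sim$irf,
                   n_components = length(truth$tau_ns),
                   mode = "reconvolution")
  fr <- fractional_intensities(fit$model)
  list(tau_true_ns = truth$tau_ns, tau_ns = fit$model$tau_ns,
       f = fr$f, B = fr$B,
       mean_tau_ns = amplitude_average_lifetime(fit$model),
       chisq_red = fit$quality$chisq_red,
       acceptable = accept_fit(fit$quality))
}

.stage_quench <- function(pars, seed) {
  pars <- pars %||% list()
  # defaults model collisional quenching of a bound chromophore: the
  # steady-state constant falls between the per-component lifetime constants
  ksv <- pars$K_sv %||% 1.35
  sr <- simulate_quench_series(baseline = pars$F0 %||% 100, K_sv = ksv,
                               noise_frac = pars$noise %||% 0.02,
                               seed = seed + 303)
  fit <- stern_volmer_fit(sr, tau0_ns = pars$tau0_ns %||% 7.5)
  ltau <- simulate_quench_series(baseline = pars$tau0_components %||%
                                   c(3.1, 7.5),
                                 K_sv = pars$K_sv_lifetime %||% c(1.52, 0.90),
                                 noise_frac = pars$noise %||% 0.02,
                                 seed = seed + 304)
  lt <- lifetime_stern_volmer(ltau)
  list(K_sv_true = ksv, K_sv = fit$K_sv, se = fit$se, k_q = fit$k_q,
       K_sv_lifetime = vapply(lt, `[[`, numeric(1), "K_sv"),
       classification = classify_quenching(fit, lt))
}

.stage_kinetics <- function(pars, seed) {
  pars <- pars %||% list()
  k <- pars$k_off %||% 1.41
  tr <- simulate_stopped_flow(k, duration_s = pars$duration_s %||% 2,
                              noise_frac = pars$noise %||% 0.02,
                              seed = seed + 404)
  fit <- fit_single_exponential(tr)
  list(k_off_true = k, k_off = fit$k_off, se = as.list(fit$se),
       n_exponentials = exponential_count_check(tr)$n)
}

.stage_spectra <- function(pars, seed) {
  pars <- pars %||% list()
  grid <- seq(400, 650, by = 1)
  # widths kept narrow enough that neither band is clipped by the grid
  apo <- simulate_spectrum(list(c(520, 25, 1)), grid,
                           noise_frac = pars$noise %||% 0,
                           seed = seed + 505)
  holo <- simulate_spectrum(list(c(480, 25, 3.01)), grid,
                            noise_frac = pars$noise %||% 0,
                            seed = seed + 506)
  enh <- fold_enhancement(holo, apo)
  cd_grid <- seq(190, 260, by = 1)
  cd <- simulate_spectrum(grid_nm = cd_grid, kind = "cd",
                          target_ratio = pars$target_ratio %||% 0.89,
                          seed = seed + 507)
  list(fold = enh$fold, lambda_max_nm = enh$lambda_max_nm,
       shift_nm = enh$shift_nm,
       ellipticity_ratio = ellipticity_ratio(cd))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report (seed ", x$provenance$seed, "), stages: ",
      paste(x$provenance$stages, collapse = ", "), "\n", sep = "")
  invisible(x)
}
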