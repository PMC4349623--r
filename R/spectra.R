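#' Construct a spectrum
#'
#' Wavelength-indexed signal: steady-state emission intensity (arbitrary
#' units) or circular-dichroism ellipticity (mdeg).
#'
#' @param wavelength_nm Strictly increasing wavelength grid, nm.
#' @param signal Signal values, same length.
#' @param kind `"emission"` or `"cd"`.
#' @param meta Optional metadata list.
#' @return Object of class `spectrum`.
#' @export
spectrum <- function(wavelength_nm, signal, kind = c("emission", "cd"),
                     meta = list()) {
  kind <- match.arg(kind)
  stopifnot(length(wavelength_nm) == length(signal),
            length(wavelength_nm) >= 2)
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelength grid must be strictly increasing")
  structure(list(wavelength_nm = as.numeric(wavelength_nm),
                 signal = as.numeric(signal), kind = kind, meta = meta),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("%s spectrum: %d points, %.4g-%.4g nm\n",
              if (x$kind == "cd") "CD" else "Emission",
              length(x$signal), min(x$wavelength_nm), max(x$wavelength_nm)))
  invisible(x)
}

.check_grids <- function(a, b) {
  if (length(a$wavelength_nm) != length(b$wavelength_nm) ||
      any(abs(a$wavelength_nm - b$wavelength_nm) >
          1e-9 * max(abs(a$wavelength_nm))))
    stop("spectrum grids do not match; use resample_spectrum() explicitly")
}

#' Trapezoidal integral of a spectrum
#'
#' @param spec A [spectrum()].
#' @param range Optional `c(lo, hi)` wavelength sub-range, nm; default the
#'   full recorded grid.
#' @return Integrated area (signal units x nm).
#' @export
integrate_spectrum <- function(spec, range = NULL) {
  stopifnot(inherits(spec, "spectrum"))
  wl <- spec$wavelength_nm; y <- spec$signal
  if (!is.null(range)) {
    keep <- wl >= range[1] & wl <= range[2]
    if (sum(keep) < 2) stop("integration range contains fewer than 2 points")
    wl <- wl[keep]; y <- y[keep]
  }
  sum(diff(wl) * (y[-1] + y[-length(y)]) / 2)
}

#' Fold enhancement between two spectra
#'
#' Ratio of whole-spectrum (or sub-range) integrals of a sample spectrum to
#' a reference spectrum, with the peak positions of both and the peak shift.
#' This is the standard way to quantify extrinsic-dye (e.g. ANS) fluorescence
#' enhancement against the apo-protein reference.
#'
#' @param spec Sample [spectrum()].
#' @param reference Reference [spectrum()] on the same grid.
#' @param range Optional integration sub-range, nm.
#' @return List of class `enhancement_result` with `fold`,
#'   `lambda_max_nm`, `lambda_max_ref_nm` and `shift_nm`.
#' @export
fold_enhancement <- function(spec, reference, range = NULL) {
  stopifnot(inherits(spec, "spectrum"), inherits(reference, "spectrum"))
  .check_grids(spec, reference)
  aref <- integrate_spectrum(reference, range)
  if (abs(aref) < .Machine$double.eps) stop("reference area is zero")
  lm_s <- lambda_max(spec)
  lm_r <- lambda_max(reference)
  structure(list(fold = integrate_spectrum(spec, range) / aref,
                 lambda_max_nm = lm_s, lambda_max_ref_nm = lm_r,
                 shift_nm = lm_s - lm_r),
            class = "enhancement_result")
}

#' @export
print.enhancement_result <- function(x, ...) {
  cat(sprintf("Fold enhancement: %.3g (lambda_max %.4g -> %.4g nm, shift %+.3g nm)\n",
              x$fold, x$lambda_max_ref_nm, x$lambda_max_nm, x$shift_nm))
  invisible(x)
}

#' Emission maximum wavelength
#'
#' Argmax refined by parabolic interpolation through the three points around
#' the discrete maximum; exact for a locally quadratic (e.g. Gaussian-top)
#' band. Plateau ties are broken toward the shorter wavelength. Optional
#' boxcar smoothing suppresses noise before peak picking.
#'
#' @param spec A [spectrum()] with at least 5 points.
#' @param smooth_box Odd boxcar width in points (default 1 = no smoothing).
#' @return Peak wavelength, nm.
#' @export
lambda_max <- function(spec, smooth_box = 1) {
  stopifnot(inherits(spec, "spectrum"), length(spec$signal) >= 5)
  y <- spec$signal
  if (smooth_box > 1) {
    k <- rep(1 / smooth_box, smooth_box)
    y <- as.numeric(stats::filter(y, k, sides = 2))
    y[is.na(y)] <- spec$signal[is.na(y)]
  }
  i <- which(y == max(y))[1]  # ties -> shortest wavelength
  n <- length(y)
  if (i == 1 || i == n) return(spec$wavelength_nm[i])
  # parabola through (i-1, i, i+1); vertex offset in grid units
  y1 <- y[i - 1]; y2 <- y[i]; y3 <- y[i + 1]
  denom <- y1 - 2 * y2 + y3
  if (denom == 0) return(spec$wavelength_nm[i])
  d <- 0.5 * (y1 - y3) / denom
  d <- max(min(d, 0.5), -0.5)
  spec$wavelength_nm[i] + d * (spec$wavelength_nm[i + 1] -
                                 spec$wavelength_nm[i])
}

#' CD ellipticity ratio theta220/theta209
#'
#' Ratio of ellipticities at 220 nm and 209 nm (linearly interpolated to the
#' exact wavelengths), a helix-content-sensitive shape index: ~1.09 for an
#' all-helix structure, smaller as coil content grows.
#'
#' @param spec_cd A CD [spectrum()] covering 209 and 220 nm.
#' @return The ratio theta(220)/theta(209).
#' @export
ellipticity_ratio <- function(spec_cd) {
  stopifnot(inherits(spec_cd, "spectrum"))
  wl <- spec_cd$wavelength_nm
  if (min(wl) > 209 || max(wl) < 220)
    stop("CD spectrum must cover 209-220 nm")
  th220 <- stats::approx(wl, spec_cd$signal, xout = 220)$y
  th209 <- stats::approx(wl, spec_cd$signal, xout = 209)$y
  if (abs(th209) < 1e-10 * max(abs(spec_cd$signal)))
    stop("theta(209) is ~0: ellipticity ratio undefined")
  th220 / th209
}

#' Differential spectrum (complex minus component)
#'
#' Pointwise subtraction, used to extract the spectrum of a bound ligand
#' from the complex under the assumption that the other component's
#' structure is unchanged by binding (recorded in the metadata).
#'
#' @param complex_spec Complex [spectrum()].
#' @param component_spec Component [spectrum()] on the same grid.
#' @return Difference `spectrum`.
#' @export
differential_spectrum <- function(complex_spec, component_spec) {
  stopifnot(inherits(complex_spec, "spectrum"),
            inherits(component_spec, "spectrum"))
  .check_grids(complex_spec, component_spec)
  spectrum(complex_spec$wavelength_nm,
           complex_spec$signal - component_spec$signal,
           kind = complex_spec$kind,
           meta = c(complex_spec$meta,
                    list(differential = TRUE,
                         assumption = "no component structural change")))
}

#' Average repeated spectral scans
#'
#' Pointwise mean of matched-grid scans, retaining the per-point standard
#' deviation (zero for a single scan).
#'
#' @param spectra List of [spectrum()] objects on identical grids.
#' @return The mean `spectrum`, with per-point `sd` in `$meta$sd`.
#' @export
average_scans <- function(spectra) {
  stopifnot(is.list(spectra), length(spectra) >= 1,
            all(vapply(spectra, inherits, logical(1), "spectrum")))
  for (s in spectra[-1]) .check_grids(spectra[[1]], s)
  mat <- do.call(cbind, lapply(spectra, `[[`, "signal"))
  sdv <- if (ncol(mat) > 1) apply(mat, 1, stats::sd) else
    rep(0, nrow(mat))
  spectrum(spectra[[1]]$wavelength_nm, rowMeans(mat),
           kind = spectra[[1]]$kind,
           meta = list(n_scans = length(spectra), sd = sdv))
}

#' Resample a spectrum onto a new grid
#'
#' Linear interpolation; no extrapolation (the new grid must lie within the
#' recorded range). Arithmetic between spectra requires exactly matching
#' grids, so resampling is always an explicit step.
#'
#' @param spec A [spectrum()].
#' @param new_grid_nm Strictly increasing target grid, nm.
#' @return Resampled `spectrum`.
#' @export
resample_spectrum <- function(spec, new_grid_nm) {
  stopifnot(inherits(spec, "spectrum"))
  if (min(new_grid_nm) < min(spec$wavelength_nm) ||
      max(new_grid_nm) > max(spec$wavelength_nm))
    stop("new grid extends beyond the recorded range")
  spectrum(new_grid_nm,
           stats::approx(spec$wavelength_nm, spec$signal,
                         xout = new_grid_nm)$y,
           kind = spec$kind, meta = spec$meta)
}

#' Mean-residue ellipticity conversion
#'
#' Optional utility converting raw ellipticity (mdeg) to mean-residue
#' ellipticity (deg cm^2/dmol): `MRE = theta_mdeg / (10 * l_cm * C_M *
#' n_residues)` with molar concentration `C_M` and path length `l_cm`.
#'
#' @param spec_cd CD [spectrum()] in mdeg.
#' @param conc_M Protein molar concentration, M.
#' @param n_residues Number of residues.
#' @param path_cm Cuvette path length, cm.
#' @return CD `spectrum` in deg cm^2/dmol.
#' @export
mean_residue_ellipticity <- function(spec_cd, conc_M, n_residues, path_cm) {
  stopifnot(inherits(spec_cd, "spectrum"), conc_M > 0, n_residues >= 1,
            path_cm > 0)
  spectrum(spec_cd$wavelength_nm,
           spec_cd$signal / (10 * path_cm * conc_M * n_residues),
           kind = "cd", meta = c(spec_cd$meta, list(units = "deg cm^2/dmol")))
}
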