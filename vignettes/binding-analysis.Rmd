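---
title: "Models and methods: binding thermodynamics and fluorescence analysis with bindspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: binding thermodynamics and fluorescence analysis with bindspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindspec)
```

# Scope

`bindspec` implements the quantitative workflow of a multi-technique
protein–ligand binding study: isothermal titration calorimetry (ITC) with
identical-sites and sequential two-site isotherms, TCSPC fluorescence-decay
reconvolution, Stern–Volmer quenching, stopped-flow dissociation kinetics,
and emission/CD spectral summaries. Every modality has a seeded synthetic
generator so the whole pipeline can be exercised, validated and benchmarked
without instrument data. The motivating system is calcium-loaded calmodulin
(and calmodulin/troponin-C chimeras) binding the calmodulin-binding domain
of the Orai1 channel and the hydrophobicity probe ANS, but nothing in the
code is specific to those molecules.

# ITC models

## Injection bookkeeping

A perfusion (overfill) cell of volume $V_0$ holds macromolecule at $M_0$;
each injection of titrant displaces an equal volume of the mixed cell
content. With $v$ the cumulative injected volume, the standard
displacement-corrected concentrations are

$$M_t = M_0\,\frac{1 - v/2V_0}{1 + v/2V_0}, \qquad
  L_t = L_{\mathrm{syr}}\,\frac{v/V_0}{1 + v/2V_0}.$$

The observed heat of injection $i$ corrects the difference of total heat
content for the displaced volume:

$$\Delta Q_i = Q_i - Q_{i-1} + \frac{dV_i}{V_0}\,\frac{Q_i + Q_{i-1}}{2}.$$

The instrument literature leaves the overfill convention to vendor
software; the package fixes the MicroCal-style convention above and tests
that the summed per-injection heats converge to the final cell heat content
as the injection volume shrinks. The cell volume defaults to 1.4 mL (a
typical VP-ITC active volume) and is configurable everywhere; an optional
flag excludes the first injection, the common remedy for syringe-diffusion
artifacts, and defaults to off so simulated round trips are exact.

## Identical sites ("one set of sites")

For $N$ identical, independent sites per macromolecule with association
constant $K_a$ and site enthalpy $\Delta H$, the bound-ligand concentration
is the closed-form root of a quadratic, giving the cell heat content

$$Q = \frac{N M_t \Delta H V_0}{2}
      \left[X - \sqrt{X^2 - \frac{4 L_t}{N M_t}}\right],
  \qquad X = 1 + \frac{L_t}{N M_t} + \frac{1}{N K_a M_t}.$$

A numerically negative discriminant (possible only through rounding) is
clamped at zero.

## Sequential two-site model

Macroscopic stepwise constants $K_{a1} \ge K_{a2}$ define the binding
polynomial $P = 1 + K_{a1} L + K_{a1} K_{a2} L^2$ in the *free* ligand
concentration $L$, with species fractions $F_1 = K_{a1} L / P$ and
$F_2 = K_{a1} K_{a2} L^2 / P$ and heat content

$$Q = M_t V_0\,[F_1 \Delta H_1 + F_2 (\Delta H_1 + \Delta H_2)].$$

$L$ solves the mass balance
$L_t = L + M_t (K_{a1} L + 2 K_{a1} K_{a2} L^2)/P$, whose left side is
strictly increasing in $L$, so bisection on $[0, L_t]$ followed by Newton
polishing converges to a unique root; the solver enforces a residual below
$10^{-12} L_t$ and is cross-checked in the tests against a dense-grid
search.

The two models are linked by an exact statistical-factor identity that the
test suite uses as an independent oracle: identical sites with $(N = 2, k)$
equals the sequential model with $(K_{a1}, K_{a2}) = (2k, k/2)$ and equal
step enthalpies, because the macroscopic constants of two independent
identical sites carry the binomial factors 2 and 1/2. Agreement is required
to $10^{-9}$ relative over a dense concentration grid.

## Fitting, identifiability, and the c-value

`fit_isotherm()` minimizes least squares over the per-injection heats by
Levenberg–Marquardt in transformed coordinates: $\log K$ (positivity),
raw $\Delta H$ and $\log N$; the sequential model is parameterized as
$K_{a2} = K_{a1} r$ with $r \in (0, 1]$, which removes label switching by
construction. Multi-start over log-spaced $K$ grids (plus an optional user
guess) guards against local minima. Asymptotic standard errors come from
the residual-scaled inverse Hessian; for the derived $K_{a2}$ the
delta method combines the variances of $\log K_{a1}$ and $\log r$.

The dimensionless $c = K_a M_0 N$ governs isotherm shape: the package warns
outside $1 \le c \le 1000$, but still fits — the weak-dye-binding scenario
(apparent $K \sim 2\times10^3$ M$^{-1}$, $c \approx 0.5$) is exactly the
regime where an incomplete-saturation titration with $N$ free is the
honest analysis, and noiseless round trips recover the generating apparent
constant to well under a percent. For such weak-probe titrations $N$ is a
free parameter near the probe stoichiometry (4–6 dye molecules per protein
is typical for ANS) and the fitted constant is an overall apparent
affinity, not a per-site constant.

## Thermodynamic linkage and buffer ionization

`thermo_derive()` applies $\Delta G = -RT\ln K_a$ with
$R = 1.9872$ cal mol$^{-1}$ K$^{-1}$ and reports
$\Delta S = (\Delta H - \Delta G)/T$ in cal mol$^{-1}$ K$^{-1}$; the
identity $\Delta G = \Delta H - T\Delta S$ then holds to machine precision.
Proton-linked binding makes the apparent enthalpy buffer-dependent,
$\Delta H_{\mathrm{app}} = \Delta H_b + n\,\Delta H_i$; with two or more
buffers of distinct ionization enthalpy, ordinary least squares yields the
proton count $n$ (positive = protonation) and the intrinsic $\Delta H_b$.

# TCSPC decay analysis

The decay model is $I(t) = A + \sum_i \alpha_i e^{-t/\tau_i}$ with up to
four components. Fractional intensities are
$f_i = \alpha_i\tau_i / \sum_j \alpha_j\tau_j$ (the standard definition;
the package documents this normalization explicitly because it is easy to
mistype) and the amplitude-average lifetime is
$\langle\tau\rangle = \sum \alpha_i\tau_i^2 / \sum \alpha_i\tau_i =
\sum f_i \tau_i$, which is always bracketed by the extreme component
lifetimes.

## Reconvolution

The measured histogram is the decay convolved with the instrument response
(prompt). The package discretizes the causal convolution on the channel
grid (FFT-based), evaluating the model at channel centers so that a delta
prompt in the first channel reproduces the direct model exactly; an
optional prompt time shift, bounded to ±10 channels and applied by linear
interpolation, absorbs timing drift between prompt and sample measurements.

## Weights and goodness of fit

Counts are Poisson. Weighting residuals by the *observed* counts
($1/\max(y_i, 1)$, Neyman weights) is common in vendor software but biases
multi-exponential fits: channels that fluctuate low are over-weighted, and
at $10^4$ peak counts this pulls the long lifetime several percent low.
`fit_decay()` therefore iterates the weights: a first pass with
observed-count weights, then re-weighting by the fitted model
($1/\max(\hat\mu_i, 1)$), which removed the bias entirely in our replicate
studies. The amplitudes and baseline enter the model linearly, so they are
profiled out by weighted linear least squares at every step (variable
projection) and only the lifetimes (and prompt shift) are iterated
nonlinearly — this makes 3-component fits on 4000-channel histograms both
fast and robust to amplitude starting values.

The reported reduced $\chi^2$ is the Pearson statistic
$\sum (y_i-\hat\mu_i)^2/\hat\mu_i$ over channels with fitted counts of at
least 5 — the region where the Gaussian approximation to Poisson counting
is sound — divided by the degrees of freedom there. For a correct model it
scatters around 1; the conventional acceptance rule, applied strictly, is
reduced $\chi^2 < 1.2$. Lifetimes below twice the channel width are flagged
"at detection limit" (a ~0.3 ns free-dye component in a 50 ps/channel
measurement is reportable but not precisely determined), and two lifetimes
within 1% of each other flag the fit degenerate.

`select_n_components()` recommends the smallest component count whose fit
is acceptable and is not improved by more than 5% in reduced $\chi^2$ by
adding one more — a deliberately simple parsimony heuristic that recovers
the generating order on clean simulations and refuses to split
near-identical lifetimes.

# Stern–Volmer quenching

Collisional quenching obeys $F_0/F = 1 + K_{sv}[Q]$ and its lifetime
analogue $\tau_0/\tau = 1 + K_{sv}[Q]$. The intercept is fixed at 1 by
default — the relation's construction, with $F_0$ taken from the $[Q] = 0$
point rather than fitted — and a free-intercept fit is available as a
diagnostic. Only the linear law is modeled; a significantly positive
quadratic trend in the residuals raises a warning (possible static
contribution or heterogeneity) rather than switching models. The
bimolecular rate constant is $k_q = K_{sv}/\tau_0$ (ns converted to s).
Per-component lifetime series are fitted independently; the classifier
labels quenching *dynamic* when the steady-state $K_{sv}$ falls within the
error-widened range of the per-component lifetime constants, and
*static-component* when it exceeds the largest one beyond the combined
errors — the textbook signature that intensity is lost without lifetime
loss.

# Stopped-flow dissociation kinetics

Displacement experiments (labeled complex mixed with excess unlabeled
trap) give pseudo-first-order dissociation,
$F(t) = c + a\,e^{-k_{\mathrm{off}} t}$. `fit_single_exponential()`
excludes points before the mixing dead time (default 2 ms, configurable),
flags flat traces instead of fitting them, warns when the trace spans fewer
than three relaxation times, and is invariant to affine rescaling of the
signal. `exponential_count_check()` accepts a second exponential only when
it improves the residual sum of squares by more than 10% *and* the
single-exponential residuals fail a runs test — parsimony under noise is
tested explicitly. No association-rate estimation is attempted: with
diffusion-limited binding the association phase is over within the dead
time.

# Spectral summaries

Emission enhancement is quantified by whole-spectrum trapezoidal
integration against a reference (apo) spectrum; the full recorded grid is
the default integration range, with explicit sub-range control. Peak
positions use parabolic refinement through the three points around the
discrete maximum (exact to < 0.05 nm for a noiseless Gaussian band), with
plateau ties broken toward the shorter wavelength and optional boxcar
smoothing first. CD spectra are summarized by the
$\theta_{220}/\theta_{209}$ ellipticity ratio (linear interpolation to the
exact wavelengths; ≈1.09 for an all-helix structure), and differential
spectra (complex minus component) carry an explicit metadata note that
they assume no structural change in the subtracted component. Operand
grids must match exactly — resampling is a separate, explicit step, never
silent. The pipeline works in raw ellipticity; mean-residue-ellipticity
conversion is an optional utility. No secondary-structure deconvolution is
attempted.

# Synthetic data: what it emulates, and what it does not

The generators produce data with the statistical structure the fitters
assume, from known ground truth and explicit seeds:

* **ITC** — model heats plus additive Gaussian noise (default SD 0.2 µcal
  per injection, a typical VP-ITC figure) and a matched blank carrying a
  constant dilution heat (default −0.5 µcal) plus noise. Typical
  simulated titrations use 20 × 10 µL injections of 1 mM titrant into
  30 µM protein (peptide binding) or 25 × 10 µL of 5 mM titrant into
  50 µM protein (weak dye binding).
* **TCSPC** — expected counts are the prompt-convolved decay scaled to a
  target peak (10,000 counts over 4000 channels in a 200 ns window by
  default), observed counts are Poisson draws; the prompt is a Gaussian of
  1 ns FWHM centered 10% into the window, plausible for a pulsed-LED
  source. Simulations of dye binding include a ~0.3 ns free-dye component
  alongside the bound-dye lifetimes.
* **Quenching** — exact hyperbolic response with multiplicative Gaussian
  noise, on a default grid of 0–0.3 M in 7 steps.
* **Stopped flow** — single-exponential decay sampled at 2 or 5 ms with
  additive noise scaled to the amplitude.
* **Spectra** — sums of Gaussian bands; CD mode mixes synthetic helix and
  coil basis shapes so a target $\theta_{220}/\theta_{209}$ can be dialed
  exactly (the pure helix basis is calibrated to 1.09).

All draws flow from one seeded generator per call; the caller's RNG state
is untouched, and identical inputs plus seed give byte-identical output.
The generators deliberately omit inner-filter and photobleaching effects,
raw power-compensation ITC signals, photon-arrival event streams, and
non-Gaussian instrument drifts. Passing round-trip tests therefore
demonstrates estimator correctness under the assumed noise models — not
robustness to every artifact of real instruments. Prompt width and ITC
heat noise are not quantities the motivating study reports; the defaults
above are stated instrument-class values and every one is configurable.

# Problem sizes and numerical choices

The replicate studies shipped in the tests use sizes chosen to make the
statistical claims meaningful while keeping the suite quick: 50 Poisson
replicates at full instrument resolution (4000 channels) for the lifetime
recovery study, 40–200 replicates for linear-fit coverage and bias checks,
and dense 100+ point grids for the model-equivalence oracle. Optimizer
tolerances are set tight (`ftol`/`ptol` $10^{-12}$–$10^{-15}$) so that
"noiseless round trips are exact" is limited by machine arithmetic, not by
early stopping. Degenerate inputs follow explicit rules documented at each
function: flat isotherms and flat traces are flagged rather than fitted,
all-equal buffer enthalpies are rejected as underdetermined, ties in peak
detection go to the shorter wavelength, and $\theta_{209} \approx 0$ makes
the ellipticity ratio an error rather than an infinity.

# Known limitations

* The ITC fitter handles single-experiment isotherms only: no global
  multi-experiment fits, competition titrations, or kinetic ITC.
* Decay analysis is per-histogram; no global/linked analysis across
  emission wavelengths and no lifetime-distribution (maximum-entropy)
  methods.
* The quenching module models strictly linear Stern–Volmer behavior;
  sphere-of-action and combined static+dynamic models are out of scope.
* Reported uncertainties are asymptotic (inverse-Hessian); replicate-based
  spread is available by running the seeded generators, as the coverage
  tests do.
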