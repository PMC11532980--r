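---
title: "Solvation-corrected equilibria: model, numerics, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solvation-corrected equilibria: model, numerics, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solvbind)
```

## The model

For a 1:1 association A + B ⇌ AB, the package works with the governing
relationship

$$\Delta G^\circ = -RT\,\ln K - [AB]_{eq}\,\Delta G^S,$$

which augments the classical expression with a term proportional to the
equilibrium complex concentration. The physical picture: forming a complex
releases water molecules from reactant surfaces into the bulk, and if a
surface-bound and a bulk water molecule differ in average free energy, the
total solvent contribution scales with how much complex has formed. All of
that (and any other linked equilibria not represented in the quotient, e.g.
counterion movement) is lumped into the single constant $\Delta G^S$,
expressed in kcal·mol⁻¹ per molar of complex so that
$[AB]\cdot\Delta G^S$ is kcal·mol⁻¹. The number of released waters and
their individual free energies are deliberately not modelled separately —
they are not identifiable from equilibrium data, and the package exposes no
fields for them.

Key consequences the package operationalises:

- **K is not constant** unless $\Delta G^S = 0$. Along an ITC titration the
  quotient drifts injection by injection.
- **The characteristic plot is linear**: $-RT\ln K$ against $[AB]$ has
  slope $\Delta G^S$ and intercept $\Delta G^\circ$. This is the estimator
  of record (`fit_solvation_line()`); fitting both parameters from a single
  titration trace is ill-conditioned, and `fit_governing_global()` warns
  accordingly.
- **Two-state folding** U ⇌ F obeys the same equation with
  $[F] = f_F P_{tot}$, so a nonzero $\Delta G^S$ makes the folded fraction
  concentration-dependent — testable with a CD dilution series at constant
  concentration × pathlength.

Assumptions inherited from the framework: activity coefficients are
constant over the (sub-millimolar to low-millimolar) concentration ranges
considered, so all concentration dependence of the quotient is attributed
to solvation; concentrations are molar and made dimensionless against a
1 M reference; $\Delta G^\circ$ and $\Delta G^S$ are constants at a given
temperature and solvent composition.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| gas constant | kcal·mol⁻¹·K⁻¹ | 1.9872×10⁻³ | matches the kcal free-energy scale used throughout |
| `dG_standard` ($\Delta G^\circ$) | kcal·mol⁻¹ | — | intercept of the characteristic plot |
| `dG_solv` ($\Delta G^S$) | kcal·mol⁻¹ per M complex | 0 | slope; 0 recovers classical behaviour; no sign restriction |
| injection schedule | — | 28 × 10 µL into 1.45 mL, syringe 10× cell | a standard VP-ITC protocol and the one used in the modelling study the simulator reproduces |
| `dilution_mode` | — | `"paper"` | constant-increment totals with fixed cell concentration, matching the modelling convention; `"displacement"` adds real perfusion-cell dilution and converges to `"paper"` as v/V → 0. Acceptance-level results use `"paper"` only |
| solver `abs_tol` / `edge_guard` | M / fraction | 1×10⁻¹⁵ / 1×10⁻¹² | see numerics below |
| `molar_mass` (folding) | g·mol⁻¹ | 14178 | bovine α-lactalbumin; a convenience default for mg·mL⁻¹ conversion, not a fitted quantity |

## Numerical choices

**Equilibrium solve.** The residual
$g(Z) = -RT\ln\!\frac{Z}{(X_t-Z)(M_t-Z)} - Z\Delta G^S - \Delta G^\circ$
runs from $+\infty$ to $-\infty$ on $(0, \min(X_t, M_t))$, so a sign change
is guaranteed on the edge-guarded interval and bracketing needs no
derivatives or starting guesses. Brent's method (`stats::uniroot`) is
followed by up to three Newton steps with the analytic derivative. The
polish matters: near saturation the quotient amplifies root error by
$1/(M_t - Z)$, and without it the "constant K at $\Delta G^S = 0$"
invariant holds only to ~10⁻⁸ instead of the required 10⁻¹⁰. The
`edge_guard` fraction (10⁻¹² of the limiting total) keeps the logarithms
finite; `Xt = 0` short-circuits to `Z = 0` before the first injection.

**Multiple roots.** For $\Delta G^S \ge 0$ the residual is strictly
decreasing and the root unique. For $\Delta G^S < 0$ the $-Z\Delta G^S$
term can create three sign changes (observed in practice only for
physically extreme magnitudes, ~10⁵); the interval is then scanned on a
4096-point grid, each bracket refined, the smallest root returned, and a
warning lists all of them. The smallest root is the one reached from the
unbound side and the only one below saturation in the regimes the
framework targets.

**Classical oracle.** `classical_Z()` evaluates the smaller quadratic root
in the cancellation-free form $2X_tM_t/(b+\sqrt{b^2-4X_tM_t})$,
$b = X_t+M_t+1/K$, stable for K up to 10¹⁵.

**One-site fit.** Nelder-Mead then BFGS on $(\log_{10}K, \Delta H, n)$,
initialised from a half-decade log-K grid with $\Delta H$ profiled out
analytically (the model is linear in $\Delta H$ at fixed K, n). Standard
errors come from the numerical Hessian of the residual sum of squares
($\mathrm{cov} \approx 2\hat\sigma^2 H^{-1}$). Levenberg-Marquardt would
also work; a derivative-free simplex plus quasi-Newton polish is equally
robust here and avoids an extra dependency.

**Van't Hoff modes.** The default regresses $\ln K = -\Delta G^\circ/(RT)$
on $1/T$ (the canonical van't Hoff plot); the alternative fits
$\Delta G^\circ = \Delta H^\circ - T\Delta S^\circ$ directly. Both invert
exact data; on inexact data they weight temperatures differently and, on
the bundled four-temperature hybridization table, differ by ~0.36
kcal·mol⁻¹ in $\Delta H^\circ$. Both are retained because published
analyses rarely state which was used; the default reproduces the
reference values.

**Error propagation.** Replicate dispersions of K map to the
$-RT\ln K$ scale by the delta method, $\mathrm{sd}(y) = RT\cdot
\mathrm{sd}(K)/K$; inverse-variance weighting is optional and off by
default because most published characteristic-plot fits are unweighted.

**Degenerate inputs.** Flat heats → explicit unidentifiable-K error; mixed
temperatures in one characteristic-plot fit → error (fit each temperature
separately); duplicate concentrations with zero spread → singular-fit
error; f outside [0, 1] in the unstacking correction → error.

## The unstacking correction

Short single strands retain temperature-dependent intramolecular base
stacking, so the ITC-measured hybridization free energy includes the cost
of melting that residual structure. To compare temperatures on a common
fully-unstacked basis the package computes
$\Delta G^\circ = \Delta_{itc}G^\circ - f\,\Delta_{un}G^\circ$ with
$\Delta_{un}G^\circ = \Delta_{un}H^\circ - T\Delta_{un}S^\circ$ summed
over both strands and $f$ the stacked fraction. The per-strand
enthalpy/entropy values are literature-derived config inputs, not
constants baked into the package. Only intercepts are corrected; slopes
($\Delta G^S$) are left untouched because the concentration dependence of
the unstacking transition itself is unknown.

## What the synthetic generators emulate — and what they don't

Noise models were chosen to match the error structure of each measurement
and fixed once:

- **Heats**: additive Gaussian per injection, default sd 2×10⁻⁸ kcal
  (~0.02 µcal), a typical integrated-peak noise floor for a sensitive
  titration calorimeter.
- **Quotients**: multiplicative lognormal with sdlog 0.05 — replicate K
  values from small-n ITC studies scatter relatively (a few percent), not
  additively.
- **CD**: additive Gaussian, default sd 0.5 signal units against basis
  bands of ~85 units; basis spectra are smooth synthetic two-band shapes,
  labelled as stand-ins, not measured spectra.
- **Grids**: K-series concentrations default to 8 points over 0.01–0.18 mM
  and CD series to 1–100 mg·mL⁻¹ at l·c = 1, mirroring the experimental
  ranges the framework was demonstrated on.

A green recovery test therefore establishes that the estimators invert the
generating model at realistic noise — not that the model is true of any
real system, and not robustness to baseline drift, injection-volume error,
heat-of-dilution backgrounds, active-fraction uncertainty, or non-two-state
folding intermediates, none of which the generators simulate.

## Open design points, as resolved here

- The conceptual decomposition of $\Delta G^S$ into a water count times a
  per-molecule free-energy difference is documented but unhoused: no API
  accepts n or per-water energies.
- The instrument comparison (`fit_one_site_classical`) asserts only the
  qualitative claim that a constant-K fit can look excellent on
  governing-equation data while its K corresponds to the late-titration
  quotient; proprietary fitting internals (weighting, convergence rules)
  are not reverse-engineered.
- The concentration-independence statistic for CD reports a number; it
  deliberately has no built-in pass threshold because no quantitative
  detection limit accompanies the "relatively constant spectra" readout it
  formalises.
- Run configuration is JSON (schema-validated, unknown keys rejected); no
  YAML parser is available in the supported dependency set.

## Known limitations

Strict 1:1 stoichiometry (no multi-site or cooperative binding
polynomials); no raw power-trace processing (the pipeline starts from
integrated, background-subtracted heats); salt/counterion linked equilibria
are absorbed into $\Delta G^S$ rather than modelled; denaturant dependence
of folding $\Delta G^\circ$ is not modelled — each solvent condition is a
separate parameter set.
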