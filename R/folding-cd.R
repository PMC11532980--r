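#' Two-state folding system
#'
#' A protein at total molar concentration `P_total` in a U <-> F two-state
#' equilibrium, governed by
#' \deqn{\Delta G^\circ = -RT\,\ln\frac{[F]}{[U]} - [F]\,\Delta G^S,}
#' with `[F] = f_F * P_total`. The folding direction is U -> F, so a positive
#' ΔG^S penalises folding as the protein concentration rises; at ΔG^S = 0 the
#' folded fraction is independent of concentration.
#'
#' @param P_total Total protein concentration, molar; alternatively give
#'   `conc_mg_per_mL` with a `molar_mass`.
#' @param params A [governing_params()] for the U -> F transition.
#' @param conc_mg_per_mL Optional mass concentration, converted with
#'   `molar_mass`.
#' @param molar_mass Molar mass, g·mol⁻¹; the default 14178 corresponds to
#'   bovine alpha-lactalbumin (a package default for convenience, not a
#'   measured quantity).
#' @return An object of class `"folding_system"`.
#' @export
folding_system <- function(P_total = NULL, params,
                           conc_mg_per_mL = NULL, molar_mass = 14178) {
  stopifnot(inherits(params, "governing_params"), molar_mass > 0)
  if (is.null(P_total) == is.null(conc_mg_per_mL)) {
    stop("supply exactly one of 'P_total' or 'conc_mg_per_mL'")
  }
  if (is.null(P_total)) P_total <- conc_mg_per_mL / molar_mass # g/L over g/mol
  stopifnot(is.numeric(P_total), length(P_total) == 1L,
            is.finite(P_total), P_total > 0)
  structure(list(P_total = P_total, params = params, molar_mass = molar_mass),
            class = "folding_system")
}

#' Equilibrium folded fraction under the governing equation
#'
#' Solves for the fraction folded f_F in (0, 1) at which
#' \deqn{-RT\,\ln\frac{f_F}{1 - f_F} - f_F P_{tot}\,\Delta G^S
#'  - \Delta G^\circ = 0.}
#' The residual runs from +Inf at f_F -> 0 to −Inf at f_F -> 1 and is
#' strictly decreasing for ΔG^S >= 0, giving a unique root; for ΔG^S < 0
#' multiple roots are possible and the smallest is returned with a warning.
#' At ΔG^S = 0 the closed form f_F = K/(1+K), K = exp(−ΔG°/RT), holds and
#' f_F does not depend on `P_total`.
#'
#' @param system A [folding_system()].
#' @param cond A [conditions()].
#' @param settings A [solver_settings()] (the edge guard and tolerance apply
#'   to f_F on (0, 1)).
#' @return f_F, dimensionless in (0, 1).
#' @examples
#' fs <- folding_system(P_total = 1e-3, params = governing_params(0, 0))
#' solve_folding_fraction(fs, conditions(temperature_C = 25))  # 0.5
#' @export
solve_folding_fraction <- function(system, cond, settings = solver_settings()) {
  stopifnot(inherits(system, "folding_system"), inherits(cond, "conditions"),
            inherits(settings, "solver_settings"))
  p <- system$params
  g <- function(f) {
    -cond$RT * (log(f) - log1p(-f)) -
      f * system$P_total * p$dG_solv - p$dG_standard
  }
  gp <- function(f) {
    -cond$RT * (1 / f + 1 / (1 - f)) - system$P_total * p$dG_solv
  }
  lo <- settings$edge_guard
  hi <- 1 - settings$edge_guard
  if (p$dG_solv >= 0) {
    if (!(g(lo) > 0 && g(hi) < 0)) {
      stop("no sign change on the guarded interval; infeasible parameters")
    }
    return(.bracket_root(g, lo, hi, settings$abs_tol, settings$max_iter, gp))
  }
  fs <- seq(lo, hi, length.out = 4096L)
  gs <- g(fs)
  sgn <- sign(gs)
  idx <- which(sgn[-1] != sgn[-length(sgn)] & sgn[-1] != 0)
  if (length(idx) == 0L) {
    stop("no sign change on the guarded interval; infeasible parameters")
  }
  roots <- vapply(idx, function(i) {
    .bracket_root(g, fs[i], fs[i + 1L], settings$abs_tol, settings$max_iter, gp)
  }, numeric(1))
  if (length(roots) > 1L) {
    warning(sprintf(
      "folding equation has %d roots; returning the smallest", length(roots)))
  }
  min(roots)
}

#' Near-UV CD spectrum container
#'
#' One wavelength scan with its acquisition metadata. In a dilution series the
#' product conc x pathlength is held constant so the number of molecules in
#' the beam — and hence the raw ellipticity for a fixed conformational state —
#' is the same for every sample.
#'
#' @param wavelength_nm Wavelength grid, nm (typically 250–320).
#' @param ellipticity Signal per wavelength (e.g. mdeg).
#' @param conc_mg_per_mL Protein concentration of the sample.
#' @param pathlength_cm Cuvette pathlength.
#' @return An object of class `"cd_spectrum"`.
#' @export
cd_spectrum <- function(wavelength_nm, ellipticity, conc_mg_per_mL = NA_real_,
                        pathlength_cm = NA_real_) {
  stopifnot(length(wavelength_nm) == length(ellipticity),
            all(is.finite(wavelength_nm)), all(is.finite(ellipticity)))
  structure(list(wavelength_nm = as.numeric(wavelength_nm),
                 ellipticity = as.numeric(ellipticity),
                 conc_mg_per_mL = conc_mg_per_mL,
                 pathlength_cm = pathlength_cm),
            class = "cd_spectrum")
}

#' Predicted two-state CD spectrum
#'
#' Linear two-basis mixing: the observed spectrum of a two-state ensemble is
#' the population-weighted sum of the pure folded and unfolded basis spectra,
#' \eqn{\theta(\lambda) = f_F\,\theta_F(\lambda) + (1-f_F)\,\theta_U(\lambda)}.
#' Any wavelength where the bases coincide (an isodichroic point) is invariant
#' under f_F.
#'
#' @param f_F Folded fraction in `[0, 1]`.
#' @param basis_folded,basis_unfolded [cd_spectrum()] objects on identical
#'   wavelength grids.
#' @return A [cd_spectrum()] (conc/pathlength metadata taken from the folded
#'   basis).
#' @export
predict_cd <- function(f_F, basis_folded, basis_unfolded) {
  stopifnot(inherits(basis_folded, "cd_spectrum"),
            inherits(basis_unfolded, "cd_spectrum"),
            is.numeric(f_F), length(f_F) == 1L, f_F >= 0, f_F <= 1)
  if (!isTRUE(all.equal(basis_folded$wavelength_nm,
                        basis_unfolded$wavelength_nm))) {
    stop("basis spectra must share one wavelength grid")
  }
  cd_spectrum(basis_folded$wavelength_nm,
              f_F * basis_folded$ellipticity +
                (1 - f_F) * basis_unfolded$ellipticity,
              conc_mg_per_mL = basis_folded$conc_mg_per_mL,
              pathlength_cm = basis_folded$pathlength_cm)
}

#' Concentration-independence statistic for a CD dilution series
#'
#' Quantifies how much a set of constant-(conc x pathlength) spectra move as
#' the protein concentration changes: the maximum over wavelengths of the
#' across-spectra range, normalised by the span between reference native and
#' unfolded signals (or, if no references are given, by the largest absolute
#' signal in the series). A value near zero supports ΔG^S ~ 0 — the
#' conformational equilibrium does not shift with concentration; the
#' pass/fail threshold is a reporting choice left to the caller.
#'
#' @param spectra List of >= 2 [cd_spectrum()] objects on one wavelength
#'   grid with constant conc x pathlength (checked to 1% relative when the
#'   metadata are present).
#' @param basis_folded,basis_unfolded Optional reference spectra defining the
#'   native-to-unfolded signal span used for normalisation.
#' @return Dimensionless non-negative statistic.
#' @export
concentration_independence_stat <- function(spectra, basis_folded = NULL,
                                            basis_unfolded = NULL) {
  stopifnot(is.list(spectra), length(spectra) >= 2L,
            all(vapply(spectra, inherits, logical(1), "cd_spectrum")))
  wl <- spectra[[1]]$wavelength_nm
  for (s in spectra[-1]) {
    if (!isTRUE(all.equal(s$wavelength_nm, wl))) {
      stop("all spectra must share one wavelength grid")
    }
  }
  lc <- vapply(spectra, function(s) s$conc_mg_per_mL * s$pathlength_cm,
               numeric(1))
  if (all(is.finite(lc)) && (max(lc) - min(lc)) > 0.01 * max(abs(lc))) {
    stop("conc x pathlength is not constant across the series")
  }
  mat <- vapply(spectra, function(s) s$ellipticity, numeric(length(wl)))
  rng <- apply(mat, 1, function(v) max(v) - min(v))
  span <- if (!is.null(basis_folded) && !is.null(basis_unfolded)) {
    max(abs(basis_folded$ellipticity - basis_unfolded$ellipticity))
  } else {
    max(abs(mat))
  }
  if (span == 0) return(0)
  max(rng) / span
}
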