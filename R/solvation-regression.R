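#' Extract solvation and standard free energies from a K-vs-concentration series
#'
#' The headline estimator of the framework: since the governing equation reads
#' \eqn{-RT\ln K = \Delta G^\circ + [AB]\,\Delta G^S}, a set of equilibrium
#' quotients measured at several complex concentrations, plotted as
#' −RT·lnK against [AB], falls on a straight line whose slope is ΔG^S and
#' whose intercept is ΔG°. This fits that line by ordinary least squares
#' (default) or by inverse-variance weighting when replicate dispersions of K
#' are available. Replicate SDs are propagated to the free-energy scale by the
#' delta method, sd(y) = RT·K_sd/K.
#'
#' @param points An [equilibrium_points()] data frame (or any data frame with
#'   columns `K`, `complex_conc`, `temperature_K` and optionally `K_sd`); all
#'   rows must share one temperature.
#' @param cond Optional [conditions()]; defaults to the points' common
#'   temperature. Supplying one that disagrees with the data is an error.
#' @param weighting `"none"` (OLS, default) or `"inverse_variance"` (requires
#'   finite `K_sd` on every point).
#' @return An object of class `"solvation_fit"`: list with `dG_solv` (slope),
#'   `dG_standard` (intercept), `se_slope`, `se_intercept`, `r_squared`,
#'   `n_points`, `weighting`, and the underlying `lm` fit.
#' @examples
#' pts <- equilibrium_points(K = c(6.1e4, 5.2e4),
#'                           complex_conc = c(1.0e-5, 1.5e-4),
#'                           temperature_K = 298.15)
#' fit_solvation_line(pts)
#' @export
fit_solvation_line <- function(points, cond = NULL,
                               weighting = c("none", "inverse_variance")) {
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(points),
            all(c("K", "complex_conc", "temperature_K") %in% names(points)))
  if (nrow(points) < 2L) stop("need at least 2 points")
  temps <- unique(points$temperature_K)
  if (length(temps) != 1L) {
    stop("all points must share one temperature; fit each temperature separately")
  }
  if (is.null(cond)) {
    cond <- conditions(temperature_K = temps)
  } else if (abs(cond$temperature_K - temps) > 1e-9) {
    stop("supplied conditions disagree with the points' temperature")
  }
  x <- points$complex_conc
  if (stats::sd(x) == 0) stop("complex concentrations have zero spread; fit is singular")
  y <- effective_deltaG(points$K, cond)

  w <- NULL
  if (weighting == "inverse_variance") {
    if (!("K_sd" %in% names(points)) || any(!is.finite(points$K_sd)) ||
        any(points$K_sd <= 0)) {
      stop("inverse-variance weighting needs a finite positive K_sd on every point")
    }
    sd_y <- cond$RT * points$K_sd / points$K
    w <- 1 / sd_y^2
  }
  fit <- stats::lm(y ~ x, weights = w)
  sm <- .quiet_perfect_fit(summary(fit))
  structure(list(
    dG_solv = unname(stats::coef(fit)[2]),
    dG_standard = unname(stats::coef(fit)[1]),
    se_slope = sm$coefficients[2, 2],
    se_intercept = sm$coefficients[1, 2],
    r_squared = sm$r.squared,
    n_points = nrow(points),
    weighting = weighting,
    temperature_K = cond$temperature_K,
    lm_fit = fit
  ), class = "solvation_fit")
}

#' @export
print.solvation_fit <- function(x, ...) {
  cat(sprintf("characteristic-plot fit (n = %d, %s, T = %.2f K)\n",
              x$n_points, x$weighting, x$temperature_K))
  cat(sprintf("  dG_solv (slope)        = %+.4g +/- %.2g kcal/mol per M complex\n",
              x$dG_solv, x$se_slope))
  cat(sprintf("  dG_standard (intercept) = %+.4g +/- %.2g kcal/mol\n",
              x$dG_standard, x$se_intercept))
  cat(sprintf("  r^2 = %.4f\n", x$r_squared))
  invisible(x)
}

#' Solvation free energy per base pair
#'
#' Divides a duplex-level ΔG^S by the number of base pairs, the per-base-pair
#' normalisation used to compare duplexes of different length.
#'
#' @param dG_solv ΔG^S in kcal·mol⁻¹ per molar complex.
#' @param n_bp Number of base pairs, >= 1.
#' @return kcal·mol⁻¹ per base pair.
#' @examples
#' per_base_pair(4600, 10)  # 460
#' @export
per_base_pair <- function(dG_solv, n_bp) {
  stopifnot(is.numeric(dG_solv), is.numeric(n_bp), length(n_bp) == 1L,
            n_bp >= 1, n_bp == round(n_bp))
  dG_solv / n_bp
}
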