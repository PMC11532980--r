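#' Configuration for the synthetic-data generators
#'
#' One seeded configuration object shared by all generators, fixing the true
#' thermodynamic parameters and the noise model of each measurement type:
#' additive Gaussian noise on injection heats, multiplicative lognormal noise
#' on equilibrium quotients (errors on K are relative), and additive Gaussian
#' noise on CD ellipticities. Identical configurations produce identical
#' outputs.
#'
#' Defaults mirror the experimental regime the package targets: a 28 x 10 uL
#' titration into a 1.45 mL cell with the syringe 10-fold above a 0.20 mM
#' cell, duplex-hybridization-scale energetics (ΔG° = −9.3 kcal·mol⁻¹,
#' ΔG^S = +4600 kcal·mol⁻¹ per molar complex, ΔH = −47 kcal·mol⁻¹), a
#' 5% relative dispersion on K (typical of small replicate sets), and a
#' ~0.02 ucal heat noise floor.
#'
#' @param seed Integer seed; every generator call is deterministic given the
#'   full config.
#' @param params True [governing_params()].
#' @param dH_true True binding enthalpy, kcal·mol⁻¹.
#' @param temperature_C Temperature, degrees Celsius.
#' @param schedule An [injection_schedule()] for ITC generation.
#' @param heat_noise_sd SD of additive Gaussian heat noise, kcal per
#'   injection.
#' @param K_lognormal_sd SD of log K under multiplicative lognormal noise
#'   (~ relative error of K for small values).
#' @param cd_noise_sd SD of additive Gaussian CD noise, signal units.
#' @param molar_mass Molar mass for mg/mL conversions in CD generation.
#' @return An object of class `"synth_config"`.
#' @export
synth_config <- function(seed = 1L,
                         params = governing_params(-9.3, 4600),
                         dH_true = -47,
                         temperature_C = 25,
                         schedule = injection_schedule(
                           n_injections = 28L,
                           injection_volume = 10e-6,
                           cell_volume = 1.45e-3,
                           syringe_conc = 2e-3,
                           cell_conc_initial = 2e-4),
                         heat_noise_sd = 2e-8,
                         K_lognormal_sd = 0.05,
                         cd_noise_sd = 0.5,
                         molar_mass = 14178) {
  stopifnot(heat_noise_sd >= 0, K_lognormal_sd >= 0, cd_noise_sd >= 0,
            inherits(params, "governing_params"),
            inherits(schedule, "injection_schedule"))
  structure(list(seed = as.integer(seed), params = params, dH_true = dH_true,
                 temperature_C = temperature_C, schedule = schedule,
                 heat_noise_sd = heat_noise_sd,
                 K_lognormal_sd = K_lognormal_sd,
                 cd_noise_sd = cd_noise_sd, molar_mass = molar_mass),
            class = "synth_config")
}

#' Generate a noisy ITC experiment
#'
#' Simulates a titration under the true governing parameters, then adds
#' independent Gaussian noise to each per-injection heat (and renormalises
#' `q_norm` accordingly). The output table uses the same schema the fitting
#' readers consume, so generated experiments round-trip through
#' [write_heats_table()] / [read_heats_table()].
#'
#' @param config A [synth_config()].
#' @return A list with `trace` (a `"titration_trace"` whose `q_kcal` column
#'   carries the noise) and `schedule`.
#' @export
gen_itc_experiment <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  cond <- conditions(temperature_C = config$temperature_C)
  tr <- simulate_titration(config$schedule, config$params, config$dH_true, cond)
  if (config$heat_noise_sd > 0) {
    tr$q_kcal <- tr$q_kcal + stats::rnorm(nrow(tr), 0, config$heat_noise_sd)
    tr$q_norm_kcal_per_mol <-
      tr$q_kcal / (tr$volume_L * config$schedule$syringe_conc)
  }
  list(trace = tr, schedule = config$schedule)
}

#' Generate a K-versus-concentration series
#'
#' For each target complex concentration on the grid, the quotient implied by
#' the governing equation, K = exp[(−ΔG° − [AB]·ΔG^S)/RT], receives
#' multiplicative lognormal noise. The reported `K_sd` is the
#' relative-dispersion approximation `K * K_lognormal_sd`, mimicking a
#' replicate standard deviation.
#'
#' @param config A [synth_config()].
#' @param conc_grid Complex concentrations, molar; defaults to eight points
#'   spanning 0.01–0.18 mM, the working range of a duplex dilution series.
#' @return An [equilibrium_points()] data frame.
#' @export
gen_K_series <- function(config,
                         conc_grid = seq(1e-5, 1.8e-4, length.out = 8)) {
  stopifnot(inherits(config, "synth_config"), all(conc_grid >= 0))
  set.seed(config$seed)
  cond <- conditions(temperature_C = config$temperature_C)
  lnK <- (-config$params$dG_standard - conc_grid * config$params$dG_solv) /
    cond$RT
  K <- exp(lnK)
  if (config$K_lognormal_sd > 0) {
    K <- K * exp(stats::rnorm(length(K), 0, config$K_lognormal_sd))
  }
  equilibrium_points(K = K, complex_conc = conc_grid,
                     temperature_K = cond$temperature_K,
                     K_sd = if (config$K_lognormal_sd > 0)
                       K * config$K_lognormal_sd else NA_real_)
}

# smooth synthetic near-UV basis spectra: a folded (native) state with a deep
# aromatic band and an unfolded (molten-globule-like) state with most of the
# tertiary signal lost. Shapes are stand-ins for real basis spectra.
.synthetic_cd_bases <- function(wavelength_nm = seq(250, 320, by = 1)) {
  wl <- wavelength_nm
  folded <- -60 * exp(-((wl - 270) / 10)^2) - 25 * exp(-((wl - 292) / 8)^2)
  unfolded <- -8 * exp(-((wl - 272) / 14)^2)
  list(folded = cd_spectrum(wl, folded),
       unfolded = cd_spectrum(wl, unfolded))
}

#' Generate a constant-(conc x pathlength) CD dilution series
#'
#' Builds smooth synthetic folded/unfolded basis spectra, solves the
#' two-state folded fraction at each concentration under the true governing
#' parameters, mixes the bases accordingly, and adds Gaussian noise.
#' Pathlengths are chosen so conc x pathlength equals `lc_product` for every
#' sample, the acquisition convention that keeps the molecule count in the
#' beam constant.
#'
#' @param config A [synth_config()]; `params` here parameterise the U -> F
#'   folding transition.
#' @param conc_list Protein concentrations, mg·mL⁻¹; defaults to a
#'   1–100 mg·mL⁻¹ two-decade series.
#' @param lc_product Constant conc x pathlength, cm·mg·mL⁻¹.
#' @param wavelength_nm Wavelength grid, nm.
#' @return A list with `spectra` (list of [cd_spectrum()]), `f_F` (folded
#'   fraction per concentration), and `bases`.
#' @export
gen_cd_series <- function(config, conc_list = c(1, 3, 10, 30, 100),
                          lc_product = 1,
                          wavelength_nm = seq(250, 320, by = 1)) {
  stopifnot(inherits(config, "synth_config"), all(conc_list > 0),
            lc_product > 0)
  set.seed(config$seed)
  cond <- conditions(temperature_C = config$temperature_C)
  bases <- .synthetic_cd_bases(wavelength_nm)
  f_F <- vapply(conc_list, function(cmg) {
    solve_folding_fraction(
      folding_system(conc_mg_per_mL = cmg, params = config$params,
                     molar_mass = config$molar_mass), cond)
  }, numeric(1))
  spectra <- lapply(seq_along(conc_list), function(i) {
    s <- predict_cd(f_F[i], bases$folded, bases$unfolded)
    s$conc_mg_per_mL <- conc_list[i]
    s$pathlength_cm <- lc_product / conc_list[i]
    if (config$cd_noise_sd > 0) {
      s$ellipticity <- s$ellipticity +
        stats::rnorm(length(s$ellipticity), 0, config$cd_noise_sd)
    }
    s
  })
  list(spectra = spectra, f_F = f_F, bases = bases)
}
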