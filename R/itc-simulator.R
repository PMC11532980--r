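#' ITC injection schedule
#'
#' Describes a serial-injection titration: a syringe species injected in equal
#' aliquots into a fixed-volume cell. The default protocol mirrors a common
#' VP-ITC setup: 28 injections of 10 uL into a 1.45 mL cell with the syringe
#' 10-fold more concentrated than the cell.
#'
#' Two accounting modes for the per-injection totals are supported:
#' \describe{
#'   \item{`"paper"`}{constant-increment totals — after injection i,
#'     `Xt_i = i * (v * syringe_conc) / V` and `Mt` stays at its starting
#'     value (no dilution). This is the convention of the modelling study the
#'     package reproduces.}
#'   \item{`"displacement"`}{perfusion-cell accounting — each injection first
#'     displaces an equal volume of well-mixed cell contents, rescaling both
#'     totals by `(1 - v/V)`, before the new titrant is added. This is what a
#'     real overfill cell does; it converges to `"paper"` as v/V -> 0.}
#' }
#'
#' @param n_injections Number of injections, >= 1.
#' @param injection_volume Volume per injection, litres.
#' @param cell_volume Cell volume, litres.
#' @param syringe_conc Syringe concentration, molar.
#' @param cell_conc_initial Starting cell concentration, molar.
#' @param first_injection_volume Optional smaller first-injection volume,
#'   litres (instruments often use a short first shot whose peak is
#'   discarded); `NULL` means all injections are equal.
#' @param dilution_mode `"paper"` or `"displacement"`.
#' @return An object of class `"injection_schedule"`.
#' @export
injection_schedule <- function(n_injections = 28L,
                               injection_volume = 10e-6,
                               cell_volume = 1.45e-3,
                               syringe_conc,
                               cell_conc_initial,
                               first_injection_volume = NULL,
                               dilution_mode = c("paper", "displacement")) {
  dilution_mode <- match.arg(dilution_mode)
  stopifnot(n_injections >= 1, injection_volume > 0, cell_volume > 0,
            syringe_conc > 0, cell_conc_initial > 0,
            is.null(first_injection_volume) || first_injection_volume > 0)
  structure(
    list(n_injections = as.integer(n_injections),
         injection_volume = injection_volume,
         cell_volume = cell_volume,
         syringe_conc = syringe_conc,
         cell_conc_initial = cell_conc_initial,
         first_injection_volume = first_injection_volume,
         dilution_mode = dilution_mode),
    class = "injection_schedule"
  )
}

#' @export
print.injection_schedule <- function(x, ...) {
  cat(sprintf(
    "injection schedule: %d x %.3g uL into %.3g mL cell; syringe %.4g M, cell %.4g M (%s mode)\n",
    x$n_injections, x$injection_volume * 1e6, x$cell_volume * 1e3,
    x$syringe_conc, x$cell_conc_initial, x$dilution_mode))
  invisible(x)
}

# per-injection volumes, honouring a first-injection override
.injection_volumes <- function(schedule) {
  v <- rep(schedule$injection_volume, schedule$n_injections)
  if (!is.null(schedule$first_injection_volume)) {
    v[1] <- schedule$first_injection_volume
  }
  v
}

#' Per-injection total concentrations
#'
#' Expands a schedule into the running totals (Xt_i, Mt_i) after each
#' injection, under the schedule's dilution mode (see
#' [injection_schedule()]).
#'
#' @param schedule An [injection_schedule()].
#' @return A data frame with columns `injection`, `volume_L`, `Xt_M`, `Mt_M`,
#'   `molar_ratio` (= Xt/Mt).
#' @examples
#' sch <- injection_schedule(syringe_conc = 2e-3, cell_conc_initial = 2e-4)
#' head(build_schedule_totals(sch))
#' @export
build_schedule_totals <- function(schedule) {
  stopifnot(inherits(schedule, "injection_schedule"))
  v <- .injection_volumes(schedule)
  n <- schedule$n_injections
  V <- schedule$cell_volume
  if (schedule$dilution_mode == "paper") {
    Xt <- cumsum(v * schedule$syringe_conc) / V
    Mt <- rep(schedule$cell_conc_initial, n)
  } else {
    Xt <- Mt <- numeric(n)
    x <- 0; m <- schedule$cell_conc_initial
    for (i in seq_len(n)) {
      keep <- 1 - v[i] / V
      x <- x * keep + v[i] * schedule$syringe_conc / V
      m <- m * keep
      Xt[i] <- x; Mt[i] <- m
    }
  }
  data.frame(injection = seq_len(n), volume_L = v,
             Xt_M = Xt, Mt_M = Mt, molar_ratio = Xt / Mt)
}

#' Simulate a titration under the governing equation
#'
#' For each injection the totals are updated, the governing equation is solved
#' for the bound concentration Z, the equilibrium quotient is evaluated at the
#' root, and the injection heat is the binding enthalpy times the increase in
#' bound complex in the cell:
#' \deqn{q_i = \Delta H_{bind}\,(Z_i - Z_{i-1})\,V_{cell}, \qquad Z_0 = 0.}
#' Heats are also normalised per mole of injectant added that injection
#' (`q_norm`, kcal·mol⁻¹), the quantity plotted in an enthalpogram.
#'
#' When ΔG^S > 0 the quotient K_i declines injection by injection while the
#' titrant is in deficit and plateaus once the cell species is nearly
#' saturated; when ΔG^S = 0 the K_i column is constant.
#'
#' @param schedule An [injection_schedule()].
#' @param params A [governing_params()].
#' @param dH_bind Molar binding enthalpy, kcal·mol⁻¹ (held constant).
#' @param cond A [conditions()].
#' @param settings A [solver_settings()].
#' @return A data frame of class `"titration_trace"` with columns
#'   `injection`, `volume_L`, `Xt_M`, `Mt_M`, `molar_ratio`, `Z_M`, `K`,
#'   `q_kcal`, `q_norm_kcal_per_mol`.
#' @examples
#' sch <- injection_schedule(syringe_conc = 2e-3, cell_conc_initial = 2e-4)
#' tr <- simulate_titration(sch, governing_params(-9.30, 4000), -47,
#'                          conditions(temperature_C = 25))
#' @export
simulate_titration <- function(schedule, params, dH_bind, cond,
                               settings = solver_settings()) {
  stopifnot(inherits(schedule, "injection_schedule"),
            inherits(params, "governing_params"),
            inherits(cond, "conditions"),
            is.numeric(dH_bind), length(dH_bind) == 1L, is.finite(dH_bind))
  tot <- build_schedule_totals(schedule)
  n <- nrow(tot)
  Z <- K <- numeric(n)
  for (i in seq_len(n)) {
    sys <- binding_system(Xt = tot$Xt_M[i], Mt = tot$Mt_M[i])
    Z[i] <- tryCatch(
      solve_Z(sys, params, cond, settings),
      error = function(e) stop(sprintf("injection %d: %s", i, conditionMessage(e)),
                               call. = FALSE)
    )
    K[i] <- if (Z[i] > 0) K_at_equilibrium(sys, Z[i]) else NA_real_
  }
  dZ <- diff(c(0, Z))
  q <- dH_bind * dZ * schedule$cell_volume
  mol_injected <- tot$volume_L * schedule$syringe_conc
  out <- cbind(tot, data.frame(Z_M = Z, K = K, q_kcal = q,
                               q_norm_kcal_per_mol = q / mol_injected))
  class(out) <- c("titration_trace", "data.frame")
  out
}

#' Match a fitted/simulated K to its complex concentration
#'
#' The pairing rule that places an ITC-derived quotient on the characteristic
#' plot: the quotient is matched with the concentration of bound complex at
#' the last injection before the molar ratio exceeds 1:1, where the cell
#' species has become the limiting reactant.
#'
#' `convention = "brandts"` applies the alternative convention used when the
#' per-injection trace is not available: the complex concentration is taken as
#' 90% of the starting cell concentration, with K from the same
#' last-pre-equivalence injection.
#'
#' @param trace A `"titration_trace"` from [simulate_titration()].
#' @param convention `"last_pre_equivalence"` (default) or `"brandts"`.
#' @param cell_conc_initial Starting cell concentration (molar); required for
#'   the `"brandts"` convention.
#' @return A one-row [equilibrium_points()] data frame (temperature is not
#'   carried by the trace and is set to `NA`; attach it when assembling a
#'   measured series), plus attribute `injection` giving the selected index.
#' @export
match_K_to_concentration <- function(trace,
                                     convention = c("last_pre_equivalence",
                                                    "brandts"),
                                     cell_conc_initial = NULL) {
  convention <- match.arg(convention)
  stopifnot(inherits(trace, "titration_trace"))
  ok <- which(trace$molar_ratio <= 1)
  if (length(ok) == 0L) {
    stop("all injections exceed molar ratio 1; schedule and cell concentration are mismatched")
  }
  i <- max(ok)
  conc <- if (convention == "brandts") {
    if (is.null(cell_conc_initial)) {
      stop("'cell_conc_initial' is required for the brandts convention")
    }
    0.90 * cell_conc_initial
  } else {
    trace$Z_M[i]
  }
  pt <- data.frame(K = trace$K[i], complex_conc = conc,
                   temperature_K = NA_real_, K_sd = NA_real_)
  class(pt) <- c("equilibrium_points", "data.frame")
  attr(pt, "injection") <- i
  pt
}
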