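#' Totals of a 1:1 binding system
#'
#' @param Xt Total titrant (injected species) concentration, molar, >= 0.
#' @param Mt Total cell-species concentration, molar, > 0.
#' @return An object of class `"binding_system"`.
#' @export
binding_system <- function(Xt, Mt) {
  stopifnot(is.numeric(Xt), length(Xt) == 1L, is.finite(Xt), Xt >= 0,
            is.numeric(Mt), length(Mt) == 1L, is.finite(Mt), Mt > 0)
  structure(list(Xt = Xt, Mt = Mt), class = "binding_system")
}

#' Root-finder settings for the governing equation
#'
#' @param abs_tol Absolute bracket-width stopping tolerance on Z, molar.
#' @param max_iter Maximum bisection/secant iterations.
#' @param edge_guard Fraction of min(Xt, Mt) excluded at each end of the
#'   search interval, keeping the log terms finite.
#' @return An object of class `"solver_settings"`.
#' @export
solver_settings <- function(abs_tol = 1e-15, max_iter = 200L,
                            edge_guard = 1e-12) {
  stopifnot(abs_tol > 0, max_iter >= 1, edge_guard > 0, edge_guard < 0.5)
  structure(list(abs_tol = abs_tol, max_iter = as.integer(max_iter),
                 edge_guard = edge_guard),
            class = "solver_settings")
}

# Safeguarded bracketing on [lo, hi] where g(lo) > 0 > g(hi). Brent's method
# (inverse-interpolation steps guarded by bisection, as implemented by
# stats::uniroot) is derivative-free and robust against the log blow-ups at
# the interval edges.
.bracket_root <- function(g, lo, hi, abs_tol, max_iter, gprime = NULL) {
  r <- stats::uniroot(g, lower = lo, upper = hi,
                      f.lower = g(lo), f.upper = g(hi),
                      tol = max(abs_tol, .Machine$double.eps * hi),
                      maxiter = max_iter)
  x <- r$root
  if (!is.null(gprime)) {
    # Newton polish: uniroot's interval tolerance is not tight enough for
    # quantities (like K near saturation) that amplify the error in the root
    for (i in 1:3) {
      d <- gprime(x)
      if (!is.finite(d) || d == 0) break
      step <- g(x) / d
      xn <- x - step
      if (!is.finite(xn) || xn <= lo || xn >= hi) break
      x <- xn
      if (abs(step) <= .Machine$double.eps * abs(x)) break
    }
  }
  x
}

#' Solve the governing equation for the equilibrium complex concentration
#'
#' Finds the bound-complex concentration Z at which the solvation-corrected
#' governing equation balances, i.e. the root of [governing_residual()] in the
#' open interval (0, min(Xt, Mt)). For ΔG^S >= 0 the residual is strictly
#' decreasing, the root is unique, and bracketed bisection refined by
#' safeguarded secant steps converges unconditionally. For ΔG^S < 0 the
#' residual may change sign more than once; the interval is then scanned on a
#' fine grid, the smallest root is returned, and a multiplicity warning lists
#' all bracketed sign changes.
#'
#' @param system A [binding_system()]; if `Xt == 0` (before the first
#'   injection) `Z = 0` is returned without iteration.
#' @param params A [governing_params()].
#' @param cond A [conditions()].
#' @param settings A [solver_settings()].
#' @return Z in molar, satisfying 0 < Z < min(Xt, Mt) (or exactly 0 for
#'   Xt = 0).
#' @examples
#' sys <- binding_system(Xt = 1e-4, Mt = 2e-4)
#' solve_Z(sys, governing_params(-9.30, 4000), conditions(temperature_C = 25))
#' @export
solve_Z <- function(system, params, cond, settings = solver_settings()) {
  stopifnot(inherits(system, "binding_system"),
            inherits(params, "governing_params"),
            inherits(cond, "conditions"),
            inherits(settings, "solver_settings"))
  if (system$Xt == 0) return(0)
  m <- min(system$Xt, system$Mt)
  lo <- settings$edge_guard * m
  hi <- (1 - settings$edge_guard) * m
  g <- function(Z) governing_residual(Z, system$Xt, system$Mt, params, cond)
  gp <- function(Z) {
    -cond$RT * (1 / Z + 1 / (system$Xt - Z) + 1 / (system$Mt - Z)) -
      params$dG_solv
  }

  if (params$dG_solv >= 0) {
    # monotone: g(lo) > 0 > g(hi) is guaranteed by the log limits
    if (!(g(lo) > 0 && g(hi) < 0)) {
      stop("no sign change on the guarded interval; infeasible parameters")
    }
    return(.bracket_root(g, lo, hi, settings$abs_tol, settings$max_iter, gp))
  }

  # dG_solv < 0: scan for (possibly multiple) sign changes
  zs <- seq(lo, hi, length.out = 4096L)
  gs <- g(zs)
  sgn <- sign(gs)
  idx <- which(sgn[-1] != sgn[-length(sgn)] & sgn[-1] != 0)
  if (length(idx) == 0L) {
    if (any(gs == 0)) return(zs[which(gs == 0)[1]])
    stop("no sign change on the guarded interval; infeasible parameters")
  }
  roots <- vapply(idx, function(i) {
    .bracket_root(g, zs[i], zs[i + 1L], settings$abs_tol, settings$max_iter, gp)
  }, numeric(1))
  if (length(roots) > 1L) {
    warning(sprintf(
      "governing equation has %d roots in (0, min(Xt, Mt)) at Z = %s; returning the smallest",
      length(roots), paste(signif(sort(roots), 6), collapse = ", ")))
  }
  min(roots)
}

#' Closed-form classical 1:1 equilibrium concentration
#'
#' In the zero-solvation limit the governing equation reduces to the classical
#' constant-K equilibrium, whose bound concentration is the smaller root of
#' \eqn{Z^2 - (X_t + M_t + 1/K)Z + X_t M_t = 0}. Evaluated in the numerically
#' stable form \eqn{Z = 2 X_t M_t / (b + \sqrt{b^2 - 4 X_t M_t})} with
#' \eqn{b = X_t + M_t + 1/K}, which avoids cancellation for large K. Used as
#' the independent oracle for [solve_Z()] and inside the classical one-site
#' ITC fit.
#'
#' @param system A [binding_system()].
#' @param K Dimensionless equilibrium constant, > 0.
#' @return Z in molar, 0 <= Z < min(Xt, Mt).
#' @export
classical_Z <- function(system, K) {
  stopifnot(inherits(system, "binding_system"),
            is.numeric(K), length(K) == 1L, is.finite(K), K > 0)
  Xt <- system$Xt; Mt <- system$Mt
  if (Xt == 0) return(0)
  b <- Xt + Mt + 1 / K
  disc <- b * b - 4 * Xt * Mt
  if (disc < 0) disc <- 0 # impossible for valid inputs; guard roundoff
  2 * Xt * Mt / (b + sqrt(disc))
}

#' Equilibrium quotient implied by a bound concentration
#'
#' K = Z / ((Xt − Z)(Mt − Z)), molar-based. This is the quotient inside the
#' logarithm of the governing equation, evaluated at the solved root.
#'
#' @param system A [binding_system()].
#' @param Z Bound-complex concentration, molar, strictly inside
#'   (0, min(Xt, Mt)).
#' @return Dimensionless K.
#' @export
K_at_equilibrium <- function(system, Z) {
  stopifnot(inherits(system, "binding_system"))
  m <- min(system$Xt, system$Mt)
  if (!is.finite(Z) || Z <= 0 || Z >= m) {
    stop("Z must lie strictly inside (0, min(Xt, Mt))")
  }
  Z / ((system$Xt - Z) * (system$Mt - Z))
}
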