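# Model heats for the classical constant-K one-site model: the bound
# concentration after injection i comes from the quadratic closed form with
# an effective cell concentration n * Mt_i (site number n absorbs active
# fraction / stoichiometry, as instrument software does).
.classical_model_heats <- function(K, dH, n, tot, cell_volume) {
  Z <- vapply(seq_len(nrow(tot)), function(i) {
    classical_Z(binding_system(Xt = tot$Xt_M[i], Mt = n * tot$Mt_M[i]), K)
  }, numeric(1))
  dH * diff(c(0, Z)) * cell_volume
}

.governing_model_heats <- function(params, dH, tot, cell_volume, cond, settings) {
  Z <- vapply(seq_len(nrow(tot)), function(i) {
    solve_Z(binding_system(Xt = tot$Xt_M[i], Mt = tot$Mt_M[i]),
            params, cond, settings)
  }, numeric(1))
  dH * diff(c(0, Z)) * cell_volume
}

# standard errors from the numerical hessian of the rss objective:
# H ~ 2 J'J, so cov(theta) ~ 2 * sigma^2 * H^{-1} with sigma^2 = rss / (N - p)
.se_from_hessian <- function(hess, rss, n_obs, n_par) {
  se <- rep(NA_real_, n_par)
  dof <- n_obs - n_par
  if (dof > 0) {
    cov <- try(2 * (rss / dof) * solve(hess), silent = TRUE)
    if (!inherits(cov, "try-error")) {
      d <- diag(cov)
      se <- ifelse(d >= 0, sqrt(d), NA_real_)
    }
  }
  se
}

# shared preprocessing: align heats to the schedule totals, optionally
# subtract a constant background and drop the first injection
.prepare_heats <- function(heats, schedule, exclude_first, background) {
  tot <- build_schedule_totals(schedule)
  if (length(heats) != nrow(tot)) {
    stop(sprintf("got %d heats for a %d-injection schedule",
                 length(heats), nrow(tot)))
  }
  heats <- heats - background
  keep <- rep(TRUE, length(heats))
  if (exclude_first) keep[1] <- FALSE
  list(tot = tot, heats = heats, keep = keep)
}

#' Fit the classical one-site (constant-K) model to ITC heats
#'
#' Least-squares fit of the Wiseman-style 1:1 binding model — the model built
#' into ITC instrument software — to a vector of integrated injection heats.
#' The fitted parameters are the apparent association constant `K_app`, the
#' apparent molar enthalpy `dH_app` (kcal·mol⁻¹), and the site number
#' `n_stoich`; the bound concentration at each injection is the closed-form
#' quadratic root with effective cell concentration `n * Mt`.
#'
#' Optimisation is Nelder-Mead on (log10 K, ΔH, n) from a coarse log-K grid
#' initialisation (ΔH scaled by linear least squares at each grid node),
#' followed by a BFGS polish. Standard errors come from the numerical Hessian
#' of the residual sum of squares.
#'
#' @param heats Per-injection heats, kcal (total heat per injection, aligned
#'   to the schedule).
#' @param schedule An [injection_schedule()].
#' @param cond A [conditions()] (carried for provenance; the classical model
#'   itself is temperature-free once K is a parameter).
#' @param init Optional named list with starting values `K`, `dH`, `n`.
#' @param exclude_first Drop the first injection from the fit (common when a
#'   short first shot is discarded)?
#' @param background Constant background injection heat, kcal, subtracted
#'   from every heat before fitting.
#' @param fix_n Optionally fix the site number at this value (e.g. `1`)
#'   instead of fitting it.
#' @return An object of class `"one_site_fit"`: a list with `K_app`,
#'   `dH_app`, `n_stoich`, `rss`, `se` (named vector), `converged`,
#'   `residuals`, `fitted`, `n_used`.
#' @export
fit_one_site_classical <- function(heats, schedule, cond, init = NULL,
                                   exclude_first = FALSE, background = 0,
                                   fix_n = NULL) {
  stopifnot(inherits(schedule, "injection_schedule"),
            inherits(cond, "conditions"), is.numeric(heats))
  prep <- .prepare_heats(heats, schedule, exclude_first, background)
  tot <- prep$tot; keep <- prep$keep; y <- prep$heats
  if (sum(keep) < 5L) stop("need at least 5 usable injections")
  if (all(abs(y[keep]) < .Machine$double.eps * 10) || stats::sd(y[keep]) == 0) {
    stop("heats are flat; K is unidentifiable from this trace")
  }
  V <- schedule$cell_volume

  n_free <- is.null(fix_n)
  obj <- function(theta) {
    K <- 10^theta[1]; dH <- theta[2]
    n <- if (n_free) theta[3] else fix_n
    if (!is.finite(K) || K <= 0 || n <= 0) return(1e30)
    mu <- .classical_model_heats(K, dH, n, tot, V)
    sum((y[keep] - mu[keep])^2)
  }

  if (is.null(init)) {
    # coarse search: for each K on a log grid (n = 1), the model is linear in
    # dH, so profile it out analytically
    best <- NULL
    for (lk in seq(2, 9, by = 0.5)) {
      shape <- .classical_model_heats(10^lk, 1, if (n_free) 1 else fix_n, tot, V)
      ss <- sum(shape[keep]^2)
      if (ss == 0) next
      dH0 <- sum(y[keep] * shape[keep]) / ss
      r <- sum((y[keep] - dH0 * shape[keep])^2)
      if (is.null(best) || r < best$rss) best <- list(lk = lk, dH = dH0, rss = r)
    }
    if (is.null(best)) stop("initialisation failed; heats carry no binding signal")
    init <- list(K = 10^best$lk, dH = best$dH, n = 1)
  }
  theta0 <- c(log10(init$K), init$dH, if (n_free) init$n)

  opt <- stats::optim(theta0, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  opt <- stats::optim(opt$par, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12),
                      hessian = TRUE)

  K <- 10^opt$par[1]; dH <- opt$par[2]
  n <- if (n_free) opt$par[3] else fix_n
  mu <- .classical_model_heats(K, dH, n, tot, V)
  p <- length(opt$par)
  se_theta <- .se_from_hessian(opt$hessian, opt$value, sum(keep), p)
  se <- c(K_app = K * log(10) * se_theta[1], dH_app = se_theta[2],
          n_stoich = if (n_free) se_theta[3] else NA_real_)

  structure(list(K_app = K, dH_app = dH, n_stoich = n,
                 rss = opt$value, se = se,
                 converged = opt$convergence == 0,
                 residuals = (y - mu)[keep], fitted = mu,
                 n_used = sum(keep)),
            class = "one_site_fit")
}

#' @export
print.one_site_fit <- function(x, ...) {
  cat(sprintf("classical one-site fit (%d injections)\n", x$n_used))
  cat(sprintf("  K_app    = %.4g  (se %.3g)\n", x$K_app, x$se[["K_app"]]))
  cat(sprintf("  dH_app   = %.4g kcal/mol  (se %.3g)\n", x$dH_app, x$se[["dH_app"]]))
  cat(sprintf("  n_stoich = %.4g\n", x$n_stoich))
  cat(sprintf("  rss = %.4g kcal^2; converged: %s\n", x$rss, x$converged))
  invisible(x)
}

#' Fit the governing (solvation-corrected) model to a single enthalpogram
#'
#' Direct least squares over (ΔG°, ΔG^S, ΔH) with the bound concentration at
#' each injection solved from the governing equation. From a single titration
#' at one cell concentration, ΔG° and ΔG^S are only weakly identifiable — the
#' same near-constant late-titration quotient can be produced by many
#' (ΔG°, ΔG^S) pairs — so a warning is emitted unless ΔG^S is fixed; the
#' multi-concentration regression ([fit_solvation_line()]) is the estimator
#' of record for ΔG^S.
#'
#' @inheritParams fit_one_site_classical
#' @param init Optional named list with starting values `dG_standard`,
#'   `dG_solv`, `dH`.
#' @param fix Optional named list of parameters to hold fixed, e.g.
#'   `list(dG_solv = 0)` (which nests the classical one-site model at n = 1).
#' @param settings A [solver_settings()] for the inner equilibrium solves.
#' @return An object of class `"governing_fit"`: list with `params` (a
#'   [governing_params()]), `dH`, `rss`, `se`, `converged`, `residuals`,
#'   `fitted`, `n_used`.
#' @export
fit_governing_global <- function(heats, schedule, cond, init = NULL,
                                 fix = list(), exclude_first = FALSE,
                                 background = 0,
                                 settings = solver_settings()) {
  stopifnot(inherits(schedule, "injection_schedule"),
            inherits(cond, "conditions"), is.numeric(heats),
            is.list(fix))
  prep <- .prepare_heats(heats, schedule, exclude_first, background)
  tot <- prep$tot; keep <- prep$keep; y <- prep$heats
  if (sum(keep) < 5L) stop("need at least 5 usable injections")
  if (all(abs(y[keep]) < .Machine$double.eps * 10)) {
    stop("heats are flat; parameters are unidentifiable from this trace")
  }
  V <- schedule$cell_volume

  free <- setdiff(c("dG_standard", "dG_solv", "dH"), names(fix))
  if (!("dG_solv" %in% names(fix))) {
    warning(paste("dG_standard and dG_solv are weakly identifiable from a",
                  "single titration; prefer fit_solvation_line on a",
                  "multi-concentration series"))
  }

  if (is.null(init)) {
    cls <- fit_one_site_classical(heats, schedule, cond,
                                  exclude_first = exclude_first,
                                  background = background, fix_n = 1)
    init <- list(dG_standard = effective_deltaG(cls$K_app, cond),
                 dG_solv = 0, dH = cls$dH_app)
  }
  full <- function(theta) {
    v <- as.list(theta); names(v) <- free
    utils::modifyList(utils::modifyList(init, fix), v)
  }
  obj <- function(theta) {
    p <- full(theta)
    mu <- try(.governing_model_heats(
      governing_params(p$dG_standard, p$dG_solv), p$dH, tot, V, cond, settings),
      silent = TRUE)
    if (inherits(mu, "try-error") || any(!is.finite(mu))) return(1e30)
    sum((y[keep] - mu[keep])^2)
  }
  theta0 <- unlist(init[free])

  opt <- stats::optim(theta0, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  if (length(theta0) == 1L) {
    opt <- stats::optim(opt$par, obj, method = "Brent",
                        lower = opt$par - 5, upper = opt$par + 5)
    opt$hessian <- stats::optimHess(opt$par, obj)
  } else {
    opt <- stats::optim(opt$par, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12),
                        hessian = TRUE)
  }

  p <- full(opt$par)
  params <- governing_params(p$dG_standard, p$dG_solv)
  mu <- .governing_model_heats(params, p$dH, tot, V, cond, settings)
  se_theta <- .se_from_hessian(opt$hessian, opt$value, sum(keep), length(opt$par))
  se <- stats::setNames(rep(NA_real_, 3), c("dG_standard", "dG_solv", "dH"))
  se[free] <- se_theta

  structure(list(params = params, dH = p$dH, rss = opt$value, se = se,
                 converged = opt$convergence == 0,
                 residuals = (y - mu)[keep], fitted = mu,
                 n_used = sum(keep), fixed = fix),
            class = "governing_fit")
}

#' @export
print.governing_fit <- function(x, ...) {
  cat(sprintf("governing-equation fit (%d injections)\n", x$n_used))
  cat(sprintf("  dG_standard = %.4g kcal/mol (se %.3g)\n",
              x$params$dG_standard, x$se[["dG_standard"]]))
  cat(sprintf("  dG_solv     = %.4g kcal/mol per M (se %.3g)\n",
              x$params$dG_solv, x$se[["dG_solv"]]))
  cat(sprintf("  dH          = %.4g kcal/mol (se %.3g)\n", x$dH, x$se[["dH"]]))
  cat(sprintf("  rss = %.4g kcal^2; converged: %s\n", x$rss, x$converged))
  if (length(x$fixed)) {
    cat("  fixed:", paste(names(x$fixed), unlist(x$fixed), sep = " = ",
                          collapse = ", "), "\n")
  }
  invisible(x)
}
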