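# Independent oracles. These deliberately re-derive everything from the raw
# formulas (no package solver calls) so that agreement with the package is a
# genuine cross-check, not a tautology.

# residual of the governing equation, written out from scratch
oracle_residual <- function(Z, Xt, Mt, dG0, dGS, T_K, R = 1.9872e-3) {
  -R * T_K * log(Z / ((Xt - Z) * (Mt - Z))) - Z * dGS - dG0
}

# brute-force root: uniform sign scan over the open interval followed by
# plain hand-rolled bisection on the bracketing cell
oracle_grid_root <- function(Xt, Mt, dG0, dGS, T_K, n_grid = 1e5,
                             n_bisect = 200) {
  m <- min(Xt, Mt)
  zs <- seq(m * 1e-9, m * (1 - 1e-9), length.out = n_grid)
  gs <- oracle_residual(zs, Xt, Mt, dG0, dGS, T_K)
  idx <- which(sign(gs[-1]) != sign(gs[-n_grid]))
  if (length(idx) == 0L) return(NULL)
  roots <- vapply(idx, function(i) {
    lo <- zs[i]; hi <- zs[i + 1L]
    flo <- oracle_residual(lo, Xt, Mt, dG0, dGS, T_K)
    for (k in seq_len(n_bisect)) {
      mid <- (lo + hi) / 2
      fm <- oracle_residual(mid, Xt, Mt, dG0, dGS, T_K)
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  roots
}

# bisection on the two-state folding residual, same hand-rolled style
oracle_folding_root <- function(P, dG0, dGS, T_K, R = 1.9872e-3) {
  g <- function(f) -R * T_K * log(f / (1 - f)) - f * P * dGS - dG0
  lo <- 1e-12; hi <- 1 - 1e-12
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    if (sign(g(mid)) == sign(g(lo))) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# the published unstacking-correction inputs for the oligo10/10c duplex
# (per-strand unstacking free energies, stacked fraction, ITC-measured dG)
oligo10_table <- function() {
  unstacking_table(
    temperature_C = c(10, 18, 25, 31),
    dG_un_strand_a = c(1.62, 1.45, 1.30, 1.18),
    dG_un_strand_b = c(1.65, 1.50, 1.37, 1.26),
    f_stacked = c(1.0, 1.0, 0.97, 0.92),
    dG_itc = c(-9.60, -9.76, -9.35, -8.82))
}

# the modelled oligo10/10c titration protocol: 28 x 10 uL into 1.45 mL,
# syringe 10-fold above a 0.20 mM cell
fig4_schedule <- function() {
  injection_schedule(n_injections = 28L, injection_volume = 10e-6,
                     cell_volume = 1.45e-3, syringe_conc = 2e-3,
                     cell_conc_initial = 2e-4)
}
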