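cond25 <- conditions(temperature_C = 25)

test_that("paper-mode totals are constant increments with the hand-computed ratio", {
  tot <- build_schedule_totals(fig4_schedule())
  # increment per injection = (10 uL * 10 * Mt) / (1.45 mL * Mt) = 0.0689655
  expect_equal(tot$molar_ratio, seq_len(28) * (10e-6 * 2e-3) / (1.45e-3 * 2e-4),
               tolerance = 1e-12)
  expect_equal(tot$molar_ratio[14], 0.965517, tolerance = 1e-6)
  expect_equal(tot$molar_ratio[15], 1.034483, tolerance = 1e-6)
  expect_true(all(tot$Mt_M == 2e-4))
  expect_true(all(diff(tot$molar_ratio) > 0))
})

test_that("displacement mode dilutes both species and converges to paper mode", {
  sch_d <- injection_schedule(n_injections = 10L, injection_volume = 10e-6,
                              cell_volume = 1.45e-3, syringe_conc = 2e-3,
                              cell_conc_initial = 2e-4,
                              dilution_mode = "displacement")
  tot_d <- build_schedule_totals(sch_d)
  expect_true(all(diff(tot_d$Mt_M) < 0))
  # tiny injections: displacement -> paper limit
  sch_tiny_d <- injection_schedule(n_injections = 5L, injection_volume = 1e-12,
                                   cell_volume = 1.45e-3, syringe_conc = 2e-3,
                                   cell_conc_initial = 2e-4,
                                   dilution_mode = "displacement")
  sch_tiny_p <- injection_schedule(n_injections = 5L, injection_volume = 1e-12,
                                   cell_volume = 1.45e-3, syringe_conc = 2e-3,
                                   cell_conc_initial = 2e-4)
  expect_equal(build_schedule_totals(sch_tiny_d)$Xt_M,
               build_schedule_totals(sch_tiny_p)$Xt_M, tolerance = 1e-8)
})

test_that("a first-injection override changes only the first increment", {
  sch <- injection_schedule(n_injections = 3L, injection_volume = 10e-6,
                            cell_volume = 1.45e-3, syringe_conc = 2e-3,
                            cell_conc_initial = 2e-4,
                            first_injection_volume = 2e-6)
  tot <- build_schedule_totals(sch)
  expect_equal(tot$volume_L, c(2e-6, 10e-6, 10e-6))
  expect_equal(tot$Xt_M[1], 2e-6 * 2e-3 / 1.45e-3)
})

test_that("simulated heats follow dH * dZ * V and conserve total heat", {
  sch <- fig4_schedule()
  p <- governing_params(-9.30, 4000)
  tr <- simulate_titration(sch, p, -47, cond25)
  expect_s3_class(tr, "titration_trace")
  expect_equal(nrow(tr), 28L)
  expect_equal(sum(tr$q_kcal), -47 * tr$Z_M[28] * 1.45e-3, tolerance = 1e-12)
  # zero enthalpy -> zero heats, same equilibria
  tr0 <- simulate_titration(sch, p, 0, cond25)
  expect_true(all(tr0$q_kcal == 0))
  expect_equal(tr0$Z_M, tr$Z_M)
})

test_that("dGS = 0 trace coincides with the classical closed-form trace", {
  sch <- fig4_schedule()
  dG0 <- -9.30
  tr <- simulate_titration(sch, governing_params(dG0, 0), -47, cond25)
  K <- K_from_deltaG(dG0, cond25)
  tot <- build_schedule_totals(sch)
  Zc <- vapply(seq_len(28), function(i) {
    classical_Z(binding_system(tot$Xt_M[i], tot$Mt_M[i]), K)
  }, numeric(1))
  qc <- -47 * diff(c(0, Zc)) * sch$cell_volume
  expect_equal(tr$q_norm_kcal_per_mol, qc / (tot$volume_L * sch$syringe_conc),
               tolerance = 1e-8)
  # and K is constant along the trace
  expect_lt(max(abs(tr$K / tr$K[1] - 1)), 1e-10)
})

test_that("positive dGS gives a declining K before 1:1 and a plateau after", {
  tr <- simulate_titration(fig4_schedule(), governing_params(-9.30, 4000),
                           -47, cond25)
  pre <- tr$K[tr$molar_ratio <= 1]
  expect_true(all(diff(pre) < 0))
  last5 <- tr$K[24:28]
  expect_lt((max(last5) - min(last5)) / min(last5), 0.05)
})

test_that("match_K_to_concentration picks the last pre-equivalence injection", {
  tr <- simulate_titration(fig4_schedule(), governing_params(-9.30, 4000),
                           -47, cond25)
  pt <- match_K_to_concentration(tr)
  expect_equal(attr(pt, "injection"), 14L)
  expect_equal(pt$K, tr$K[14])
  expect_equal(pt$complex_conc, tr$Z_M[14])
  # brandts convention: 90% of the starting cell concentration
  ptb <- match_K_to_concentration(tr, convention = "brandts",
                                  cell_conc_initial = 2e-4)
  expect_equal(ptb$complex_conc, 0.9 * 2e-4)
  # single injection at ratio 0.5 selects itself
  sch1 <- injection_schedule(n_injections = 1L, injection_volume = 10e-6,
                             cell_volume = 1.45e-3, syringe_conc = 1.45e-2,
                             cell_conc_initial = 2e-4)
  tr1 <- simulate_titration(sch1, governing_params(-9.30, 0), -47, cond25)
  expect_equal(attr(match_K_to_concentration(tr1), "injection"), 1L)
  # all ratios beyond 1:1 is a schedule mismatch
  sch_over <- injection_schedule(n_injections = 2L, injection_volume = 100e-6,
                                 cell_volume = 1.45e-3, syringe_conc = 1e-2,
                                 cell_conc_initial = 2e-4)
  tr_over <- simulate_titration(sch_over, governing_params(-9.30, 0), -47, cond25)
  expect_error(match_K_to_concentration(tr_over), "mismatch")
})
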