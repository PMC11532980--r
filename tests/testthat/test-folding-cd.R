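cond25 <- conditions(temperature_C = 25)

test_that("folded fraction reduces to the classical closed form at dGS = 0", {
  # midpoint identity
  fs0 <- folding_system(P_total = 1e-3, params = governing_params(0, 0))
  expect_equal(solve_folding_fraction(fs0, cond25), 0.5, tolerance = 1e-12)
  # f = K/(1+K) independent of P_total
  for (dG0 in c(-2, -0.5, 0.3, 1.5)) {
    K <- K_from_deltaG(dG0, cond25)
    for (P in c(1e-5, 1e-3, 1e-1)) {
      fs <- folding_system(P_total = P, params = governing_params(dG0, 0))
      expect_equal(solve_folding_fraction(fs, cond25), K / (1 + K),
                   tolerance = 1e-10)
    }
  }
})

test_that("positive dGS drives the folded fraction down with concentration", {
  p <- governing_params(-0.5, 500)
  Ps <- c(1e-5, 1e-4, 1e-3, 7e-3)
  f <- vapply(Ps, function(P) {
    solve_folding_fraction(folding_system(P_total = P, params = p), cond25)
  }, numeric(1))
  expect_true(all(diff(f) < 0))
  # cross-check one point against the hand-rolled bisection oracle
  expect_equal(f[4], oracle_folding_root(7e-3, -0.5, 500, 298.15),
               tolerance = 1e-8)
  # negative dGS has the opposite monotonicity
  pneg <- governing_params(-0.5, -500)
  fneg <- vapply(Ps, function(P) {
    suppressWarnings(solve_folding_fraction(
      folding_system(P_total = P, params = pneg), cond25))
  }, numeric(1))
  expect_true(all(diff(fneg) > 0))
})

test_that("mg/mL conversion uses the molar mass", {
  fs <- folding_system(conc_mg_per_mL = 14.178, params = governing_params(0, 0),
                       molar_mass = 14178)
  expect_equal(fs$P_total, 1e-3)
  expect_error(folding_system(params = governing_params(0, 0)), "exactly one")
})

test_that("two-state spectral mixing obeys its endpoint and isodichroic identities", {
  wl <- seq(250, 320, by = 5)
  thF <- -50 * exp(-((wl - 270) / 10)^2)
  thU <- -5 * exp(-((wl - 272) / 14)^2)
  bF <- cd_spectrum(wl, thF)
  bU <- cd_spectrum(wl, thU)
  expect_equal(predict_cd(1, bF, bU)$ellipticity, thF)
  expect_equal(predict_cd(0, bF, bU)$ellipticity, thU)
  expect_equal(predict_cd(0.5, bF, bU)$ellipticity, (thF + thU) / 2)
  # isodichroic point: equal basis signal is invariant under f_F
  iso <- which.min(abs(thF - thU))
  thU2 <- thU; thU2[iso] <- thF[iso]
  bU2 <- cd_spectrum(wl, thU2)
  sig <- vapply(seq(0, 1, by = 0.1), function(f) {
    predict_cd(f, bF, bU2)$ellipticity[iso]
  }, numeric(1))
  expect_equal(max(sig) - min(sig), 0)
  # grid mismatch rejected
  expect_error(predict_cd(0.5, bF, cd_spectrum(wl + 1, thU)), "grid")
})

test_that("concentration-independence statistic separates dGS = 0 from dGS > 0", {
  cfg0 <- synth_config(seed = 5, params = governing_params(-0.3, 0),
                       cd_noise_sd = 0)
  s0 <- gen_cd_series(cfg0)
  expect_equal(concentration_independence_stat(s0$spectra), 0)
  cfg1 <- synth_config(seed = 5, params = governing_params(-0.3, 500),
                       cd_noise_sd = 0)
  s1 <- gen_cd_series(cfg1)
  stat1 <- concentration_independence_stat(s1$spectra)
  expect_gt(stat1, 0)
  # larger dGS moves the spectra more
  cfg2 <- synth_config(seed = 5, params = governing_params(-0.3, 2000),
                       cd_noise_sd = 0)
  s2 <- gen_cd_series(cfg2)
  expect_gt(concentration_independence_stat(s2$spectra), stat1)
  # identical spectra give exactly zero
  expect_equal(concentration_independence_stat(list(s0$spectra[[1]],
                                                    s0$spectra[[1]])), 0)
})

test_that("the statistic enforces a constant conc x pathlength series", {
  wl <- seq(250, 320, by = 5)
  a <- cd_spectrum(wl, rep(-1, length(wl)), conc_mg_per_mL = 1, pathlength_cm = 1)
  b <- cd_spectrum(wl, rep(-1, length(wl)), conc_mg_per_mL = 10, pathlength_cm = 1)
  expect_error(concentration_independence_stat(list(a, b)), "not constant")
  b$pathlength_cm <- 0.1
  expect_equal(concentration_independence_stat(list(a, b)), 0)
})
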