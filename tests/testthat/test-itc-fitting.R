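cond25 <- conditions(temperature_C = 25)

classical_trace <- function(K, dH, sch) {
  tot <- build_schedule_totals(sch)
  Z <- vapply(seq_len(nrow(tot)), function(i) {
    classical_Z(binding_system(tot$Xt_M[i], tot$Mt_M[i]), K)
  }, numeric(1))
  dH * diff(c(0, Z)) * sch$cell_volume
}

test_that("classical self-consistency: noiseless parameters are recovered to 4 sig figs", {
  sch <- fig4_schedule()
  q <- classical_trace(2.03e6, -47, sch)
  fit <- fit_one_site_classical(q, sch, cond25)
  expect_true(fit$converged)
  expect_equal(fit$K_app, 2.03e6, tolerance = 1e-4)
  expect_equal(fit$dH_app, -47, tolerance = 1e-4)
  expect_equal(fit$n_stoich, 1, tolerance = 1e-4)
  expect_lt(fit$rss, 1e-14)
})

test_that("flat heats are rejected as unidentifiable", {
  sch <- fig4_schedule()
  expect_error(fit_one_site_classical(rep(0, 28), sch, cond25),
               "unidentifiable")
  expect_error(fit_one_site_classical(rep(1e-6, 28), sch, cond25),
               "unidentifiable")
  expect_error(fit_one_site_classical(1:3 * 1e-6, sch, cond25),
               "3 heats for a 28-injection")
})

test_that("first-injection exclusion and background subtraction are honoured", {
  sch <- fig4_schedule()
  q <- classical_trace(2.03e6, -47, sch)
  q_bg <- q + 5e-7                       # constant background offset
  fit <- fit_one_site_classical(q_bg, sch, cond25, background = 5e-7)
  expect_equal(fit$K_app, 2.03e6, tolerance = 1e-4)
  q_bad1 <- q; q_bad1[1] <- q[1] * 0.2   # corrupted first shot
  fit2 <- fit_one_site_classical(q_bad1, sch, cond25, exclude_first = TRUE)
  expect_equal(fit2$K_app, 2.03e6, tolerance = 1e-4)
  expect_equal(fit2$n_used, 27L)
})

test_that("classical fit of a solvation-governed trace lands near the matched K", {
  sch <- fig4_schedule()
  tr <- simulate_titration(sch, governing_params(-9.30, 4000), -47, cond25)
  fit <- fit_one_site_classical(tr$q_kcal, sch, cond25)
  K_match <- match_K_to_concentration(tr)$K
  expect_lt(max(fit$K_app / K_match, K_match / fit$K_app), 1.5)
  # and the fit is close in heat space ("deceivingly good")
  expect_lt(sqrt(fit$rss / fit$n_used), 0.02 * max(abs(tr$q_kcal)))
})

test_that("governing fit recovers dG0 and dH when dGS is fixed at truth", {
  sch <- fig4_schedule()
  tr <- simulate_titration(sch, governing_params(-9.30, 4000), -47, cond25)
  fit <- fit_governing_global(tr$q_kcal, sch, cond25,
                              fix = list(dG_solv = 4000))
  expect_equal(fit$params$dG_standard, -9.30, tolerance = 1e-3)
  expect_equal(fit$dH, -47, tolerance = 1e-3)
})

test_that("model nesting: governing fit at dGS = 0 equals classical fit at n = 1", {
  sch <- fig4_schedule()
  set.seed(7)
  q <- classical_trace(2.03e6, -47, sch)
  q <- q + stats::rnorm(28, 0, 0.01 * max(abs(q)))
  g <- fit_governing_global(q, sch, cond25, fix = list(dG_solv = 0))
  c1 <- fit_one_site_classical(q, sch, cond25, fix_n = 1)
  expect_equal(g$rss, c1$rss, tolerance = 1e-6)
  expect_equal(K_from_deltaG(g$params$dG_standard, cond25), c1$K_app,
               tolerance = 1e-4)
})

test_that("free-dGS fit warns about weak identifiability and profiles flat", {
  sch <- fig4_schedule()
  tr <- simulate_titration(sch, governing_params(-9.30, 4000), -47, cond25)
  expect_warning(fit_governing_global(tr$q_kcal, sch, cond25),
                 "weakly identifiable")
  # rss profile over a dGS grid with (dG0, dH) refit is nearly flat near truth
  rss <- vapply(c(3000, 4000, 5000), function(dgs) {
    suppressWarnings(fit_governing_global(tr$q_kcal, sch, cond25,
                                          fix = list(dG_solv = dgs)))$rss
  }, numeric(1))
  scale <- sum(tr$q_kcal^2)
  expect_true(all(rss / scale < 1e-4))
})

test_that("recovery under 2% heat noise keeps median K error below 10%", {
  # 2% relative Gaussian noise on every injection heat
  sch <- fig4_schedule()
  q0 <- classical_trace(2.03e6, -47, sch)
  errs <- vapply(1:50, function(s) {
    set.seed(s)
    q <- q0 + stats::rnorm(28, 0, 0.02 * abs(q0))
    f <- fit_one_site_classical(q, sch, cond25)
    abs(f$K_app / 2.03e6 - 1)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.10)
})
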