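# Hs-Tp copula, percentile wave conditions, and the simulation ensemble

test_that("the Gaussian copula parameter is recovered from synthetic data", {
  cl <- generate_wave_climate(n_years = 30, rho = 0.5, seed = 7)
  cop <- fit_hs_tp_copula(cl)
  expect_equal(cop$rho, 0.5, tolerance = 0.05)
  expect_equal(cop$tau, 2 / pi * asin(cop$rho), tolerance = 1e-12)
  # independent pairs
  cl0 <- generate_wave_climate(n_years = 30, rho = 0, seed = 8)
  expect_lt(abs(fit_hs_tp_copula(cl0)$rho), 0.06)
  # comonotone pairs: tau -> 1
  x <- sort(rexp(500))
  com <- data.frame(hs = x, tp = 2 * x + 1)
  expect_gt(fit_hs_tp_copula(com)$rho, 0.99)
  expect_error(fit_hs_tp_copula(data.frame(hs = rep(1, 200),
                                           tp = rexp(200))),
               "degenerate")
  expect_error(fit_hs_tp_copula(cl[1:50, ]), "100")
})

test_that("percentile conditions cover 0.1 to 100 with copula-linked Tp", {
  cl <- generate_wave_climate(n_years = 30, rho = 0.5, seed = 7)
  cop <- fit_hs_tp_copula(cl)
  conds <- build_conditions(cl, cop)
  expect_equal(nrow(conds), 1000)
  expect_equal(conds$percentile, seq(0.1, 100, by = 0.1))
  expect_true(all(diff(conds$hs) >= 0))
  expect_equal(conds$hs[1000], max(cl$hs))
  # positive dependence: tp increases with the percentile overall
  expect_gt(cor(conds$percentile, conds$tp, method = "kendall"), 0.5)
  # independence copula: tp constant at its marginal median
  cop0 <- cop
  cop0$rho <- 0
  conds0 <- build_conditions(cl, cop0)
  expect_true(all(abs(conds0$tp - median(cl$tp)) < 1e-9))
})

test_that("the ensemble runs state x condition with resumable rows", {
  b <- flume_bathymetry(depth = 4, length = 60)
  states <- list(s1 = 0.01, s2 = 0.2)
  conds <- data.frame(percentile = c(50, 75, 90), hs = c(0.5, 0.8, 1.1),
                      tp = c(7, 8, 9))
  ens <- run_ensemble(states, conds, b, duration = 60, seed = 5,
                      sc_by_state = c(s1 = 3.5, s2 = 1.5))
  expect_equal(nrow(ens), 6)
  expect_true(all(!ens$failed))
  expect_equal(ens$sc[ens$state == "s1"], rep(3.5, 3))
  # swapping state labels permutes rows but not values
  ens2 <- run_ensemble(list(s2 = 0.2, s1 = 0.01), conds, b, duration = 60,
                       seed = 5)
  m1 <- ens[order(ens$state, ens$condition), c("r2", "hs_nearshore")]
  m2 <- ens2[order(ens2$state, ens2$condition), c("r2", "hs_nearshore")]
  expect_equal(m1$r2, m2$r2, tolerance = 1e-12)
})

test_that("energy absorption is the flux deficit, clipped to [0, 1]", {
  fake <- structure(list(flux_toe = 1000, flux_flat = 230),
                    class = "reef_simulation")
  expect_equal(energy_absorption(fake), 0.77)
  fake$flux_flat <- 0
  expect_equal(energy_absorption(fake), 1)
  fake$flux_flat <- 1200 # reflection noise can exceed the toe flux
  expect_equal(energy_absorption(fake), 0)
  expect_error(energy_absorption(structure(list(flux_toe = NA_real_),
                                           class = "reef_simulation")),
               "missing")
})
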