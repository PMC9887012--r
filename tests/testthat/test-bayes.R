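# Bayesian run-up interaction model

sim_runup_data <- function(n, alpha, beta, gamma, sigma, sigz = 0,
                           seed = 1) {
  set.seed(seed)
  hs <- runif(n, 0.5, 4)
  sc <- runif(n, 1, 4)
  mu <- (alpha + sigz) * hs + (beta + sigz) * sc +
    (gamma + sigz) * sc * hs
  data.frame(ru = mu + rnorm(n, 0, sigma), hs = hs, sc = sc)
}

test_that("effective slopes are recovered from simulated data", {
  d <- sim_runup_data(400, 0.3, -0.1, -0.05, 0.05, seed = 7)
  fit <- fit_runup_model(d, chains = 2, draws = 1500, warmup = 500,
                         seed = 1)
  expect_lt(max(fit$rhat, na.rm = TRUE), 1.05)
  D <- fit$draws
  eff <- c(mean(D[, "alpha"] + D[, "sigma_z"]),
           mean(D[, "beta"] + D[, "sigma_z"]),
           mean(D[, "gamma"] + D[, "sigma_z"]))
  expect_lt(max(abs(eff - c(0.3, -0.1, -0.05))), 0.02)
  expect_lt(abs(mean(D[, "sigma"]) - 0.05), 0.005)
  # draws respect the prior supports
  expect_true(all(D[, "sigma"] > 0) && all(D[, "sigma_z"] > 0))
  # determinism under a fixed seed
  fit2 <- fit_runup_model(d, chains = 2, draws = 1500, warmup = 500,
                          seed = 1)
  expect_equal(fit$summary, fit2$summary, tolerance = 1e-12)
})

test_that("a null interaction stays concentrated near zero", {
  d <- sim_runup_data(400, 0.3, -0.1, 0, 0.05, seed = 11)
  fit <- fit_runup_model(d, chains = 2, draws = 1500, warmup = 500,
                         seed = 2)
  D <- fit$draws
  eff_gamma <- D[, "gamma"] + D[, "sigma_z"]
  expect_lt(abs(mean(eff_gamma)), 0.02)
})

test_that("retained draw count follows chains x (draws - warmup)", {
  d <- sim_runup_data(100, 0.2, -0.1, 0, 0.1, seed = 3)
  fit <- fit_runup_model(d, chains = 4, draws = 400, warmup = 150,
                         seed = 3)
  expect_equal(fit$n_retained, 4 * 250)
})

test_that("input validation and convergence gate work", {
  d <- sim_runup_data(30, 0.2, -0.1, 0, 0.1)
  expect_error(fit_runup_model(d), "50")
  d2 <- sim_runup_data(100, 0.2, -0.1, 0, 0.1)
  d2$sc <- 2 # degenerate predictor
  expect_error(fit_runup_model(d2), "degenerate")
})

test_that("prediction grids and residual run-up behave", {
  d <- sim_runup_data(300, 0.3, -0.1, -0.05, 0.05, seed = 5)
  fit <- fit_runup_model(d, chains = 2, draws = 1000, warmup = 400,
                         seed = 4)
  pr <- predict_runup(fit, hs_grid = 1:6,
                      sc_grid = seq(1.25, 4.25, length.out = 11))
  expect_equal(nrow(pr), 66)
  # negative interaction: run-up reduction per unit SC grows with Hs
  slope_at <- function(h) {
    s <- pr[pr$hs == h, ]
    coef(lm(mean ~ sc, s))[["sc"]]
  }
  expect_lt(slope_at(6), slope_at(1))
  rr <- residual_runup(pr)
  mins <- tapply(rr$residual, rr$hs, min)
  expect_true(all(abs(mins) < 1e-12))
  # shift invariance within an Hs level
  pr2 <- pr
  pr2$mean[pr2$hs == 3] <- pr2$mean[pr2$hs == 3] + 1
  rr2 <- residual_runup(pr2)
  expect_equal(rr2$residual[rr2$hs == 3], rr$residual[rr$hs == 3],
               tolerance = 1e-12)
})
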