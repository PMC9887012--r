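# GPD return curves and frequency amplification

rgpd <- function(n, sigma, xi, u = 0) {
  if (abs(xi) < 1e-12) return(u + sigma * rexp(n))
  u + sigma / xi * ((1 - runif(n))^(-xi) - 1)
}

test_that("GPD parameters are recovered by the weighted MLE", {
  set.seed(42)
  x <- rgpd(2000, sigma = 1, xi = 0.1)
  cv <- fit_gpd(x, threshold_value = 0, min_exceedances = 30)
  expect_lt(abs(cv$sigma - 1), 0.1)
  expect_lt(abs(cv$xi - 0.1), 0.08)
  # exponential data is the xi = 0 sub-family
  ce <- fit_gpd(rexp(2000), threshold_value = 0)
  expect_lt(abs(ce$xi), 0.08)
  # estimation error shrinks with n (averaged over replicates)
  err <- vapply(c(200, 10000), function(n) {
    mean(vapply(1:4, function(r) {
      set.seed(n + r)
      f <- fit_gpd(rgpd(n, 1, 0.1), threshold_value = 0)
      abs(f$sigma - 1) + abs(f$xi - 0.1)
    }, numeric(1)))
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("too few exceedances raise an error", {
  expect_error(fit_gpd(runif(100), threshold_value = 2), "exceedances")
})

test_that("return levels follow the closed-form GPD formula", {
  cv <- structure(list(u = 0, sigma = 1, xi = 0, lambda_u = 1),
                  class = "return_curve")
  expect_equal(return_level(cv, exp(1)), 1, tolerance = 1e-12)
  Ts <- c(2, 5, 10, 50, 100)
  expect_true(all(diff(vapply(Ts, function(t) return_level(cv, t),
                              numeric(1))) > 0))
  # bounded tail for xi < 0
  cvn <- structure(list(u = 1, sigma = 0.5, xi = -0.2, lambda_u = 2),
                   class = "return_curve")
  bound <- cvn$u - cvn$sigma / cvn$xi
  expect_true(all(vapply(c(10, 1e3, 1e6),
                         function(t) return_level(cvn, t),
                         numeric(1)) < bound))
  expect_error(return_level(cv, 0.5), "resolvable")
})

test_that("frequency amplification matches closed forms", {
  c1 <- structure(list(u = 1, sigma = 0.4, xi = 0, lambda_u = 2),
                  class = "return_curve")
  # identical curves: factor 1 at all T
  expect_equal(frequency_amplification(c1, c1, c(5, 50, 500)),
               rep(1, 3), tolerance = 1e-9)
  # xi = 0 curves differing only in threshold by delta: factor exp(delta/sigma)
  c2 <- c1
  c2$u <- 1.5
  f <- frequency_amplification(c1, c2, c(10, 100))
  expect_equal(f, rep(exp(0.5 / 0.4), 2), tolerance = 1e-9)
  # level below the degraded threshold is reported as a lower bound
  c_hi <- c1
  c_hi$u <- 5
  flb <- frequency_amplification(c1, c_hi, 2)
  expect_gte(flb, 1)
})

test_that("amplification is >= 1 under stochastic dominance", {
  set.seed(9)
  healthy <- rgpd(3000, 0.3, 0.05, u = 0.8)
  degraded <- healthy + 0.15 # dominates
  ch <- fit_gpd(healthy, threshold = 0.8)
  cd <- fit_gpd(degraded, threshold = 0.8)
  f <- frequency_amplification(ch, cd, c(2, 10, 50))
  expect_true(all(f >= 1))
})

test_that("amplification is invariant to monotone relabeling of the axis", {
  set.seed(10)
  h <- rgpd(4000, 0.3, 0, u = 1)
  d <- rgpd(4000, 0.35, 0, u = 1.2)
  f1 <- frequency_amplification(fit_gpd(h, threshold = 0.85),
                                fit_gpd(d, threshold = 0.85), 20)
  sc <- 2.5 # linear rescale of the run-up axis
  f2 <- frequency_amplification(fit_gpd(sc * h, threshold = 0.85),
                                fit_gpd(sc * d, threshold = 0.85), 20)
  expect_equal(f1, f2, tolerance = 1e-3) # MLE convergence tolerance
})
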