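# Boussinesq solver: formula oracles, conservation, dispersion, solitary
# waves, run-up statistics

test_that("wave friction factor follows the explicit Jonsson form", {
  expect_equal(friction_factor(1, 1), exp(5.213 - 5.977), tolerance = 1e-9)
  expect_equal(friction_factor(1e-6, 10), exp(5.213 * (1e-7)^0.194 - 5.977),
               tolerance = 1e-9)
  # monotone increasing in kn, capped beyond kn/a0 = 1
  kn <- seq(0.01, 0.9, 0.01)
  expect_true(all(diff(friction_factor(kn, 1)) >= 0))
  expect_equal(friction_factor(2, 1), friction_factor(1, 1))
  expect_error(friction_factor(-0.1, 1), "positive")
})

test_that("bed shear is an odd quadratic law", {
  expect_equal(bed_shear(0, 0.1), 0)
  expect_equal(bed_shear(1, 0.1, rho = 1025), 51.25)
  expect_equal(bed_shear(-1, 0.1, rho = 1025), -51.25)
  expect_equal(bed_shear(2, 0.05), -bed_shear(-2, 0.05))
})

test_that("Stockdon run-up matches direct evaluation", {
  expect_equal(stockdon_runup(2, 100, 0.1), 1.3078, tolerance = 1e-3)
  expect_equal(stockdon_runup(0, 100, 0.1), 0)
  h <- seq(0.5, 4, 0.5)
  expect_true(all(diff(stockdon_runup(h, 150, 0.1)) > 0))
})

test_that("R_2% is the 98th percentile with linear interpolation", {
  expect_equal(as.numeric(r2_percent(rep(1, 100))), 1)
  expect_equal(as.numeric(r2_percent(1:100)), 98.02)
  set.seed(1)
  x <- runif(200)
  expect_equal(as.numeric(r2_percent(x)),
               as.numeric(r2_percent(sample(x))))
  expect_true(attr(r2_percent(1:10), "low_confidence"))
  expect_error(r2_percent(numeric(0)), "empty")
})

test_that("still water with no forcing stays still", {
  n <- 50
  st <- list(zeta = rep(0, n), U = rep(0, n), d = rep(4, n), dx = 1)
  out <- boussinesq_step(st, config = model_config(), n_steps = 50)
  expect_lt(max(abs(out$zeta)), 1e-14)
  expect_lt(max(abs(out$U)), 1e-14)
})

test_that("mass is conserved to 1e-6 in a closed frictionless basin", {
  d0 <- 5
  n <- 200
  x <- (1:n)
  st <- list(zeta = 0.1 * exp(-((x - 100) / 10)^2), U = rep(0, n),
             d = rep(d0, n), dx = 1)
  out <- boussinesq_step(st, config = model_config(), n_steps = 1000,
                         breaking = FALSE)
  expect_lt(out$mass_err / out$volume0, 1e-6)
})

test_that("linear dispersion matches the B = 1/15 relation within 1%", {
  cfg <- model_config()
  d0 <- 5
  for (kh in c(0.5, 1, 2, pi)) {
    k <- kh / d0
    L <- 2 * pi / k
    ppw <- 100
    dx <- L / ppw
    n <- ppw
    x <- (0:(n - 1)) * dx
    a <- 0.001
    c_an <- bq_phase_speed(k, d0)
    om <- k * c_an
    dt <- 0.05 * dx / sqrt(9.81 * d0)
    nst <- ceiling(5 * (2 * pi / om) / dt)
    arg <- reefshield:::bq_args(rep(d0, n), dx, dt, nst, cfg,
                                zeta0 = a * cos(k * x),
                                U0 = a * om / (k * d0) * cos(k * x),
                                periodic = TRUE, use_roller = FALSE,
                                use_swash = FALSE, out_every = nst)
    arg$filter_every <- 0L
    res <- reefshield:::bq_run_cpp(arg)
    A0 <- sum(a * cos(k * x) * exp(-1i * k * x))
    AT <- sum(res$zeta * exp(-1i * k * x))
    Tend <- nst * dt
    dphi <- Arg(A0 / AT)
    phase <- 2 * pi * round((k * c_an * Tend - dphi) / (2 * pi)) + dphi
    c_meas <- phase / (k * Tend)
    expect_lt(abs(c_meas - c_an) / c_an, 0.01,
              label = sprintf("phase speed error at kh = %.2f", kh))
  }
})

test_that("a solitary wave propagates shape-preservingly", {
  cfg <- model_config()
  d0 <- 1
  H <- 0.05
  n <- 3000
  dx <- 0.05
  x <- (1:n) * dx
  kap <- sqrt(3 * H / (4 * d0^3))
  zeta0 <- H / cosh(kap * (x - 20))^2
  cs <- sqrt(9.81 * (d0 + H))
  dt <- 0.2 * dx / sqrt(9.81 * d0)
  st <- list(zeta = zeta0, U = cs * zeta0 / (d0 + zeta0),
             d = rep(d0, n), dx = dx, dt = dt)
  # settle, then measure amplitude drift over ~2 effective lengths x 25
  o1 <- boussinesq_step(st, config = cfg, n_steps = ceiling(40 / cs / dt),
                        breaking = FALSE)
  a1 <- max(o1$zeta)
  o2 <- boussinesq_step(o1, config = cfg, n_steps = ceiling(80 / cs / dt),
                        breaking = FALSE)
  a2 <- max(o2$zeta)
  expect_lt(abs(a2 - a1) / a1, 0.02)
})

test_that("non-breaking solitary run-up is within 10% of the Synolakis law", {
  cfg <- model_config()
  d0 <- 1
  H <- 0.02
  cotb <- 10
  dx <- 0.05
  x <- seq(0, 40 + cotb * 1.3, by = dx)
  d <- ifelse(x < 40, d0, d0 - (x - 40) / cotb)
  n <- length(x)
  kap <- sqrt(3 * H / (4 * d0^3))
  zeta0 <- H / cosh(kap * (x - 15))^2
  cs <- sqrt(9.81 * (d0 + H))
  U0 <- cs * zeta0 / (d0 + zeta0)
  U0[d <= 0] <- 0
  zeta0[d <= 0] <- -d[d <= 0] + cfg$h_film
  dt <- 0.15 * dx / sqrt(9.81 * d0)
  arg <- reefshield:::bq_args(d, dx, dt, ceiling(40 / dt), cfg,
                              zeta0 = zeta0, U0 = U0,
                              swash_mask = d < 0.02 & d > -0.2,
                              use_roller = FALSE, use_swash = TRUE,
                              out_every = max(1, floor(0.05 / dt)))
  res <- reefshield:::bq_run_cpp(arg)
  expect_true(res$stable)
  R_meas <- max(res$R_t, na.rm = TRUE)
  R_an <- 2.831 * sqrt(cotb) * H^(5 / 4) # Synolakis run-up law (d0 = 1)
  expect_lt(abs(R_meas - R_an) / R_an, 0.10)
})

test_that("nearshore Hs equals 4 sqrt(m0) for a monochromatic wave", {
  cfg <- model_config()
  d0 <- 5
  a <- 0.05
  k <- reefshield:::bq_wavenumber(2 * pi / 8, d0)
  L <- 2 * pi / k
  n <- 128
  dx <- L / n
  x <- (0:(n - 1)) * dx
  om <- k * bq_phase_speed(k, d0)
  dt <- 0.1 * dx / sqrt(9.81 * d0)
  nst <- ceiling(10 * (2 * pi / om) / dt)
  arg <- reefshield:::bq_args(rep(d0, n), dx, dt, nst, cfg,
                              zeta0 = a * cos(k * x),
                              U0 = a * om / (k * d0) * cos(k * x),
                              periodic = TRUE, use_roller = FALSE,
                              use_swash = FALSE, out_every = nst)
  arg$filter_every <- 0L
  res <- reefshield:::bq_run_cpp(arg)
  hs <- 4 * sqrt(mean(res$m0))
  expect_equal(hs, 4 * a / sqrt(2), tolerance = 0.03)
})

test_that("run-up maxima extraction finds events against a drifting level", {
  t <- seq(0, 200, 0.1)
  R <- 0.002 * t + 0.3 * sin(2 * pi * t / 10)
  mx <- runup_maxima(R, window = 300)
  expect_gt(length(mx), 15)
  # each event maximum should reflect the oscillation amplitude
  expect_gt(median(diff(range(R)) > 0.3), 0)
})

test_that("instability is detected and reported", {
  n <- 50
  st <- list(zeta = rep(50, n), U = rep(0, n), d = rep(2, n), dx = 1)
  expect_error(boussinesq_step(st, n_steps = 10), "unstable")
})
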