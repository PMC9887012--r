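# pressure depth-correction, spectral roughness inversion, SC -> kn, and
# roughness profiles

test_that("depth correction recovers a monochromatic wave at the bed", {
  h <- 3
  a <- 0.4
  f0 <- 0.1
  rate <- 4
  tt <- (0:(1199)) / rate
  k <- airy_wavenumber(2 * pi * f0, h)
  p <- a / cosh(k * h) * cos(2 * pi * f0 * tt)
  eta <- depth_correct_pressure(p, h, rate)
  expect_equal(max(abs(eta)), a, tolerance = 0.01)
  # sensor at the surface: amplification 1 at all frequencies
  eta_s <- depth_correct_pressure(p, h, rate, sensor_height = h)
  expect_equal(sd(eta_s), sd(p - mean(p)), tolerance = 1e-6)
  expect_error(depth_correct_pressure(p, h, rate, cutoff_hz = 3),
               "Nyquist")
})

test_that("kn is recovered from synthetic paired records within 5%", {
  for (kn_true in c(0.05, 0.2, 0.6)) {
    pr <- generate_pressure_records(kn_true = kn_true, n_bursts = 4,
                                    burst_seconds = 600, seed = 11)
    ea <- depth_correct_pressure(pr$pressure[, , 1], pr$depths[1],
                                 pr$rate_hz)
    eb <- depth_correct_pressure(pr$pressure[, , 2], pr$depths[2],
                                 pr$rate_hz)
    est <- estimate_kn_spectral(ea, eb, pr$separation, pr$depths,
                                pr$rate_hz)
    expect_equal(nrow(est), 4)
    expect_lt(abs(median(est$kn, na.rm = TRUE) - kn_true) / kn_true, 0.05)
  }
})

test_that("sc_to_kn follows the power law and rejects SC < 1", {
  expect_equal(sc_to_kn(1), 0.01)
  expect_equal(sc_to_kn(3.86), 0.01 * 3.86^2.98, tolerance = 1e-12)
  expect_equal(sc_to_kn(3.86), 0.560, tolerance = 1e-3)
  expect_equal(sc_to_kn(1.58), 0.0391, tolerance = 1e-3)
  expect_true(all(diff(sc_to_kn(seq(1, 5, 0.1))) > 0))
  expect_error(sc_to_kn(0.9), ">= 1")
})

test_that("kn profiles assign section roughness with coefficients", {
  b <- small_bathymetry()
  kp <- build_kn_profile(2, b, coefficients = list(reef_crest = 0.6,
                                                   back_reef = 0.4),
                         d50 = 63e-6)
  expect_equal(nrow(kp), nrow(b))
  expect_true(all(kp$kn > 0))
  kn_fore <- unique(kp$kn[b$section == "fore_reef"])
  expect_equal(kn_fore, sc_to_kn(2))
  expect_equal(unique(kp$kn[b$section == "reef_crest"]) / kn_fore, 0.6)
  expect_equal(unique(kp$kn[b$section == "back_reef"]) / kn_fore, 0.4)
  # sand roughness 2.5 d50
  expect_equal(unique(kp$kn[b$section == "sand"]), 2.5 * 63e-6)
  # identity coefficients give a uniform reef
  kp1 <- build_kn_profile(2, b)
  reef <- b$section %in% c("fore_reef", "reef_crest", "back_reef")
  expect_equal(unique(kp1$kn[reef]), sc_to_kn(2))
  expect_error(build_kn_profile(2, b, coefficients = list(back_reef = 1)),
               "missing coefficient")
})

test_that("roughness ensemble produces one profile per SC replicate", {
  b <- small_bathymetry()
  sc_ens <- data.frame(year = rep(c(2011, 2016), each = 3),
                       replicate = rep(1:3, 2),
                       sc = c(1.5, 1.6, 1.7, 3.4, 3.9, 3.7))
  ens <- roughness_ensemble(sc_ens, b)
  expect_equal(nrow(ens), 6 * nrow(b))
  reps <- representative_kn_profile(ens)
  expect_named(reps, c("2011", "2016"))
  # pointwise median at fore reef = sc_to_kn(median sc)
  i_fore <- b$section == "fore_reef"
  expect_equal(unique(reps[["2016"]]$kn[i_fore]),
               median(sc_to_kn(c(3.4, 3.9, 3.7))))
})
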