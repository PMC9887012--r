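# synthetic input generators: survey tables, bathymetry, wave climate,
# pressure records

test_that("survey table follows the disturbance-recovery cover trajectory", {
  sv <- generate_survey_table(seed = 3)
  tot <- tapply(sv$cover, sv$year, sum)
  expect_equal(unname(tot[["2005"]]), 0.50, tolerance = 1e-12)
  expect_equal(unname(tot[["2011"]]), 0.03, tolerance = 1e-12)
  expect_true(all(sv$cover >= 0))
  expect_true(all(tot <= 1 + 1e-9))
  # recovery is Pocillopora-dominated
  s16 <- sv[sv$year == 2016, ]
  expect_gt(s16$cover[s16$taxon == "Pocillopora"],
            max(s16$cover[s16$taxon != "Pocillopora"]))
  # all size samples positive
  expect_true(all(unlist(sv$size_samples) > 0))
  # determinism
  sv2 <- generate_survey_table(seed = 3)
  expect_identical(sv$cover, sv2$cover)
  expect_identical(sv$size_samples, sv2$size_samples)
})

test_that("zero-cover trajectory yields an empty reef", {
  traj <- data.frame(year = 2020, Acropora = 0, Pocillopora = 0,
                     Porites = 0)
  sv <- generate_survey_table(disturbance_trajectory = traj, seed = 1)
  expect_true(all(sv$cover == 0))
  expect_true(all(vapply(sv$size_samples, nrow, integer(1)) == 0))
})

test_that("invalid cover trajectories are rejected", {
  bad <- data.frame(year = 2020, Acropora = 0.7, Pocillopora = 0.6,
                    Porites = 0)
  expect_error(generate_survey_table(disturbance_trajectory = bad),
               "sum to at most 1")
  neg <- data.frame(year = 2020, Acropora = -0.1, Pocillopora = 0,
                    Porites = 0)
  expect_error(generate_survey_table(disturbance_trajectory = neg))
})

test_that("bathymetry starts at 20 m depth with labelled sections", {
  b <- generate_bathymetry()
  expect_equal(b$z[1], -20)
  expect_true(all(diff(b$x) > 0))
  expect_setequal(unique(b$section),
                  c("fore_reef", "reef_crest", "back_reef", "sand",
                    "beach"))
  # one contiguous run per label
  expect_equal(length(rle(b$section)$values),
               length(unique(b$section)))
  # crest is the shallowest submerged point of the reef
  crest_z <- max(b$z[b$section == "reef_crest"])
  expect_gte(crest_z, max(b$z[b$section %in% c("fore_reef", "back_reef")]))
})

test_that("degenerate flat-bottom flume profile is constant", {
  b <- flume_bathymetry(depth = 5)
  expect_true(all(abs(b$z + 5) < 1e-9))
})

test_that("non-monotone segment specifications are rejected", {
  expect_error(generate_bathymetry(list(crest_depth = 2, flat_depth = 1)),
               "non-monotone")
  expect_error(generate_bathymetry(list(
    segments = data.frame(length = -5, end_z = -1, label = "sand"))),
    "non-monotone")
})

test_that("wave climate has weekly resolution and the requested dependence", {
  cl <- generate_wave_climate(n_years = 30, rho = 0.5, seed = 7)
  expect_equal(nrow(cl), 1560)
  expect_true(all(cl$hs > 0) && all(cl$tp > 0))
  # Kendall tau ~ (2/pi) asin(rho) = 1/3 for rho = 0.5
  tau <- cor(cl$hs, cl$tp, method = "kendall")
  expect_equal(tau, 2 / pi * asin(0.5), tolerance = 0.12)
  # independence
  cl0 <- generate_wave_climate(n_years = 30, rho = 0, seed = 8)
  expect_lt(abs(cor(cl0$hs, cl0$tp, method = "kendall")), 0.05)
  expect_error(generate_wave_climate(rho = 1), "dependence")
})

test_that("pressure records have the right burst geometry", {
  pr <- generate_pressure_records(n_bursts = 2, burst_seconds = 900,
                                  rate_hz = 4, seed = 1)
  expect_equal(dim(pr$pressure), c(3600, 2, 2))
  expect_error(generate_pressure_records(sensor_depths = 3), "2 sensors")
  expect_error(generate_pressure_records(sensor_depths = c(3, -1)),
               "positive")
})

test_that("frictionless pressure records carry equal spectral flux", {
  pr <- generate_pressure_records(kn_true = 0, n_bursts = 2,
                                  burst_seconds = 300, snr = Inf, seed = 3)
  ea <- depth_correct_pressure(pr$pressure[, , 1], pr$depths[1], pr$rate_hz)
  eb <- depth_correct_pressure(pr$pressure[, , 2], pr$depths[2], pr$rate_hz)
  est <- estimate_kn_spectral(ea, eb, pr$separation, pr$depths, pr$rate_hz)
  expect_true(all(est$flagged))
  expect_true(all(abs(est$eps) < 1e-6))
})
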