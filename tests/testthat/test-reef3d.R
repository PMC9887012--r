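# coral shapes, reef population, and the rumple index

test_that("coral shapes respect their bounding box and determinism", {
  m <- generate_coral_shape("Porites", 0.2, 0.2, 0.1, seed = 1,
                            resolution = 24)
  bb <- apply(m$vertices, 2, function(c) diff(range(c)))
  expect_equal(unname(bb), c(0.2, 0.2, 0.1), tolerance = 1e-9)
  m2 <- generate_coral_shape("Porites", 0.2, 0.2, 0.1, seed = 1,
                             resolution = 24)
  expect_identical(m$vertices, m2$vertices)
  expect_error(generate_coral_shape("Porites", -0.1, 0.2, 0.1), "positive")
})

test_that("full hemisphere proxy has surface/footprint ratio 2", {
  # width = length = 2 * height -> hemisphere
  m <- generate_coral_shape("Porites", 0.2, 0.2, 0.1, seed = 1,
                            resolution = 64)
  expect_equal(rumple_index(m), 2, tolerance = 2e-3)
})

test_that("per-taxon rumple ordering holds under the default shapes", {
  r <- vapply(c("Pocillopora", "Acropora", "Porites"), function(tx) {
    mean(vapply(1:3, function(s) {
      rumple_index(generate_coral_shape(tx, 0.3, 0.3, 0.18, seed = s,
                                        resolution = 32))
    }, numeric(1)))
  }, numeric(1))
  expect_gt(r[["Pocillopora"]], r[["Acropora"]])
  expect_gt(r[["Acropora"]], r[["Porites"]])
})

test_that("rumple index matches closed forms on analytic surfaces", {
  # flat plane and 45-degree plane as rasterized height fields
  flat <- matrix(0, 101, 101)
  expect_equal(rumple_index(flat, 0.01), 1, tolerance = 1e-12)
  incline <- matrix(rep(seq(0, 1, length.out = 101), 101), 101, 101)
  expect_equal(rumple_index(incline, 0.01), sqrt(2), tolerance = 1e-9)
  expect_error(rumple_index(matrix(NA_real_, 3, 3), 0.01), "degenerate")
})

test_that("OBJ round trip preserves the mesh", {
  m <- generate_coral_shape("Pocillopora", 0.3, 0.25, 0.15, seed = 2,
                            resolution = 12)
  f <- tempfile(fileext = ".obj")
  write_obj(m, f)
  m2 <- read_obj(f, taxon = "Pocillopora")
  expect_equal(m2$vertices, unname(m$vertices), tolerance = 1e-5)
  expect_equal(nrow(m2$faces), nrow(m$faces))
  unlink(f)
})

test_that("population reaches cover by area bookkeeping", {
  bank <- small_bank()
  sub <- flat_substrate(160, 1)
  # fixed footprint 0.04 m^2 colonies: pi r^2 = 0.04 -> w = 0.22568
  w0 <- 2 * sqrt(0.04 / pi)
  szs <- list(Porites = cbind(width = rep(w0, 5), length = rep(w0, 5),
                              height = rep(0.1, 5)))
  cs <- populate_cross_section(sub, c(Porites = 0.5), szs, bank, seed = 2,
                               cell = 0.05)
  expect_equal(nrow(cs$colonies), 2000, tolerance = 1)
  expect_gte(cs$cover_achieved[["Porites"]], 0.5)
  # determinism
  cs2 <- populate_cross_section(sub, c(Porites = 0.5), szs, bank, seed = 2,
                                cell = 0.05)
  expect_identical(cs$colonies, cs2$colonies)
  # zero cover -> no colonies, SC = substrate rumple = 1
  cs0 <- populate_cross_section(sub, c(Porites = 0), szs, bank, seed = 2,
                                cell = 0.05)
  expect_equal(nrow(cs0$colonies), 0)
  expect_equal(rumple_index(cs0), 1, tolerance = 1e-9)
  # unreachable target
  expect_error(populate_cross_section(sub, c(Porites = 0.7, Acropora = 0.5),
                                      szs, bank),
               "unreachable")
})

test_that("structural complexity increases with cover and height", {
  bank <- small_bank()
  sub <- flat_substrate(20, 1)
  szs <- function(h) list(Pocillopora = cbind(width = rep(0.3, 5),
                                              length = rep(0.3, 5),
                                              height = rep(h, 5)))
  sc <- function(cov, h, seed = 3) {
    rumple_index(populate_cross_section(sub, c(Pocillopora = cov), szs(h),
                                        bank, seed = seed, cell = 0.02))
  }
  expect_gt(sc(0.4, 0.15), sc(0.15, 0.15))
  expect_gt(sc(0.3, 0.25), sc(0.3, 0.1))
})

test_that("complexity ensemble has the right shape and summary", {
  bank <- small_bank()
  sub <- flat_substrate(10, 0.5)
  traj <- data.frame(year = c(1, 2), Acropora = c(0.05, 0.1),
                     Pocillopora = c(0.05, 0.2), Porites = c(0.05, 0.1))
  sv <- generate_survey_table(disturbance_trajectory = traj,
                              n_size_samples = 10, seed = 5)
  ens <- complexity_ensemble(sv, sub, bank, n_replicates = 5, seed = 9,
                             cell = 0.04)
  expect_equal(nrow(ens), 10)
  expect_true(all(ens$sc >= 1))
  sm <- sc_summary(ens)
  expect_equal(sm$n, c(5, 5))
  # higher-cover year is more complex
  expect_gt(sm$median[2], sm$median[1])
  expect_true(all(sm$q05 <= sm$median & sm$median <= sm$q95))
})
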