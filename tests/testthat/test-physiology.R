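post_params <- liana_parameters("posterior-median")
def_params <- liana_parameters("default")

test_that("biomass allometries evaluate and stay monotone", {
  expect_equal(leaf_biomass(1, post_params), post_params$b1Bl)
  expect_equal(leaf_biomass(10, post_params), 0.0096 * 10^1.85,
               tolerance = 1e-12)
  expect_equal(leaf_biomass(10, post_params), 0.680, tolerance = 0.01)
  expect_equal(fine_root_biomass(7, post_params),
               post_params$q * leaf_biomass(7, post_params))
  d <- seq(0.5, 80, length.out = 200)
  for (f in list(leaf_biomass, stem_biomass, total_biomass)) {
    expect_true(all(diff(f(d, post_params)) > 0))
  }
  expect_error(leaf_biomass(-1, post_params), "positive")
})

test_that("leaf-area crossover between default and posterior sets is near 8.4 cm", {
  la_diff <- function(d) {
    leaf_area_plant(d, post_params) - leaf_area_plant(d, def_params)
  }
  cross <- uniroot(la_diff, c(2, 30))$root
  expect_lt(abs(cross - 8.4), 0.2)
})

test_that("height allometry saturates, shifts and inverts", {
  p <- post_params
  expect_lt(p$h_max - height_from_dbh(1e5, p), 1e-6)
  d <- seq(1, 100, length.out = 50)
  expect_true(all(diff(height_from_dbh(d, p)) > 0))
  expect_equal(height_from_dbh(7, p, delta_dbh = 5),
               height_from_dbh(12, p), tolerance = 1e-12)
  h <- height_from_dbh(15, p)
  expect_equal(dbh_from_height(h, p), 15, tolerance = 1e-9)
  expect_error(dbh_from_height(p$h_max + 1, p), "h_max")
})

test_that("rooting depth deepens with height and honours the sign convention", {
  expect_equal(rooting_depth(1, post_params), -post_params$b1Rd)
  expect_equal(rooting_depth(16, post_params), -0.5, tolerance = 1e-9)
  prior <- liana_parameters("prior-median")
  expect_equal(rooting_depth(16, prior), -1.05 * 16^0.325, tolerance = 1e-9)
  expect_lt(rooting_depth(16, prior), -2.5)  # default lianas root deep
  expect_gt(rooting_depth(16, post_params), -1)  # data confine them to ~1 m
  expect_error(rooting_depth(0, post_params), "positive")
})

test_that("vulnerability curve hits its anchors and is monotone", {
  p <- post_params
  expect_equal(stem_conductivity(0, p), p$K_max)
  expect_equal(stem_conductivity(-abs(p$P50), p), p$K_max / 2,
               tolerance = 1e-12)
  p2 <- p; p2$K_exp <- 2
  expect_equal(stem_conductivity(-2 * abs(p2$P50), p2),
               p2$K_max * 2^-4, tolerance = 1e-12)
  psi <- seq(0, -400, length.out = 1000)
  expect_true(all(diff(stem_conductivity(psi, p)) <= 0))
  expect_error(stem_conductivity(1, p), "psi")
})

test_that("stomatal stress anchors, turgor-loss cutoff and monotonicity", {
  p <- post_params
  expect_equal(stomatal_stress(0, p), 1)
  expect_equal(stomatal_stress(-abs(p$stoma_psi_b), p), 0.5,
               tolerance = 1e-12)
  p3 <- p; p3$stoma_psi_c <- 3; p3$leaf_TLP <- 1e5
  expect_equal(stomatal_stress(-2 * abs(p3$stoma_psi_b), p3), 1 / 9,
               tolerance = 1e-12)
  expect_equal(stomatal_stress(-abs(p$leaf_TLP) - 1, p), 0)
  psi <- seq(0, -abs(p$leaf_TLP), length.out = 1000)
  f <- stomatal_stress(psi, p)
  expect_true(all(diff(f) <= 1e-12))
  expect_true(all(f >= 0 & f <= 1))
})

test_that("assimilation co-limitation and dark respiration", {
  p <- post_params
  a0 <- leaf_assimilation(0, 1, p)
  expect_equal(a0$gross, 0)
  expect_equal(a0$net, -p$dark_respiration * p$V_m0)
  asat <- leaf_assimilation(1e9, 0.7, p)
  expect_equal(asat$gross, 0.7 * p$V_m0, tolerance = 1e-4)
  a <- leaf_assimilation(1000, 1, p)
  expect_equal(a$gross, (0.057 * 1000 * 35.54) / (0.057 * 1000 + 35.54),
               tolerance = 1e-6)
  expect_equal(a$gross, 21.9, tolerance = 0.01)
})

test_that("Ball-Berry conductance floors at gs_min and scales linearly", {
  p <- post_params
  expect_equal(stomatal_conductance(-5, 0.8, 370, p), p$gs_min)
  g1 <- stomatal_conductance(10, 0.8, 370, p) - p$gs_min
  expect_equal(g1, 10.48 * 10 * 0.8 / 370, tolerance = 1e-9)
  expect_equal(g1, 0.2266, tolerance = 1e-3)
  p2 <- p; p2$stomatal_slope <- 2 * p$stomatal_slope
  expect_equal(stomatal_conductance(10, 0.8, 370, p2) - p2$gs_min, 2 * g1,
               tolerance = 1e-12)
  expect_error(stomatal_conductance(1, 0.5, -1, p), "ca")
})
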