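short_met <- function(days = 40, precip = 8, par = 430) {
  data.frame(date = seq(as.Date("2004-01-01"), by = "day",
                        length.out = days),
             precip_mm = precip, par = par, tair = 26, rh = 0.85)
}

test_that("a zero-PAR day yields zero GPP but positive respiration", {
  f <- mini_forest()
  met <- short_met(32, par = 0)
  sim <- run_simulation(f, met, years = 32 / 365.25, seed = 1)
  fl <- fluxes(sim)
  expect_equal(sum(fl$gpp), 0)
  expect_gt(sum(fl$resp_auto), 0)
  expect_true(all(fl$npp <= 0))
})

test_that("two identical patches produce identical fluxes", {
  inv1 <- data.frame(patch_id = 1, stem_id = 1:3,
                     growth_form = c("tree", "tree", "liana"),
                     dbh_cm = c(35, 20, 8),
                     wood_density_g_cm3 = c(0.45, 0.65, NA),
                     density_multiplier = 1)
  inv2 <- inv1; inv2$patch_id <- 2
  f <- initialize_from_inventory(rbind(inv1, inv2), default_pfts(),
                                 sim_config(patch_area = 400))
  f <- daily_step(f, list(precip_mm = 6, par = 400, tair = 26, rh = 0.8))
  p1 <- f$patches[[1]]; p2 <- f$patches[[2]]
  expect_equal(p1$cohorts, p2$cohorts)
  expect_equal(p1$soil_theta, p2$soil_theta)
  expect_equal(p1$acc, p2$acc)
})

test_that("the daily water budget closes per patch", {
  f <- mini_forest()
  met <- short_met(45, precip = 3)  # drying conditions stress the budget
  for (k in seq_len(nrow(met))) {
    f <- daily_step(f, as.list(met[k, ]))
    for (p in f$patches) expect_lt(p$day$residual_rel, 1e-9)
  }
})

test_that("runs are reproducible given identical inputs", {
  f <- mini_forest()
  met <- short_met(70)
  a <- run_simulation(f, met, years = 70 / 365.25, seed = 1)
  b <- run_simulation(f, met, years = 70 / 365.25, seed = 1)
  expect_identical(a$fluxes, b$fluxes)
  expect_identical(a$forest_final$patches, b$forest_final$patches)
})

test_that("monthly demography closes the cohort carbon balance", {
  f <- mini_forest()
  met <- short_met(95, precip = 7)
  sim <- run_simulation(f, met, years = 95 / 365.25, seed = 1)
  expect_lt(sim$diagnostics$max_carbon_residual, 1e-6)
  # pools and densities stay non-negative
  for (p in sim$forest_final$patches) {
    expect_true(all(p$cohorts$density >= 0))
    expect_true(all(p$cohorts$bleaf >= 0))
    expect_true(all(p$cohorts$bstem >= 0))
  }
})

test_that("carbon-starvation mortality follows the logistic in the cb ratio", {
  p <- liana_parameters("posterior-median")
  rate_at <- function(cbbar) {
    p$mort3 + p$mort1 / (1 + exp(p$mort2 * cbbar))
  }
  # healthy cohorts: the density-dependent term vanishes
  expect_equal(rate_at(1), p$mort3 + p$mort1 * exp(-p$mort2) /
                 (1 + exp(-p$mort2)), tolerance = 1e-12)
  expect_lt(rate_at(1) - p$mort3, 1e-5)
  # fully starved cohorts sit at the logistic midpoint
  expect_equal(rate_at(0), p$mort3 + p$mort1 / 2, tolerance = 1e-12)
  # starvation in the model: a dark run drives the ratio to zero
  f <- mini_forest()
  met <- short_met(40, par = 0)
  sim <- run_simulation(f, met, years = 35 / 365.25, seed = 1)
  for (pa in sim$forest_final$patches) {
    expect_true(all(pa$cb[, ncol(pa$cb)] == 0))
  }
})

test_that("liana_share handles degenerate compositions", {
  fl <- data.frame(month = rep(1:2, each = 2),
                   pft = rep(c("liana", "early"), 2),
                   gpp = c(1, 1, 2, 0))
  expect_equal(liana_share(fl), c(0.5, 1))
  fl$gpp <- c(0, 1, 0, 3)
  expect_equal(liana_share(fl), c(0, 0))
  fl$gpp <- 0
  expect_true(all(is.na(liana_share(fl))))
})

test_that("malformed forcing is rejected", {
  f <- mini_forest()
  expect_error(daily_step(f, list(precip_mm = NA, par = 1, tair = 2,
                                  rh = 0.5)), "non-finite")
  expect_error(run_simulation(f, data.frame(date = Sys.Date()), years = 1),
               "lacks columns")
})
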