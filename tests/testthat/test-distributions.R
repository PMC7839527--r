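test_that("prior quantiles reproduce the tabulated prior medians", {
  tab <- liana_prior_table()
  # rows whose printed median is inconsistent with the stated family
  # constants (documented in the vignette) are excluded
  excluded <- c("b1Bl", "V_m0", "SLA", "mort2")
  for (i in seq_len(nrow(tab))) {
    if (tab$name[i] %in% excluded) next
    med <- trait_quantile(tab$prior[[i]], 0.5)
    expect_printed(med, tab$prior_median[i])
  }
})

test_that("quantile families follow the stated parameterizations", {
  expect_equal(trait_quantile(trait_prior("k", "lognormal", -3, 0.75), 0.5),
               exp(-3), tolerance = 1e-12)
  expect_equal(trait_quantile(trait_prior("b", "uniform", 1.6, 2.2), 0.5),
               1.9)
  expect_equal(trait_quantile(trait_prior("h", "normal", 0.87, 0.087), 0.5),
               0.87)
  expect_equal(trait_quantile(trait_prior("a", "gamma", 4.46, 59.7), 0.5),
               0.069, tolerance = 0.005)
  # gamma uses the rate (not scale) parameterization
  expect_equal(trait_quantile(trait_prior("a", "gamma", 2, 4), 0.25),
               qgamma(0.25, shape = 2, rate = 4))
})

test_that("negation reverses the quantile order on the use scale", {
  p50 <- trait_prior("P50", "normal", 150, 50, negate = TRUE)
  for (p in c(0.1, 0.25, 0.5, 0.9)) {
    expect_equal(trait_quantile(p50, p, use_scale = TRUE),
                 -qnorm(1 - p, 150, 50), tolerance = 1e-12)
  }
  # use-scale quantile function must still be increasing in p
  q <- trait_quantile(p50, c(0.1, 0.4, 0.6, 0.9), use_scale = TRUE)
  expect_true(all(diff(q) > 0))
})

test_that("quantile functions are strictly increasing on (0,1)", {
  tab <- liana_prior_table()
  p <- seq(0.01, 0.99, length.out = 25)
  for (i in seq_len(nrow(tab))) {
    q <- trait_quantile(tab$prior[[i]], p)
    expect_true(all(diff(q) >= 0), info = tab$name[i])
    expect_true(all(is.finite(q)), info = tab$name[i])
  }
})

test_that("invalid constants and probabilities are rejected by field", {
  expect_error(trait_prior("x", "uniform", 2, 1), "a < b")
  expect_error(trait_prior("x", "normal", 0, -1), "b > 0")
  expect_error(trait_prior("x", "gamma", -1, 1), "a > 0")
  expect_error(trait_prior("x", "weibull", 0, 1), "a > 0")
  d <- trait_prior("x", "normal", 0, 1)
  expect_error(trait_quantile(d, 0), "p")
  expect_error(trait_quantile(d, 1), "p")
  expect_error(trait_quantile(d, c(0.5, 1.2)), "p")
})

test_that("coefficient of variation matches closed forms", {
  expect_equal(coefficient_of_variation(rep(5, 100)), 0)
  set.seed(42)
  u <- runif(1e6)
  expect_equal(coefficient_of_variation(u), (1 / sqrt(12)) / 0.5,
               tolerance = 0.01)
  ln <- rlnorm(1e6, 0, 0.5)
  expect_equal(coefficient_of_variation(ln),
               sqrt(exp(0.25) * (exp(0.25) - 1)) / 1, tolerance = 0.01)
  expect_error(coefficient_of_variation(c(-1, 0, 1)), "zero")
})

test_that("analytic prior sd agrees with large-sample draws", {
  tab <- liana_prior_table()
  set.seed(7)
  for (nm in c("K_max", "quantum_efficiency", "growth_respiration",
               "root_turnover", "b2Ht", "rho")) {
    pr <- tab$prior[[which(tab$name == nm)]]
    expect_equal(trait_prior_sd(pr), sd(trait_sample(pr, 2e5)),
                 tolerance = 0.02, info = nm)
  }
})

test_that("the unit scale factor is applied to quantiles and draws", {
  wc <- trait_prior("wood_capacitance", "lognormal", 2, 0.5, scale = 1e-3)
  expect_equal(trait_quantile(wc, 0.5), exp(2) / 1000, tolerance = 1e-12)
  set.seed(1)
  expect_true(all(trait_sample(wc, 1000) < 0.1))
})
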