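test_that("the quantile design places the seven +/- SD probability levels", {
  d <- sensitivity_design(trait_prior("z", "normal", 0, 1))
  expect_equal(d$prob, pnorm(-3:3), tolerance = 1e-12)
  expect_equal(d$value, -3:3, tolerance = 1e-9)
  u <- sensitivity_design(trait_prior("u", "uniform", 0, 1))
  expect_equal(u$value, u$prob, tolerance = 1e-9)
  k <- sensitivity_design(trait_prior("K_max", "lognormal", -3, 0.75))
  expect_equal(k$value[k$z == 0], 0.05, tolerance = 0.005)
  expect_warning(sensitivity_design(rep(3, 100)), "degenerate")
})

test_that("empirical designs use the draw quantiles", {
  set.seed(5)
  post <- trait_posterior("x", rnorm(50000, 10, 2))
  d <- sensitivity_design(post)
  expect_equal(d$value[d$z == 0], 10, tolerance = 0.05)
  expect_equal(d$value[d$z == 1] - d$value[d$z == -1], 4, tolerance = 0.1)
})

test_that("evaluate_design runs the model per design point", {
  d <- sensitivity_design(trait_prior("x", "uniform", 1, 3))
  cst <- evaluate_design(function(b) 7, d)
  expect_equal(cst$response, rep(7, 7))
  lin <- evaluate_design(function(b) 2 * b, d)
  expect_equal(lin$response, 2 * d$value)
  mono <- evaluate_design(function(b) b^3, d)
  expect_true(all(diff(mono$response) > 0))
  # failures are tolerated down to four points
  flaky <- function(b) if (b < 1.2) stop("boom") else b
  expect_silent(evaluate_design(flaky, d))
  expect_error(evaluate_design(function(b) stop("no"), d), "fewer than 4")
})

test_that("the response spline interpolates exactly and extrapolates linearly", {
  x <- c(-3, -2, -1, 0, 1, 2, 3)
  yl <- 2 * x + 1
  g <- fit_response_spline(x, yl)
  grid <- seq(-5, 5, length.out = 300)
  expect_lt(max(abs(g(grid) - (2 * grid + 1))), 1e-12)
  yq <- x^2
  gq <- fit_response_spline(x, yq)
  inner <- seq(-3, 3, length.out = 200)
  expect_lt(max(abs(gq(inner) - inner^2)) / max(inner^2), 0.05)
  expect_equal(gq(x), yq, tolerance = 1e-12)
  # beyond the nodes the slope is frozen
  expect_equal(gq(5) - gq(4), gq(4) - gq(3), tolerance = 1e-9)
  expect_error(fit_response_spline(c(1, 1, 2, 3), c(1, 2, 3, 4)),
               "duplicated")
  expect_error(fit_response_spline(1:3, 1:3), "4")
})

test_that("elasticity has the closed-form values", {
  g_const <- function(b, deriv = 0) if (deriv == 0) rep(5, length(b))
                                    else rep(0, length(b))
  expect_equal(elasticity(g_const, 2), 0)
  for (k in c(0.5, 1, 2, 3)) {
    g_pow <- local({
      kk <- k
      function(b, deriv = 0) if (deriv == 0) b^kk else kk * b^(kk - 1)
    })
    for (bmed in c(0.5, 1, 4)) {
      expect_equal(elasticity(g_pow, bmed), k, tolerance = 1e-12)
    }
  }
  g_aff <- function(b, deriv = 0) if (deriv == 0) 2 * b + 2
                                  else rep(2, length(b))
  expect_equal(elasticity(g_aff, 1), 0.5, tolerance = 1e-12)
  g_zero <- function(b, deriv = 0) if (deriv == 0) rep(0, length(b))
                                   else rep(1, length(b))
  expect_warning(e <- elasticity(g_zero, 1), "undefined")
  expect_true(is.na(e))
})

test_that("spline-based elasticity matches the power law on the design", {
  pr <- trait_prior("x", "lognormal", 0, 0.3)
  s <- run_sensitivity(function(b) b^2, pr)
  # the spline derivative at the median node is a slope-limited finite
  # difference, so the power-law exponent is recovered approximately
  expect_equal(s$elasticity, 2, tolerance = 0.05)
})
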