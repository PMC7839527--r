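kmax_prior <- function() trait_prior("K_max", "lognormal", -3, 0.75)

test_that("with no observations the posterior equals the prior", {
  pr <- kmax_prior()
  post <- run_meta_analysis(pr, NULL, mcmc_settings(2, 3000, 500, seed = 3))
  expect_s3_class(post, "trait_posterior")
  expect_identical(post$source, "prior-only")
  # posterior median within MC error of the analytic prior median
  se_med <- 1.2533 * sd(post$samples) / sqrt(length(post$samples))
  expect_lt(abs(post$median - trait_quantile(pr, 0.5)), 4 * se_med)
})

test_that("known truth is recovered and matches a frequentist oracle", {
  pr <- kmax_prior()
  obs <- generate_trait_dataset("K_max", true_mean = 0.1,
                                between_sd = 0.02, within_sd = 0.01,
                                n_studies = 5, obs_per_study = 10,
                                seed = 7)
  post <- run_meta_analysis(pr, obs, mcmc_settings(2, 3000, 500, seed = 4))
  ci <- quantile(post, c(0.025, 0.975))
  expect_gt(0.1, ci[1])
  expect_lt(0.1, ci[2])
  expect_lt(post$cv, coefficient_of_variation(pr))
  # independent route: REML random-effects meta-analysis of the same table
  or <- metafor::rma(yi = obs$mean, sei = obs$se, method = "REML")
  expect_lt(abs(post$median - as.numeric(or$beta)),
            4 * as.numeric(or$se) + 0.01)
})

test_that("a single uninformative observation leaves the prior unchanged", {
  pr <- trait_prior("b2Ht", "normal", 0.87, 0.087)
  obs <- data.frame(trait = "b2Ht", mean = 0.9,
                    se = 1e6 * trait_prior_sd(pr), n = 1,
                    study_id = "s1", site_id = "a")
  post <- run_meta_analysis(pr, obs, mcmc_settings(2, 4000, 1000, seed = 5))
  set.seed(99)
  ks <- suppressWarnings(
    ks.test(post$samples, trait_sample(pr, 20000))$statistic)
  expect_lt(as.numeric(ks), 0.05)
})

test_that("the sampler is reproducible and validates its inputs", {
  pr <- kmax_prior()
  obs <- generate_trait_dataset("K_max", 0.08, 0.01, 0.01, 4, 4, seed = 2)
  a <- run_meta_analysis(pr, obs, mcmc_settings(2, 800, 200, seed = 11))
  b <- run_meta_analysis(pr, obs, mcmc_settings(2, 800, 200, seed = 11))
  expect_identical(a$samples, b$samples)
  obs_bad <- obs
  obs_bad$trait[1] <- "SLA"
  expect_error(run_meta_analysis(pr, obs_bad, mcmc_settings(2, 800, 200)),
               "mix")
  obs_bad2 <- obs
  obs_bad2$se[2] <- -1
  expect_error(run_meta_analysis(pr, obs_bad2, mcmc_settings(2, 800, 200)),
               "positive")
})

test_that("posterior CV shrinks below prior CV with informative data", {
  pr <- kmax_prior()
  obs <- generate_trait_dataset("K_max", 0.06, 0.005, 0.005,
                                n_studies = 6, obs_per_study = 4, seed = 21)
  post <- run_meta_analysis(pr, obs, mcmc_settings(2, 2000, 500, seed = 6))
  expect_lt(post$cv, coefficient_of_variation(pr))
})

test_that("allometric priors recover known power laws", {
  x <- c(2, 5, 10, 20, 40)
  y <- 0.02 * x^1.9
  fit <- fit_allometric_prior(x, y, "Bl", seed = 1)
  expect_equal(fit$slope$median, 1.9, tolerance = 1e-8)
  expect_equal(fit$intercept$median, 0.02, tolerance = 1e-8)
  expect_lt(fit$slope$cv, 1e-6)

  set.seed(31)
  xn <- runif(200, 1, 50)
  yn <- 0.02 * xn^1.9 * exp(rnorm(200, 0, 0.1))
  fitn <- fit_allometric_prior(xn, yn, "Bl", seed = 2)
  expect_lt(abs(fitn$slope$median - 1.9), 0.05)
  expect_error(fit_allometric_prior(c(-1, 2, 3), c(1, 2, 3)), "positive")
  expect_error(fit_allometric_prior(c(1, 2), c(1, 2)), "3 points")
})
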