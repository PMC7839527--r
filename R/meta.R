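#' Trait posterior container
#'
#' Wraps posterior draws of a trait's across-study mean with its summary
#' statistics. The coefficient of variation is
#' `cv = sqrt(Var[beta0]) / |median(beta0)|`.
#'
#' @param trait parameter identifier.
#' @param samples numeric vector of posterior draws (storage scale).
#' @param source one of `"prior-only"`, `"meta-analysis"`,
#'   `"allometric-fit"`.
#' @param provenance optional list recording settings and warnings.
#' @return Object of class `trait_posterior`.
#' @export
trait_posterior <- function(trait, samples,
                            source = c("meta-analysis", "prior-only",
                                       "allometric-fit"),
                            provenance = list()) {
  source <- match.arg(source)
  samples <- as.numeric(samples)
  if (!length(samples) || any(!is.finite(samples)))
    stop("samples must be a non-empty finite vector for trait '", trait, "'",
         call. = FALSE)
  med <- stats::median(samples)
  v <- stats::var(samples)
  if (is.na(v)) v <- 0
  structure(list(trait = trait, samples = samples, median = med,
                 variance = v,
                 cv = if (med != 0) sqrt(v) / abs(med) else NA_real_,
                 source = source, provenance = provenance),
            class = "trait_posterior")
}

#' @export
print.trait_posterior <- function(x, ...) {
  cat(sprintf("<trait_posterior> %s (%s): median %.4g, cv %.3g, %d draws\n",
              x$trait, x$source, x$median, x$cv, length(x$samples)))
  if (!is.null(x$provenance$rhat_warning))
    cat("  warning: ", x$provenance$rhat_warning, "\n")
  invisible(x)
}

#' @export
coef.trait_posterior <- function(object, ...) {
  stats::setNames(object$median, object$trait)
}

#' @export
quantile.trait_posterior <- function(x, probs = c(0.025, 0.5, 0.975), ...) {
  stats::quantile(x$samples, probs = probs, names = TRUE)
}

#' Coefficient of variation of a posterior
#'
#' `CV = sqrt(Var[beta0]) / |median(beta0)|` from the empirical draws.
#'
#' @param x a [trait_posterior], [trait_prior] (evaluated analytically via
#'   a large quantile grid), or numeric draw vector.
#' @param trait label used in error messages for bare vectors.
#' @return The coefficient of variation.
#' @export
coefficient_of_variation <- function(x, trait = "trait") {
  if (inherits(x, "trait_posterior")) {
    if (x$median == 0) stop("median of '", x$trait,
                            "' is zero; CV undefined", call. = FALSE)
    return(sqrt(x$variance) / abs(x$median))
  }
  if (inherits(x, "trait_prior")) {
    med <- trait_quantile(x, 0.5)
    if (med == 0) stop("median of '", x$name, "' is zero; CV undefined",
                       call. = FALSE)
    return(trait_prior_sd(x) / abs(med))
  }
  x <- as.numeric(x)
  if (!length(x)) stop("empty sample for '", trait, "'", call. = FALSE)
  med <- stats::median(x)
  if (med == 0) stop("median of '", trait, "' is zero; CV undefined",
                     call. = FALSE)
  s <- stats::sd(x)
  if (is.na(s)) s <- 0
  s / abs(med)
}

# split-Rhat of Gelman et al. on a draws matrix (iterations x chains)
split_rhat <- function(draws) {
  half <- floor(nrow(draws) / 2)
  if (half < 2) return(NA_real_)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[half + seq_len(half), , drop = FALSE])
  m <- ncol(sub); n <- nrow(sub)
  mu <- colMeans(sub)
  b <- n * stats::var(mu)
  wv <- mean(apply(sub, 2, stats::var))
  if (wv == 0) return(1)
  sqrt(((n - 1) / n * wv + b / n) / wv)
}

#' MCMC settings for the trait meta-analysis
#'
#' @param n_chains number of chains.
#' @param n_iter draws per chain (after which burn-in is removed).
#' @param n_burn burn-in draws discarded per chain.
#' @param seed integer seed.
#' @return Named list.
#' @export
mcmc_settings <- function(n_chains = 4, n_iter = 5000, n_burn = 1000,
                          seed = 1L) {
  stopifnot(n_iter > n_burn, n_chains >= 1)
  list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
       n_burn = as.integer(n_burn), seed = as.integer(seed))
}

#' Bayesian random-effects trait meta-analysis
#'
#' Two-level hierarchical model for mean trait observations:
#' `y_i ~ Normal(theta_study(i), s_i^2)`, study effects
#' `theta_j ~ Normal(beta0, tau^2)`, with the packaged trait prior on the
#' across-study mean `beta0` and a weakly-informative inverse-gamma prior
#' on `tau^2`. Sampling is Metropolis-within-Gibbs: study effects and
#' `tau^2` have conjugate updates; `beta0` uses a random-walk Metropolis
#' step against the (arbitrary-family) prior density. With no observations
#' the posterior is the prior, sampled directly. Missing standard errors
#' are imputed as the prior sd divided by `sqrt(n)` when `n` is known,
#' else the prior sd (flagged in the provenance).
#'
#' @param prior a [trait_prior].
#' @param obs data frame of observations with columns `trait`, `mean`
#'   (storage scale), `se`, `n`, `study_id` (and optionally `site_id`).
#' @param settings a [mcmc_settings()].
#' @return A [trait_posterior] of the across-study mean, with split-Rhat
#'   and any convergence warning recorded in its provenance.
#' @export
run_meta_analysis <- function(prior, obs = NULL,
                              settings = mcmc_settings()) {
  stopifnot(inherits(prior, "trait_prior"))
  n_keep <- settings$n_iter - settings$n_burn
  if (is.null(obs) || nrow(obs) == 0) {
    set.seed(settings$seed)
    draws <- trait_sample(prior, n_keep * settings$n_chains)
    return(trait_posterior(prior$name, draws, source = "prior-only",
                           provenance = list(settings = settings)))
  }
  if (!all(obs$trait == prior$name))
    stop("observations mix trait names: expected '", prior$name, "'",
         call. = FALSE)
  if (any(!is.finite(obs$mean)))
    stop("non-finite observation means", call. = FALSE)
  if (!is.null(obs$se) && any(!is.na(obs$se) & obs$se <= 0))
    stop("standard errors must be positive when present", call. = FALSE)

  prior_sd <- trait_prior_sd(prior)
  se <- if (is.null(obs$se)) rep(NA_real_, nrow(obs)) else obs$se
  nn <- if (is.null(obs$n)) rep(NA_real_, nrow(obs)) else obs$n
  imputed <- is.na(se)
  se[imputed] <- ifelse(!is.na(nn[imputed]),
                        prior_sd / sqrt(pmax(nn[imputed], 1)), prior_sd)
  study <- as.integer(factor(obs$study_id))
  j_n <- max(study)
  y <- obs$mean
  w <- 1 / se^2
  sw_j <- vapply(seq_len(j_n), function(j) sum(w[study == j]), numeric(1))
  swy_j <- vapply(seq_len(j_n), function(j) sum((w * y)[study == j]),
                  numeric(1))

  support <- switch(prior$family,
                    uniform = prior$scale * c(prior$a, prior$b),
                    normal = c(-Inf, Inf),
                    beta = prior$scale * c(0, 1),
                    c(0, Inf))
  a0 <- b0 <- 0.001  # weakly-informative inverse-gamma on tau^2
  prop_sd <- prior_sd / 2

  run_chain <- function(chain) {
    set.seed(settings$seed + 1000L * chain)
    beta0 <- trait_quantile(prior, 0.2 + 0.2 * ((chain - 1) %% 4))
    tau2 <- prior_sd^2 / 4
    theta <- rep(beta0, j_n)
    out <- numeric(settings$n_iter)
    for (it in seq_len(settings$n_iter)) {
      prec <- sw_j + 1 / tau2
      theta <- stats::rnorm(j_n, (swy_j + beta0 / tau2) / prec,
                            sqrt(1 / prec))
      tau2 <- 1 / stats::rgamma(1, a0 + j_n / 2,
                                b0 + sum((theta - beta0)^2) / 2)
      cand <- beta0 + stats::rnorm(1, 0, prop_sd)
      if (cand > support[1] && cand < support[2]) {
        lr <- sum(stats::dnorm(theta, cand, sqrt(tau2), log = TRUE)) -
          sum(stats::dnorm(theta, beta0, sqrt(tau2), log = TRUE)) +
          trait_log_density(prior, cand) - trait_log_density(prior, beta0)
        if (is.finite(lr) && log(stats::runif(1)) < lr) beta0 <- cand
      }
      out[it] <- beta0
    }
    out
  }
  chains <- vapply(seq_len(settings$n_chains), run_chain,
                   numeric(settings$n_iter))
  kept <- chains[(settings$n_burn + 1):settings$n_iter, , drop = FALSE]
  rhat <- split_rhat(kept)
  prov <- list(settings = settings, rhat = rhat,
               n_obs = nrow(obs), n_studies = j_n,
               se_imputed = sum(imputed))
  if (is.finite(rhat) && rhat > 1.1) {
    prov$rhat_warning <- sprintf(
      "split-Rhat %.3f > 1.1: chains may not have converged", rhat)
    warning("trait '", prior$name, "': ", prov$rhat_warning, call. = FALSE)
  }
  trait_posterior(prior$name, as.numeric(kept), source = "meta-analysis",
                  provenance = prov)
}

#' Data-informed prior for an allometric coefficient pair
#'
#' Fits `log(y) = log(b1) + b2 * log(x)` by ordinary least squares and
#' draws the coefficient pair from its bivariate-normal sampling
#' distribution, exponentiating the intercept. Used for the liana
#' allometries (leaf biomass, stem biomass, rooting depth), for which too
#' few studies exist for the hierarchical meta-analysis.
#'
#' @param x predictor values (DBH in cm, or height in m), strictly positive.
#' @param y response values (kg_C, or depth magnitude in m), strictly
#'   positive (sign conventions applied downstream).
#' @param trait_pair label, e.g. `"Bl"`.
#' @param n_draws posterior draws.
#' @param seed integer seed.
#' @return List with elements `intercept` and `slope`, both
#'   [trait_posterior] objects (source `"allometric-fit"`).
#' @export
fit_allometric_prior <- function(x, y, trait_pair = "allom", n_draws = 4000,
                                 seed = 1L) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("x must be strictly positive", call. = FALSE)
  if (any(!is.finite(y)) || any(y <= 0))
    stop("y must be strictly positive", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  fit <- stats::lm(log(y) ~ log(x))
  cf <- stats::coef(fit)
  sig2 <- stats::deviance(fit)
  set.seed(seed)
  if (sig2 < 1e-24) {  # noiseless data: degenerate point-mass posterior
    draws <- matrix(rep(cf, each = n_draws), ncol = 2)
  } else {
    draws <- MASS::mvrnorm(n_draws, cf, stats::vcov(fit))
  }
  list(intercept = trait_posterior(paste0("b1", trait_pair),
                                   exp(draws[, 1]),
                                   source = "allometric-fit"),
       slope = trait_posterior(paste0("b2", trait_pair), draws[, 2],
                               source = "allometric-fit"))
}

#' Prior/posterior comparison plot
#'
#' @param x a [trait_posterior].
#' @param prior optional [trait_prior] overlaid as a density.
#' @param ... passed to [graphics::plot()].
#' @export
plot.trait_posterior <- function(x, prior = NULL, ...) {
  d <- stats::density(x$samples)
  graphics::plot(d, main = x$trait, xlab = "value", ...)
  if (!is.null(prior)) {
    xx <- seq(min(d$x), max(d$x), length.out = 200)
    graphics::lines(xx, exp(trait_log_density(prior, xx)), lty = 2)
    graphics::legend("topright", c("posterior", "prior"), lty = c(1, 2),
                     bty = "n")
  }
  invisible(x)
}
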