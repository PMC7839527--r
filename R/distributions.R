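#' Trait prior distribution
#'
#' Constructs a named prior distribution for a plant-trait parameter. The two
#' constants `a` and `b` are interpreted per family as: uniform(min = a,
#' max = b); normal(mean = a, sd = b); lognormal(meanlog = a, sdlog = b);
#' gamma(shape = a, rate = b); beta(shape1 = a, shape2 = b);
#' weibull(shape = a, scale = b).
#'
#' Priors are stored on the positive ("storage") scale. Traits that are
#' physically negative (water potentials, rooting depth intercept) carry
#' `negate = TRUE` and are multiplied by -1 at use time. A few priors are
#' specified on a rescaled unit system; `scale` is applied multiplicatively
#' after quantile evaluation or sampling.
#'
#' @param name parameter identifier.
#' @param family one of `"uniform"`, `"normal"`, `"lognormal"`, `"gamma"`,
#'   `"beta"`, `"weibull"`.
#' @param a,b the two distribution constants (see Details).
#' @param negate logical; is the trait used with its sign flipped?
#' @param scale multiplicative unit-conversion factor applied after sampling.
#' @param units free-text units of the trait on the storage scale.
#' @return An object of class `trait_prior`.
#' @examples
#' kmax <- trait_prior("K_max", "lognormal", -3, 0.75)
#' trait_quantile(kmax, 0.5) # 0.0498
#' @export
trait_prior <- function(name, family, a, b, negate = FALSE, scale = 1,
                        units = "") {
  family <- match.arg(family, c("uniform", "normal", "lognormal", "gamma",
                                "beta", "weibull"))
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a non-empty string", call. = FALSE)
  if (!is.finite(a)) stop("'a' must be finite for trait '", name, "'",
                          call. = FALSE)
  if (!is.finite(b)) stop("'b' must be finite for trait '", name, "'",
                          call. = FALSE)
  if (family == "uniform" && !(a < b))
    stop("uniform prior for '", name, "' requires a < b", call. = FALSE)
  if (family %in% c("normal", "lognormal") && !(b > 0))
    stop(family, " prior for '", name, "' requires b > 0", call. = FALSE)
  if (family %in% c("gamma", "beta", "weibull") && !(a > 0 && b > 0))
    stop(family, " prior for '", name, "' requires a > 0 and b > 0",
         call. = FALSE)
  if (!is.finite(scale) || scale <= 0)
    stop("'scale' must be a positive number for trait '", name, "'",
         call. = FALSE)
  structure(
    list(name = name, family = family, a = a, b = b,
         negate = isTRUE(negate), scale = scale, units = units),
    class = "trait_prior"
  )
}

#' @export
print.trait_prior <- function(x, ...) {
  cat(sprintf("<trait_prior> %s ~ %s(%g, %g)%s%s\n", x$name, x$family,
              x$a, x$b,
              if (x$scale != 1) sprintf(" x %g", x$scale) else "",
              if (x$negate) " [negated at use]" else ""))
  cat(sprintf("  median %g%s\n", trait_quantile(x, 0.5),
              if (nzchar(x$units)) paste0(" ", x$units) else ""))
  invisible(x)
}

q_fun <- function(family) {
  switch(family,
         uniform   = function(p, a, b) stats::qunif(p, a, b),
         normal    = function(p, a, b) stats::qnorm(p, a, b),
         lognormal = function(p, a, b) stats::qlnorm(p, a, b),
         gamma     = function(p, a, b) stats::qgamma(p, shape = a, rate = b),
         beta      = function(p, a, b) stats::qbeta(p, a, b),
         weibull   = function(p, a, b) stats::qweibull(p, shape = a, scale = b))
}

d_fun <- function(family) {
  switch(family,
         uniform   = function(x, a, b) stats::dunif(x, a, b, log = TRUE),
         normal    = function(x, a, b) stats::dnorm(x, a, b, log = TRUE),
         lognormal = function(x, a, b) stats::dlnorm(x, a, b, log = TRUE),
         gamma     = function(x, a, b) stats::dgamma(x, shape = a, rate = b,
                                                     log = TRUE),
         beta      = function(x, a, b) stats::dbeta(x, a, b, log = TRUE),
         weibull   = function(x, a, b) stats::dweibull(x, shape = a, scale = b,
                                                       log = TRUE))
}

#' Quantile of a trait distribution
#'
#' Evaluates the p-quantile of a trait prior. By default the value is
#' returned on the positive storage scale (the scale on which prior medians
#' are tabulated). With `use_scale = TRUE` the negation flag is applied,
#' which reverses the order of quantiles: the p-quantile of the negated
#' variable is minus the (1-p)-quantile.
#'
#' @param dist a [trait_prior].
#' @param p probabilities, strictly inside (0, 1).
#' @param use_scale apply the negation convention (model-use scale)?
#' @return Numeric vector of quantiles.
#' @export
trait_quantile <- function(dist, p, use_scale = FALSE) {
  stopifnot(inherits(dist, "trait_prior"))
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("'p' must lie strictly in (0, 1) for trait '", dist$name, "'",
         call. = FALSE)
  qf <- q_fun(dist$family)
  if (use_scale && dist$negate) {
    -dist$scale * qf(1 - p, dist$a, dist$b)
  } else {
    dist$scale * qf(p, dist$a, dist$b)
  }
}

#' Random draws from a trait distribution
#'
#' @param dist a [trait_prior].
#' @param n number of draws.
#' @param use_scale apply the negation convention?
#' @return Numeric vector of length `n` (storage scale unless `use_scale`).
#' @export
trait_sample <- function(dist, n, use_scale = FALSE) {
  stopifnot(inherits(dist, "trait_prior"))
  x <- trait_quantile(dist, stats::runif(n), use_scale = FALSE)
  if (use_scale && dist$negate) -x else x
}

#' Log-density of a trait distribution on the storage scale
#'
#' @param dist a [trait_prior].
#' @param x values on the storage scale (scale factor included).
#' @return Log-density values (includes the Jacobian of the scale factor).
#' @export
trait_log_density <- function(dist, x) {
  stopifnot(inherits(dist, "trait_prior"))
  d_fun(dist$family)(x / dist$scale, dist$a, dist$b) - log(dist$scale)
}

#' Standard deviation of a trait prior (storage scale)
#'
#' Closed forms for all six families; used for imputing missing standard
#' errors and scaling Metropolis proposals.
#'
#' @param dist a [trait_prior].
#' @return The prior standard deviation.
#' @export
trait_prior_sd <- function(dist) {
  stopifnot(inherits(dist, "trait_prior"))
  a <- dist$a; b <- dist$b
  sd0 <- switch(dist$family,
    uniform   = (b - a) / sqrt(12),
    normal    = b,
    lognormal = sqrt((exp(b^2) - 1) * exp(2 * a + b^2)),
    gamma     = sqrt(a) / b,
    beta      = sqrt(a * b / ((a + b)^2 * (a + b + 1))),
    weibull   = b * sqrt(gamma(1 + 2 / a) - gamma(1 + 1 / a)^2))
  dist$scale * sd0
}

#' Convert storage-scale values to model-use scale
#'
#' Applies the negation convention of a trait: values of traits flagged
#' `negate` are multiplied by -1 (water potentials, rooting-depth intercept).
#'
#' @param dist a [trait_prior].
#' @param x storage-scale values.
#' @return Use-scale values.
#' @export
trait_use_value <- function(dist, x) {
  stopifnot(inherits(dist, "trait_prior"))
  if (dist$negate) -x else x
}
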