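#' One-at-a-time quantile design
#'
#' The seven design points of the sensitivity analysis: median and +/- 1, 2,
#' 3 SD expressed as normal-CDF probability levels
#' `Phi(z), z = -3..3`, pushed through the trait's own quantile function
#' (analytic for priors, empirical for posterior draw sets). This makes the
#' "+/- SD" design meaningful for skewed and bounded prior families.
#'
#' @param x a [trait_prior], [trait_posterior], or numeric draw vector.
#' @return Data frame with columns `z`, `prob`, `value` (storage scale).
#' @export
sensitivity_design <- function(x) {
  z <- -3:3
  p <- stats::pnorm(z)
  values <-
    if (inherits(x, "trait_prior")) trait_quantile(x, p)
    else if (inherits(x, "trait_posterior"))
      as.numeric(stats::quantile(x$samples, p, names = FALSE))
    else as.numeric(stats::quantile(as.numeric(x), p, names = FALSE))
  if (length(unique(values)) < 7) {
    warning("degenerate distribution: design collapses to ",
            length(unique(values)), " distinct values", call. = FALSE)
  }
  data.frame(z = z, prob = p, value = values)
}

#' Evaluate a model over a sensitivity design
#'
#' Runs the model once per design value with all other parameters at their
#' medians (the runner closes over those). Failed runs are recorded as
#' missing; at least four successful points are required downstream.
#'
#' @param runner function taking a single storage-scale trait value and
#'   returning a scalar model response.
#' @param design data frame from [sensitivity_design()].
#' @return The design with a `response` column.
#' @export
evaluate_design <- function(runner, design) {
  stopifnot(is.function(runner), is.data.frame(design))
  design$response <- vapply(design$value, function(v) {
    out <- tryCatch(runner(v), error = function(e) NA_real_)
    if (!is.numeric(out) || length(out) != 1) NA_real_ else as.numeric(out)
  }, numeric(1))
  if (sum(is.finite(design$response)) < 4)
    stop("fewer than 4 successful design evaluations", call. = FALSE)
  design
}

#' Monotone Hermite cubic response spline
#'
#' C1 piecewise-cubic Hermite interpolant through the (design value,
#' response) points using the monotonicity-preserving Fritsch-Carlson slope
#' rule, with linear extrapolation beyond the outer design points (so
#' posterior tails beyond the design span do not pick up spurious
#' curvature). Exact at the nodes.
#'
#' @param values strictly increasing design values.
#' @param responses model responses at the design values.
#' @return A function of class `response_spline`: `g(beta, deriv = 0)`.
#' @export
fit_response_spline <- function(values, responses) {
  ok <- is.finite(values) & is.finite(responses)
  x <- values[ok]; y <- responses[ok]
  if (length(x) < 4) stop("need at least 4 finite points", call. = FALSE)
  if (anyDuplicated(x)) stop("duplicated design values", call. = FALSE)
  ord <- order(x); x <- x[ord]; y <- y[ord]
  f <- stats::splinefun(x, y, method = "monoH.FC")
  x_lo <- x[1]; x_hi <- x[length(x)]
  s_lo <- f(x_lo, deriv = 1); s_hi <- f(x_hi, deriv = 1)
  y_lo <- y[1]; y_hi <- y[length(x)]
  g <- function(beta, deriv = 0) {
    beta <- as.numeric(beta)
    out <- numeric(length(beta))
    lo <- beta < x_lo; hi <- beta > x_hi; mid <- !lo & !hi
    if (deriv == 0) {
      out[mid] <- f(beta[mid])
      out[lo] <- y_lo + s_lo * (beta[lo] - x_lo)
      out[hi] <- y_hi + s_hi * (beta[hi] - x_hi)
    } else if (deriv == 1) {
      out[mid] <- f(beta[mid], deriv = 1)
      out[lo] <- s_lo
      out[hi] <- s_hi
    } else stop("deriv must be 0 or 1", call. = FALSE)
    out
  }
  attr(g, "knots") <- x
  class(g) <- c("response_spline", "function")
  g
}

#' Model elasticity at the posterior median
#'
#' Normalized sensitivity `eps = g'(beta_med) * beta_med / g(beta_med)`:
#' the local power-law exponent of the model response in the trait.
#'
#' @param g a [fit_response_spline()] interpolant.
#' @param beta_med the trait's (posterior) median, storage scale.
#' @return The elasticity; `NA` with a warning when `g(beta_med) = 0`.
#' @export
elasticity <- function(g, beta_med) {
  g0 <- g(beta_med)
  if (!is.finite(g0) || g0 == 0) {
    warning("g(beta_med) is zero; elasticity undefined", call. = FALSE)
    return(NA_real_)
  }
  g(beta_med, deriv = 1) * beta_med / g0
}

#' Full one-at-a-time sensitivity for one trait
#'
#' Convenience wrapper: design, model evaluations, spline, elasticity and
#' the posterior-propagated output variance `Var[g(beta0)]`.
#'
#' @param runner scalar model runner (see [evaluate_design()]).
#' @param dist the trait's [trait_prior] or [trait_posterior].
#' @param trait trait name (defaults from `dist`).
#' @return Object of class `sensitivity_result`.
#' @export
run_sensitivity <- function(runner, dist, trait = NULL) {
  if (is.null(trait))
    trait <- if (inherits(dist, "trait_prior")) dist$name else dist$trait
  design <- evaluate_design(runner, sensitivity_design(dist))
  g <- fit_response_spline(design$value, design$response)
  med <- design$value[design$z == 0]
  draws <- if (inherits(dist, "trait_prior"))
    trait_sample(dist, 4000) else dist$samples
  structure(list(trait = trait, design = design, spline = g,
                 elasticity = elasticity(g, med),
                 variance = stats::var(g(draws)),
                 median = med, draws = draws),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result> %s: elasticity %.3g, Var[g(beta0)] %.3g\n",
              x$trait, x$elasticity, x$variance))
  invisible(x)
}

#' @export
plot.sensitivity_result <- function(x, ...) {
  d <- x$design
  xx <- seq(min(d$value), max(d$value), length.out = 200)
  graphics::plot(d$value, d$response, pch = 19, xlab = x$trait,
                 ylab = "model response", ...)
  graphics::lines(xx, x$spline(xx))
  invisible(x)
}
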