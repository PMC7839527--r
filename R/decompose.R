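#' Variance decomposition across traits
#'
#' Propagates each trait's posterior through its response spline and
#' decomposes the total parametric output variance:
#' `Var_p = Var[g_p(beta0_p)]`, `tot_var = sum_p Var_p`, and the partial
#' (relative) variances `rel_var_p = Var_p / tot_var`. Relative variances
#' are additionally aggregated over the packaged classification of each
#' parameter into competition type (light / water / unclassified), plant
#' organ and ecophysiological process.
#'
#' @param splines named list of [fit_response_spline()] functions (or
#'   `sensitivity_result` objects), one per trait.
#' @param posteriors named list matching `splines`: [trait_posterior]
#'   objects, [trait_prior]s (sampled), or numeric draw vectors.
#' @param classification data frame as [parameter_classification()];
#'   traits absent from it fall into the `unclassified` classes.
#' @param n_prior_draws draws used when a prior must be sampled.
#' @return Object of class `decomposition_table`.
#' @export
variance_decomposition <- function(splines, posteriors,
                                   classification = parameter_classification(),
                                   n_prior_draws = 4000) {
  stopifnot(length(splines) > 0,
            identical(sort(names(splines)), sort(names(posteriors))))
  traits <- names(splines)
  vars <- vapply(traits, function(tr) {
    g <- splines[[tr]]
    if (inherits(g, "sensitivity_result")) g <- g$spline
    post <- posteriors[[tr]]
    draws <- if (inherits(post, "trait_posterior")) post$samples
    else if (inherits(post, "trait_prior")) trait_sample(post, n_prior_draws)
    else as.numeric(post)
    if (!length(draws)) stop("empty draw set for trait '", tr, "'",
                             call. = FALSE)
    stats::var(g(draws))
  }, numeric(1))
  tot <- sum(vars)
  rel <- if (tot > 0) vars / tot else rep(NA_real_, length(vars))
  cls <- classification[match(traits, classification$parameter), ]
  cls$competition[is.na(cls$competition)] <- "unclassified"
  cls$organ[is.na(cls$organ)] <- "entire_plant"
  cls$process[is.na(cls$process)] <- "structural"
  tab <- data.frame(trait = traits, variance = unname(vars),
                    rel_var = unname(rel),
                    competition = cls$competition, organ = cls$organ,
                    process = cls$process, stringsAsFactors = FALSE,
                    row.names = NULL)
  agg <- function(by) {
    out <- tapply(tab$rel_var, tab[[by]], sum)
    out[order(-out)]
  }
  structure(list(table = tab[order(-tab$rel_var), ], tot_var = tot,
                 competition = agg("competition"), organ = agg("organ"),
                 process = agg("process")),
            class = "decomposition_table")
}

#' @export
print.decomposition_table <- function(x, ...) {
  cat(sprintf("<decomposition_table> %d traits, total variance %.4g (sd %.4g)\n",
              nrow(x$table), x$tot_var, sqrt(x$tot_var)))
  top <- utils::head(x$table, 5)
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %-20s %5.1f%%\n", top$trait[i], 100 * top$rel_var[i]))
  cat("Competition shares:",
      paste(sprintf("%s %.1f%%", names(x$competition),
                    100 * x$competition), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.decomposition_table <- function(object, ...) {
  list(table = object$table, tot_var = object$tot_var,
       competition = object$competition, organ = object$organ,
       process = object$process)
}

#' @export
plot.decomposition_table <- function(x, ...) {
  tab <- x$table
  graphics::barplot(rev(100 * tab$rel_var), names.arg = rev(tab$trait),
                    horiz = TRUE, las = 1, xlab = "relative variance (%)",
                    ...)
  invisible(x)
}

#' Competition-type shares of the total parametric variance
#'
#' @param x a `decomposition_table`.
#' @return Named vector with the water, light and unclassified shares
#'   (fractions summing to 1).
#' @export
competition_shares <- function(x) {
  stopifnot(inherits(x, "decomposition_table"))
  out <- c(water = 0, light = 0, unclassified = 0)
  out[names(x$competition)] <- x$competition
  out
}
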