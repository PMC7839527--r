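#' The packaged liana prior table
#'
#' Reads the shipped table of the 32 liana parameters: prior family and
#' constants, negation flag, unit scale, tabulated prior/posterior medians
#' and meta-analysis sample sizes.
#'
#' @return A data frame with one row per parameter and a `prior` list column
#'   of [trait_prior] objects.
#' @export
liana_prior_table <- function() {
  path <- system.file("extdata", "liana_priors.csv", package = "lianacomp")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$prior <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    trait_prior(r$name, family_long(r$family), r$a, r$b,
                negate = r$negate, scale = r$scale, units = r$units)
  })
  tab
}

family_long <- function(x) {
  map <- c(unif = "uniform", uniform = "uniform", norm = "normal",
           normal = "normal", lnorm = "lognormal", lognormal = "lognormal",
           gamma = "gamma", beta = "beta", weibull = "weibull")
  out <- unname(map[tolower(x)])
  if (any(is.na(out))) stop("unknown distribution family: ",
                            paste(x[is.na(out)], collapse = ", "),
                            call. = FALSE)
  out
}

#' Parameter classification by competition type, organ and process
#'
#' @return Data frame with columns `parameter`, `competition` (light, water
#'   or unclassified), `organ` and `process`.
#' @export
parameter_classification <- function() {
  utils::read.csv(system.file("extdata", "parameter_classification.csv",
                              package = "lianacomp"),
                  stringsAsFactors = FALSE)
}

# Structural constants shared by every PFT; not part of the 32-trait list.
structural_defaults <- function() {
  list(h_max = 35,      # asymptotic height of the DBH-height curve (m)
       gs_min = 0.01,   # residual stomatal conductance (mol m-2 s-1)
       mort1 = 1)       # amplitude of carbon-starvation mortality (year^-1)
}

#' Construct and validate a PFT parameter set
#'
#' A parameter set is a named list of the 32 liana-analysis traits on the
#' positive storage scale (water potentials are stored positive and negated
#' where used) plus a growth form and structural constants.
#'
#' @param values named list or vector with the 32 trait values.
#' @param growth_form `"liana"` or `"tree"`.
#' @param name label for printing.
#' @param ... overrides for structural constants (`h_max`, `gs_min`, `mort1`).
#' @return An object of class `pft_params` (a named list).
#' @export
pft_parameter_set <- function(values, growth_form = c("liana", "tree"),
                              name = growth_form, ...) {
  growth_form <- match.arg(growth_form)
  values <- as.list(values)
  needed <- parameter_classification()$parameter
  missing <- setdiff(needed, names(values))
  if (length(missing))
    stop("missing parameters: ", paste(missing, collapse = ", "),
         call. = FALSE)
  v <- lapply(values[needed], as.numeric)
  bad <- names(v)[!vapply(v, function(x) is.finite(x) && x >= 0, logical(1))]
  if (length(bad))
    stop("non-finite or negative parameter values: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (v$reproduction_carbon >= 1)
    stop("reproduction_carbon must be < 1", call. = FALSE)
  if (v$growth_respiration >= 1)
    stop("growth_respiration must be < 1", call. = FALSE)
  if (v$root_beta >= 1)
    stop("root_beta must be < 1", call. = FALSE)
  out <- c(v, structural_defaults())
  extra <- list(...)
  out[names(extra)] <- extra
  out$growth_form <- growth_form
  out$name <- name
  class(out) <- "pft_params"
  out
}

#' @export
print.pft_params <- function(x, ...) {
  cat(sprintf("<pft_params> %s (%s form)\n", x$name, x$growth_form))
  cat(sprintf("  V_m0 %.3g, SLA %.3g, K_max %.3g, P50 -%.3g m, rho %.3g\n",
              x$V_m0, x$SLA, x$K_max, x$P50, x$rho))
  invisible(x)
}

#' Packaged liana parameter sets
#'
#' Builds the liana PFT parameter set from the shipped trait table using
#' either the prior medians, the posterior medians from the trait
#' meta-analysis (falling back to the prior median where no observations
#' were available), or the legacy model defaults.
#'
#' @param source `"posterior-median"`, `"prior-median"` or `"default"`.
#' @return A [pft_parameter_set()].
#' @export
liana_parameters <- function(source = c("posterior-median", "prior-median",
                                        "default")) {
  source <- match.arg(source)
  tab <- liana_prior_table()
  vals <- switch(source,
    "prior-median" = tab$prior_median,
    "default" = ifelse(is.na(tab$ed2_default), tab$prior_median,
                       tab$ed2_default),
    "posterior-median" = ifelse(is.na(tab$posterior_median), tab$prior_median,
                                tab$posterior_median))
  names(vals) <- tab$name
  # the liana height asymptote sits above the trees' so the offset
  # allometry can always represent a canopy-topping climber
  pft_parameter_set(vals, growth_form = "liana",
                    name = paste0("liana:", source), h_max = 40)
}

#' Packaged tropical tree parameter sets
#'
#' Early-, mid- and late-successional evergreen tropical tree PFTs. Tree
#' parameters are held fixed throughout the analysis; only liana parameters
#' vary.
#'
#' @param pft `"early"`, `"mid"` or `"late"`.
#' @return A [pft_parameter_set()].
#' @export
tree_parameters <- function(pft = c("early", "mid", "late")) {
  pft <- match.arg(pft)
  tab <- utils::read.csv(system.file("extdata", "tree_pfts.csv",
                                     package = "lianacomp"),
                         stringsAsFactors = FALSE)
  vals <- tab[[pft]]
  names(vals) <- tab$parameter
  pft_parameter_set(vals, growth_form = "tree", name = paste0("tree:", pft))
}

#' The default PFT ensemble: one liana plus three tree PFTs
#'
#' @param liana_source passed to [liana_parameters()].
#' @return Named list of four [pft_parameter_set()] objects
#'   (`liana`, `early`, `mid`, `late`).
#' @export
default_pfts <- function(liana_source = "posterior-median") {
  list(liana = liana_parameters(liana_source),
       early = tree_parameters("early"),
       mid = tree_parameters("mid"),
       late = tree_parameters("late"))
}

#' Replace liana trait values in a PFT ensemble
#'
#' Utility used by the sensitivity and ensemble workflows: returns a copy of
#' `pfts` in which the named liana traits take new storage-scale values.
#'
#' @param pfts a PFT ensemble as returned by [default_pfts()].
#' @param values named numeric vector of storage-scale trait values.
#' @return The modified ensemble.
#' @export
set_liana_traits <- function(pfts, values) {
  stopifnot(is.list(pfts), "liana" %in% names(pfts))
  unknown <- setdiff(names(values), parameter_classification()$parameter)
  if (length(unknown))
    stop("unknown liana traits: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  pfts$liana[names(values)] <- as.list(as.numeric(values))
  pfts
}
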