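#' Allometric biomass pools
#'
#' Power-law allometries on DBH (cm): leaf biomass `Bl = b1Bl * dbh^b2Bl`,
#' structural stem biomass `Bs = b1Bs * dbh^b2Bs`, and fine-root biomass
#' `Br = q * Bl`. All in kg carbon per plant.
#'
#' @param dbh diameter at breast height (cm), strictly positive.
#' @param params a [pft_parameter_set()].
#' @return Biomass (kg_C per plant).
#' @export
leaf_biomass <- function(dbh, params) {
  check_dbh(dbh)
  params$b1Bl * dbh^params$b2Bl
}

#' @rdname leaf_biomass
#' @export
stem_biomass <- function(dbh, params) {
  check_dbh(dbh)
  params$b1Bs * dbh^params$b2Bs
}

#' @rdname leaf_biomass
#' @export
fine_root_biomass <- function(dbh, params) {
  params$q * leaf_biomass(dbh, params)
}

#' @rdname leaf_biomass
#' @export
total_biomass <- function(dbh, params) {
  check_dbh(dbh)
  (1 + params$q) * params$b1Bl * dbh^params$b2Bl +
    params$b1Bs * dbh^params$b2Bs
}

# derivative of total biomass w.r.t. DBH (kg_C / cm)
total_biomass_slope <- function(dbh, params) {
  (1 + params$q) * params$b1Bl * params$b2Bl * dbh^(params$b2Bl - 1) +
    params$b1Bs * params$b2Bs * dbh^(params$b2Bs - 1)
}

# invert total_biomass with vectorized Newton iterations; used so monthly
# diameter growth conserves carbon exactly rather than to first order
dbh_from_total_biomass <- function(btot, dbh0, params) {
  d <- pmax(dbh0, 1e-3)
  for (i in 1:40) {
    f <- total_biomass(d, params) - btot
    step <- f / total_biomass_slope(d, params)
    step <- pmax(pmin(step, 0.5 * d), -0.5 * d)
    d <- d - step
    if (all(abs(f) <= 1e-12 * pmax(btot, 1e-12))) break
  }
  d
}

#' Leaf area per plant
#'
#' `SLA * Bl`, in m2 of one-sided leaf area per plant.
#' @inheritParams leaf_biomass
#' @export
leaf_area_plant <- function(dbh, params) {
  params$SLA * leaf_biomass(dbh, params)
}

check_dbh <- function(dbh) {
  if (any(!is.finite(dbh)) || any(dbh <= 0))
    stop("dbh must be positive and finite", call. = FALSE)
}

#' Height from DBH
#'
#' Saturating exponential height allometry,
#' `h = h_max * (1 - exp(-b1Ht * (dbh + delta_dbh)^b2Ht))`. For lianas the
#' per-cohort offset `delta_dbh` shifts the curve so a climbing cohort's
#' height tracks its host canopy; trees use `delta_dbh = 0`.
#'
#' @param dbh DBH (cm).
#' @param params a [pft_parameter_set()].
#' @param delta_dbh allometric DBH offset (cm); `dbh + delta_dbh` > 0.
#' @return Height (m), bounded above by `params$h_max`.
#' @export
height_from_dbh <- function(dbh, params, delta_dbh = 0) {
  check_dbh(dbh)
  if (any(dbh + delta_dbh <= 0))
    stop("dbh + delta_dbh must be positive", call. = FALSE)
  params$h_max * (1 - exp(-params$b1Ht * (dbh + delta_dbh)^params$b2Ht))
}

#' Inverse height allometry
#'
#' DBH at which the (unshifted) height allometry reaches a given height.
#' Used to refresh the liana DBH offset after the climbing height cap.
#'
#' @param height height (m), must be < `h_max`.
#' @param params a [pft_parameter_set()].
#' @return Allometric DBH (cm).
#' @export
dbh_from_height <- function(height, params) {
  if (any(!is.finite(height)) || any(height <= 0) ||
      any(height >= params$h_max))
    stop("height must lie in (0, h_max)", call. = FALSE)
  (-log(1 - height / params$h_max) / params$b1Ht)^(1 / params$b2Ht)
}

#' Rooting depth from height
#'
#' `depth = -b1Rd * height^b2Rd` (m, negative downward). `b1Rd` is stored
#' positive and negated at use.
#'
#' @param height plant height (m), positive.
#' @param params a [pft_parameter_set()].
#' @return Rooting depth (m, negative).
#' @export
rooting_depth <- function(height, params) {
  if (any(!is.finite(height)) || any(height <= 0))
    stop("height must be positive", call. = FALSE)
  -params$b1Rd * height^params$b2Rd
}

#' Xylem vulnerability curve
#'
#' Weibull-type loss of stem conductivity with water potential,
#' `K(psi) = K_max * exp(-ln(2) * (psi / P50)^K_exp)`, anchored so that
#' `K(0) = K_max` and `K(P50) = K_max / 2`.
#'
#' @param psi stem water potential (m H2O, <= 0).
#' @param params a [pft_parameter_set()] (P50 stored positive).
#' @return Conductivity in the units of `K_max`.
#' @export
stem_conductivity <- function(psi, params) {
  if (any(psi > 0)) stop("psi must be <= 0", call. = FALSE)
  p50 <- -abs(params$P50)
  params$K_max * exp(-log(2) * (psi / p50)^params$K_exp)
}

#' Stomatal drought-stress factor
#'
#' Sigmoidal down-regulation of stomatal opening with leaf water potential:
#' `f = 1 / (1 + (psi_leaf / stoma_psi_b)^stoma_psi_c)`, equal to 1/2 at
#' `stoma_psi_b`, with a hard cut to zero at or below the leaf turgor loss
#' point.
#'
#' @param psi_leaf leaf water potential (m H2O, <= 0).
#' @param params a [pft_parameter_set()] (`stoma_psi_b`, `leaf_TLP` stored
#'   positive).
#' @return Stress factor in \[0, 1\].
#' @export
stomatal_stress <- function(psi_leaf, params) {
  if (any(psi_leaf > 0)) stop("psi_leaf must be <= 0", call. = FALSE)
  b <- -abs(params$stoma_psi_b)
  f <- 1 / (1 + (psi_leaf / b)^params$stoma_psi_c)
  f[psi_leaf <= -abs(params$leaf_TLP)] <- 0
  f
}

#' Leaf-level carbon assimilation
#'
#' Co-limited light/capacity hyperbola for gross assimilation,
#' `A_g = f_sw * (alpha * PAR * V_m) / (alpha * PAR + V_m)`, with leaf dark
#' respiration `R_leaf = dark_respiration * V_m` paid in light and dark.
#' No temperature response is applied; `V_m0` is used as-is and CO2 is held
#' constant.
#'
#' @param par photosynthetically active radiation (umol m-2 s-1, >= 0).
#' @param f_sw soil-water stress factor in \[0, 1\].
#' @param params a [pft_parameter_set()].
#' @return List with `gross` and `net` assimilation (umol_C m-2 s-1) and
#'   `r_leaf`.
#' @export
leaf_assimilation <- function(par, f_sw, params) {
  if (any(par < 0)) stop("par must be >= 0", call. = FALSE)
  alpha <- params$quantum_efficiency
  vm <- params$V_m0
  gross <- f_sw * alpha * par * vm / (alpha * par + vm)
  r_leaf <- params$dark_respiration * vm
  list(gross = gross, net = gross - r_leaf, r_leaf = r_leaf)
}

#' Ball-Berry stomatal conductance
#'
#' `g_s = gs_min + m * max(A_net, 0) * rh / ca`, floored at the residual
#' conductance `gs_min`.
#'
#' @param a_net net assimilation (umol_C m-2 s-1).
#' @param rh relative humidity as a fraction.
#' @param ca atmospheric CO2 mole fraction (ppm), positive.
#' @param params a [pft_parameter_set()].
#' @return Stomatal conductance to water vapour (mol m-2 s-1).
#' @export
stomatal_conductance <- function(a_net, rh, ca, params) {
  if (any(ca <= 0)) stop("ca must be positive", call. = FALSE)
  pmax(params$gs_min,
       params$stomatal_slope * pmax(a_net, 0) * rh / ca + params$gs_min)
}

#' Leaf-to-air vapour mole-fraction deficit
#'
#' Saturation vapour pressure by the Magnus formula, deficit converted to a
#' mole fraction at standard pressure.
#'
#' @param tair air temperature (deg C).
#' @param rh relative humidity fraction in \[0, 1\].
#' @return Mole-fraction deficit (mol/mol).
#' @export
vpd_mole_fraction <- function(tair, rh) {
  esat_kpa <- 0.6108 * exp(17.27 * tair / (tair + 237.3))
  pmax(esat_kpa * (1 - rh), 0) / 101.325
}
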