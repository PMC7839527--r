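#' Plant hydraulic state
#'
#' @param psi_stem,psi_leaf stem and leaf water potentials (m H2O, <= 0).
#' @return Object of class `hydraulic_state` (a list of two numeric
#'   vectors; vectorized over cohorts).
#' @export
hydraulic_state <- function(psi_stem, psi_leaf) {
  if (any(psi_stem > 0) || any(psi_leaf > 0))
    stop("water potentials must be <= 0", call. = FALSE)
  structure(list(psi_stem = as.numeric(psi_stem),
                 psi_leaf = as.numeric(psi_leaf)),
            class = "hydraulic_state")
}

# Conductances of the soil->stem and stem->leaf pathways (kg s-1 per m of
# water-potential difference), vectorized over cohorts.
#
# The sapwood proxy is the mean stem cross-section derived from structural
# biomass and wood density (carbon-to-biomass factor 2, sapwood fraction
# f_sap); the soil->root pathway is additionally throttled by fine-root
# area (SRA * Br) through a saturating availability factor.
hydraulic_conductances <- function(psi_stem, geom, params,
                                   constants = hydro_constants()) {
  k <- stem_conductivity(psi_stem, params)
  a_sap <- constants$f_sap * 2 * geom$bstem / (params$rho * 1000) /
    pmax(geom$height, 0.5)
  g_sl <- k * a_sap / pmax(geom$height, 0.5)
  rai <- params$SRA * geom$broot
  g_sr <- constants$c_sr * g_sl * rai / (rai + constants$rai_half)
  list(g_sr = g_sr, g_sl = g_sl)
}

#' Tunable constants of the hydraulic pathway
#'
#' @param f_sap sapwood fraction of the stem cross-section.
#' @param c_sr ratio of soil-to-root to stem-to-leaf conductance scaling.
#' @param rai_half fine-root area (m2 per plant) at which the root
#'   availability factor reaches one half.
#' @return Named list of constants.
#' @export
hydro_constants <- function(f_sap = 0.3, c_sr = 2, rai_half = 50) {
  list(f_sap = f_sap, c_sr = c_sr, rai_half = rai_half)
}

# Precomputed per-cohort constants of the hydraulic pathway; geometry and
# parameters only change at the monthly demography step.
hydro_cache <- function(geom, params, constants = hydro_constants()) {
  h <- pmax(geom$height, 0.5)
  g_geom <- constants$f_sap * 2 * geom$bstem / (params$rho * 1000) / h^2
  rai <- params$SRA * geom$broot
  list(h = geom$height,
       g_geom = g_geom,
       rf = constants$c_sr * rai / (rai + constants$rai_half),
       c_s = pmax(params$wood_capacitance * 2 * geom$bstem, 1e-9),
       c_l = pmax(params$leaf_capacitance * 2 * geom$bleaf, 1e-9),
       k_max = params$K_max, k_exp = params$K_exp,
       p50 = -abs(params$P50), tlp = -abs(params$leaf_TLP))
}

# One backward-Euler step of the two-compartment storage system; exact
# linear solve with conductances frozen at the entry stem potential, so
# extraction - transpiration = storage change identically.
hydro_core <- function(psi_s, psi_l, psi0, demand, ca, dt, g_sr_mult = 1) {
  g_sl <- ca$k_max * exp(-log(2) * (psi_s / ca$p50)^ca$k_exp) * ca$g_geom
  g_sr <- g_sl * ca$rf * g_sr_mult
  as_ <- dt / ca$c_s
  al_ <- dt / ca$c_l
  a11 <- 1 + as_ * (g_sr + g_sl)
  a12 <- -as_ * g_sl
  a21 <- -al_ * g_sl
  a22 <- 1 + al_ * g_sl
  b1 <- psi_s + as_ * g_sr * psi0 + as_ * g_sl * ca$h
  e <- demand
  b2 <- psi_l - al_ * g_sl * ca$h - al_ * e
  det <- a11 * a22 - a12 * a21
  ps <- (b1 * a22 - a12 * b2) / det
  pl <- (a11 * b2 - a21 * b1) / det
  viol <- pl < ca$tlp & e > 0
  if (any(viol)) {
    ps_c <- (psi_s + as_ * g_sr * psi0 + as_ * g_sl * (ca$tlp + ca$h)) / a11
    e_lim <- g_sl * (ps_c - ca$tlp - ca$h) - (ca$tlp - psi_l) / al_
    e <- ifelse(viol, pmin(pmax(e_lim, 0), demand), e)
    b2 <- psi_l - al_ * g_sl * ca$h - al_ * e
    ps <- (b1 * a22 - a12 * b2) / det
    pl <- (a11 * b2 - a21 * b1) / det
  }
  list(psi_s = pmin(ps, 0), psi_l = pmin(pl, 0),
       transpiration = e * dt,
       extraction = g_sr * (psi0 - ps) * dt)
}

#' One hydraulic sub-step
#'
#' Advances the two-compartment (stem storage, leaf storage) hydraulic
#' system over `dt` seconds given an effective soil water potential and a
#' transpiration demand. Flows are soil->stem
#' `q1 = G_sr * (psi_soil - psi_stem)` and stem->leaf
#' `q2 = G_sl * (psi_stem - psi_leaf - h)` with the gravitational head `h`
#' equal to plant height (potentials in m H2O). The update is an exact
#' backward-Euler solve of the linearized system (conductances frozen at the
#' entry stem potential), which is unconditionally stable and conserves
#' water identically: extraction - transpiration = change in stored water.
#' Realized transpiration is capped so the leaf potential does not fall
#' below the turgor loss point.
#'
#' All arguments are vectorized over cohorts.
#'
#' @param state a [hydraulic_state()].
#' @param soil_psi_eff root-weighted effective soil water potential (m, <= 0).
#' @param demand transpiration demand (kg water per plant per s, >= 0).
#' @param geom list with `height` (m), `bleaf`, `bstem`, `broot` (kg_C).
#' @param params a [pft_parameter_set()].
#' @param dt time step (s), positive.
#' @param constants see [hydro_constants()].
#' @param g_sr_mult multiplier on the soil-to-root conductance (used to
#'   throttle uptake when a soil layer cannot supply the aggregate demand).
#' @return List: updated `state`, `transpiration`, `extraction`,
#'   `storage_change` (kg water per plant over the step).
#' @export
hydraulic_substep <- function(state, soil_psi_eff, demand, geom, params, dt,
                              constants = hydro_constants(), g_sr_mult = 1) {
  if (!all(is.finite(state$psi_stem)) || !all(is.finite(state$psi_leaf)))
    stop("non-finite hydraulic state", call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  psi_s <- state$psi_stem
  psi_l <- state$psi_leaf
  n <- length(psi_s)
  demand <- rep_len(as.numeric(demand), n)
  soil_psi_eff <- rep_len(as.numeric(soil_psi_eff), n)
  geom <- lapply(geom, rep_len, n)
  h <- geom$height
  c_s <- pmax(params$wood_capacitance * 2 * geom$bstem, 1e-9)
  c_l <- pmax(params$leaf_capacitance * 2 * geom$bleaf, 1e-9)
  g_sr_mult <- rep_len(g_sr_mult, n)
  demand <- pmax(demand, 0)
  ca <- hydro_cache(geom, params, constants)

  # automatic sub-stepping for accuracy when dt is much larger than the
  # fastest relaxation time (the implicit solve itself is always stable)
  g0 <- ca$k_max * ca$g_geom
  relax <- pmax(dt * g0 * (1 + ca$rf) / c_s, dt * g0 / c_l)
  n_sub <- min(max(1L, ceiling(max(relax, 0) / 50)), 64L)
  dts <- dt / n_sub

  e_tot <- ex_tot <- numeric(n)
  for (s in seq_len(n_sub)) {
    res <- hydro_core(psi_s, psi_l, soil_psi_eff, demand, ca, dts,
                      g_sr_mult)
    psi_s <- res$psi_s
    psi_l <- res$psi_l
    e_tot <- e_tot + res$transpiration
    ex_tot <- ex_tot + res$extraction
  }
  new_state <- hydraulic_state(psi_s, psi_l)
  storage <- c_s * (psi_s - state$psi_stem) + c_l * (psi_l - state$psi_leaf)
  list(state = new_state, transpiration = e_tot, extraction = ex_tot,
       storage_change = storage)
}
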