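# Per-cohort parameter vectors for a patch: a list shaped like a parameter
# set but with one value per cohort, so the physiology functions vectorize
# across mixed-PFT cohort tables.
param_vectors <- function(pft_names, pfts,
                          fields = c("SLA", "V_m0", "quantum_efficiency",
                                     "dark_respiration", "stomatal_slope",
                                     "gs_min", "stoma_psi_b", "stoma_psi_c",
                                     "leaf_TLP", "K_max", "K_exp", "P50",
                                     "SRA", "rho", "wood_capacitance",
                                     "leaf_capacitance", "root_beta",
                                     "b1Rd", "b2Rd")) {
  out <- lapply(fields, function(f)
    vapply(pft_names, function(p) pfts[[p]][[f]], numeric(1), USE.NAMES = FALSE))
  names(out) <- fields
  out
}

MOL_H2O <- 0.018   # kg water per mol
KGC_PER_UMOL <- 12e-9

# One day of physiology and hydraulics for a single patch.
# Returns the updated patch plus the day's water-budget terms and per-PFT
# fluxes; monthly per-plant accumulators (gpp, rleaf, transpiration) are
# stored in patch$acc.
patch_daily_step <- function(pa, met, pfts, config) {
  soil <- config$soil
  theta <- pa$soil_theta
  theta_start <- theta
  precip <- met$precip_mm

  # interception and infiltration (top-down fill, excess drains)
  interception <- config$interception_frac * precip
  p_eff <- precip - interception
  for (l in seq_len(soil$n_layers)) {
    cap <- (soil$theta_sat - theta[l]) * soil$thickness[l] * 1000
    add <- min(p_eff, cap)
    theta[l] <- theta[l] + add / (1000 * soil$thickness[l])
    p_eff <- p_eff - add
  }
  drainage <- p_eff

  co <- pa$cohorts
  n <- nrow(co)
  extraction_total <- 0
  transp_plant <- numeric(n)
  gpp_plant <- numeric(n)
  if (n > 0) {
    # cohort geometry, parameters, root profiles and the canopy light
    # profile only change at the monthly demography step; cache them
    if (is.null(pa$cache)) {
      pv <- param_vectors(co$pft, pfts)
      la <- pv$SLA * co$bleaf                    # m2 leaf per plant
      lai <- la * co$density                     # m2 m-2 per cohort
      cum_above <- cumsum(c(0, lai[-n]))
      fr <- t(vapply(seq_len(n), function(i)
        root_fractions(rooting_depth(pmax(co$height[i], 0.5),
                                     list(b1Rd = pv$b1Rd[i],
                                          b2Rd = pv$b2Rd[i])),
                       soil, pv$root_beta[i]),
        numeric(soil$n_layers)))
      geom <- list(height = co$height, bleaf = co$bleaf,
                   bstem = co$bstem, broot = co$broot)
      pa$cache <- list(
        pv = pv, la = la, lai = lai, lai_tot = sum(lai), fr = fr,
        light_frac = exp(-config$k_light * (cum_above + 0.5 * lai)),
        geom = geom, hyd = hydro_cache(geom, pv, config$hydro),
        rleaf_day = pv$dark_respiration * pv$V_m0 * la * 86400 *
          KGC_PER_UMOL)
    }
    pv <- pa$cache$pv
    la <- pa$cache$la
    fr <- pa$cache$fr
    hyd <- pa$cache$hyd
    par_i <- met$par * pa$cache$light_frac
    d_mf <- vpd_mole_fraction(met$tair, met$rh)
    psi_s <- co$psi_stem
    psi_l <- co$psi_leaf

    night_s <- 86400 - config$daylength_s
    steps <- c(rep(config$daylength_s / config$n_day_substeps,
                   config$n_day_substeps),
               rep(night_s / config$n_night_substeps,
                   config$n_night_substeps))
    is_day <- c(rep(TRUE, config$n_day_substeps),
                rep(FALSE, config$n_night_substeps))

    for (s in seq_along(steps)) {
      dt <- steps[s]
      psi_lay <- soil_psi(theta, soil)
      psi_eff <- as.numeric(fr %*% psi_lay)
      f_sw <- stomatal_stress(psi_l, pv)
      asm <- leaf_assimilation(if (is_day[s]) par_i else 0, f_sw, pv)
      gs <- stomatal_conductance(asm$net, met$rh, config$ca, pv)
      demand <- 1.6 * gs * d_mf * MOL_H2O * la
      res <- hydro_core(psi_s, psi_l, psi_eff, demand, hyd, dt)
      # throttle roots where a layer cannot supply the aggregate demand
      need_l <- as.numeric(crossprod(fr, co$density * res$extraction))
      avail_l <- pmax(theta - soil$theta_res, 0) * soil$thickness * 1000
      if (any(need_l > avail_l + 1e-12)) {
        scale_l <- ifelse(need_l > 0, pmin(1, avail_l / pmax(need_l, 1e-12)),
                          1)
        r_i <- as.numeric(fr %*% scale_l)
        res <- hydro_core(psi_s, psi_l, psi_eff, demand, hyd, dt,
                          g_sr_mult = r_i)
        w <- fr * rep(scale_l, each = n)
        rs <- rowSums(w)
        w <- w / ifelse(rs > 0, rs, 1)
      } else {
        w <- fr
      }
      take_l <- as.numeric(crossprod(w, co$density * res$extraction))
      theta <- theta - take_l / (1000 * soil$thickness)
      extraction_total <- extraction_total + sum(take_l)
      psi_s <- res$psi_s
      psi_l <- res$psi_l
      transp_plant <- transp_plant + res$transpiration
      if (is_day[s])
        gpp_plant <- gpp_plant + asm$gross * la * dt * KGC_PER_UMOL
    }
    co$psi_stem <- psi_s
    co$psi_leaf <- psi_l
    pa$cohorts <- co
    pa$acc$gpp <- pa$acc$gpp + gpp_plant
    pa$acc$rleaf <- pa$acc$rleaf + pa$cache$rleaf_day
    pa$acc$transp <- pa$acc$transp + transp_plant
    lai_tot <- pa$cache$lai_tot
  } else {
    lai_tot <- 0
  }

  # soil evaporation from the top layer, shaded by the canopy
  wet <- max((theta[1] - soil$theta_res) / (soil$theta_sat - soil$theta_res),
             0)
  pot <- config$soil_evap_max * exp(-config$k_light * lai_tot) * wet *
    (met$par > 0)
  soil_evap <- min(pot, max(theta[1] - soil$theta_res, 0) *
                     soil$thickness[1] * 1000)
  theta[1] <- theta[1] - soil_evap / (1000 * soil$thickness[1])

  pa$soil_theta <- theta
  d_theta <- sum((theta - theta_start) * soil$thickness) * 1000
  residual <- precip - interception - drainage - soil_evap -
    extraction_total - d_theta
  pa$day <- list(
    interception = interception, drainage = drainage, soil_evap = soil_evap,
    extraction = extraction_total, precip = precip,
    residual_rel = abs(residual) / max(precip, extraction_total, 1))
  pa
}

#' One daily simulation step
#'
#' Runs light competition (Beer-Lambert profile through the height-ordered
#' cohorts), leaf assimilation with stomatal drought down-regulation,
#' hydraulic transport with layered root water uptake, and the soil water
#' bucket (interception, infiltration, drainage, soil evaporation) for
#' every patch.
#'
#' @param forest a `liana_forest`.
#' @param met one-row list/data.frame with `precip_mm`, `par`, `tair`, `rh`.
#' @return The updated forest; per-patch daily water terms are in
#'   `patch$day` and monthly per-plant accumulators in `patch$acc`.
#' @export
daily_step <- function(forest, met) {
  if (any(!is.finite(c(met$precip_mm, met$par, met$tair, met$rh))))
    stop("non-finite meteorological forcing", call. = FALSE)
  forest$patches <- lapply(forest$patches, function(pa) {
    if (is.null(pa$acc))
      pa$acc <- list(gpp = numeric(nrow(pa$cohorts)),
                     rleaf = numeric(nrow(pa$cohorts)),
                     transp = numeric(nrow(pa$cohorts)), ndays = 0)
    pa <- patch_daily_step(pa, met, forest$pfts, forest$config)
    pa$acc$ndays <- pa$acc$ndays + 1
    pa
  })
  forest
}

#' Monthly demography: allocation, growth, mortality, recruitment
#'
#' Closes each cohort's monthly carbon balance
#' `CB = GPP - R_leaf - R_root - R_growth`, pays tissue turnover (from
#' storage, shedding leaves and fine roots when storage is exhausted),
#' routes a `reproduction_carbon` fraction of the surplus to a recruit pool
#' and converts the remainder into diameter growth by inverting the total
#' biomass allometry (carbon-exact). Trees take their height from
#' allometry; lianas compute a potential height from their offset allometry
#' which is then capped at the patch's tallest tree height plus `h_offset`,
#' updating the DBH offset. Mortality combines a density-independent rate
#' with a carbon-starvation logistic on the trailing 12-month carbon-balance
#' ratio. Recruit pools above the seed threshold spawn 1-cm cohorts.
#'
#' @param forest a `liana_forest` with accumulated daily fluxes.
#' @param days_in_month days accumulated in the closing month.
#' @return The updated forest. Per-patch monthly per-PFT summaries are left
#'   in `patch$month` (GPP, NPP, autotrophic respiration, carbon residual).
#' @export
monthly_demography <- function(forest, days_in_month = NULL) {
  pfts <- forest$pfts
  config <- forest$config
  forest$patches <- lapply(forest$patches, function(pa) {
    co <- pa$cohorts
    n <- nrow(co)
    if (n == 0 || is.null(pa$acc) || pa$acc$ndays == 0) {
      pa$month <- NULL
      return(pa)
    }
    ndays <- if (is.null(days_in_month)) pa$acc$ndays else days_in_month
    sec <- ndays * 86400
    pv <- param_vectors(co$pft, pfts,
                        fields = c("root_respiration", "growth_respiration",
                                   "leaf_turnover", "root_turnover",
                                   "reproduction_carbon", "mort1", "mort2",
                                   "mort3", "b1Bl", "b2Bl", "b1Bs", "b2Bs",
                                   "q", "b1Ht", "b2Ht", "h_max"))
    gpp <- pa$acc$gpp
    rleaf <- pa$acc$rleaf
    rroot <- pv$root_respiration * co$broot * sec * KGC_PER_UMOL
    cb_pre <- gpp - rleaf - rroot
    rg <- pv$growth_respiration * pmax(cb_pre, 0)
    cb <- cb_pre - rg
    turn <- (pv$leaf_turnover * co$bleaf + pv$root_turnover * co$broot) / 12

    pools0 <- co$bleaf + co$bstem + co$broot + co$bstorage
    rem <- cb - turn
    repro <- numeric(n)
    turn_eff <- turn

    # deficit branch: draw storage, then shed canopy/fine roots
    neg <- which(rem < 0)
    for (i in neg) {
      use <- min(co$bstorage[i], -rem[i])
      co$bstorage[i] <- co$bstorage[i] - use
      still <- -rem[i] - use
      if (still > 0) {
        shedable <- 0.999 * (co$bleaf[i] + co$broot[i])
        shed <- min(still, shedable)
        frac <- shed / (co$bleaf[i] + co$broot[i])
        co$bleaf[i] <- co$bleaf[i] * (1 - frac)
        co$broot[i] <- co$broot[i] * (1 - frac)
        unpaid <- still - shed
        turn_eff[i] <- turn[i] - unpaid  # tissue simply not replaced
      }
    }

    # surplus branch: refill pools toward allometric targets, then
    # reproduction and carbon-exact diameter growth
    pos <- which(rem > 0)
    if (length(pos)) {
      for (i in pos) {
        p <- pfts[[co$pft[i]]]
        target <- total_biomass(co$dbh[i], p)
        pools_now <- co$bleaf[i] + co$bstem[i] + co$broot[i]
        deficit <- max(target - pools_now, 0)
        refill <- min(rem[i], deficit)
        if (refill > 0 && pools_now > 0) {
          co$bleaf[i] <- co$bleaf[i] + refill * co$bleaf[i] / pools_now
          co$bstem[i] <- co$bstem[i] + refill * co$bstem[i] / pools_now
          co$broot[i] <- co$broot[i] + refill * co$broot[i] / pools_now
        }
        surplus <- rem[i] - refill
        if (surplus > 0) {
          rp <- pv$reproduction_carbon[i] * surplus
          repro[i] <- rp
          growth <- surplus - rp
          new_total <- pools_now + refill + growth
          d_new <- dbh_from_total_biomass(new_total, co$dbh[i], p)
          co$dbh[i] <- d_new
          co$bleaf[i] <- leaf_biomass(d_new, p)
          co$bstem[i] <- stem_biomass(d_new, p)
          co$broot[i] <- fine_root_biomass(d_new, p)
        }
      }
    }

    # carbon closure per cohort-month
    pools1 <- co$bleaf + co$bstem + co$broot + co$bstorage
    residual <- gpp - (rleaf + rroot + rg + turn_eff + repro +
                         (pools1 - pools0))
    carbon_residual_rel <- max(abs(residual) / pmax(gpp, 1e-9))

    # carbon-balance ratio and mortality
    ratio <- ifelse(turn > 0, pmin(pmax(cb / turn, 0), 1),
                    as.numeric(cb >= 0))
    pa$cb <- cbind(pa$cb[, -1, drop = FALSE], ratio)
    cbbar <- rowMeans(pa$cb)
    rate <- pv$mort3 + pv$mort1 / (1 + exp(pv$mort2 * cbbar))
    co$density <- co$density * exp(-rate / 12)

    # heights: trees from allometry, lianas capped by the climbing rule
    is_tree <- vapply(co$pft, function(p) pfts[[p]]$growth_form == "tree",
                      logical(1))
    for (i in which(is_tree)) {
      co$height[i] <- height_from_dbh(co$dbh[i], pfts[[co$pft[i]]])
    }
    h_top <- if (any(is_tree)) max(co$height[is_tree]) else -Inf
    for (i in which(!is_tree)) {
      p <- pfts[[co$pft[i]]]
      h_pot <- height_from_dbh(co$dbh[i], p, co$delta_dbh[i])
      cap <- h_top + config$h_offset
      if (is.finite(h_top) && h_pot > cap) {
        co$height[i] <- cap
        co$delta_dbh[i] <-
          dbh_from_height(min(cap, p$h_max * (1 - 1e-9)), p) - co$dbh[i]
      } else {
        co$height[i] <- h_pot
      }
    }

    # recruitment into a per-PFT seed pool (kg_C m-2)
    if (length(pa$recruit) == 0)
      pa$recruit <- stats::setNames(numeric(length(pfts)), names(pfts))
    add <- tapply(repro * co$density, co$pft, sum)
    pa$recruit[names(add)] <- pa$recruit[names(add)] + add
    new_rows <- NULL
    for (pft in names(pa$recruit)) {
      if (pa$recruit[pft] >= config$seed_threshold) {
        p <- pfts[[pft]]
        dens <- pa$recruit[pft] / total_biomass(1, p)
        psi0 <- sum(root_fractions(1, config$soil, 0) *
                      soil_psi(pa$soil_theta, config$soil))
        new_rows <- rbind(new_rows, new_cohort_df(
          pft = pft, density = dens, dbh = 1, delta_dbh = 0,
          height = height_from_dbh(1, p), bleaf = leaf_biomass(1, p),
          bstem = stem_biomass(1, p), broot = fine_root_biomass(1, p),
          bstorage = 0, psi_stem = min(psi0, 0),
          psi_leaf = min(psi0, 0) - height_from_dbh(1, p)))
        pa$recruit[pft] <- 0
      }
    }
    if (!is.null(new_rows)) {
      co <- rbind(co, new_rows)
      pa$cb <- rbind(pa$cb, matrix(1, nrow(new_rows), 12))
    }

    # drop vanishing cohorts, keep the canopy ordering
    keep <- co$density > config$density_floor
    co <- co[keep, , drop = FALSE]
    pa$cb <- pa$cb[keep, , drop = FALSE]
    ord <- order(-co$height)
    co <- co[ord, , drop = FALSE]
    rownames(co) <- NULL
    pa$cb <- pa$cb[ord, , drop = FALSE]

    # per-PFT monthly summary (per m2 ground) before resetting accumulators
    dens0 <- pa$cohorts$density  # densities before this month's mortality
    pftv <- pa$cohorts$pft
    agg <- function(x) tapply(x * dens0, pftv, sum)
    pa$month <- list(
      gpp = agg(gpp), npp = agg(cb),
      resp = agg(rleaf + rroot + rg),
      transp = agg(pa$acc$transp),
      carbon_residual_rel = carbon_residual_rel,
      ndays = ndays)
    pa$cohorts <- co
    pa$acc <- NULL
    pa$cache <- NULL
    pa
  })
  forest
}

#' Run the coupled simulation
#'
#' Interleaves [daily_step()] over the meteorological series with
#' [monthly_demography()] at each month boundary, for `years` years
#' (the forcing is recycled when shorter). Deterministic given its inputs.
#'
#' @param forest a `liana_forest`.
#' @param met daily forcing data frame with columns `date`, `precip_mm`,
#'   `par`, `tair`, `rh`.
#' @param years simulation horizon in years.
#' @param seed integer; retained in the result for provenance (the core is
#'   deterministic).
#' @return Object of class `liana_sim`: monthly per-PFT flux table,
#'   site water/ET terms, closure diagnostics, initial and final forest.
#' @export
run_simulation <- function(forest, met, years = 5, seed = 1L) {
  stopifnot(inherits(forest, "liana_forest"))
  req <- c("date", "precip_mm", "par", "tair", "rh")
  miss <- setdiff(req, names(met))
  if (length(miss)) stop("met lacks columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  n_days <- round(years * 365.25)
  idx <- rep_len(seq_len(nrow(met)), n_days)
  mkeys <- format(as.Date(met$date), "%Y-%m")

  fluxes <- list()
  site <- list()
  diag <- list(max_water_residual = 0, max_carbon_residual = 0,
               height_cap_violations = 0L)
  forest0 <- forest
  cur_month <- mkeys[idx[1]]
  month_counter <- 0L
  day_in_month <- 0L
  acc_site <- c(precip = 0, interception = 0, drainage = 0, soil_evap = 0,
                extraction = 0)

  close_month <- function(forest, ndays) {
    forest <- monthly_demography(forest, ndays)
    month_counter <<- month_counter + 1L
    w <- vapply(forest$patches, function(p) p$area_weight, numeric(1))
    pft_names <- names(forest$pfts)
    sum_pft <- function(field) {
      vapply(pft_names, function(pf) {
        sum(vapply(seq_along(forest$patches), function(i) {
          m <- forest$patches[[i]]$month
          if (is.null(m) || is.na(m[[field]][pf])) 0
          else w[i] * m[[field]][pf]
        }, numeric(1)))
      }, numeric(1))
    }
    gpp <- sum_pft("gpp"); npp <- sum_pft("npp")
    resp <- sum_pft("resp"); transp <- sum_pft("transp")
    lai <- agb <- stats::setNames(numeric(length(pft_names)), pft_names)
    for (i in seq_along(forest$patches)) {
      co <- forest$patches[[i]]$cohorts
      if (nrow(co)) {
        sla <- vapply(co$pft, function(p) forest$pfts[[p]]$SLA, numeric(1))
        l <- tapply(sla * co$bleaf * co$density, co$pft, sum)
        a <- tapply((co$bleaf + co$bstem + co$bstorage) * co$density,
                    co$pft, sum)
        lai[names(l)] <- lai[names(l)] + w[i] * l
        agb[names(a)] <- agb[names(a)] + w[i] * a
      }
      cr <- forest$patches[[i]]$month$carbon_residual_rel
      if (!is.null(cr))
        diag$max_carbon_residual <<- max(diag$max_carbon_residual, cr)
      # climbing invariant audit
      pa <- forest$patches[[i]]
      ht <- tallest_tree_height(pa, forest$pfts)
      if (is.finite(ht) && nrow(pa$cohorts)) {
        li <- vapply(pa$cohorts$pft,
                     function(p) forest$pfts[[p]]$growth_form == "liana",
                     logical(1))
        over <- pa$cohorts$height[li] >
          ht + forest$config$h_offset + 1e-9
        diag$height_cap_violations <<-
          diag$height_cap_violations + sum(over)
      }
    }
    fluxes[[month_counter]] <<- data.frame(
      month = month_counter, pft = pft_names, gpp = unname(gpp),
      npp = unname(npp), resp_auto = unname(resp),
      transpiration = unname(transp) / ndays,
      lai = unname(lai), agb = unname(agb), stringsAsFactors = FALSE)
    site[[month_counter]] <<- data.frame(
      month = month_counter, ndays = ndays, precip = acc_site[["precip"]],
      interception = acc_site[["interception"]],
      drainage = acc_site[["drainage"]],
      soil_evap = acc_site[["soil_evap"]],
      extraction = acc_site[["extraction"]])
    acc_site[] <<- 0
    forest
  }

  met_v <- list(precip_mm = met$precip_mm, par = met$par, tair = met$tair,
                rh = met$rh)
  for (k in seq_len(n_days)) {
    j <- idx[k]
    row <- list(precip_mm = met_v$precip_mm[j], par = met_v$par[j],
                tair = met_v$tair[j], rh = met_v$rh[j])
    m <- mkeys[j]
    if (m != cur_month && day_in_month > 0) {
      forest <- close_month(forest, day_in_month)
      cur_month <- m
      day_in_month <- 0L
    }
    forest <- daily_step(forest, row)
    day_in_month <- day_in_month + 1L
    w <- vapply(forest$patches, function(p) p$area_weight, numeric(1))
    for (i in seq_along(forest$patches)) {
      d <- forest$patches[[i]]$day
      diag$max_water_residual <- max(diag$max_water_residual, d$residual_rel)
      acc_site <- acc_site + w[i] * c(d$precip, d$interception, d$drainage,
                                      d$soil_evap, d$extraction)
    }
  }
  if (day_in_month > 0) forest <- close_month(forest, day_in_month)

  structure(list(fluxes = do.call(rbind, fluxes),
                 site = do.call(rbind, site),
                 diagnostics = diag, forest_init = forest0,
                 forest_final = forest, years = years, seed = seed),
            class = "liana_sim")
}

#' Monthly flux table of a simulation
#'
#' @param sim a `liana_sim`.
#' @return Data frame of monthly per-PFT fluxes (kg_C m-2 month-1 for GPP,
#'   NPP and respiration; kg_w m-2 day-1 for transpiration; LAI m2 m-2;
#'   AGB kg_C m-2).
#' @export
fluxes <- function(sim) {
  stopifnot(inherits(sim, "liana_sim"))
  sim$fluxes
}

#' Liana share of an ecosystem flux
#'
#' Fraction of a monthly flux contributed by the liana PFT; months with a
#' non-positive ecosystem total are returned as `NA`.
#'
#' @param sim a `liana_sim` (or its flux table).
#' @param variable flux column, e.g. `"gpp"`.
#' @return Numeric vector over months, in \[0, 1\].
#' @export
liana_share <- function(sim, variable = "gpp") {
  fl <- if (inherits(sim, "liana_sim")) sim$fluxes else sim
  stopifnot(variable %in% names(fl))
  months <- sort(unique(fl$month))
  vapply(months, function(m) {
    sub <- fl[fl$month == m, ]
    tot <- sum(sub[[variable]])
    if (tot <= 0) return(NA_real_)
    sum(sub[[variable]][sub$pft == "liana"]) / tot
  }, numeric(1))
}

#' @export
print.liana_sim <- function(x, ...) {
  ny <- x$years
  gpp <- sum(x$fluxes$gpp)
  cat(sprintf("<liana_sim> %g years, %d monthly records\n", ny,
              max(x$fluxes$month)))
  cat(sprintf("  mean ecosystem GPP %.2f kg_C m-2 yr-1; liana share %.1f%%\n",
              gpp / ny, 100 * mean(liana_share(x), na.rm = TRUE)))
  cat(sprintf("  max water residual %.2e, max carbon residual %.2e\n",
              x$diagnostics$max_water_residual,
              x$diagnostics$max_carbon_residual))
  invisible(x)
}

#' @export
summary.liana_sim <- function(object, ...) {
  fl <- object$fluxes
  out <- do.call(rbind, lapply(split(fl, fl$pft), function(s)
    data.frame(pft = s$pft[1], gpp_kgC_m2_yr = sum(s$gpp) / object$years,
               npp_kgC_m2_yr = sum(s$npp) / object$years,
               mean_lai = mean(s$lai), final_agb = s$agb[nrow(s)])))
  rownames(out) <- NULL
  out
}

#' @export
plot.liana_sim <- function(x, variable = "gpp", ...) {
  fl <- x$fluxes
  pfts <- unique(fl$pft)
  cols <- grDevices::hcl.colors(length(pfts), "Dark 3")
  graphics::matplot(
    sapply(pfts, function(p) fl[[variable]][fl$pft == p]),
    type = "l", lty = 1, col = cols, xlab = "month",
    ylab = variable, ...)
  graphics::legend("topright", legend = pfts, col = cols, lty = 1, bty = "n")
  invisible(x)
}
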