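#' Soil column configuration
#'
#' Layered bucket with Clapp-Hornberger water retention,
#' `psi = psi_sat * (theta / theta_sat)^(-b)`. Defaults describe a
#' clay-loam; interfaces in metres below the surface.
#'
#' @param interfaces layer interface depths (m, increasing, starting above
#'   the first interface at 0).
#' @param theta_sat,theta_res saturated and residual volumetric water
#'   content (m3/m3).
#' @param psi_sat air-entry water potential (m H2O, negative).
#' @param b_ret retention-curve exponent.
#' @return List of class `soil_config` including layer thicknesses.
#' @export
soil_config <- function(interfaces = c(0.05, 0.15, 0.3, 0.5, 0.75, 1, 2, 4, 8),
                        theta_sat = 0.45, theta_res = 0.08,
                        psi_sat = -0.35, b_ret = 6.5) {
  stopifnot(all(diff(interfaces) > 0), interfaces[1] > 0,
            theta_res < theta_sat, psi_sat < 0, b_ret > 0)
  bounds <- c(0, interfaces)
  structure(list(interfaces = interfaces,
                 lower = interfaces, upper = bounds[-length(bounds)],
                 thickness = diff(bounds),
                 n_layers = length(interfaces),
                 theta_sat = theta_sat, theta_res = theta_res,
                 psi_sat = psi_sat, b_ret = b_ret),
            class = "soil_config")
}

# matric potential (m) of each layer
soil_psi <- function(theta, soil) {
  soil$psi_sat * (pmax(theta, 1e-4) / soil$theta_sat)^(-soil$b_ret)
}

# fraction of a cohort's fine roots in each soil layer: (1 - root_beta)
# uniform over [0, rooting depth], root_beta spread uniformly over the
# layers below, capped at the column bottom
root_fractions <- function(depth, soil, root_beta) {
  zr <- min(abs(depth), max(soil$lower))
  in_zone <- pmax(pmin(soil$lower, zr) - soil$upper, 0)
  f_main <- in_zone / sum(in_zone)
  below <- pmax(pmin(soil$lower, max(soil$lower)) -
                  pmax(soil$upper, zr), 0)
  if (sum(below) > 0) {
    f_below <- below / sum(below)
    (1 - root_beta) * f_main + root_beta * f_below
  } else {
    f_main
  }
}

#' Simulation configuration defaults
#'
#' Every named physical or numerical constant of the simulator in one
#' place; all overridable.
#'
#' @param patch_area patch footprint used to convert stems to densities (m2).
#' @param h_offset maximum height a liana may overtop the tallest tree (m).
#' @param dbh_threshold liana DBH (cm) above which a cohort is assumed
#'   canopy-reaching at initialization.
#' @param wd_cuts wood-density cut points (g cm-3) separating early/mid/late
#'   tree PFTs.
#' @param k_light Beer-Lambert canopy extinction coefficient.
#' @param ca atmospheric CO2 (ppm), held fixed.
#' @param interception_frac fraction of daily precipitation intercepted and
#'   evaporated by the canopy.
#' @param soil_evap_max potential soil evaporation (kg m-2 day-1) under an
#'   open canopy.
#' @param n_day_substeps,n_night_substeps hydraulic sub-steps per daytime
#'   and nighttime period.
#' @param daylength_s daytime duration (s).
#' @param seed_threshold recruit-pool size (kg_C m-2) that triggers a new
#'   cohort at 1 cm DBH.
#' @param density_floor cohorts below this stem density (m-2) are dropped.
#' @param dbh_bins DBH bin edges (cm) used to merge inventory stems into
#'   cohorts.
#' @param hydro constants of the hydraulic pathway, see [hydro_constants()].
#' @param soil a [soil_config()].
#' @return Named list of class `sim_config`.
#' @export
sim_config <- function(patch_area = 400, h_offset = 0.5, dbh_threshold = 3,
                       wd_cuts = c(0.53, 0.71), k_light = 0.5, ca = 370,
                       interception_frac = 0.1, soil_evap_max = 3,
                       n_day_substeps = 6L, n_night_substeps = 2L,
                       daylength_s = 43200,
                       seed_threshold = 0.02, density_floor = 1e-8,
                       dbh_bins = c(1, 2, 3, 5, 7.5, 10, 15, 20, 30, 45, 65,
                                    100, 200),
                       hydro = hydro_constants(), soil = soil_config()) {
  structure(list(patch_area = patch_area, h_offset = h_offset,
                 dbh_threshold = dbh_threshold, wd_cuts = wd_cuts,
                 k_light = k_light, ca = ca,
                 interception_frac = interception_frac,
                 soil_evap_max = soil_evap_max,
                 n_day_substeps = as.integer(n_day_substeps),
                 n_night_substeps = as.integer(n_night_substeps),
                 daylength_s = daylength_s,
                 seed_threshold = seed_threshold,
                 density_floor = density_floor, dbh_bins = dbh_bins,
                 hydro = hydro, soil = soil),
            class = "sim_config")
}

new_cohort_df <- function(pft = character(), density = numeric(),
                          dbh = numeric(), delta_dbh = numeric(),
                          height = numeric(), bleaf = numeric(),
                          bstem = numeric(), broot = numeric(),
                          bstorage = numeric(), psi_stem = numeric(),
                          psi_leaf = numeric()) {
  data.frame(pft = pft, density = density, dbh = dbh, delta_dbh = delta_dbh,
             height = height, bleaf = bleaf, bstem = bstem, broot = broot,
             bstorage = bstorage, psi_stem = psi_stem, psi_leaf = psi_leaf,
             stringsAsFactors = FALSE)
}

new_patch <- function(id, area_weight, cohorts, soil_theta, age = NA_real_) {
  list(id = id, area_weight = area_weight, age = age,
       cohorts = cohorts,
       cb = matrix(1, nrow = nrow(cohorts), ncol = 12),
       recruit = numeric(0),
       soil_theta = soil_theta)
}

#' Tallest tree height within a patch
#'
#' @param patch a patch element of a [initialize_from_inventory()] forest.
#' @param pfts the forest's PFT parameter list.
#' @return Height (m) of the tallest tree cohort, or `-Inf` when the patch
#'   holds no trees.
#' @export
tallest_tree_height <- function(patch, pfts) {
  co <- patch$cohorts
  is_tree <- vapply(co$pft, function(p) pfts[[p]]$growth_form == "tree",
                    logical(1))
  if (!any(is_tree)) return(-Inf)
  max(co$height[is_tree])
}

#' Initialize a forest from an inventory table
#'
#' Builds the demographic state from stem records. Trees are assigned to
#' the early/mid/late PFT by wood density; stems of one PFT within a DBH bin
#' are merged into cohorts (density-weighted mean DBH). Tree heights follow
#' the height allometry. Liana cohorts at or above the canopy-reaching DBH
#' threshold are placed just above the tallest tree of their patch
#' (`h_offset`), and their DBH offset is recorded as the difference between
#' the allometric DBH at that height and the actual DBH; smaller lianas
#' follow their own allometry. Biomass pools are allometric; soil starts
#' near saturation; plant water potentials start in equilibrium with the
#' soil.
#'
#' @param inventory data frame with columns `patch_id`, `stem_id`,
#'   `growth_form` (`"tree"`/`"liana"`), `dbh_cm`, `wood_density_g_cm3`
#'   (trees), `density_multiplier` (stems represented per record).
#' @param pfts PFT list as from [default_pfts()].
#' @param config a [sim_config()].
#' @return Object of class `liana_forest`.
#' @export
initialize_from_inventory <- function(inventory, pfts, config = sim_config()) {
  req <- c("patch_id", "growth_form", "dbh_cm")
  miss <- setdiff(req, names(inventory))
  if (length(miss)) stop("inventory lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(!is.finite(inventory$dbh_cm)) || any(inventory$dbh_cm <= 0))
    stop("all stems must have positive DBH", call. = FALSE)
  if (!all(inventory$growth_form %in% c("tree", "liana")))
    stop("growth_form must be 'tree' or 'liana'", call. = FALSE)
  if (is.null(inventory$density_multiplier))
    inventory$density_multiplier <- 1
  soil <- config$soil
  theta0 <- rep(0.95 * soil$theta_sat, soil$n_layers)
  patch_ids <- sort(unique(inventory$patch_id))
  w <- 1 / length(patch_ids)

  inventory$pft <- ifelse(
    inventory$growth_form == "liana", "liana",
    c("early", "mid", "late")[1 +
        findInterval(ifelse(is.na(inventory$wood_density_g_cm3), 0.6,
                            inventory$wood_density_g_cm3), config$wd_cuts)])

  patches <- lapply(patch_ids, function(pid) {
    inv <- inventory[inventory$patch_id == pid, ]
    inv$bin <- findInterval(inv$dbh_cm, config$dbh_bins)
    agg_key <- interaction(inv$pft, inv$bin, drop = TRUE)
    dens <- tapply(inv$density_multiplier, agg_key, sum) / config$patch_area
    dbh <- tapply(inv$density_multiplier * inv$dbh_cm, agg_key, sum) /
      tapply(inv$density_multiplier, agg_key, sum)
    pft <- tapply(inv$pft, agg_key, function(x) x[1])
    co <- new_cohort_df(pft = as.character(pft), density = as.numeric(dens),
                        dbh = as.numeric(dbh),
                        delta_dbh = 0, height = NA_real_,
                        bleaf = NA_real_, bstem = NA_real_, broot = NA_real_,
                        bstorage = 0, psi_stem = NA_real_,
                        psi_leaf = NA_real_)
    for (i in seq_len(nrow(co))) {
      p <- pfts[[co$pft[i]]]
      co$height[i] <- height_from_dbh(co$dbh[i], p)
      co$bleaf[i] <- leaf_biomass(co$dbh[i], p)
      co$bstem[i] <- stem_biomass(co$dbh[i], p)
      co$broot[i] <- fine_root_biomass(co$dbh[i], p)
    }
    # climbing rule: canopy-reaching lianas sit just above the tallest tree
    is_tree <- vapply(co$pft, function(x) pfts[[x]]$growth_form == "tree",
                      logical(1))
    h_top <- if (any(is_tree)) max(co$height[is_tree]) else -Inf
    for (i in which(!is_tree)) {
      p <- pfts[[co$pft[i]]]
      if (co$dbh[i] >= config$dbh_threshold) {
        if (is.finite(h_top)) {
          h <- h_top + config$h_offset
          co$height[i] <- h
          co$delta_dbh[i] <-
            dbh_from_height(min(h, p$h_max * (1 - 1e-9)), p) - co$dbh[i]
        } else {
          warning("patch ", pid, ": canopy-reaching liana without any tree; ",
                  "height cap inactive", call. = FALSE)
        }
      }
    }
    psi0 <- sum(root_fractions(1, soil, 0) * soil_psi(theta0, soil))
    co$psi_stem <- psi0
    co$psi_leaf <- psi0 - co$height
    co <- co[order(-co$height), ]
    rownames(co) <- NULL
    new_patch(pid, w, co, theta0)
  })
  structure(list(patches = patches, pfts = pfts, config = config),
            class = "liana_forest")
}

#' Remove all liana cohorts from a forest
#'
#' The no-liana scenario: deletes liana cohorts from every patch and leaves
#' everything else untouched. Idempotent.
#'
#' @param forest a `liana_forest`.
#' @return The forest without lianas.
#' @export
remove_lianas <- function(forest) {
  stopifnot(inherits(forest, "liana_forest"))
  forest$patches <- lapply(forest$patches, function(pa) {
    keep <- vapply(pa$cohorts$pft,
                   function(p) forest$pfts[[p]]$growth_form == "tree",
                   logical(1))
    pa$cohorts <- pa$cohorts[keep, , drop = FALSE]
    rownames(pa$cohorts) <- NULL
    pa$cb <- pa$cb[keep, , drop = FALSE]
    pa$cache <- NULL
    pa$acc <- NULL
    pa
  })
  forest
}

#' @export
print.liana_forest <- function(x, ...) {
  nco <- vapply(x$patches, function(p) nrow(p$cohorts), integer(1))
  cat(sprintf("<liana_forest> %d patches, %d cohorts\n",
              length(x$patches), sum(nco)))
  invisible(x)
}

#' @export
summary.liana_forest <- function(object, ...) {
  rows <- do.call(rbind, lapply(object$patches, function(pa) {
    co <- pa$cohorts
    data.frame(patch = pa$id, pft = co$pft,
               density_ha = co$density * 1e4, dbh = co$dbh,
               height = co$height, stringsAsFactors = FALSE)
  }))
  agg <- stats::aggregate(density_ha ~ pft, rows, sum)
  agg$density_ha <- agg$density_ha / length(object$patches)
  cat("Mean stem density by PFT (ha^-1):\n")
  print(agg, row.names = FALSE)
  invisible(rows)
}
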