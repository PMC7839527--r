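#' Site templates for the two emulated forests
#'
#' Aggregate features of the two seasonally contrasting neotropical sites
#' the generators emulate: a drier, strongly seasonal, liana-rich site
#' ("bci") and a wetter site with a short dry season and fewer lianas
#' ("paracou"). All quantities are site-level means used as generator
#' targets, not data.
#'
#' @param name `"bci"` or `"paracou"`.
#' @param n_patches,patch_area desk-scale patch grid (count, m2).
#' @return Object of class `site_template`.
#' @export
site_template <- function(name = c("bci", "paracou"), n_patches = 10,
                          patch_area = 400) {
  name <- match.arg(name)
  base <- list(n_patches = n_patches, patch_area = patch_area,
               tree_dbh_range = c(10, 150))
  tpl <- if (name == "bci") {
    c(base, list(
      name = "bci", annual_precip = 2640, annual_precip_sd = 94,
      strong_dry_months = 1:3, dry_months = 4L,
      mean_temp = 25.6,
      liana_density_ha = 1428.9, liana_dbh_range = c(1, 15),
      tree_density_ha = 416.0, tree_basal_area = 26.7,
      liana_basal_area = 1.01))
  } else {
    c(base, list(
      name = "paracou", annual_precip = 3088, annual_precip_sd = 117,
      strong_dry_months = c(9L, 10L), dry_months = c(8L, 11L),
      mean_temp = 26.0,
      liana_density_ha = 126.3, liana_dbh_range = c(2, 15),
      tree_density_ha = 319.4, tree_basal_area = 19.2,
      liana_basal_area = 0.34))
  }
  stopifnot(all(tpl$strong_dry_months %in% 1:12),
            all(tpl$dry_months %in% 1:12),
            tpl$liana_density_ha >= 0, tpl$tree_density_ha >= 0)
  structure(tpl, class = "site_template")
}

#' @export
print.site_template <- function(x, ...) {
  cat(sprintf("<site_template> %s: %g mm yr-1, dry months %s, lianas %g ha-1\n",
              x$name, x$annual_precip,
              paste(sort(c(x$strong_dry_months, x$dry_months)),
                    collapse = ","),
              x$liana_density_ha))
  invisible(x)
}

# monthly rainfall targets (mm): strong-dry months ~45, dry ~80, wet months
# share the remaining annual total with a smooth seasonal shape and a floor
# keeping them safely above the dry threshold
monthly_precip_targets <- function(template, annual_total) {
  m <- 1:12
  target <- rep(NA_real_, 12)
  target[template$strong_dry_months] <- 45
  target[template$dry_months] <- 80
  wet <- which(is.na(target))
  remaining <- annual_total - sum(target, na.rm = TRUE)
  # distance (in months, circular) from the dry season centre shapes the wet
  # season peak
  centre <- mean(c(template$strong_dry_months))
  d <- pmin(abs(m[wet] - centre), 12 - abs(m[wet] - centre))
  w <- 0.5 + d / max(d)
  target[wet] <- pmax(remaining * w / sum(w), 120)
  target <- target * c(rep(1, 12))
  # rescale the wet months so the annual total is exact
  target[wet] <- target[wet] *
    (annual_total - sum(target[-wet])) / sum(target[wet])
  if (any(target[wet] < 100))
    stop("infeasible template: wet-month targets fall below 100 mm",
         call. = FALSE)
  target
}

#' Generate daily meteorological forcing
#'
#' Seasonal rainfall honouring the template's dry-season definition
#' (strong-dry months below 60 mm, dry months below 100 mm, wet months
#' above 100 mm, annual totals drawn around the template mean), realized
#' as wet/dry day sequences from a first-order chain with gamma rain
#' amounts rescaled to exact monthly totals. PAR, air temperature and
#' relative humidity carry a mild anti-correlated seasonality.
#'
#' @param template a [site_template()].
#' @param years number of years.
#' @param seed integer seed.
#' @return Daily data frame: `date`, `precip_mm`, `par` (daytime mean,
#'   umol m-2 s-1), `tair` (deg C), `rh` (fraction).
#' @export
generate_met <- function(template, years = 5, seed = 1L) {
  stopifnot(inherits(template, "site_template"), years >= 1)
  set.seed(seed)
  days <- seq(as.Date("2004-01-01"), by = "day",
              length.out = round(years * 365.25))
  mon <- as.integer(format(days, "%m"))
  yr <- as.integer(format(days, "%Y"))
  out <- data.frame(date = days, precip_mm = 0, par = 0, tair = 0, rh = 0)
  dryish <- c(template$strong_dry_months, template$dry_months)
  for (y in unique(yr)) {
    annual <- stats::rnorm(1, template$annual_precip,
                           template$annual_precip_sd)
    targets <- monthly_precip_targets(template, annual)
    for (m in 1:12) {
      sel <- which(yr == y & mon == m)
      if (!length(sel)) next
      nd <- length(sel)
      p_wet <- min(0.9, max(0.15, targets[m] / 300))
      wet <- stats::runif(nd) < p_wet
      if (!any(wet)) wet[sample(nd, 1)] <- TRUE
      amt <- numeric(nd)
      amt[wet] <- stats::rgamma(sum(wet), shape = 0.8, rate = 0.08)
      amt <- amt * targets[m] / sum(amt)
      out$precip_mm[sel] <- amt
      seas <- if (m %in% dryish) 1.15 else 1
      out$par[sel] <- pmax(stats::rnorm(nd, 430 * seas, 40), 100)
      out$tair[sel] <- stats::rnorm(nd, template$mean_temp +
                                      (seas - 1) * 5, 0.8)
      out$rh[sel] <- pmin(pmax(stats::rnorm(
        nd, if (m %in% dryish) 0.72 else 0.86, 0.04), 0.35), 0.98)
    }
  }
  out
}

# inverse-CDF of a truncated power law f(d) ~ d^-alpha on [lo, hi]
qtrunc_powerlaw <- function(p, alpha, lo, hi) {
  if (abs(alpha - 1) < 1e-9) {
    lo * (hi / lo)^p
  } else {
    a1 <- 1 - alpha
    (lo^a1 + p * (hi^a1 - lo^a1))^(1 / a1)
  }
}

# exponent of the truncated power law whose mean squared diameter matches
# the target basal area per stem (two-moment matching)
powerlaw_exponent_for_ba <- function(mean_d2, lo, hi) {
  f <- function(alpha) {
    p <- seq(0.0005, 0.9995, length.out = 2000)
    mean(qtrunc_powerlaw(p, alpha, lo, hi)^2) - mean_d2
  }
  stats::uniroot(f, c(1.01, 6))$root
}

#' Generate a synthetic forest inventory
#'
#' Emulates the statistical structure of the study sites: tree DBHs from a
#' truncated power law whose exponent is solved so stem density and basal
#' area jointly match the template (stratified quantile placement keeps
#' site-level moments tight); wood densities populating all three tree
#' PFTs; and patch-level liana loading from a right-skewed lognormal
#' multiplier (normalized to mean one across patches) spanning near-liana-
#' free to heavily infested patches.
#'
#' @param template a [site_template()].
#' @param seed integer seed.
#' @return Inventory data frame (`patch_id`, `stem_id`, `growth_form`,
#'   `dbh_cm`, `wood_density_g_cm3`, `density_multiplier`).
#' @export
generate_inventory <- function(template, seed = 1L) {
  stopifnot(inherits(template, "site_template"))
  set.seed(seed)
  np <- template$n_patches
  area_ha <- template$patch_area / 1e4
  lo <- template$tree_dbh_range[1]; hi <- template$tree_dbh_range[2]
  # basal area per stem (cm2): BA[m2/ha] / density[1/ha] * 1e4
  mean_d2 <- template$tree_basal_area / template$tree_density_ha * 1e4 /
    (pi / 4)
  alpha <- powerlaw_exponent_for_ba(mean_d2, lo, hi)

  n_trees_site <- round(template$tree_density_ha * area_ha * np)
  # stratified quantiles with a small jitter: tight site-level moments,
  # patch-level variety through random assignment
  p <- (seq_len(n_trees_site) - stats::runif(n_trees_site)) / n_trees_site
  tree_dbh <- qtrunc_powerlaw(sample(p), alpha, lo, hi)
  tree_patch <- rep_len(sample(np), n_trees_site)
  wd_class <- sample(c("early", "mid", "late"), n_trees_site, replace = TRUE,
                     prob = c(0.35, 0.40, 0.25))
  wd <- ifelse(wd_class == "early", stats::runif(n_trees_site, 0.30, 0.52),
        ifelse(wd_class == "mid", stats::runif(n_trees_site, 0.54, 0.70),
               stats::runif(n_trees_site, 0.72, 0.92)))

  inv_tree <- data.frame(patch_id = tree_patch,
                         growth_form = "tree", dbh_cm = tree_dbh,
                         wood_density_g_cm3 = wd,
                         density_multiplier = 1)

  inv_liana <- NULL
  if (template$liana_density_ha > 0) {
    mult <- stats::rlnorm(np, meanlog = -0.5 * 1.1^2, sdlog = 1.1)
    mult <- mult / mean(mult)  # exact site-mean loading
    n_li <- round(template$liana_density_ha * area_ha * mult)
    llo <- template$liana_dbh_range[1]; lhi <- template$liana_dbh_range[2]
    inv_liana <- do.call(rbind, lapply(seq_len(np), function(pid) {
      if (n_li[pid] == 0) return(NULL)
      pq <- (seq_len(n_li[pid]) - stats::runif(n_li[pid])) / n_li[pid]
      data.frame(patch_id = pid, growth_form = "liana",
                 dbh_cm = qtrunc_powerlaw(pq, 2.3, llo, lhi),
                 wood_density_g_cm3 = NA_real_,
                 density_multiplier = 1)
    }))
  }
  inv <- rbind(inv_tree, inv_liana)
  inv <- inv[order(inv$patch_id), ]
  inv$stem_id <- seq_len(nrow(inv))
  rownames(inv) <- NULL
  inv[, c("patch_id", "stem_id", "growth_form", "dbh_cm",
          "wood_density_g_cm3", "density_multiplier")]
}

#' Extrapolate small-tree density classes
#'
#' Fills missing 1-10 cm DBH classes by ordinary least squares on the
#' log-log relation between DBH class midpoint and stem density fitted to
#' the observed classes at or above 10 cm, optionally splitting the
#' predictions across tree PFTs by their observed relative frequency.
#'
#' @param density_by_class data frame with `dbh_mid` (cm) and `density`
#'   (stems per ha) for observed classes (>= 10 cm used for the fit).
#' @param new_mids class midpoints to fill (default 1-9 cm).
#' @param pft_freq optional named frequencies used to split predictions.
#' @return The input table with predicted classes appended (`source`
#'   column distinguishes observed from extrapolated; per-PFT columns when
#'   `pft_freq` is given) plus the fitted `slope`/`intercept` attributes.
#' @export
extrapolate_small_trees <- function(density_by_class, new_mids = 1:9,
                                    pft_freq = NULL) {
  obs <- density_by_class[density_by_class$dbh_mid >= 10 &
                            density_by_class$density > 0, ]
  if (nrow(obs) < 2)
    stop("need at least 2 observed classes at or above 10 cm", call. = FALSE)
  fit <- stats::lm(log(density) ~ log(dbh_mid), data = obs)
  pred <- exp(stats::predict(fit, data.frame(dbh_mid = new_mids)))
  out <- rbind(
    data.frame(dbh_mid = density_by_class$dbh_mid,
               density = density_by_class$density, source = "observed"),
    data.frame(dbh_mid = new_mids, density = pred, source = "extrapolated"))
  if (!is.null(pft_freq)) {
    freq <- pft_freq / sum(pft_freq)
    for (p in names(freq)) out[[paste0("density_", p)]] <- out$density * freq[[p]]
  }
  out <- out[order(out$dbh_mid), ]
  rownames(out) <- NULL
  attr(out, "slope") <- unname(stats::coef(fit)[2])
  attr(out, "intercept") <- unname(stats::coef(fit)[1])
  out
}

#' Generate a synthetic trait observation dataset
#'
#' Hierarchical truth: study means drawn around a known true across-study
#' mean with between-study spread, observed means around their study mean
#' with within-study spread, and standard errors
#' `within_sd / sqrt(per_study_n)`. Feeds the meta-analysis calibration
#' experiments.
#'
#' @param trait trait name.
#' @param true_mean the known across-study mean.
#' @param between_sd,within_sd between- and within-study standard
#'   deviations (>= 0).
#' @param n_studies number of studies.
#' @param obs_per_study mean observations per study.
#' @param per_study_n sample size behind each observed mean.
#' @param seed integer seed.
#' @return Observation data frame (`trait`, `mean`, `se`, `n`, `study_id`,
#'   `site_id`).
#' @export
generate_trait_dataset <- function(trait, true_mean, between_sd, within_sd,
                                   n_studies = 5, obs_per_study = 5,
                                   per_study_n = 10, seed = 1L) {
  stopifnot(between_sd >= 0, within_sd >= 0, n_studies >= 1,
            obs_per_study >= 1)
  set.seed(seed)
  study_means <- stats::rnorm(n_studies, true_mean, between_sd)
  do.call(rbind, lapply(seq_len(n_studies), function(j) {
    k <- obs_per_study
    data.frame(trait = trait,
               mean = stats::rnorm(k, study_means[j], within_sd),
               se = rep(within_sd / sqrt(per_study_n), k),
               n = rep(per_study_n, k),
               study_id = sprintf("study_%02d", j),
               site_id = sprintf("site_%02d", 1 + (j - 1) %% 3))
  }))
}

#' Build a ready-to-run synthetic forest
#'
#' Convenience wrapper chaining [generate_inventory()] and
#' [initialize_from_inventory()] for a site template.
#'
#' @param template a [site_template()].
#' @param pfts PFT list, see [default_pfts()].
#' @param config a [sim_config()] (its `patch_area` is taken from the
#'   template).
#' @param seed integer seed.
#' @return A `liana_forest`.
#' @export
synthetic_forest <- function(template, pfts = default_pfts(),
                             config = sim_config(), seed = 1L) {
  config$patch_area <- template$patch_area
  inv <- generate_inventory(template, seed = seed)
  initialize_from_inventory(inv, pfts, config)
}
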