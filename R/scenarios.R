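#' Dry-season masks from monthly rainfall
#'
#' A month is dry when its rainfall is below 100 mm and strongly dry below
#' 60 mm (the strong-dry months are a subset of the dry ones).
#'
#' @param monthly_precip numeric vector of monthly rainfall totals (mm), or
#'   a daily met data frame with `date` and `precip_mm` (aggregated here).
#' @param dry_mm,strong_mm classification thresholds (mm).
#' @return List with logical vectors `dry` and `strong_dry` and the
#'   monthly totals used.
#' @export
dry_season_mask <- function(monthly_precip, dry_mm = 100, strong_mm = 60) {
  if (is.data.frame(monthly_precip)) {
    key <- format(as.Date(monthly_precip$date), "%Y-%m")
    monthly_precip <- as.numeric(
      tapply(monthly_precip$precip_mm, key, sum)[unique(key)])
  }
  if (any(!is.finite(monthly_precip)) || any(monthly_precip < 0))
    stop("monthly precipitation must be finite and non-negative",
         call. = FALSE)
  list(dry = monthly_precip < dry_mm,
       strong_dry = monthly_precip < strong_mm,
       monthly_precip = monthly_precip)
}

#' Young-patch selection
#'
#' Ranks patches by three age proxies and relaxes thresholds from the
#' extremes until at least `min_count` patches qualify: highest initial
#' liana stem density, lowest share of late-successional trees, and lowest
#' patch (tallest-cohort) height. At each relaxation step a patch
#' qualifies when it passes all three thresholds.
#'
#' @param forest a `liana_forest`.
#' @param min_count minimum number of patches to select.
#' @return List with `ids` of the selected patches and the `metrics` table.
#' @export
select_young_patches <- function(forest, min_count = 1) {
  stopifnot(inherits(forest, "liana_forest"))
  n <- length(forest$patches)
  if (min_count > n)
    stop("min_count (", min_count, ") exceeds patch count (", n, ")",
         call. = FALSE)
  metrics <- do.call(rbind, lapply(forest$patches, function(pa) {
    co <- pa$cohorts
    gf <- vapply(co$pft, function(p) forest$pfts[[p]]$growth_form,
                 character(1))
    tree_d <- sum(co$density[gf == "tree"])
    data.frame(
      id = pa$id,
      liana_density = sum(co$density[gf == "liana"]),
      late_share = if (tree_d > 0)
        sum(co$density[co$pft == "late"]) / tree_d else 0,
      height = if (nrow(co)) max(co$height) else 0)
  }))
  for (q in seq(0, 1, by = 0.02)) {
    sel <- metrics$liana_density >=
             stats::quantile(metrics$liana_density, 1 - q) &
           metrics$late_share <= stats::quantile(metrics$late_share, q) &
           metrics$height <= stats::quantile(metrics$height, q)
    if (sum(sel) >= min_count) break
  }
  list(ids = metrics$id[sel], metrics = metrics)
}

#' Restrict a forest to a subset of patches
#'
#' Keeps the named patches and renormalizes their area weights; used to
#' run the uncertainty analysis on young patches only.
#'
#' @param forest a `liana_forest`.
#' @param ids patch ids to keep.
#' @return The reduced forest.
#' @export
subset_patches <- function(forest, ids) {
  stopifnot(inherits(forest, "liana_forest"))
  keep <- vapply(forest$patches, function(p) p$id %in% ids, logical(1))
  if (!any(keep)) stop("no patches match the requested ids", call. = FALSE)
  forest$patches <- forest$patches[keep]
  w <- vapply(forest$patches, function(p) p$area_weight, numeric(1))
  forest$patches <- lapply(forest$patches, function(p) {
    p$area_weight <- p$area_weight / sum(w)
    p
  })
  forest
}

#' Seasonal aggregate of a monthly flux series
#'
#' @param sim a `liana_sim`.
#' @param mask logical vector over the simulation's months (recycled), e.g.
#'   a dry-season mask.
#' @param variable flux column.
#' @param pft PFT name, or `"ecosystem"` for the total.
#' @return Mean monthly value of the flux over the masked months.
#' @export
masked_flux_mean <- function(sim, mask, variable = "gpp",
                             pft = "ecosystem") {
  fl <- fluxes(sim)
  months <- sort(unique(fl$month))
  mask <- rep_len(mask, length(months))
  per_month <- vapply(months, function(m) {
    sub <- fl[fl$month == m, ]
    if (pft == "ecosystem") sum(sub[[variable]])
    else sum(sub[[variable]][sub$pft == pft])
  }, numeric(1))
  mean(per_month[mask])
}
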