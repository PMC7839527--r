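test_that("generated rainfall honours the site dry-season structure", {
  for (seed in c(1, 7)) {
    tpl <- site_template("bci")
    met <- generate_met(tpl, years = 3, seed = seed)
    key <- format(met$date, "%Y")
    annual <- tapply(met$precip_mm, key, sum)
    expect_true(all(abs(annual - 2640) <= 3 * 94))
    monthly <- tapply(met$precip_mm,
                      format(met$date, "%Y-%m"), sum)
    mon <- as.integer(substr(names(monthly), 6, 7))
    expect_true(all(monthly[mon %in% 1:3] < 60))
    expect_true(all(monthly[mon == 4] < 100))
    expect_true(all(monthly[!(mon %in% 1:4)] >= 100))
    # exactly three strong-dry months per year
    expect_equal(sum(monthly < 60) / 3, 3)
  }
})

test_that("the wetter site has its short dry season in boreal autumn", {
  tpl <- site_template("paracou")
  met <- generate_met(tpl, years = 2, seed = 5)
  monthly <- tapply(met$precip_mm, format(met$date, "%Y-%m"), sum)
  mon <- as.integer(substr(names(monthly), 6, 7))
  expect_true(all(monthly[mon %in% c(9, 10)] < 60))
  expect_true(all(monthly[mon %in% c(8, 11)] < 100))
  expect_true(all(monthly[mon %in% c(1:7, 12)] >= 100))
  # the two templates differ in the directions the analysis exploits
  bci <- site_template("bci")
  expect_lt(bci$annual_precip, tpl$annual_precip)
  expect_gt(bci$liana_density_ha, tpl$liana_density_ha)
})

test_that("met generation is deterministic per seed", {
  tpl <- site_template("bci")
  expect_identical(generate_met(tpl, 1, seed = 4),
                   generate_met(tpl, 1, seed = 4))
  expect_false(identical(generate_met(tpl, 1, seed = 4)$precip_mm,
                         generate_met(tpl, 1, seed = 5)$precip_mm))
})

test_that("inventories hit the template density and basal-area targets", {
  tpl <- site_template("bci", n_patches = 10)
  inv <- generate_inventory(tpl, seed = 2)
  area_ha <- tpl$n_patches * tpl$patch_area / 1e4
  liana_dens <- sum(inv$growth_form == "liana") / area_ha
  expect_lt(abs(liana_dens - 1428.9) / 1428.9, 0.1)
  trees <- inv[inv$growth_form == "tree", ]
  tree_dens <- nrow(trees) / area_ha
  expect_lt(abs(tree_dens - 416) / 416, 0.1)
  ba <- sum(pi / 4 * (trees$dbh_cm / 100)^2) / area_ha
  expect_lt(abs(ba - 26.7) / 26.7, 0.1)
  # all three tree PFT wood-density classes are populated
  wd <- trees$wood_density_g_cm3
  expect_true(any(wd < 0.53) && any(wd >= 0.53 & wd < 0.71) &&
                any(wd >= 0.71))
  # patch-level liana loading is heterogeneous and right-skewed
  per_patch <- table(factor(inv$patch_id[inv$growth_form == "liana"],
                            levels = 1:10))
  expect_gt(max(per_patch) / max(mean(per_patch), 1), 1.5)
})

test_that("a liana-free template yields a tree-only inventory", {
  tpl <- site_template("paracou")
  tpl$liana_density_ha <- 0
  inv <- generate_inventory(tpl, seed = 3)
  expect_true(all(inv$growth_form == "tree"))
})

test_that("small-tree extrapolation continues the size distribution", {
  mids <- c(12.5, 17.5, 25, 35, 50)
  exact <- data.frame(dbh_mid = mids, density = 5000 * mids^-2)
  out <- extrapolate_small_trees(exact, new_mids = c(2, 5, 8))
  pred <- out$density[out$source == "extrapolated"]
  expect_equal(pred, 5000 * c(2, 5, 8)^-2, tolerance = 1e-9)
  expect_equal(attr(out, "slope"), -2, tolerance = 1e-9)

  set.seed(9)
  noisy <- data.frame(dbh_mid = mids,
                      density = 5000 * mids^-2 * exp(rnorm(5, 0, 0.1)))
  outn <- extrapolate_small_trees(noisy)
  expect_lt(abs(attr(outn, "slope") + 2), 0.2)

  one <- data.frame(dbh_mid = 20, density = 10)
  expect_error(extrapolate_small_trees(one), "at least 2")

  # predictions split across PFTs by relative frequency
  outf <- extrapolate_small_trees(exact, new_mids = 5,
                                  pft_freq = c(early = 3, mid = 1))
  row <- outf[outf$source == "extrapolated", ]
  expect_equal(row$density_early, 0.75 * row$density)
})

test_that("trait datasets reduce to the truth without noise and are reproducible", {
  zero <- generate_trait_dataset("SLA", 20, 0, 0, n_studies = 3,
                                 obs_per_study = 4, seed = 1)
  expect_true(all(zero$mean == 20))
  a <- generate_trait_dataset("SLA", 20, 2, 1, seed = 8)
  b <- generate_trait_dataset("SLA", 20, 2, 1, seed = 8)
  expect_identical(a, b)
  expect_equal(length(unique(a$study_id)), 5)
  expect_true(all(a$se == 1 / sqrt(10)))
})
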