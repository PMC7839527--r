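pfts <- default_pfts()

toy_inventory <- function(liana_dbh = 10, tree_dbh = c(40, 25)) {
  rbind(
    data.frame(patch_id = 1, stem_id = seq_along(tree_dbh),
               growth_form = "tree", dbh_cm = tree_dbh,
               wood_density_g_cm3 = c(0.45, 0.65)[seq_along(tree_dbh)],
               density_multiplier = 1),
    if (!is.null(liana_dbh))
      data.frame(patch_id = 1, stem_id = 100 + seq_along(liana_dbh),
                 growth_form = "liana", dbh_cm = liana_dbh,
                 wood_density_g_cm3 = NA, density_multiplier = 1))
}

test_that("canopy-reaching lianas sit h_offset above the tallest tree", {
  cfg <- sim_config(patch_area = 400, h_offset = 0.5)
  f <- initialize_from_inventory(toy_inventory(liana_dbh = 10), pfts, cfg)
  co <- f$patches[[1]]$cohorts
  li <- co[co$pft == "liana", ]
  h_top <- max(co$height[co$pft != "liana"])
  expect_equal(li$height, h_top + 0.5, tolerance = 1e-9)
  # the DBH offset records the deviation from the prescribed allometry
  expect_equal(height_from_dbh(li$dbh, pfts$liana, li$delta_dbh),
               h_top + 0.5, tolerance = 1e-6)
  expect_gt(li$delta_dbh, 0)
})

test_that("small lianas below the DBH threshold follow their own allometry", {
  cfg <- sim_config(patch_area = 400, dbh_threshold = 3)
  f <- initialize_from_inventory(toy_inventory(liana_dbh = 2), pfts, cfg)
  li <- f$patches[[1]]$cohorts
  li <- li[li$pft == "liana", ]
  expect_equal(li$delta_dbh, 0)
  expect_equal(li$height, height_from_dbh(2, pfts$liana), tolerance = 1e-9)
})

test_that("a canopy liana with no host tree keeps its allometry with a warning", {
  inv <- data.frame(patch_id = 1, stem_id = 1, growth_form = "liana",
                    dbh_cm = 10, wood_density_g_cm3 = NA,
                    density_multiplier = 1)
  expect_warning(f <- initialize_from_inventory(inv, pfts, sim_config()),
                 "cap inactive")
  co <- f$patches[[1]]$cohorts
  expect_equal(co$height, height_from_dbh(10, pfts$liana), tolerance = 1e-9)
})

test_that("trees are classified into PFTs by wood density cut points", {
  inv <- data.frame(patch_id = 1, stem_id = 1:3, growth_form = "tree",
                    dbh_cm = c(20, 20, 20),
                    wood_density_g_cm3 = c(0.4, 0.6, 0.8),
                    density_multiplier = 1)
  f <- initialize_from_inventory(inv, pfts, sim_config())
  expect_setequal(f$patches[[1]]$cohorts$pft, c("early", "mid", "late"))
})

test_that("inventory merging conserves stem density", {
  tpl <- site_template("bci", n_patches = 3)
  inv <- generate_inventory(tpl, seed = 5)
  f <- initialize_from_inventory(inv, pfts,
                                 sim_config(patch_area = tpl$patch_area))
  dens_in <- nrow(inv) / (3 * tpl$patch_area)
  dens_out <- mean(vapply(f$patches,
                          function(p) sum(p$cohorts$density), numeric(1)))
  expect_equal(dens_out, dens_in, tolerance = 1e-9)
  # cohorts are ordered canopy-first
  for (p in f$patches) expect_true(all(diff(p$cohorts$height) <= 0))
  expect_equal(sum(vapply(f$patches, function(p) p$area_weight,
                          numeric(1))), 1)
})

test_that("remove_lianas deletes lianas only and is idempotent", {
  f <- mini_forest()
  n_tree <- sum(vapply(f$patches, function(p)
    sum(p$cohorts$pft != "liana"), integer(1)))
  f1 <- remove_lianas(f)
  expect_equal(sum(vapply(f1$patches, function(p)
    sum(p$cohorts$pft == "liana"), integer(1))), 0)
  expect_equal(sum(vapply(f1$patches, function(p)
    nrow(p$cohorts), integer(1))), n_tree)
  f2 <- remove_lianas(f1)
  expect_identical(f2$patches, f1$patches)
  # a liana-free forest is untouched
  expect_identical(remove_lianas(f1)$patches, f1$patches)
})

test_that("invalid inventories are rejected", {
  inv <- toy_inventory()
  inv$dbh_cm[1] <- -3
  expect_error(initialize_from_inventory(inv, pfts, sim_config()),
               "positive DBH")
  inv2 <- toy_inventory()
  inv2$growth_form[1] <- "shrub"
  expect_error(initialize_from_inventory(inv2, pfts, sim_config()),
               "growth_form")
})
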