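# Shared fixtures, built once per test run. The seasonally dry, liana-rich
# site fixture (10 patches, 5 years) backs the conservation, climbing and
# liana-removal suites; it is cached because several files interrogate the
# same pair of runs.
fixture_env <- new.env(parent = emptyenv())

bci_fixture <- function() {
  if (is.null(fixture_env$bci)) {
    tpl <- site_template("bci", n_patches = 10)
    inv <- generate_inventory(tpl, seed = 101)
    met <- generate_met(tpl, years = 5, seed = 202)
    forest <- initialize_from_inventory(
      inv, default_pfts(), sim_config(patch_area = tpl$patch_area))
    sim <- run_simulation(forest, met, years = 5, seed = 1)
    sim_noliana <- run_simulation(remove_lianas(forest), met, years = 5,
                                  seed = 1)
    fixture_env$bci <- list(template = tpl, inventory = inv, met = met,
                            forest = forest, sim = sim,
                            sim_noliana = sim_noliana)
  }
  fixture_env$bci
}

# a small two-patch forest for fast unit checks
mini_forest <- function(seed = 11) {
  tpl <- site_template("bci", n_patches = 2)
  inv <- generate_inventory(tpl, seed = seed)
  initialize_from_inventory(inv, default_pfts(),
                            sim_config(patch_area = tpl$patch_area))
}

# agreement with a printed table value at its printed decimal precision
expect_printed <- function(computed, printed) {
  s <- format(printed, scientific = FALSE, trim = TRUE)
  d <- if (grepl("\\.", s)) nchar(sub(".*\\.", "", s)) else 0
  expect_lt(abs(computed - printed), 0.51 * 10^(-d))
}
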