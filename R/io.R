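# strict column validation shared by the readers; reports 1-based data row
# numbers (header excluded) for offending values
check_columns <- function(tab, spec, path) {
  miss <- setdiff(names(spec), names(tab))
  if (length(miss))
    stop(basename(path), ": missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in names(spec)) {
    rule <- spec[[col]]
    x <- tab[[col]]
    bad <- which(!rule$ok(x))
    if (length(bad))
      stop(basename(path), ": invalid '", col, "' at row ", bad[1],
           " (", rule$msg, ")", call. = FALSE)
  }
  tab
}

finite_pos <- function(strict = TRUE) {
  list(ok = function(x) is.finite(x) & (if (strict) x > 0 else x >= 0),
       msg = if (strict) "must be a positive number"
             else "must be a non-negative number")
}

#' Read and write the comma-delimited file dialects
#'
#' Inventory tables, daily meteorological series and trait observation
#' tables travel as plain comma-separated text with ISO-8601 dates.
#' Readers validate strictly and report the offending field and row.
#'
#' @param path file path.
#' @return The validated data frame.
#' @export
read_inventory <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(tab, list(
    patch_id = list(ok = function(x) !is.na(x), msg = "must not be missing"),
    growth_form = list(ok = function(x) x %in% c("tree", "liana"),
                       msg = "must be 'tree' or 'liana'"),
    dbh_cm = finite_pos(),
    density_multiplier = finite_pos()), path)
}

#' @rdname read_inventory
#' @param inventory inventory table.
#' @export
write_inventory <- function(inventory, path) {
  utils::write.csv(inventory, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_inventory
#' @export
read_met <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- check_columns(tab, list(
    date = list(ok = function(x) !is.na(as.Date(x, optional = TRUE)),
                msg = "must be an ISO-8601 date"),
    precip_mm = finite_pos(strict = FALSE),
    par = finite_pos(strict = FALSE),
    tair = list(ok = is.finite, msg = "must be a finite temperature"),
    rh = list(ok = function(x) is.finite(x) & x >= 0 & x <= 1,
              msg = "must be a fraction in [0, 1]")), path)
  tab$date <- as.Date(tab$date)
  tab
}

#' @rdname read_inventory
#' @param met daily met table.
#' @export
write_met <- function(met, path) {
  met$date <- format(as.Date(met$date), "%Y-%m-%d")
  utils::write.csv(met, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_inventory
#' @export
read_trait_observations <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(tab, list(
    trait = list(ok = function(x) !is.na(x) & nzchar(x),
                 msg = "must be a trait name"),
    mean = list(ok = is.finite, msg = "must be a finite number"),
    study_id = list(ok = function(x) !is.na(x), msg = "must not be missing")),
    path)
}

#' @rdname read_inventory
#' @param obs trait observation table.
#' @export
write_trait_observations <- function(obs, path) {
  utils::write.csv(obs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Structured configuration shared by the pipeline stages, read from JSON
#' or YAML by extension. Unknown keys are rejected; defaults fill the rest
#' and the resolved configuration is written beside outputs by
#' [write_results()].
#'
#' @param path configuration file (`.json`, `.yml`/`.yaml`).
#' @return Named list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- default_run_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, raw)
  cfg$defaults_applied <- setdiff(names(defaults), names(raw))
  class(cfg) <- "run_config"
  cfg
}

#' @rdname load_config
#' @export
default_run_config <- function() {
  list(site = "bci", years = 5, seed = 1L, ensemble_n = 250,
       sensitivity_output = "liana_gpp",
       dry_season_only = FALSE, young_patches_only = FALSE,
       no_lianas = FALSE, parameter_set = "posterior-median",
       n_patches = 10, patch_area = 400, h_offset = 0.5,
       dbh_threshold = 3, k_light = 0.5, ca = 370)
}

#' Write result objects with a reproducibility manifest
#'
#' Writes each data frame as CSV and each other object as JSON, then a
#' `manifest.json` with file checksums, the seed, package version and the
#' resolved configuration, sufficient to re-run the analysis exactly.
#'
#' @param dir output directory (created).
#' @param objects named list of result objects.
#' @param seed the run seed.
#' @param config optional resolved configuration list.
#' @return Invisibly, the manifest list.
#' @export
write_results <- function(dir, objects, seed = NA_integer_, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(objects)) {
    obj <- objects[[nm]]
    if (is.data.frame(obj)) {
      f <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(obj, f, row.names = FALSE)
    } else {
      f <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA,
                           force = TRUE, pretty = TRUE)
    }
    files <- c(files, f)
  }
  manifest <- list(
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))),
    seed = seed,
    package_version = as.character(utils::packageVersion("lianacomp")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
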