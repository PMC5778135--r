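# Text-based serialization: gridded fields as self-describing JSON
# rasters, tables as UTF-8 CSV, configuration as YAML, bundle manifests
# as JSON with checksums.  All numeric payloads round-trip bit-exactly
# (17 significant digits).

FULL_PRECISION <- I(17)

#' Write a gridded field to a JSON raster file
#'
#' Self-describing: cell-centre `lat`/`lon` coordinate vectors, mandatory
#' `units`, land `mask` and the value matrix at full precision.
#'
#' @param field a `gridded_field`.
#' @param path output path.
#' @param meta optional named list stored under `meta` (e.g. config hash,
#'   seed, package version).
#' @return `path`, invisibly.
#' @export
write_gridded <- function(field, path, meta = NULL) {
  stopifnot(inherits(field, "gridded_field"))
  payload <- list(units = field$units, lat = field$grid$lat,
                  lon = field$grid$lon,
                  resolution = field$grid$resolution,
                  mask = field$mask, values = field$values)
  if (!is.null(meta)) payload$meta <- meta
  writeLines(jsonlite::toJSON(payload, digits = FULL_PRECISION,
                              auto_unbox = TRUE), path, useBytes = TRUE)
  invisible(path)
}

#' Read a gridded field from a JSON raster file
#'
#' Validates the mandatory units attribute and coordinate monotonicity;
#' a south-up (descending-latitude) file is reoriented north-up with
#' values preserved.
#'
#' @param path file written by [write_gridded()].
#' @return a `gridded_field`.
#' @export
read_gridded <- function(path) {
  p <- jsonlite::fromJSON(path)
  if (is.null(p$units) || !nzchar(p$units))
    stop("format error in ", path, ": missing 'units' attribute")
  lat <- as.numeric(p$lat); lon <- as.numeric(p$lon)
  vals <- as.matrix(p$values); mask <- matrix(as.logical(p$mask),
                                              nrow(vals), ncol(vals))
  dlat <- diff(lat); dlon <- diff(lon)
  if (any(dlon <= 0))
    stop("format error in ", path, ": 'lon' coordinate is not ",
         "strictly increasing")
  if (all(dlat < 0)) {           # south-up file: flip to north-up
    lat <- rev(lat)
    vals <- vals[rev(seq_len(nrow(vals))), , drop = FALSE]
    mask <- mask[rev(seq_len(nrow(mask))), , drop = FALSE]
  } else if (any(dlat <= 0)) {
    stop("format error in ", path, ": 'lat' coordinate is not monotone")
  }
  res <- if (!is.null(p$resolution)) p$resolution else lat[2] - lat[1]
  g <- grid_spec(lat[1] - res / 2, lat[length(lat)] + res / 2,
                 lon[1] - res / 2, lon[length(lon)] + res / 2, res)
  gridded_field(vals, g, p$units, mask)
}

#' Read an IER coefficient table from CSV
#'
#' Expected columns: `disease`, `age_bin` (blank for COPD/LC), `alpha`,
#' `gamma`, `delta`.  All coefficient invariants are checked at load.
#'
#' @param path CSV path.
#' @param counterfactual no-risk concentration, ug m-3.
#' @return an `ier_coefficients` object.
#' @export
read_ier_csv <- function(path, counterfactual = 5.8) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(age_bin = "character"))
  ier_coefficients(tab, counterfactual)
}

#' Write an IER coefficient table to CSV
#' @param coeffs an `ier_coefficients` object.
#' @param path output CSV path.
#' @export
write_ier_csv <- function(coeffs, path) {
  utils::write.csv(coeffs$table, path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write / read the zone baseline-mortality table
#'
#' Columns: `zone`, `disease`, `rate`, `a`, `b`, `se_a`, `se_b`.  Reading
#' requires the zone map (from the grid partition) and zone GDP table to
#' rebuild the full object; negative exponents are rejected at load.
#'
#' @param mortality a `baseline_mortality` object.
#' @param path CSV path.
#' @export
write_mortality_csv <- function(mortality, path) {
  utils::write.csv(mortality$table, path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_mortality_csv
#' @param zone_map integer matrix of zone ids.
#' @param zone_gdp data frame `zone`, `gdp`.
#' @param grid,mask grid and land mask the zone map lives on.
#' @export
read_mortality_csv <- function(path, zone_map, zone_gdp, grid, mask) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("zone", "disease", "rate", "a", "b", "se_a", "se_b")
  if (!all(need %in% names(tab)))
    stop("mortality table must have columns ", paste(need, collapse = ", "))
  if (any(tab$b < 0))
    stop("negative GDP-mortality exponent at row ", which(tab$b < 0)[1])
  if (any(tab$rate < 0))
    stop("negative baseline rate at row ", which(tab$rate < 0)[1])
  structure(list(table = tab, zone_map = zone_map, zone_gdp = zone_gdp,
                 grid = grid, mask = mask),
            class = "baseline_mortality")
}

#' Read national age fractions from CSV
#'
#' Rows are decades (first column `decade`), remaining columns the age
#' bins; each row must sum to 1 within 1e-9 and violations name the
#' offending decade.
#'
#' @param path CSV path.
#' @return matrix decades x bins.
#' @export
read_age_fractions_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  sums <- rowSums(m)
  bad <- which(abs(sums - 1) > 1e-9)
  if (length(bad))
    stop("age fractions for decade ", rownames(m)[bad[1]], " sum to ",
         format(sums[bad[1]], digits = 10), ", not 1")
  m
}

# ---- configuration -------------------------------------------------------

config_to_list <- function(config) {
  list(seed = config$seed,
       grid = config$grid[c("lat_min", "lat_max", "lon_min", "lon_max",
                            "resolution")],
       n_models = config$n_models,
       national_mean_pm25 = config$national_mean_pm25,
       hotspot = config$hotspot, noise_sd = config$noise_sd,
       noise_length_scale = config$noise_length_scale,
       scenario_trends = lapply(config$scenario_trends, as.numeric),
       meteorology_effect = lapply(config$meteorology_effect, as.numeric),
       ssp_population = lapply(config$ssp_population, as.list),
       gdp_growth = lapply(config$gdp_growth, as.list),
       gdp_ppp_ref = config$gdp_ppp_ref,
       baseline_gdp_percap = config$baseline_gdp_percap,
       mortality_coeff = as.list(config$mortality_coeff),
       n_zone_side = config$n_zone_side,
       zone_gdp_jitter_sd = config$zone_gdp_jitter_sd,
       zone_rate_jitter_sd = config$zone_rate_jitter_sd,
       eta_mean = config$eta_mean,
       age_lambda_start = config$age_lambda_start,
       age_lambda_end = config$age_lambda_end)
}

#' Write / read a synthetic configuration as YAML
#' @param config a `synthetic_config`.
#' @param path YAML path.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path, precision = 17L)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  l <- yaml::read_yaml(path)
  synthetic_config(
    seed = l$seed,
    lat_min = l$grid$lat_min, lat_max = l$grid$lat_max,
    lon_min = l$grid$lon_min, lon_max = l$grid$lon_max,
    resolution = l$grid$resolution,
    n_models = l$n_models,
    national_mean_pm25 = l$national_mean_pm25,
    hotspot = l$hotspot, noise_sd = l$noise_sd,
    noise_length_scale = l$noise_length_scale,
    scenario_trends = lapply(l$scenario_trends, as.numeric),
    meteorology_effect = lapply(l$meteorology_effect, as.numeric),
    ssp_population = lapply(l$ssp_population, function(x) unlist(x)),
    gdp_growth = lapply(l$gdp_growth, function(x) unlist(x)),
    gdp_ppp_ref = l$gdp_ppp_ref,
    baseline_gdp_percap = l$baseline_gdp_percap,
    mortality_coeff = as.data.frame(l$mortality_coeff,
                                    stringsAsFactors = FALSE),
    n_zone_side = l$n_zone_side,
    zone_gdp_jitter_sd = l$zone_gdp_jitter_sd,
    zone_rate_jitter_sd = l$zone_rate_jitter_sd,
    eta_mean = l$eta_mean,
    age_lambda_start = l$age_lambda_start,
    age_lambda_end = l$age_lambda_end)
}

#' Deterministic hash of a configuration
#'
#' MD5 of the canonical JSON rendering; embedded in manifests and output
#' metadata so a run is traceable to its exact configuration.
#'
#' @param config a `synthetic_config`.
#' @return hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config_to_list(config),
                              digits = FULL_PRECISION, auto_unbox = TRUE),
             tmp, useBytes = TRUE)
  unname(tools::md5sum(tmp))
}

# ---- fixture bundle ------------------------------------------------------

write_record_json <- function(record, path) {
  payload <- list(model_id = record$model_id,
                  model_index = record$model_index,
                  scenario = record$scenario, pentad = record$pentad,
                  species = lapply(record$species, `[[`, "values"),
                  aod = record$aod$values)
  writeLines(jsonlite::toJSON(payload, digits = FULL_PRECISION,
                              auto_unbox = TRUE), path, useBytes = TRUE)
  invisible(path)
}

read_record_json <- function(path, grid, mask) {
  p <- jsonlite::fromJSON(path)
  species <- lapply(p$species, function(v)
    gridded_field(as.matrix(v), grid, "ug m-3", mask))
  structure(list(model_id = p$model_id, model_index = p$model_index,
                 scenario = p$scenario, pentad = p$pentad,
                 species = species,
                 aod = gridded_field(as.matrix(p$aod), grid, "1", mask)),
            class = "model_pentad_record")
}

#' Serialize a complete synthetic input bundle
#'
#' Generates every pipeline input from `config` and writes it under
#' `out_dir`: baseline rasters, per-model per-pentad ensemble records for
#' every configured scenario, per-SSP drivers, zone mortality and GDP
#' tables, the default IER coefficient table and the configuration
#' itself.  A `manifest.json` lists each file with its MD5 checksum plus
#' the seed, config hash and package version.
#'
#' @param config a `synthetic_config`.
#' @param out_dir writable directory (created if absent).
#' @return the manifest, invisibly.
#' @export
write_fixture_bundle <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create bundle directory ", out_dir)
  rel_files <- character(0)
  put <- function(rel) rel_files <<- c(rel_files, rel)
  write_config_yaml(config, file.path(out_dir, "config.yaml"))
  put("config.yaml")
  base <- generate_baseline_fields(config)
  for (nm in names(base)) {
    write_gridded(base[[nm]], file.path(out_dir, paste0("baseline_", nm,
                                                        ".json")))
    put(paste0("baseline_", nm, ".json"))
  }
  for (sc in names(config$scenario_trends)) {
    ens <- generate_model_ensemble(config, sc)
    scdir <- file.path(out_dir, "ensemble", sc)
    dir.create(scdir, recursive = TRUE, showWarnings = FALSE)
    for (m in ens$models) {
      rel <- file.path("ensemble", sc, paste0(m, "_baseline.json"))
      write_record_json(ens$baseline[[m]], file.path(out_dir, rel)); put(rel)
      for (p in ens$pentads) {
        rel <- file.path("ensemble", sc, paste0(m, "_", p, ".json"))
        write_record_json(ens$records[[m]][[p]], file.path(out_dir, rel))
        put(rel)
      }
    }
  }
  drv_dir <- file.path(out_dir, "drivers")
  dir.create(drv_dir, showWarnings = FALSE)
  for (ssp in names(config$ssp_population)) {
    d <- generate_scenario_drivers(config, ssp)
    payload <- list(ssp = d$ssp, pop_total = as.list(d$pop_total),
                    age_fractions = d$age_fractions,
                    age_bins = colnames(d$age_fractions),
                    decades = rownames(d$age_fractions),
                    gdp = as.list(d$gdp),
                    settlement = d$settlement$values)
    rel <- file.path("drivers", paste0(ssp, ".json"))
    writeLines(jsonlite::toJSON(payload, digits = FULL_PRECISION,
                                auto_unbox = TRUE),
               file.path(out_dir, rel), useBytes = TRUE)
    put(rel)
  }
  mort <- generate_baseline_mortality(config)
  write_mortality_csv(mort, file.path(out_dir, "mortality.csv"))
  put("mortality.csv")
  utils::write.csv(mort$zone_gdp, file.path(out_dir, "zones.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  put("zones.csv")
  write_ier_csv(default_ier_coefficients(),
                file.path(out_dir, "ier_coefficients.csv"))
  put("ier_coefficients.csv")
  sums <- tools::md5sum(file.path(out_dir, rel_files))
  manifest <- list(
    package = "pm25burden",
    version = as.character(utils::packageVersion("pm25burden")),
    seed = config$seed, config_hash = config_hash(config),
    n_models = config$n_models, n_pentads = length(config$pentads),
    scenarios = names(config$scenario_trends),
    files = stats::setNames(as.list(unname(sums)), rel_files))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "manifest.json"), useBytes = TRUE)
  invisible(manifest)
}

#' Read a synthetic input bundle back into memory
#'
#' Inverse of [write_fixture_bundle()]; every array round-trips exactly.
#'
#' @param dir bundle directory.
#' @return list with `config`, `baseline` fields, `ensembles` (per
#'   scenario), `drivers` (per SSP), `mortality`, `ier` and the
#'   `manifest`.
#' @export
read_fixture_bundle <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::fromJSON(man_path)
  config <- read_config_yaml(file.path(dir, "config.yaml"))
  g <- config$grid; mask <- config$mask
  baseline <- list(
    pm25 = read_gridded(file.path(dir, "baseline_pm25.json")),
    aod = read_gridded(file.path(dir, "baseline_aod.json")),
    eta_true = read_gridded(file.path(dir, "baseline_eta_true.json")))
  ensembles <- lapply(names(config$scenario_trends), function(sc) {
    models <- sprintf("model%02d", seq_len(config$n_models))
    bl <- lapply(models, function(m)
      read_record_json(file.path(dir, "ensemble", sc,
                                 paste0(m, "_baseline.json")), g, mask))
    recs <- lapply(models, function(m)
      stats::setNames(lapply(config$pentads, function(p)
        read_record_json(file.path(dir, "ensemble", sc,
                                   paste0(m, "_", p, ".json")), g, mask)),
        config$pentads))
    names(bl) <- models; names(recs) <- models
    structure(list(scenario = sc, models = models, pentads = config$pentads,
                   baseline = bl, records = recs, grid = g, mask = mask),
              class = "model_ensemble")
  })
  names(ensembles) <- names(config$scenario_trends)
  drivers <- lapply(names(config$ssp_population), function(ssp) {
    p <- jsonlite::fromJSON(file.path(dir, "drivers",
                                      paste0(ssp, ".json")))
    settlement <- gridded_field(as.matrix(p$settlement), g, "1", mask)
    fr <- as.matrix(p$age_fractions)
    dimnames(fr) <- list(p$decades, p$age_bins)
    totals <- unlist(p$pop_total)
    share <- settlement$values * mask / sum(settlement$values * mask)
    population <- stats::setNames(lapply(names(totals), function(lab)
      gridded_field(totals[[lab]] * share, g, "persons", mask)),
      names(totals))
    structure(list(ssp = p$ssp, decades = p$decades, pop_total = totals,
                   settlement = settlement, population = population,
                   age_fractions = fr,
                   gdp = as.data.frame(p$gdp, stringsAsFactors = FALSE),
                   grid = g, mask = mask),
              class = "scenario_drivers")
  })
  names(drivers) <- names(config$ssp_population)
  zone_gdp <- utils::read.csv(file.path(dir, "zones.csv"),
                              stringsAsFactors = FALSE)
  mortality <- read_mortality_csv(file.path(dir, "mortality.csv"),
                                  zone_partition(g, config$n_zone_side),
                                  zone_gdp, g, mask)
  ier <- read_ier_csv(file.path(dir, "ier_coefficients.csv"))
  list(config = config, baseline = baseline, ensembles = ensembles,
       drivers = drivers, mortality = mortality, ier = ier,
       manifest = manifest)
}
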