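# Seeded generator of every input the projection pipeline consumes.
#
# The generator emulates the statistical structure of the real inputs: a
# spatially heterogeneous satellite-derived baseline PM2.5 field with a
# high-exposure hotspot, a 13-member model ensemble sharing a per-scenario
# emission trend plus member-specific multiplicative noise, AOD fields
# consistent with a per-cell conversion factor, pathway-shaped population
# and GDP trajectories, and baseline mortality falling with GDP.

PENTAD_LABELS <- sprintf("%d-%d", seq(2011, 2096, by = 5), seq(2015, 2100, by = 5))
DECADE_LABELS <- sprintf("%d-%d", seq(2011, 2091, by = 10), seq(2020, 2100, by = 10))
DECADE_YEARS  <- seq(2011, 2091, by = 10)
AGE_BINS <- c("25-29", "30-34", "35-39", "40-44", "45-49", "50-54",
              "55-59", "60-64", "65-69", "70-74", "75-79", "80+")
DISEASES <- c("COPD", "IHD", "stroke", "LC")
AGE_SPECIFIC_DISEASES <- c("IHD", "stroke")

# Mass shares of total PM2.5 attributed to each reported species, chosen so
# that the speciated sum (including inferred ammonium and the size-resolved
# sea-salt and dust fractions) reconstructs the total exactly.
SPECIES_SHARES <- c(BC = 0.08, OA = 0.25, SO4 = 0.32, SS_contrib = 0.06,
                    dust_contrib = 0.17)  # NH4 = 0.375 * SO4 share = 0.12
POA_FRACTION <- 0.6  # POA / OA in the generator; SOA carries the rest

#' Default per-pentad emission trend factors for both pathways
#' @return named list of length-18 numeric vectors.
#' @export
default_scenario_trends <- function() {
  list(
    # stabilization pathway: exposure peaks in 2026-2030, falls below the
    # baseline level after 2050
    rcp45 = c(1.04, 1.08, 1.12, 1.14, 1.12, 1.08, 1.04, 1.00, 0.96, 0.91,
              0.86, 0.82, 0.78, 0.74, 0.70, 0.67, 0.64, 0.62),
    # high-emission pathway: peaks in 2036-2040, drops below baseline only
    # after 2090
    rcp85 = c(1.05, 1.10, 1.15, 1.19, 1.22, 1.24, 1.23, 1.21, 1.19, 1.16,
              1.13, 1.10, 1.07, 1.05, 1.03, 1.01, 0.99, 0.97)
  )
}

#' Default per-pentad meteorological modulation for both pathways
#' @return named list of length-18 numeric vectors.
#' @export
default_meteorology_effect <- function() {
  list(
    # growing suppression of exposure, ~7% early century to ~17% at the end
    rcp45 = seq(-0.07, -0.17, length.out = 18),
    # weak early suppression, mid-century enhancement, favourable again in
    # the final decade
    rcp85 = c(-0.050, -0.045, -0.040, -0.030, -0.020, -0.010, 0.005, 0.010,
              0.020, 0.025, 0.030, 0.030, 0.025, 0.020, 0.015, 0.010,
              -0.010, -0.020)
  )
}

#' Default national adult population trajectories per pathway
#' @return named list of baseline-plus-nine-decade totals (persons).
#' @export
default_ssp_population <- function() {
  # national adult (>25 yr) totals in persons, indexed baseline (2001) then
  # the first year of each decade 2011..2091; only the SSP3 analogue keeps
  # rising to the end of the century, the others peak mid-century
  mk <- function(x) stats::setNames(x * 1e6, c("baseline", DECADE_LABELS))
  list(
    SSP1 = mk(c(480, 560, 640, 710, 760, 790, 780, 750, 700, 650)),
    SSP2 = mk(c(480, 560, 650, 730, 800, 850, 870, 860, 840, 810)),
    SSP3 = mk(c(480, 560, 660, 760, 850, 930, 1000, 1060, 1110, 1150)),
    SSP4 = mk(c(480, 560, 645, 720, 780, 820, 830, 820, 795, 760)),
    SSP5 = mk(c(480, 560, 635, 700, 745, 770, 765, 740, 700, 655))
  )
}

#' Default decade GDP-PPP growth factors per pathway
#' @return named list of length-9 numeric vectors.
#' @export
default_gdp_growth <- function() {
  # decade growth factors of mean GDP-PPP relative to the 2010 reference;
  # strictly increasing for every pathway, fastest for the SSP5 analogue
  mk <- function(x) stats::setNames(x, DECADE_LABELS)
  list(
    SSP1 = mk(c(1.3, 1.9, 2.7, 3.6, 4.6, 5.7, 6.8, 7.9, 9.0)),
    SSP2 = mk(c(1.25, 1.7, 2.3, 3.0, 3.8, 4.6, 5.5, 6.3, 7.0)),
    SSP3 = mk(c(1.2, 1.45, 1.75, 2.1, 2.45, 2.8, 3.1, 3.35, 3.5)),
    SSP4 = mk(c(1.22, 1.6, 2.1, 2.6, 3.2, 3.8, 4.3, 4.7, 5.0)),
    SSP5 = mk(c(1.35, 2.1, 3.2, 4.5, 5.9, 7.4, 9.0, 10.5, 12.0))
  )
}

#' Default GDP-to-baseline-mortality curve coefficients
#' @return data frame with disease, rate, b, se_b, se_rate_frac.
#' @export
default_mortality_coeff <- function() {
  # GDP -> baseline-mortality power-law exponents and baseline-period
  # national rates (deaths per adult per year); lung cancer is held
  # GDP-invariant
  data.frame(
    disease = DISEASES,
    rate = c(0.0013, 0.0025, 0.0012, 0.0002),
    b = c(0.30, 0.25, 0.35, 0.0),
    se_b = c(0.04, 0.04, 0.04, 0.0),
    se_rate_frac = c(0.10, 0.10, 0.10, 0.0),
    stringsAsFactors = FALSE
  )
}

#' Configuration of the synthetic study conditions
#'
#' Bundles every tunable of the synthetic input generator: grid, ensemble
#' size, per-pathway emission trends and meteorology effects, hotspot
#' geometry, demographic/economic trajectories and the GDP to
#' baseline-mortality curve.  Defaults reproduce the study conditions the
#' pipeline is designed for: a 0.5 degree national domain, 13 ensemble
#' members, 18 pentads (2011-2015 to 2096-2100), a 34.5 ug m-3 baseline
#' national mean, and five population pathways of which only the SSP3
#' analogue keeps growing to 2100.
#'
#' @param seed integer master seed; every generated artifact is a pure
#'   function of (seed, config).
#' @param lat_min,lat_max,lon_min,lon_max,resolution study domain, degrees.
#' @param n_models ensemble size.
#' @param national_mean_pm25 target land-mean baseline PM2.5 (ug m-3).
#' @param hotspot list(lat, lon, radius, amplitude): Gaussian high-exposure
#'   bump (degrees, ug m-3) emulating a polluted basin.
#' @param noise_sd member-level multiplicative log-noise scale.
#' @param noise_length_scale spatial correlation length of member noise, in
#'   cells.
#' @param scenario_trends named list: per emission scenario, per-pentad
#'   multiplicative factor on baseline emissions-driven PM2.5.
#' @param meteorology_effect named list: per-scenario per-pentad fractional
#'   modulation applied only in the speciated (mass-sum) mode.
#' @param ssp_population named list of national adult totals (baseline plus
#'   nine decades).
#' @param gdp_growth named list of decade growth factors of GDP-PPP
#'   relative to the reference year.
#' @param gdp_ppp_ref reference-year national GDP-PPP (arbitrary currency).
#' @param baseline_gdp_percap anchor constant-price GDP (per capita) at
#'   which zone baseline mortality rates are calibrated.
#' @param mortality_coeff data frame disease/rate/b/se_b/se_rate_frac.
#' @param n_zone_side zones per side of the rectangular partition.
#' @param zone_gdp_jitter_sd,zone_rate_jitter_sd relative spread of zone
#'   GDP and zone mortality rates around national values (0 = uniform).
#' @param eta_mean mean of the true PM2.5/AOD conversion field (ug m-3 per
#'   unit AOD).
#' @param age_lambda_start,age_lambda_end geometric age-structure decay at
#'   baseline and in the final decade; the decline over time shifts mass
#'   toward the older bins.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             lat_min = 6.5, lat_max = 37.5,
                             lon_min = 67.5, lon_max = 97.5,
                             resolution = 0.5,
                             n_models = 13L,
                             national_mean_pm25 = 34.5,
                             hotspot = list(lat = 26.5, lon = 83.5,
                                            radius = 4, amplitude = 40),
                             noise_sd = 0.15,
                             noise_length_scale = 4,
                             scenario_trends = default_scenario_trends(),
                             meteorology_effect = default_meteorology_effect(),
                             ssp_population = default_ssp_population(),
                             gdp_growth = default_gdp_growth(),
                             gdp_ppp_ref = 4000,
                             baseline_gdp_percap = 1500,
                             mortality_coeff = default_mortality_coeff(),
                             n_zone_side = 4L,
                             zone_gdp_jitter_sd = 0.25,
                             zone_rate_jitter_sd = 0.10,
                             eta_mean = 80,
                             age_lambda_start = 0.28,
                             age_lambda_end = 0.10) {
  grid <- grid_spec(lat_min, lat_max, lon_min, lon_max, resolution)
  n_pentads <- length(PENTAD_LABELS)
  for (sc in names(scenario_trends))
    if (length(scenario_trends[[sc]]) != n_pentads)
      stop("configuration error: scenario_trends['", sc, "'] must have ",
           n_pentads, " pentad entries")
  for (sc in names(meteorology_effect))
    if (length(meteorology_effect[[sc]]) != n_pentads)
      stop("configuration error: meteorology_effect['", sc, "'] must have ",
           n_pentads, " pentad entries")
  if (!setequal(names(scenario_trends), names(meteorology_effect)))
    stop("configuration error: scenario_trends and meteorology_effect must ",
         "cover the same scenarios")
  # exactly one pathway may keep growing to the final decade
  mono <- vapply(ssp_population, function(p) {
    dec <- p[names(p) != "baseline"]
    all(diff(dec) >= 0)
  }, logical(1))
  peak_ok <- vapply(ssp_population, function(p) {
    dec <- p[names(p) != "baseline"]
    which.max(dec) < length(dec)
  }, logical(1))
  if (sum(mono) != 1L || !all(peak_ok | mono))
    stop("configuration error: exactly one population pathway must be ",
         "monotone non-decreasing; all others must peak before the final decade")
  if (!all(DISEASES %in% mortality_coeff$disease))
    stop("configuration error: mortality_coeff must cover ",
         paste(DISEASES, collapse = ", "))
  if (any(mortality_coeff$b < 0))
    stop("configuration error: negative GDP-mortality exponent")
  mask <- default_land_mask(grid)
  structure(list(
    seed = as.integer(seed), grid = grid, mask = mask,
    n_models = as.integer(n_models),
    pentads = PENTAD_LABELS, decades = DECADE_LABELS,
    baseline_window = "2001-2005",
    national_mean_pm25 = national_mean_pm25,
    hotspot = hotspot, noise_sd = noise_sd,
    noise_length_scale = noise_length_scale,
    scenario_trends = scenario_trends,
    meteorology_effect = meteorology_effect,
    ssp_population = ssp_population,
    gdp_growth = gdp_growth, gdp_ppp_ref = gdp_ppp_ref,
    baseline_gdp_percap = baseline_gdp_percap,
    mortality_coeff = mortality_coeff,
    n_zone_side = as.integer(n_zone_side),
    zone_gdp_jitter_sd = zone_gdp_jitter_sd,
    zone_rate_jitter_sd = zone_rate_jitter_sd,
    eta_mean = eta_mean,
    age_lambda_start = age_lambda_start, age_lambda_end = age_lambda_end
  ), class = "synthetic_config")
}

#' Generate the satellite-style baseline PM2.5 and AOD fields
#'
#' Builds a smooth positive baseline surface with a configurable
#' high-exposure hotspot, rescaled so its area-weighted land mean hits the
#' configured national target exactly.  AOD is derived as PM2.5 divided by
#' a smooth positive conversion field `eta_true`, which is returned for
#' test oracles.
#'
#' @param config a [synthetic_config()].
#' @return list with `gridded_field`s `pm25`, `aod` and `eta_true`.
#' @export
generate_baseline_fields <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  g <- config$grid; mask <- config$mask
  set.seed(config$seed + 11L)
  f1 <- smooth_random_field(g$nlat, g$nlon, config$noise_length_scale * 1.5)
  pattern <- 1 + 0.3 * f1 / max(abs(f1))
  hs <- config$hotspot
  LAT <- matrix(g$lat, g$nlat, g$nlon)
  LON <- matrix(g$lon, g$nlat, g$nlon, byrow = TRUE)
  bump <- hs$amplitude * exp(-((LAT - hs$lat)^2 + (LON - hs$lon)^2) /
                             (2 * hs$radius^2))
  raw <- gridded_field(pattern * config$national_mean_pm25 + bump,
                       g, "ug m-3", mask)
  pm <- field_map(raw, function(v) v * config$national_mean_pm25 / land_mean(raw))
  f2 <- smooth_random_field(g$nlat, g$nlon, config$noise_length_scale * 2)
  eta <- gridded_field(config$eta_mean * (1 + 0.2 * f2 / max(abs(f2))),
                       g, "ug m-3 per AOD", mask)
  aod <- field_map2(pm, eta, `/`, units = "1")
  list(pm25 = pm, aod = aod, eta_true = eta)
}

# split a total-PM2.5 matrix into the species a given member reports
species_from_total <- function(total, model_index) {
  sh <- SPECIES_SHARES
  sp <- list(BC = sh[["BC"]] * total,
             SO4 = sh[["SO4"]] * total,
             SS = sh[["SS_contrib"]] * total / 0.25,
             dust = sh[["dust_contrib"]] * total / 0.1)
  oa <- sh[["OA"]] * total
  if (model_index == 1L) {            # reference member reports both
    sp$POA <- POA_FRACTION * oa; sp$SOA <- (1 - POA_FRACTION) * oa
  } else if (model_index %in% c(2L, 3L)) {
    sp$POA <- POA_FRACTION * oa       # primary-only reporters
  } else if (model_index %in% c(4L, 5L)) {
    sp$SOA <- (1 - POA_FRACTION) * oa # secondary-only reporters
  } else {
    sp$OA <- oa
  }
  sp
}

make_record <- function(model_id, model_index, scenario, pentad, total, aod,
                        grid, mask) {
  species <- lapply(species_from_total(total, model_index),
                    function(v) gridded_field(v, grid, "ug m-3", mask))
  structure(list(model_id = model_id, model_index = model_index,
                 scenario = scenario, pentad = pentad, species = species,
                 aod = gridded_field(aod, grid, "1", mask)),
            class = "model_pentad_record")
}

#' Generate the multi-model ensemble for one emission scenario
#'
#' Each member's speciated total tracks `baseline x trend x (1 + met)` with
#' member- and pentad-specific multiplicative lognormal noise, spatially
#' correlated via Gaussian smoothing; its AOD tracks `baseline_aod x trend`
#' with the *same* noise draw, so AOD carries the emission signal but not
#' the meteorological term.  Member 1 reports both primary and secondary
#' organic aerosol, members 2-3 only POA, members 4-5 only SOA, the rest a
#' combined OA field, emulating reporting gaps in real archives.  A
#' baseline-window record per member (trend 1, no meteorology term) is
#' included.
#'
#' @param config a [synthetic_config()].
#' @param scenario scenario label present in `config$scenario_trends`.
#' @return object of class `model_ensemble` with elements `baseline`
#'   (list per model) and `records` (list per model, per pentad).
#' @export
generate_model_ensemble <- function(config, scenario) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!scenario %in% names(config$scenario_trends))
    stop("unknown scenario '", scenario, "'; configured: ",
         paste(names(config$scenario_trends), collapse = ", "))
  base <- generate_baseline_fields(config)
  g <- config$grid; mask <- config$mask
  trend <- config$scenario_trends[[scenario]]
  met <- config$meteorology_effect[[scenario]]
  sc_index <- match(scenario, sort(names(config$scenario_trends)))
  set.seed(config$seed + 1000L * sc_index + 100L)
  noise <- function() {
    if (config$noise_sd == 0) return(matrix(1, g$nlat, g$nlon))
    z <- smooth_random_field(g$nlat, g$nlon, config$noise_length_scale)
    exp(config$noise_sd * z - 0.5 * config$noise_sd^2)
  }
  models <- sprintf("model%02d", seq_len(config$n_models))
  baseline <- vector("list", config$n_models)
  records <- vector("list", config$n_models)
  for (m in seq_len(config$n_models)) {
    nb <- noise()
    baseline[[m]] <- make_record(models[m], m, scenario, "baseline",
                                 base$pm25$values * nb, base$aod$values * nb,
                                 g, mask)
    per_pentad <- vector("list", length(config$pentads))
    for (p in seq_along(config$pentads)) {
      np <- noise()
      tot <- base$pm25$values * trend[p] * (1 + met[p]) * np
      aod <- base$aod$values * trend[p] * np
      per_pentad[[p]] <- make_record(models[m], m, scenario,
                                     config$pentads[p], tot, aod, g, mask)
    }
    names(per_pentad) <- config$pentads
    records[[m]] <- per_pentad
  }
  names(baseline) <- models; names(records) <- models
  structure(list(scenario = scenario, models = models,
                 pentads = config$pentads, baseline = baseline,
                 records = records, grid = g, mask = mask),
            class = "model_ensemble")
}

# zone ids plus zone constant-price GDP, shared by drivers and mortality
generate_zone_table <- function(config) {
  k <- config$n_zone_side
  zones <- zone_partition(config$grid, k)
  ids <- sort(unique(zones[config$mask]))
  set.seed(config$seed + 41L)
  jit <- stats::rnorm(k * k, 0, config$zone_gdp_jitter_sd)
  gdp <- config$baseline_gdp_percap * pmax(0.3, 1 + jit)
  list(zone_map = zones,
       table = data.frame(zone = ids, gdp = gdp[ids]))
}

#' Generate demographic and economic drivers for one pathway
#'
#' Gridded adult population per decade (national totals allocated
#' proportionally to a fixed settlement field), national age fractions per
#' decade (shifting toward older bins over time), and a strictly rising
#' GDP trajectory expressed as IIASA-like and OECD-like GDP-PPP series
#' around a common reference.
#'
#' @param config a [synthetic_config()].
#' @param ssp pathway label in `names(config$ssp_population)`.
#' @param settlement optional `gridded_field` overriding the generated
#'   settlement surface (used by proportional-allocation tests).
#' @return object of class `scenario_drivers`.
#' @export
generate_scenario_drivers <- function(config, ssp, settlement = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!ssp %in% names(config$ssp_population))
    stop("unknown SSP '", ssp, "'")
  g <- config$grid; mask <- config$mask
  if (is.null(settlement)) {
    set.seed(config$seed + 31L)
    s <- smooth_random_field(g$nlat, g$nlon, config$noise_length_scale * 1.5)
    settlement <- gridded_field(exp(1.2 * s) * mask, g, "1", mask)
  }
  share <- settlement$values * mask / sum(settlement$values * mask)
  totals <- config$ssp_population[[ssp]]
  labels <- names(totals)
  population <- lapply(labels, function(lab)
    gridded_field(totals[[lab]] * share, g, "persons", mask))
  names(population) <- labels
  # age fractions: geometric decay over bins, flattening over time
  nb <- length(AGE_BINS)
  lam <- seq(config$age_lambda_start, config$age_lambda_end,
             length.out = length(labels))
  fr <- t(vapply(lam, function(l) {
    w <- exp(-l * (seq_len(nb) - 1)); w / sum(w)
  }, numeric(nb)))
  dimnames(fr) <- list(labels, AGE_BINS)
  growth <- c(baseline = 1, config$gdp_growth[[ssp]])
  gdp <- data.frame(
    decade = labels,
    year = c(2001, DECADE_YEARS),
    gdp_ppp_iiasa = growth * 1.08 * config$gdp_ppp_ref,
    gdp_ppp_oecd = growth * 0.92 * config$gdp_ppp_ref,
    gdp_ppp_ref = config$gdp_ppp_ref,
    stringsAsFactors = FALSE
  )
  structure(list(ssp = ssp, decades = labels, pop_total = totals,
                 settlement = settlement, population = population,
                 age_fractions = fr, gdp = gdp, grid = g, mask = mask),
            class = "scenario_drivers")
}

#' Generate the zone-level baseline mortality table
#'
#' Per-zone, per-disease baseline-period rates consistent with the
#' configured GDP to mortality power law evaluated at each zone's baseline
#' GDP, with optional multiplicative zone jitter.  The lung-cancer rate is
#' GDP-invariant (exponent 0).
#'
#' @param config a [synthetic_config()].
#' @return object of class `baseline_mortality`: a table with columns
#'   zone, disease, rate, a, b, se_a, se_b plus the zone map and zone GDP.
#' @export
generate_baseline_mortality <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  zt <- generate_zone_table(config)
  mc <- config$mortality_coeff
  if (!all(DISEASES %in% mc$disease)) stop("missing disease in mortality_coeff")
  set.seed(config$seed + 51L)
  rows <- list()
  for (j in DISEASES) {
    cj <- mc[mc$disease == j, ][1, ]
    jit <- stats::rnorm(nrow(zt$table), 0, config$zone_rate_jitter_sd)
    a_nat <- cj$rate * config$baseline_gdp_percap^cj$b
    a <- a_nat * pmax(0.2, 1 + jit)
    rate <- a * zt$table$gdp^(-cj$b)
    rows[[j]] <- data.frame(zone = zt$table$zone, disease = j, rate = rate,
                            a = a, b = cj$b, se_a = cj$se_rate_frac * a,
                            se_b = cj$se_b, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows); rownames(tab) <- NULL
  structure(list(table = tab, zone_map = zt$zone_map,
                 zone_gdp = zt$table, grid = config$grid, mask = config$mask),
            class = "baseline_mortality")
}
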