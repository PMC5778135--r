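# Conversion of decadal exposure surfaces into attributable premature
# mortality: IER relative risk, GDP-adjusted baseline mortality, age
# disaggregation and uncertainty bands.

#' Integrated exposure-response coefficient set
#'
#' One (alpha, gamma, delta) triple per disease, age-resolved for the
#' cardiovascular causes (IHD, stroke), plus the counterfactual
#' concentration below which no excess risk is assigned.
#'
#' @param table data frame with columns `disease`, `age_bin` (empty/NA for
#'   COPD and LC), `alpha`, `gamma`, `delta`.
#' @param counterfactual no-risk concentration in ug m-3 (default 5.8).
#' @return object of class `ier_coefficients`.
#' @export
ier_coefficients <- function(table, counterfactual = 5.8) {
  need <- c("disease", "age_bin", "alpha", "gamma", "delta")
  if (!all(need %in% names(table)))
    stop("IER table must have columns ", paste(need, collapse = ", "))
  table$age_bin[is.na(table$age_bin)] <- ""
  bad <- which(!(table$alpha > 0 & table$gamma > 0 & table$delta > 0))
  if (length(bad))
    stop("non-positive IER coefficient at row ", bad[1],
         " (disease ", table$disease[bad[1]], ")")
  if (counterfactual < 0) stop("counterfactual concentration must be >= 0")
  for (j in setdiff(DISEASES, AGE_SPECIFIC_DISEASES)) {
    r <- table[table$disease == j, ]
    if (nrow(r) != 1 || nzchar(r$age_bin))
      stop("disease ", j, " must carry exactly one coefficient triple ",
           "with a blank age bin")
  }
  for (j in AGE_SPECIFIC_DISEASES) {
    r <- table[table$disease == j, ]
    if (!setequal(r$age_bin, AGE_BINS))
      stop("disease ", j, " must carry one triple per age bin (",
           paste(AGE_BINS, collapse = ", "), ")")
  }
  structure(list(table = table, counterfactual = counterfactual),
            class = "ier_coefficients")
}

#' Illustrative default IER coefficients
#'
#' A synthetic, non-authoritative coefficient set with the qualitative
#' shape of published exposure-response look-up tables (risk amplitude
#' declining with age for the cardiovascular causes).  Intended for tests
#' and demonstrations; substantive analyses should load a vetted table
#' with [read_ier_csv()].
#'
#' @param counterfactual no-risk concentration, ug m-3.
#' @return an `ier_coefficients` object.
#' @export
default_ier_coefficients <- function(counterfactual = 5.8) {
  nb <- length(AGE_BINS)
  ihd_alpha <- seq(1.2, 0.35, length.out = nb)
  stroke_alpha <- seq(1.0, 0.30, length.out = nb)
  tab <- rbind(
    data.frame(disease = "COPD", age_bin = "", alpha = 0.50, gamma = 0.05,
               delta = 0.70, stringsAsFactors = FALSE),
    data.frame(disease = "LC", age_bin = "", alpha = 0.60, gamma = 0.04,
               delta = 0.75, stringsAsFactors = FALSE),
    data.frame(disease = "IHD", age_bin = AGE_BINS, alpha = ihd_alpha,
               gamma = 0.07, delta = 0.60, stringsAsFactors = FALSE),
    data.frame(disease = "stroke", age_bin = AGE_BINS, alpha = stroke_alpha,
               gamma = 0.065, delta = 0.62, stringsAsFactors = FALSE)
  )
  ier_coefficients(tab, counterfactual)
}

#' IER relative risk at a given exposure
#'
#' `RR = 1 + alpha * (1 - exp(-gamma * dPM^delta))` with
#' `dPM = max(PM2.5 - counterfactual, 0)`, so RR is 1 at or below the
#' counterfactual and saturates at `1 + alpha`.
#'
#' @param pm25 concentration(s), ug m-3; vector or matrix.
#' @param coeffs an `ier_coefficients` object.
#' @param disease one of COPD, IHD, stroke, LC.
#' @param age_bin age bin label; required for IHD and stroke.
#' @return relative risk, same shape as `pm25`.
#' @export
ier_relative_risk <- function(pm25, coeffs, disease, age_bin = NULL) {
  stopifnot(inherits(coeffs, "ier_coefficients"))
  if (any(pm25 < 0, na.rm = TRUE)) stop("negative PM2.5 concentration")
  tab <- coeffs$table
  if (disease %in% AGE_SPECIFIC_DISEASES) {
    if (is.null(age_bin))
      stop("age_bin is required for age-specific disease ", disease)
    row <- tab[tab$disease == disease & tab$age_bin == age_bin, ]
  } else {
    row <- tab[tab$disease == disease & !nzchar(tab$age_bin), ]
  }
  if (nrow(row) != 1) stop("no IER coefficients for ", disease,
                           if (!is.null(age_bin)) paste0(" / ", age_bin))
  dpm <- pmax(pm25 - coeffs$counterfactual, 0)
  1 + row$alpha * (1 - exp(-row$gamma * dpm^row$delta))
}

#' Attributable deaths from relative risk
#'
#' `dM = y * (RR - 1) / RR * P` - the classical attributable-fraction
#' relation, linear in both the baseline rate and the exposed population.
#'
#' @param rr relative risk (>= 1), any numeric shape.
#' @param y baseline mortality rate, deaths per person per year.
#' @param population exposed persons.
#' @return attributable deaths per year, same shape.
#' @export
attributable_deaths <- function(rr, y, population) {
  if (any(rr < 1, na.rm = TRUE))
    stop("relative risk below 1; upstream computation is inconsistent")
  if (any(y < 0, na.rm = TRUE) || any(population < 0, na.rm = TRUE))
    stop("negative baseline rate or population")
  y * (rr - 1) / rr * population
}

#' Split a decade's population grid into age bins
#'
#' Cell population times the national age fraction of the decade; the bins
#' sum back to the total grid exactly.
#'
#' @param drivers a `scenario_drivers`.
#' @param decade decade label (or `"baseline"`).
#' @return named list of per-bin `gridded_field`s.
#' @export
age_disaggregate <- function(drivers, decade) {
  fr <- drivers$age_fractions[decade, ]
  if (abs(sum(fr) - 1) > 1e-9)
    stop("age fractions for ", decade, " sum to ", sum(fr), ", not 1")
  pop <- drivers$population[[decade]]
  stats::setNames(lapply(fr, function(f) field_map(pop, function(v) v * f)),
                  names(fr))
}

#' GDP growth factor and zone GDP for a decade
#'
#' The decade growth factor is the mean of the IIASA-like and OECD-like
#' GDP-PPP projections divided by the reference-year GDP-PPP; it is
#' applied uniformly to every zone's constant-price baseline GDP.
#'
#' @param drivers a `scenario_drivers`.
#' @param decade decade label (or `"baseline"`).
#' @param zone_baseline_gdp numeric vector of zone constant-price GDP.
#' @return list with scalar `growth` and vector `zone_gdp`.
#' @export
project_gdp <- function(drivers, decade, zone_baseline_gdp = NULL) {
  row <- drivers$gdp[drivers$gdp$decade == decade, ]
  if (nrow(row) != 1) stop("decade ", decade, " absent from GDP table")
  if (row$gdp_ppp_ref <= 0) stop("non-positive reference GDP-PPP")
  g <- (row$gdp_ppp_iiasa + row$gdp_ppp_oecd) / 2 / row$gdp_ppp_ref
  list(growth = g,
       zone_gdp = if (is.null(zone_baseline_gdp)) NULL
                  else zone_baseline_gdp * g)
}

#' GDP-adjusted baseline mortality rate
#'
#' Power-law decline `y(GDP) = a * GDP^(-b)`; lung cancer carries `b = 0`
#' and is therefore GDP-invariant.  `shift` moves both coefficients by
#' that many standard errors in the direction that raises the predicted
#' rate (`+1` for the upper uncertainty arm, `-1` for the lower).
#'
#' @param mortality a `baseline_mortality` object.
#' @param zone_gdp numeric vector of current zone GDP, aligned with
#'   `mortality$zone_gdp$zone`.
#' @param disease disease label.
#' @param shift coefficient shift in standard errors (default 0).
#' @return named vector of rates per zone.
#' @export
adjust_baseline_mortality <- function(mortality, zone_gdp, disease, shift = 0) {
  tab <- mortality$table[mortality$table$disease == disease, ]
  if (nrow(tab) == 0) stop("no baseline mortality entries for ", disease)
  if (length(zone_gdp) != nrow(tab))
    stop("zone_gdp length does not match the number of zones")
  a <- pmax(tab$a + shift * tab$se_a, 0)
  b <- tab$b - shift * tab$se_b
  y <- a * zone_gdp^(-b)
  stats::setNames(y, tab$zone)
}

# map per-zone rates onto the grid through the zone id matrix
zone_rates_to_grid <- function(rates, zone_map) {
  k2 <- max(zone_map)
  lut <- rep(0, k2)
  lut[as.integer(names(rates))] <- rates
  matrix(lut[zone_map], nrow(zone_map), ncol(zone_map))
}

#' Attributable mortality for one decade
#'
#' For COPD and LC the full adult population and a single coefficient
#' triple are used; for IHD and stroke age-bin populations meet age-bin
#' relative risks and the contributions are summed.  Every cell inherits
#' the baseline mortality rate of its zone, adjusted to the decade's GDP.
#'
#' @param exposure decadal exposure `gridded_field` (ug m-3).
#' @param drivers a `scenario_drivers`.
#' @param mortality a `baseline_mortality`.
#' @param coeffs an `ier_coefficients`.
#' @param decade decade label (or `"baseline"`).
#' @param population optional override of the decade's population grid.
#' @param age_fractions optional override of the decade's age fractions.
#' @param gdp_growth optional override of the decade's GDP growth factor
#'   (1 freezes GDP at baseline).
#' @param coeff_shift mortality-coefficient shift in standard errors.
#' @return object of class `mortality_result`: national totals per
#'   disease, the per-grid total field, and the exposed population.
#' @export
decade_mortality <- function(exposure, drivers, mortality, coeffs, decade,
                             population = NULL, age_fractions = NULL,
                             gdp_growth = NULL, coeff_shift = 0) {
  stopifnot(inherits(mortality, "baseline_mortality"),
            inherits(coeffs, "ier_coefficients"))
  if (is.null(population)) {
    if (!decade %in% names(drivers$population))
      stop("decade ", decade, " absent from population drivers")
    population <- drivers$population[[decade]]
  }
  if (is.null(age_fractions)) age_fractions <- drivers$age_fractions[decade, ]
  if (abs(sum(age_fractions) - 1) > 1e-9)
    stop("age fractions do not sum to 1")
  if (is.null(gdp_growth)) gdp_growth <- project_gdp(drivers, decade)$growth
  check_compatible(exposure, population)
  mask <- exposure$mask
  pm <- exposure$values
  P <- population$values
  zone_gdp <- mortality$zone_gdp$gdp * gdp_growth
  by_disease <- stats::setNames(numeric(length(DISEASES)), DISEASES)
  field <- matrix(0, nrow(pm), ncol(pm))
  for (j in DISEASES) {
    y <- adjust_baseline_mortality(mortality, zone_gdp, j, shift = coeff_shift)
    yg <- zone_rates_to_grid(y, mortality$zone_map)
    if (j %in% AGE_SPECIFIC_DISEASES) {
      dm <- matrix(0, nrow(pm), ncol(pm))
      for (bin in AGE_BINS) {
        rr <- ier_relative_risk(pm, coeffs, j, bin)
        dm <- dm + attributable_deaths(rr, yg, P * age_fractions[[bin]])
      }
    } else {
      rr <- ier_relative_risk(pm, coeffs, j)
      dm <- attributable_deaths(rr, yg, P)
    }
    dm[!mask] <- 0
    by_disease[[j]] <- sum(dm)
    field <- field + dm
  }
  structure(list(
    decade = decade, by_disease = by_disease, total = sum(by_disease),
    field = gridded_field(field, exposure$grid, "deaths yr-1", mask),
    population_total = sum(P[mask])
  ), class = "mortality_result")
}

#' Low/central/high mortality bands
#'
#' The lower (upper) arm re-evaluates the whole pipeline at the ensemble
#' mean minus (plus) one sigma of exposure with the GDP-mortality
#' coefficients shifted down (up) by one standard error - the joint mode.
#' In quadrature mode the two perturbations are applied separately and
#' their effects on the national total combined in quadrature.
#' Monotonicity of the chain in both inputs guarantees
#' `low <= central <= high`.
#'
#' @param exposure_mean,exposure_sigma decadal ensemble mean and spread.
#' @param drivers,mortality,coeffs,decade,population,age_fractions,gdp_growth
#'   forwarded to [decade_mortality()].
#' @param mode `"joint"` (default) or `"quadrature"`.
#' @return list with `central` (`mortality_result`), scalars `low`,
#'   `high`, and the low/high per-grid fields in joint mode.
#' @export
decade_mortality_bands <- function(exposure_mean, exposure_sigma, drivers,
                                   mortality, coeffs, decade,
                                   population = NULL, age_fractions = NULL,
                                   gdp_growth = NULL,
                                   mode = c("joint", "quadrature")) {
  mode <- match.arg(mode)
  run <- function(expo, shift)
    decade_mortality(expo, drivers, mortality, coeffs, decade,
                     population = population, age_fractions = age_fractions,
                     gdp_growth = gdp_growth, coeff_shift = shift)
  central <- run(exposure_mean, 0)
  lo_exp <- field_map2(exposure_mean, exposure_sigma,
                       function(m, s) pmax(m - s, 0))
  hi_exp <- field_map2(exposure_mean, exposure_sigma, `+`)
  if (mode == "joint") {
    lo <- run(lo_exp, -1); hi <- run(hi_exp, 1)
    list(central = central, low = lo$total, high = hi$total,
         low_field = lo$field, high_field = hi$field)
  } else {
    d_exp <- run(hi_exp, 0)$total - central$total
    d_coef <- run(exposure_mean, 1)$total - central$total
    half <- sqrt(d_exp^2 + d_coef^2)
    list(central = central, low = max(central$total - half, 0),
         high = central$total + half,
         low_field = NULL, high_field = NULL)
  }
}

#' Crude attributable-mortality rate per 100,000 exposed adults
#'
#' @param result a `mortality_result`.
#' @param drivers a `scenario_drivers` (for the national adult total).
#' @param decade decade label.
#' @return deaths per year per 100,000 exposed population.
#' @export
crude_rate <- function(result, drivers, decade) {
  pop <- drivers$pop_total[[decade]]
  if (is.null(pop) || is.na(pop) || pop <= 0)
    stop("non-positive exposed population for ", decade)
  1e5 * result$total / pop
}
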