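# Scenario-matrix orchestration and the counterfactual sensitivity
# decomposition (demography, epidemiology, meteorology, policy caps).

REPRESENTATIVE_DECADES <- c("2031-2040", "2061-2070", "2091-2100")
DEFAULT_IT_TARGETS <- c("2031-2040" = 35, "2061-2070" = 25, "2091-2100" = 15)

#' Emission-pathway x socioeconomic-pathway scenario matrix
#'
#' The combination of the high-emission pathway with the green-growth SSP1
#' storyline is internally inconsistent and marked infeasible; with two
#' emission pathways and five SSPs the feasible matrix has 9 cells.
#'
#' @param rcps emission-pathway labels; a label containing `"85"` is
#'   treated as the high-emission analogue.
#' @param ssps socioeconomic-pathway labels.
#' @return data frame with columns `rcp`, `ssp`, `feasible`.
#' @export
scenario_matrix <- function(rcps = c("rcp45", "rcp85"),
                            ssps = paste0("SSP", 1:5)) {
  m <- expand.grid(rcp = rcps, ssp = ssps, stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  m$feasible <- !(grepl("85", m$rcp) & m$ssp == "SSP1")
  m[order(m$ssp, m$rcp), c("rcp", "ssp", "feasible")]
}

assert_feasible <- function(rcp, ssp) {
  if (grepl("85", rcp) && ssp == "SSP1")
    stop("refusing infeasible scenario combination (", rcp, ", ", ssp,
         "): a high-emission pathway is inconsistent with the green-growth ",
         "SSP1 storyline")
  invisible(TRUE)
}

#' National mortality burden for every feasible scenario combination
#'
#' Evaluates [decade_mortality_bands()] for each requested (emission
#' pathway, SSP) pair and decade.  Explicitly requesting the infeasible
#' pair raises an error rather than silently skipping it.
#'
#' @param exposures named list (by rcp label) of `exposure_projection`s.
#' @param drivers_list named list (by SSP label) of `scenario_drivers`.
#' @param mortality a `baseline_mortality`.
#' @param coeffs an `ier_coefficients`.
#' @param decades decade labels to evaluate (default all nine).
#' @param pairs optional data frame of `rcp`, `ssp` rows to run; defaults
#'   to the feasible cells of [scenario_matrix()] over the supplied
#'   inputs.
#' @param uncertainty `"joint"` or `"quadrature"` band combination.
#' @return data frame: decade, rcp, ssp, central, low, high, crude_rate.
#' @export
run_matrix <- function(exposures, drivers_list, mortality, coeffs,
                       decades = DECADE_LABELS, pairs = NULL,
                       uncertainty = c("joint", "quadrature")) {
  uncertainty <- match.arg(uncertainty)
  if (is.null(pairs)) {
    pairs <- scenario_matrix(names(exposures), names(drivers_list))
    pairs <- pairs[pairs$feasible, ]
  }
  out <- list()
  for (r in seq_len(nrow(pairs))) {
    rcp <- pairs$rcp[r]; ssp <- pairs$ssp[r]
    assert_feasible(rcp, ssp)
    proj <- exposures[[rcp]]; drv <- drivers_list[[ssp]]
    if (is.null(proj)) stop("no exposure projection for ", rcp)
    if (is.null(drv)) stop("no drivers for ", ssp)
    for (d in decades) {
      b <- decade_mortality_bands(proj$decade_mean[[d]],
                                  proj$decade_sigma[[d]], drv, mortality,
                                  coeffs, d, mode = uncertainty)
      out[[length(out) + 1L]] <- data.frame(
        decade = d, rcp = rcp, ssp = ssp,
        central = b$central$total, low = b$low, high = b$high,
        crude_rate = crude_rate(b$central, drv, d),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Baseline-period reference burden
#'
#' Mortality evaluated with baseline exposure, baseline population and age
#' structure, and GDP frozen at baseline - the reference all sensitivity
#' deltas are measured against.
#'
#' @param baseline_exposure satellite-derived baseline `gridded_field`.
#' @param drivers a `scenario_drivers`.
#' @param mortality a `baseline_mortality`.
#' @param coeffs an `ier_coefficients`.
#' @return a `mortality_result`.
#' @export
baseline_burden <- function(baseline_exposure, drivers, mortality, coeffs) {
  decade_mortality(baseline_exposure, drivers, mortality, coeffs, "baseline",
                   gdp_growth = 1)
}

#' SA1: demographic transition alone
#'
#' Population (total and age structure) moves to the decade's values;
#' exposure and baseline mortality stay at baseline.  Positive deltas mean
#' demography alone raises the burden.
#'
#' @param drivers a `scenario_drivers`.
#' @param baseline_exposure,mortality,coeffs baseline-period state.
#' @param decades decades to evaluate (default the three representative
#'   decades).
#' @return data frame: study, ssp, decade, delta (deaths per year).
#' @export
sa1_demography <- function(drivers, baseline_exposure, mortality, coeffs,
                           decades = REPRESENTATIVE_DECADES) {
  ref <- baseline_burden(baseline_exposure, drivers, mortality, coeffs)
  delta <- vapply(decades, function(d)
    decade_mortality(baseline_exposure, drivers, mortality, coeffs, d,
                     gdp_growth = 1)$total - ref$total, numeric(1))
  data.frame(study = "SA1", ssp = drivers$ssp, decade = decades,
             delta = unname(delta), stringsAsFactors = FALSE)
}

#' SA2: epidemiologic transition alone
#'
#' Baseline mortality follows the decade's GDP; exposure and population
#' stay at baseline.  Negative deltas mean economic growth alone lowers
#' the burden.
#'
#' @inheritParams sa1_demography
#' @return data frame: study, ssp, decade, delta.
#' @export
sa2_epidemiology <- function(drivers, baseline_exposure, mortality, coeffs,
                             decades = REPRESENTATIVE_DECADES) {
  ref <- baseline_burden(baseline_exposure, drivers, mortality, coeffs)
  delta <- vapply(decades, function(d)
    decade_mortality(baseline_exposure, drivers, mortality, coeffs, d,
                     population = drivers$population[["baseline"]],
                     age_fractions = drivers$age_fractions["baseline", ],
                     gdp_growth = project_gdp(drivers, d)$growth)$total -
      ref$total, numeric(1))
  data.frame(study = "SA2", ssp = drivers$ssp, decade = decades,
             delta = unname(delta), stringsAsFactors = FALSE)
}

#' SA3: climate-change-induced meteorology
#'
#' Difference between the burden computed from the emission-only exposure
#' estimate (approach 2, AOD with fixed conversion factor) and from the
#' full estimate (approach 1, speciated sum); population and baseline
#' mortality follow the decade in both arms, so only exposure differs.
#' Positive values are deaths averted by the meteorological change.
#'
#' @param proj_approach1 `exposure_projection` with approach
#'   `"species_sum"`.
#' @param proj_approach2 `exposure_projection` with approach
#'   `"aod_ratio"`, same scenario.
#' @param drivers a `scenario_drivers`.
#' @param mortality,coeffs health-model inputs.
#' @param decades decades to evaluate.
#' @return data frame: study, ssp, rcp, decade, delta (positive =
#'   averted).
#' @export
sa3_meteorology <- function(proj_approach1, proj_approach2, drivers,
                            mortality, coeffs,
                            decades = REPRESENTATIVE_DECADES) {
  if (proj_approach1$approach != "species_sum" ||
      proj_approach2$approach != "aod_ratio")
    stop("approach mismatch: SA3 needs a species_sum and an aod_ratio ",
         "projection")
  if (proj_approach1$scenario != proj_approach2$scenario)
    stop("scenario mismatch between the two projections")
  delta <- vapply(decades, function(d)
    decade_mortality(proj_approach2$decade_mean[[d]], drivers, mortality,
                     coeffs, d)$total -
    decade_mortality(proj_approach1$decade_mean[[d]], drivers, mortality,
                     coeffs, d)$total, numeric(1))
  data.frame(study = "SA3", ssp = drivers$ssp,
             rcp = proj_approach1$scenario, decade = decades,
             delta = unname(delta), stringsAsFactors = FALSE)
}

#' Cap a decade's exposure to a national-mean target
#'
#' If the area-weighted land mean exceeds the target, every land cell is
#' scaled by `target / mean` so the national mean meets the target
#' exactly; otherwise the field is returned unchanged.
#'
#' @param exposure decadal `gridded_field`.
#' @param target national-mean concentration target, ug m-3 (> 0).
#' @return list with `capped` (`gridded_field`), logical `capped_applied`
#'   and the scaling `factor`.
#' @export
sa4_policy_cap <- function(exposure, target) {
  if (!is.numeric(target) || target <= 0)
    stop("policy target must be a positive concentration")
  nat <- land_mean(exposure)
  if (nat <= target)
    return(list(capped = exposure, capped_applied = FALSE, factor = 1))
  f <- target / nat
  list(capped = field_map(exposure, function(v) v * f),
       capped_applied = TRUE, factor = f)
}

#' SA4: staged air-quality policy caps
#'
#' Applies the interim-target cap of each representative decade (35, 25
#' and 15 ug m-3 national mean by near, distant and far future) and
#' reports the burden change; deltas are non-positive, their magnitude is
#' the averted mortality.
#'
#' @param proj an `exposure_projection`.
#' @param drivers,mortality,coeffs health-model inputs.
#' @param targets named vector decade -> national-mean target.
#' @return data frame: study, ssp, rcp, decade, delta (<= 0), averted.
#' @export
sa4_policy <- function(proj, drivers, mortality, coeffs,
                       targets = DEFAULT_IT_TARGETS) {
  rows <- lapply(names(targets), function(d) {
    cap <- sa4_policy_cap(proj$decade_mean[[d]], targets[[d]])
    unc <- decade_mortality(proj$decade_mean[[d]], drivers, mortality,
                            coeffs, d)$total
    cpd <- decade_mortality(cap$capped, drivers, mortality, coeffs, d)$total
    data.frame(study = "SA4", ssp = drivers$ssp, rcp = proj$scenario,
               decade = d, delta = cpd - unc, averted = unc - cpd,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cross-SSP range of the high-emission burden excess
#'
#' For one decade, the percentage increase of the high-emission pathway's
#' burden over the stabilization pathway's, per SSP, reduced to its
#' (min, max) across SSPs.
#'
#' @param burden data frame with columns `decade`, `ssp`, `rcp` and a
#'   value column (central burden).
#' @param decade decade label.
#' @param value_col name of the burden column (default `"central"`).
#' @param digits rounding of the returned bounds (default 1 decimal).
#' @return named numeric `c(min, max)` in percent.
#' @export
rcp_increase_range <- function(burden, decade, value_col = "central",
                               digits = 1) {
  b <- burden[burden$decade == decade, ]
  rcps <- sort(unique(b$rcp))
  if (length(rcps) != 2)
    stop("expected exactly two emission pathways, got ",
         paste(rcps, collapse = ", "))
  lo <- rcps[!grepl("85", rcps)]; hi <- rcps[grepl("85", rcps)]
  pct <- vapply(unique(b$ssp), function(s) {
    v45 <- b[b$ssp == s & b$rcp == lo, value_col]
    v85 <- b[b$ssp == s & b$rcp == hi, value_col]
    if (length(v45) != 1 || length(v85) != 1) return(NA_real_)
    100 * (v85 - v45) / v45
  }, numeric(1))
  pct <- pct[is.finite(pct)]
  if (!length(pct)) stop("no SSP present under both pathways for ", decade)
  round(c(min = min(pct), max = max(pct)), digits)
}

#' Formatted national reporting tables
#'
#' A decade x scenario burden table (millions per year, two decimals), a
#' sensitivity-delta table (thousands per year, one decimal) and the
#' per-decade cross-SSP (min, max) percentage excess of the high-emission
#' pathway.
#'
#' @param matrix_df output of [run_matrix()].
#' @param sa_df optional row-bound sensitivity data frames.
#' @param out_dir optional directory; when given the tables are written as
#'   UTF-8 CSV.
#' @return list with `burden` (wide data frame), `sensitivity`,
#'   `rcp_increase`.
#' @export
report_tables <- function(matrix_df, sa_df = NULL, out_dir = NULL) {
  md <- matrix_df
  md$cell <- sprintf("%.2f (± %.2f)", md$central / 1e6,
                     (md$high - md$low) / 2 / 1e6)
  md$col <- paste(md$ssp, md$rcp, sep = "_")
  wide <- stats::reshape(md[, c("decade", "col", "cell")],
                         idvar = "decade", timevar = "col",
                         direction = "wide")
  names(wide) <- sub("^cell\\.", "", names(wide))
  rownames(wide) <- NULL
  inc <- do.call(rbind, lapply(unique(matrix_df$decade), function(d) {
    r <- rcp_increase_range(matrix_df, d)
    data.frame(decade = d, min_pct = r[["min"]], max_pct = r[["max"]],
               stringsAsFactors = FALSE)
  }))
  sens <- NULL
  if (!is.null(sa_df)) {
    sens <- sa_df
    sens$delta_thousand <- round(sens$delta / 1e3, 1)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(wide, file.path(out_dir, "burden_table.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    utils::write.csv(inc, file.path(out_dir, "rcp_increase.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    if (!is.null(sens))
      utils::write.csv(sens, file.path(out_dir, "sensitivity_table.csv"),
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  list(burden = wide, sensitivity = sens, rcp_increase = inc)
}
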