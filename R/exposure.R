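# Per-model exposure estimation and ensemble projection.
#
# Two estimation approaches: (1) speciated mass summation, which carries
# both emission and meteorology signals, and (2) conversion of model AOD
# with a fixed baseline-period PM2.5/AOD ratio, which by construction
# responds to emissions only.  Per-model relative changes from the model's
# own baseline window are applied back onto the satellite-derived baseline
# surface, so systematic model biases cancel.

#' Speciated PM2.5 for one ensemble member record
#'
#' PM2.5 = BC + OA + SO4 + NH4 + 0.25 SS + 0.1 dust, with ammonium
#' inferred as NH4 = 36 SO4 / 96 (all sulphate assumed to be ammonium
#' sulphate).  If the member reports no combined OA, OA = POA + SOA; a
#' missing one of POA/SOA is imputed cell-wise with the reference member's
#' SOA/POA ratio.
#'
#' @param record a `model_pentad_record`.
#' @param reference the reference member's record for the same window;
#'   must report both POA and SOA.  May be omitted when `record` itself
#'   needs no imputation.
#' @return `gridded_field` of PM2.5 in ug m-3, plus an attribute
#'   `n_zero_ratio` counting cells where a zero reference denominator
#'   forced the imputed component to 0.
#' @export
pm25_from_species <- function(record, reference = NULL) {
  sp <- record$species
  for (need in c("BC", "SO4", "SS", "dust"))
    if (is.null(sp[[need]]))
      stop("missing required species '", need, "' in record ",
           record$model_id, "/", record$pentad)
  n_zero <- 0L
  if (!is.null(sp$OA)) {
    oa <- sp$OA$values
  } else if (!is.null(sp$POA) && !is.null(sp$SOA)) {
    oa <- sp$POA$values + sp$SOA$values
  } else {
    if (is.null(reference))
      stop("record reports only one organic component and no reference ",
           "member was supplied")
    rs <- reference$species
    if (is.null(rs$POA) || is.null(rs$SOA))
      stop("reference member must report both POA and SOA")
    if (!is.null(sp$POA)) {
      ratio <- rs$SOA$values / rs$POA$values   # SOA per unit POA
      bad <- !is.finite(ratio) | rs$POA$values == 0
      ratio[bad] <- 0; n_zero <- sum(bad & record$species$POA$mask)
      oa <- sp$POA$values * (1 + ratio)
    } else if (!is.null(sp$SOA)) {
      ratio <- rs$POA$values / rs$SOA$values
      bad <- !is.finite(ratio) | rs$SOA$values == 0
      ratio[bad] <- 0; n_zero <- sum(bad & record$species$SOA$mask)
      oa <- sp$SOA$values * (1 + ratio)
    } else {
      stop("record reports neither OA nor POA/SOA")
    }
  }
  nh4 <- 36 * sp$SO4$values / 96
  pm <- sp$BC$values + oa + sp$SO4$values + nh4 +
    0.25 * sp$SS$values + 0.1 * sp$dust$values
  out <- gridded_field(pm, sp$BC$grid, "ug m-3", sp$BC$mask)
  attr(out, "n_zero_ratio") <- n_zero
  out
}

#' Convert AOD to surface PM2.5 with a conversion factor
#'
#' @param aod `gridded_field` of aerosol optical depth.
#' @param eta a `conversion_factor` (see [compute_eta()]).
#' @return `gridded_field` of PM2.5 in ug m-3.
#' @export
pm25_from_aod <- function(aod, eta) {
  stopifnot(inherits(eta, "conversion_factor"))
  field_map2(aod, eta$eta, `*`, units = "ug m-3")
}

#' Baseline-period PM2.5/AOD conversion factor
#'
#' The ratio field is fixed thereafter for every future window: applying
#' it to projected AOD yields exposure driven by emissions alone.
#'
#' @param baseline_pm25,baseline_aod baseline `gridded_field`s.
#' @return object of class `conversion_factor` holding `eta`.
#' @export
compute_eta <- function(baseline_pm25, baseline_aod) {
  check_compatible(baseline_pm25, baseline_aod)
  bad <- baseline_aod$mask & baseline_aod$values <= 0
  if (any(bad))
    stop("non-positive AOD on ", sum(bad), " land cell(s); first at index ",
         which(bad)[1])
  eta <- field_map2(baseline_pm25, baseline_aod, `/`, units = "ug m-3 per AOD")
  structure(list(eta = eta), class = "conversion_factor")
}

#' Scale the satellite baseline by a member's relative change
#'
#' `proj = sat + sat * (model_pentad - model_baseline) / model_baseline`,
#' floored at zero (floored cells are counted in attribute `n_floored`).
#'
#' @param model_pentad_pm25,model_baseline_pm25 the member's estimate for
#'   the target window and for the baseline window.
#' @param satellite_baseline satellite-derived baseline exposure.
#' @return projected `gridded_field` in ug m-3.
#' @export
project_pentad <- function(model_pentad_pm25, model_baseline_pm25,
                           satellite_baseline) {
  check_compatible(model_pentad_pm25, model_baseline_pm25)
  check_compatible(model_pentad_pm25, satellite_baseline)
  if (any(model_baseline_pm25$mask & model_baseline_pm25$values <= 0))
    stop("model baseline PM2.5 is zero on a land cell; relative change undefined")
  rel <- (model_pentad_pm25$values - model_baseline_pm25$values) /
    model_baseline_pm25$values
  proj <- satellite_baseline$values * (1 + rel)
  n_floored <- sum(proj < 0 & satellite_baseline$mask)
  proj[proj < 0] <- 0
  out <- gridded_field(proj, satellite_baseline$grid, "ug m-3",
                       satellite_baseline$mask)
  attr(out, "n_floored") <- n_floored
  out
}

#' Cell-wise ensemble mean and spread
#'
#' @param member_fields list of >= 2 `gridded_field`s on a common grid.
#' @return list with `mean` and `sigma` (sample standard deviation, n-1).
#' @export
ensemble_summarize <- function(member_fields) {
  n <- length(member_fields)
  if (n < 2) stop("ensemble summary requires at least 2 members")
  for (f in member_fields[-1]) check_compatible(member_fields[[1]], f)
  g <- member_fields[[1]]$grid; mask <- member_fields[[1]]$mask
  arr <- vapply(member_fields, function(f) f$values,
                matrix(0, g$nlat, g$nlon))
  mu <- apply(arr, c(1, 2), mean)
  sg <- apply(arr, c(1, 2), stats::sd)
  list(mean = gridded_field(mu, g, member_fields[[1]]$units, mask),
       sigma = gridded_field(sg, g, member_fields[[1]]$units, mask))
}

# pentad pair belonging to each decade: decade d <- pentads (2d-1, 2d)
decade_pentads <- function(decade) {
  d <- match(decade, DECADE_LABELS)
  if (is.na(d)) stop("unknown decade label '", decade, "'")
  PENTAD_LABELS[c(2 * d - 1, 2 * d)]
}

#' Average two consecutive pentads into a decadal field
#'
#' @param pentad_a,pentad_b `gridded_field`s for two consecutive pentads.
#' @param labels optional character(2) of pentad labels; when supplied,
#'   non-consecutive labels raise an error.
#' @return cell-wise mean `gridded_field`.
#' @export
decade_average <- function(pentad_a, pentad_b, labels = NULL) {
  if (!is.null(labels)) {
    i <- match(labels, PENTAD_LABELS)
    if (anyNA(i) || i[2] != i[1] + 1L)
      stop("pentads ", paste(labels, collapse = ", "), " are not consecutive")
  }
  field_map2(pentad_a, pentad_b, function(a, b) (a + b) / 2)
}

#' Project exposure for one scenario under one estimation approach
#'
#' For every member and pentad the member's PM2.5 is estimated (speciated
#' sum or AOD conversion), its relative change from the member's own
#' baseline window is applied to the satellite baseline, and the member
#' projections are summarised cell-wise (mean, 1-sigma spread).  Decadal
#' fields average the two constituent pentads per member before
#' summarising.
#'
#' @param ensemble a `model_ensemble`.
#' @param satellite_baseline satellite-derived baseline `gridded_field`.
#' @param eta `conversion_factor`; required for `approach = "aod_ratio"`.
#' @param approach `"species_sum"` (approach 1) or `"aod_ratio"`
#'   (approach 2).
#' @param relative_change `"per_model"` (default: change computed per
#'   member, then summarised) or `"ensemble_mean"` (central field from the
#'   ensemble-mean relative change; spread still per member).
#' @param keep_members retain per-member decade fields (needed by some
#'   diagnostics; default `FALSE`).
#' @return object of class `exposure_projection` with per-pentad and
#'   per-decade `mean` and `sigma` field lists.
#' @export
project_exposure <- function(ensemble, satellite_baseline, eta = NULL,
                             approach = c("species_sum", "aod_ratio"),
                             relative_change = c("per_model", "ensemble_mean"),
                             keep_members = FALSE) {
  approach <- match.arg(approach)
  relative_change <- match.arg(relative_change)
  stopifnot(inherits(ensemble, "model_ensemble"))
  if (approach == "aod_ratio" && is.null(eta))
    stop("approach 'aod_ratio' requires a conversion factor (eta)")
  member_pm <- function(record, reference)
    if (approach == "species_sum") pm25_from_species(record, reference)
    else pm25_from_aod(record$aod, eta)
  nm <- length(ensemble$models)
  ref_base <- ensemble$baseline[[1]]
  member_proj <- lapply(seq_len(nm), function(m) {
    bl <- member_pm(ensemble$baseline[[m]], ref_base)
    lapply(ensemble$pentads, function(p) {
      rec <- ensemble$records[[m]][[p]]
      project_pentad(member_pm(rec, ensemble$records[[1]][[p]]), bl,
                     satellite_baseline)
    })
  })
  for (m in seq_len(nm)) names(member_proj[[m]]) <- ensemble$pentads
  pent_sum <- lapply(ensemble$pentads, function(p)
    ensemble_summarize(lapply(member_proj, `[[`, p)))
  names(pent_sum) <- ensemble$pentads
  if (relative_change == "ensemble_mean") {
    # central estimate from the mean relative change across the ensemble
    for (p in ensemble$pentads) {
      rels <- lapply(seq_len(nm), function(m) {
        bl <- member_pm(ensemble$baseline[[m]], ref_base)
        rec <- ensemble$records[[m]][[p]]
        (member_pm(rec, ensemble$records[[1]][[p]])$values - bl$values) /
          bl$values
      })
      mrel <- Reduce(`+`, rels) / nm
      v <- satellite_baseline$values * (1 + mrel); v[v < 0] <- 0
      pent_sum[[p]]$mean <- gridded_field(v, satellite_baseline$grid,
                                          "ug m-3", satellite_baseline$mask)
    }
  }
  member_dec <- lapply(member_proj, function(pl)
    stats::setNames(lapply(DECADE_LABELS, function(d) {
      pp <- decade_pentads(d)
      decade_average(pl[[pp[1]]], pl[[pp[2]]], labels = pp)
    }), DECADE_LABELS))
  dec_sum <- lapply(DECADE_LABELS, function(d)
    ensemble_summarize(lapply(member_dec, `[[`, d)))
  names(dec_sum) <- DECADE_LABELS
  if (relative_change == "ensemble_mean") {
    for (d in DECADE_LABELS) {
      pp <- decade_pentads(d)
      dec_sum[[d]]$mean <- decade_average(pent_sum[[pp[1]]]$mean,
                                          pent_sum[[pp[2]]]$mean, labels = pp)
    }
  }
  structure(list(
    scenario = ensemble$scenario, approach = approach,
    relative_change = relative_change,
    pentads = ensemble$pentads, decades = DECADE_LABELS,
    pentad_mean = lapply(pent_sum, `[[`, "mean"),
    pentad_sigma = lapply(pent_sum, `[[`, "sigma"),
    decade_mean = lapply(dec_sum, `[[`, "mean"),
    decade_sigma = lapply(dec_sum, `[[`, "sigma"),
    member_decade = if (keep_members) member_dec else NULL
  ), class = "exposure_projection")
}

#' Meteorology contribution as the difference between approaches
#'
#' Per-decade cell-wise difference (approach 2 minus approach 1).
#' Positive values mean climate-change-induced meteorology suppresses
#' exposure (the emission-only estimate sits above the full estimate).
#'
#' @param proj_approach2,proj_approach1 `exposure_projection`s of the same
#'   scenario.
#' @return named list of per-decade difference `gridded_field`s.
#' @export
meteorology_delta <- function(proj_approach2, proj_approach1) {
  if (proj_approach2$scenario != proj_approach1$scenario)
    stop("scenario mismatch between the two projections")
  stats::setNames(lapply(proj_approach2$decades, function(d)
    field_map2(proj_approach2$decade_mean[[d]],
               proj_approach1$decade_mean[[d]], `-`)),
    proj_approach2$decades)
}
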