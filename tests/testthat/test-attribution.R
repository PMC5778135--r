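# shared small-world state for the attribution tests
attr_state <- local({
  cfg <- small_config(noise_sd = 0, n_models = 3)
  base <- generate_baseline_fields(cfg)
  eta <- compute_eta(base$pm25, base$aod)
  projections <- lapply(names(cfg$scenario_trends), function(sc) {
    ens <- generate_model_ensemble(cfg, sc)
    list(species_sum = project_exposure(ens, base$pm25,
                                        approach = "species_sum"),
         aod_ratio = project_exposure(ens, base$pm25, eta,
                                      approach = "aod_ratio"))
  })
  names(projections) <- names(cfg$scenario_trends)
  drivers <- lapply(names(cfg$ssp_population),
                    function(s) generate_scenario_drivers(cfg, s))
  names(drivers) <- names(cfg$ssp_population)
  list(cfg = cfg, base = base, eta = eta, projections = projections,
       drivers = drivers, mortality = generate_baseline_mortality(cfg),
       coeffs = default_ier_coefficients())
})

test_that("the feasible scenario matrix has nine cells and refuses the tenth", {
  m <- scenario_matrix()
  expect_equal(nrow(m), 10)
  expect_equal(sum(m$feasible), 9)
  expect_false(m$feasible[m$rcp == "rcp85" & m$ssp == "SSP1"])
  st <- attr_state
  expect_error(
    run_matrix(lapply(st$projections, `[[`, "species_sum"), st$drivers,
               st$mortality, st$coeffs, decades = "2031-2040",
               pairs = data.frame(rcp = "rcp85", ssp = "SSP1")),
    "refusing infeasible")
})

test_that("matrix burden responds to exposure and drivers as expected", {
  st <- attr_state
  exposures <- lapply(st$projections, `[[`, "species_sum")
  decades <- c("2031-2040", "2061-2070", "2091-2100")
  mat <- run_matrix(exposures, st$drivers, st$mortality, st$coeffs,
                    decades = decades)
  expect_equal(nrow(mat), 9 * length(decades))
  # rerunning is bit-identical (no hidden state)
  mat2 <- run_matrix(exposures, st$drivers, st$mortality, st$coeffs,
                     decades = decades)
  expect_identical(mat, mat2)
  # higher-exposure pathway with monotone-population SSP3 dominates
  for (d in decades) {
    sub <- mat[mat$decade == d, ]
    top <- sub[which.max(sub$central), ]
    expect_equal(top$ssp, "SSP3")
    expect_equal(top$rcp, "rcp85")
  }
  # degenerate matrix: identical drivers and exposures -> equal cells
  same_drv <- stats::setNames(rep(list(st$drivers$SSP2), 5),
                              names(st$drivers))
  same_exp <- stats::setNames(rep(list(exposures$rcp45), 2),
                              names(exposures))
  flat <- run_matrix(same_exp, same_drv, st$mortality, st$coeffs,
                     decades = "2031-2040")
  expect_lt(diff(range(flat$central)), 1e-9 * flat$central[1])
  # raising exposure in one pathway raises that column for every SSP
  boosted <- exposures
  boosted$rcp45 <- exposures$rcp85
  boosted$rcp45$scenario <- "rcp45"
  boosted$rcp45$decade_mean <- lapply(exposures$rcp85$decade_mean,
                                      function(f)
                                        field_map(f, function(v) v * 1.3))
  up <- run_matrix(boosted, st$drivers, st$mortality, st$coeffs,
                   decades = "2031-2040")
  for (s in paste0("SSP", 2:5)) {
    expect_gt(up$central[up$ssp == s & up$rcp == "rcp45"],
              up$central[up$ssp == s & up$rcp == "rcp85"])
  }
})

test_that("SA1 isolates demography with exact linear identities", {
  st <- attr_state
  drv <- st$drivers$SSP2
  ref <- baseline_burden(st$base$pm25, drv, st$mortality, st$coeffs)
  # decade population identical to baseline -> zero delta
  d <- "2031-2040"
  drv0 <- override_drivers(drv, d,
                           population = drv$population[["baseline"]],
                           age_fractions = drv$age_fractions["baseline", ])
  sa0 <- sa1_demography(drv0, st$base$pm25, st$mortality, st$coeffs, d)
  expect_equal(sa0$delta, 0, tolerance = 1e-9 * ref$total)
  # uniform doubling at fixed age structure -> +100% of the reference
  drv2 <- override_drivers(drv, d,
    population = field_map(drv$population[["baseline"]],
                           function(v) 2 * v),
    age_fractions = drv$age_fractions["baseline", ])
  sa2x <- sa1_demography(drv2, st$base$pm25, st$mortality, st$coeffs, d)
  expect_equal(sa2x$delta, ref$total, tolerance = 1e-9 * ref$total)
  # aging alone raises the burden when risk grows with age
  nb <- length(pm25burden:::AGE_BINS)
  rising <- st$coeffs$table
  rising$alpha[rising$disease == "IHD"] <- seq(0.3, 1.2, length.out = nb)
  rising$alpha[rising$disease == "stroke"] <- seq(0.25, 1.0,
                                                  length.out = nb)
  co_rising <- ier_coefficients(rising)
  fr_old <- drv$age_fractions["baseline", ]
  fr_old <- rev(as.numeric(fr_old)); names(fr_old) <- pm25burden:::AGE_BINS
  drv_old <- override_drivers(drv, d,
                              population = drv$population[["baseline"]],
                              age_fractions = fr_old)
  sa_old <- sa1_demography(drv_old, st$base$pm25, st$mortality, co_rising, d)
  expect_gt(sa_old$delta, 0)
})

test_that("SA2 isolates the epidemiologic transition", {
  st <- attr_state
  drv <- st$drivers$SSP2
  ref <- baseline_burden(st$base$pm25, drv, st$mortality, st$coeffs)
  # GDP frozen at baseline -> zero delta
  drv0 <- drv
  drv0$gdp[drv0$gdp$decade == "2061-2070",
           c("gdp_ppp_iiasa", "gdp_ppp_oecd")] <- drv0$gdp$gdp_ppp_ref[1]
  sa0 <- sa2_epidemiology(drv0, st$base$pm25, st$mortality, st$coeffs,
                          "2061-2070")
  expect_equal(sa0$delta, 0, tolerance = 1e-12 * ref$total)
  # rising GDP with a decreasing rate curve lowers the burden each decade
  sa <- sa2_epidemiology(drv, st$base$pm25, st$mortality, st$coeffs,
                         c("2031-2040", "2061-2070", "2091-2100"))
  expect_true(all(sa$delta < 0))
  # linearity in the baseline rate: halving the rates halves the burden
  mort_half <- st$mortality
  mort_half$table$a <- mort_half$table$a / 2
  mort_half$table$rate <- mort_half$table$rate / 2
  half <- baseline_burden(st$base$pm25, drv, mort_half, st$coeffs)
  expect_equal(half$total - ref$total, -0.5 * ref$total,
               tolerance = 1e-12 * ref$total)
})

test_that("joint demographic-epidemiologic shift decomposes additively", {
  st <- attr_state
  drv <- st$drivers$SSP4
  ref <- baseline_burden(st$base$pm25, drv, st$mortality, st$coeffs)$total
  cP <- 1.8; cY <- 0.6
  d <- "2061-2070"
  pop2 <- field_map(drv$population[["baseline"]], function(v) cP * v)
  mort2 <- st$mortality
  mort2$table$a <- cY * mort2$table$a
  joint <- decade_mortality(st$base$pm25, drv, mort2, st$coeffs, d,
                            population = pop2,
                            age_fractions = drv$age_fractions["baseline", ],
                            gdp_growth = 1)$total - ref
  sa1 <- (cP - 1) * ref
  sa2 <- (cY - 1) * ref
  interaction <- (cP - 1) * (cY - 1) * ref
  expect_equal(joint, sa1 + sa2 + interaction, tolerance = 1e-9)
})

test_that("SA3 recovers the planted meteorological signal", {
  st <- attr_state
  # zero meteorology term -> exactly zero delta
  cfg0 <- small_config(noise_sd = 0.1, meteorology_effect = flat_met())
  base0 <- generate_baseline_fields(cfg0)
  eta0 <- compute_eta(base0$pm25, base0$aod)
  ens0 <- generate_model_ensemble(cfg0, "rcp45")
  p1 <- project_exposure(ens0, base0$pm25, approach = "species_sum")
  p2 <- project_exposure(ens0, base0$pm25, eta0, approach = "aod_ratio")
  drv0 <- generate_scenario_drivers(cfg0, "SSP2")
  mort0 <- generate_baseline_mortality(cfg0)
  sa0 <- sa3_meteorology(p1, p2, drv0, mort0, st$coeffs)
  expect_equal(sa0$delta, rep(0, 3), tolerance = 1e-6)
  # planted suppression of increasing magnitude -> positive, monotone SA3
  run_planted <- function(supp) {
    cfg <- small_config(noise_sd = 0,
                        meteorology_effect = flat_met(supp, supp))
    base <- generate_baseline_fields(cfg)
    eta <- compute_eta(base$pm25, base$aod)
    ens <- generate_model_ensemble(cfg, "rcp45")
    q1 <- project_exposure(ens, base$pm25, approach = "species_sum")
    q2 <- project_exposure(ens, base$pm25, eta, approach = "aod_ratio")
    sa3_meteorology(q1, q2, generate_scenario_drivers(cfg, "SSP2"),
                    generate_baseline_mortality(cfg), st$coeffs)$delta
  }
  weak <- run_planted(-0.05)
  strong <- run_planted(-0.15)
  expect_true(all(weak > 0))
  expect_true(all(strong > weak))
  expect_error(sa3_meteorology(p1, p1, drv0, mort0, st$coeffs),
               "approach mismatch")
})

test_that("SA4 policy caps hit the target mean and avert deaths", {
  st <- attr_state
  g <- st$cfg$grid
  over <- field_map(st$base$pm25, function(v) v * 2)  # mean 69
  cap <- sa4_policy_cap(over, 35)
  expect_true(cap$capped_applied)
  expect_equal(land_mean(cap$capped), 35, tolerance = 1e-9 * 35)
  expect_equal(cap$factor, 35 / land_mean(over), tolerance = 1e-12)
  under <- field_map(st$base$pm25, function(v) v * 0.3)  # mean ~10
  cap2 <- sa4_policy_cap(under, 15)
  expect_false(cap2$capped_applied)
  expect_identical(cap2$capped$values, under$values)
  expect_error(sa4_policy_cap(over, -1), "positive")
  sa <- sa4_policy(st$projections$rcp85$species_sum, st$drivers$SSP3,
                   st$mortality, st$coeffs)
  expect_true(all(sa$averted >= 0))
  expect_true(all(sa$delta <= 0))
  # the far-future 15 ug target forces capping here, so deaths are averted
  expect_gt(sa$averted[sa$decade == "2031-2040"], 0)
})

test_that("reporting reproduces ranges derivable from a published table", {
  tab <- utils::read.csv(pm25burden_extdata("published_burden_table.csv"),
                         stringsAsFactors = FALSE)
  near <- rcp_increase_range(tab, "2031-2040")
  expect_equal(unname(near), c(2.4, 4.0))
  far <- rcp_increase_range(tab, "2091-2100", digits = 3)
  expect_equal(unname(far), c(28.571, 38.889), tolerance = 1e-3)
  # equal pathway columns -> zero excess
  eq <- tab; eq$central[eq$rcp == "rcp85"] <- eq$central[eq$rcp == "rcp45"]
  expect_equal(unname(rcp_increase_range(eq, "2061-2070")), c(0, 0))
  # formatted tables and totals consistency
  st <- attr_state
  exposures <- lapply(st$projections, `[[`, "species_sum")
  mat <- run_matrix(exposures, st$drivers, st$mortality, st$coeffs,
                    decades = c("2031-2040", "2091-2100"))
  rep <- report_tables(mat)
  expect_equal(nrow(rep$burden), 2)
  expect_equal(ncol(rep$burden), 10)   # decade + 9 feasible cells
  expect_equal(nrow(rep$rcp_increase), 2)
})
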