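test_that("IER relative risk obeys its closed-form identities", {
  co <- ier_coefficients(data.frame(
    disease = c("COPD", "LC", rep("IHD", 12), rep("stroke", 12)),
    age_bin = c("", "", pm25burden:::AGE_BINS, pm25burden:::AGE_BINS),
    alpha = c(1.0, 0.6, rep(0.9, 12), rep(0.8, 12)),
    gamma = c(0.07, 0.04, rep(0.07, 12), rep(0.065, 12)),
    delta = c(0.6, 0.75, rep(0.6, 12), rep(0.62, 12)),
    stringsAsFactors = FALSE))
  # no excess risk at or below the counterfactual
  expect_equal(ier_relative_risk(5.8, co, "COPD"), 1)
  expect_equal(ier_relative_risk(c(0, 2, 5.8), co, "COPD"), rep(1, 3))
  # saturation at 1 + alpha
  expect_equal(ier_relative_risk(1e9, co, "COPD"), 2, tolerance = 1e-9)
  expect_lte(ier_relative_risk(500, co, "COPD"), 2)
  # frozen spot value: 1 + 1*(1 - exp(-0.07 * 29.2^0.6))
  expect_equal(ier_relative_risk(35, co, "COPD"), 1.4114322985,
               tolerance = 1e-9)
  expect_error(ier_relative_risk(35, co, "IHD"), "age_bin")
  expect_equal(ier_relative_risk(35, co, "IHD", "40-44"),
               1 + 0.9 * (1 - exp(-0.07 * 29.2^0.6)), tolerance = 1e-12)
})

test_that("relative risk is monotone in concentration for random coefficients", {
  set.seed(101)
  for (i in 1:25) {
    tab <- data.frame(
      disease = c("COPD", "LC", rep("IHD", 12), rep("stroke", 12)),
      age_bin = c("", "", pm25burden:::AGE_BINS, pm25burden:::AGE_BINS),
      alpha = runif(26, 0.05, 3), gamma = runif(26, 0.005, 0.5),
      delta = runif(26, 0.2, 1.5), stringsAsFactors = FALSE)
    co <- ier_coefficients(tab)
    pm <- sort(runif(40, 0, 300))
    rr <- ier_relative_risk(pm, co, "COPD")
    expect_true(all(diff(rr) >= -1e-12))
    expect_true(all(rr >= 1 & rr <= 1 + tab$alpha[1] + 1e-12))
  }
})

test_that("attributable deaths follow the attributable-fraction relation", {
  expect_equal(attributable_deaths(2, 0.01, 1e5), 500)
  expect_equal(attributable_deaths(1, 0.02, 1e6), 0)
  expect_equal(attributable_deaths(1.7, 0.01, 2e5),
               2 * attributable_deaths(1.7, 0.01, 1e5))
  expect_error(attributable_deaths(0.9, 0.01, 1e5), "below 1")
  rr <- seq(1, 30, by = 0.5)
  af <- (rr - 1) / rr
  expect_true(all(af >= 0 & af < 1))
})

test_that("age disaggregation conserves the total population", {
  cfg <- small_config()
  d <- generate_scenario_drivers(cfg, "SSP2")
  bins <- age_disaggregate(d, "2041-2050")
  tot <- Reduce(`+`, lapply(bins, `[[`, "values"))
  expect_equal(tot, d$population[["2041-2050"]]$values, tolerance = 1e-9)
  # hand case: two effective bins
  d2 <- d
  d2$age_fractions["2041-2050", ] <- c(0.6, 0.4, rep(0, 10))
  bins2 <- age_disaggregate(d2, "2041-2050")
  cell <- which(d$mask)[1]
  p <- d$population[["2041-2050"]]$values[cell]
  expect_equal(bins2[[1]]$values[cell], 0.6 * p)
  expect_equal(bins2[[2]]$values[cell], 0.4 * p)
  d2$age_fractions["2041-2050", 1] <- 0.58
  expect_error(age_disaggregate(d2, "2041-2050"), "sum to")
})

test_that("GDP projection applies the mean-PPP growth factor uniformly", {
  drv <- list(gdp = data.frame(decade = c("baseline", "2031-2040"),
                               gdp_ppp_iiasa = c(10, 30),
                               gdp_ppp_oecd = c(10, 30),
                               gdp_ppp_ref = 10))
  expect_equal(project_gdp(drv, "2031-2040", 100)$zone_gdp, 300)
  drv$gdp$gdp_ppp_iiasa[2] <- 12; drv$gdp$gdp_ppp_oecd[2] <- 8
  expect_equal(project_gdp(drv, "2031-2040", 100)$zone_gdp, 100)
  expect_equal(project_gdp(drv, "baseline")$growth, 1)
  drv$gdp$gdp_ppp_ref <- 0
  expect_error(project_gdp(drv, "2031-2040"), "non-positive reference")
})

test_that("GDP-adjusted mortality is an anchored scale-invariant power law", {
  cfg <- small_config()
  mort <- generate_baseline_mortality(cfg)
  g0 <- mort$zone_gdp$gdp
  for (j in c("COPD", "IHD", "stroke")) {
    y0 <- adjust_baseline_mortality(mort, g0, j)
    tab <- mort$table[mort$table$disease == j, ]
    expect_equal(unname(y0), tab$rate, tolerance = 1e-12)  # anchoring
    b <- tab$b[1]
    for (s in c(1, 3.7)) {
      r <- adjust_baseline_mortality(mort, 2 * s * g0, j) /
        adjust_baseline_mortality(mort, s * g0, j)
      expect_equal(unname(r), rep(2^(-b), length(g0)), tolerance = 1e-12)
    }
  }
  expect_equal(unname(adjust_baseline_mortality(mort, 5 * g0, "LC")),
               mort$table$rate[mort$table$disease == "LC"],
               tolerance = 1e-12)
})

test_that("decade mortality matches a single-cell hand computation", {
  g1 <- grid_spec(10, 11, 70, 71, 1)
  expo <- uniform_field(35, g1)
  pop <- uniform_field(1e6, g1, units = "persons")
  co <- default_ier_coefficients()
  zone_map <- matrix(1L, 1, 1)
  tab <- do.call(rbind, lapply(pm25burden:::DISEASES, function(j)
    data.frame(zone = 1L, disease = j, rate = 0.002, a = 0.002, b = 0,
               se_a = 0, se_b = 0, stringsAsFactors = FALSE)))
  mort <- structure(list(table = tab, zone_map = zone_map,
                         zone_gdp = data.frame(zone = 1L, gdp = 1),
                         grid = g1, mask = matrix(TRUE, 1, 1)),
                    class = "baseline_mortality")
  fr <- rep(1 / 12, 12); names(fr) <- pm25burden:::AGE_BINS
  drv <- list(ssp = "X", population = list("2031-2040" = pop),
              age_fractions = matrix(fr, 1, 12,
                                     dimnames = list("2031-2040",
                                                     pm25burden:::AGE_BINS)),
              gdp = data.frame(decade = "2031-2040", gdp_ppp_iiasa = 1,
                               gdp_ppp_oecd = 1, gdp_ppp_ref = 1),
              pop_total = c("2031-2040" = 1e6))
  res <- decade_mortality(expo, drv, mort, co, "2031-2040")
  # independent evaluation of the chain for each disease
  af <- function(a, gm, dl) {
    rr <- 1 + a * (1 - exp(-gm * (35 - 5.8)^dl)); (rr - 1) / rr
  }
  want_copd <- 0.002 * af(0.50, 0.05, 0.70) * 1e6
  want_lc <- 0.002 * af(0.60, 0.04, 0.75) * 1e6
  ihd <- co$table[co$table$disease == "IHD", ]
  want_ihd <- sum(0.002 * af(ihd$alpha, ihd$gamma, ihd$delta) * 1e6 / 12)
  expect_equal(unname(res$by_disease[["COPD"]]), want_copd,
               tolerance = 1e-12)
  expect_equal(unname(res$by_disease[["LC"]]), want_lc, tolerance = 1e-12)
  expect_equal(unname(res$by_disease[["IHD"]]), want_ihd, tolerance = 1e-12)
  # exposure at the counterfactual produces zero burden
  expect_equal(decade_mortality(uniform_field(5.8, g1), drv, mort, co,
                                "2031-2040")$total, 0)
  expect_equal(crude_rate(res, drv, "2031-2040"), 1e5 * res$total / 1e6)
})

test_that("vectorized decade mortality equals a brute-force triple loop", {
  cfg <- small_config(lat_min = 10, lat_max = 16, lon_min = 70,
                      lon_max = 76, resolution = 1, n_models = 3)
  base <- generate_baseline_fields(cfg)
  drv <- generate_scenario_drivers(cfg, "SSP2")
  mort <- generate_baseline_mortality(cfg)
  co <- default_ier_coefficients()
  d <- "2041-2050"
  res <- decade_mortality(base$pm25, drv, mort, co, d)
  # oracle: per-cell, per-disease, per-age loop straight from the formulas
  g <- project_gdp(drv, d)$growth
  fr <- drv$age_fractions[d, ]
  P <- drv$population[[d]]$values
  total <- 0
  for (i in seq_len(cfg$grid$nlat)) for (jj in seq_len(cfg$grid$nlon)) {
    if (!cfg$mask[i, jj]) next
    z <- mort$zone_map[i, jj]
    pm <- base$pm25$values[i, jj]
    for (dis in pm25burden:::DISEASES) {
      row <- mort$table[mort$table$disease == dis & mort$table$zone == z, ]
      y <- row$a * (mort$zone_gdp$gdp[mort$zone_gdp$zone == z] * g)^(-row$b)
      if (dis %in% c("IHD", "stroke")) {
        for (bin in pm25burden:::AGE_BINS) {
          rr <- ier_relative_risk(pm, co, dis, bin)
          total <- total + y * (rr - 1) / rr * P[i, jj] * fr[[bin]]
        }
      } else {
        rr <- ier_relative_risk(pm, co, dis)
        total <- total + y * (rr - 1) / rr * P[i, jj]
      }
    }
  }
  expect_equal(res$total, total, tolerance = 1e-9)
  # aggregation order does not matter: the per-grid field re-sums to it
  expect_equal(sum(res$field$values), res$total, tolerance = 1e-9)
  half <- sum(res$field$values[1:3, ]) + sum(res$field$values[4:6, ])
  expect_equal(half, res$total, tolerance = 1e-9)
})

test_that("uncertainty bands are ordered, collapse at zero spread, and nest", {
  cfg0 <- small_config(
    noise_sd = 0,
    mortality_coeff = within(default_mortality_coeff(), {
      se_b <- 0 * se_b; se_rate_frac <- 0 * se_rate_frac
    }))
  base <- generate_baseline_fields(cfg0)
  drv <- generate_scenario_drivers(cfg0, "SSP2")
  mort0 <- generate_baseline_mortality(cfg0)
  co <- default_ier_coefficients()
  zero_sigma <- uniform_field(0, cfg0$grid, mask = cfg0$mask)
  b0 <- decade_mortality_bands(base$pm25, zero_sigma, drv, mort0, co,
                               "2031-2040")
  expect_equal(b0$low, b0$central$total)
  expect_equal(b0$high, b0$central$total)
  # with spread and coefficient error the band is ordered and widens
  cfg <- small_config(noise_sd = 0)
  mort <- generate_baseline_mortality(cfg)
  s1 <- uniform_field(2, cfg$grid, mask = cfg$mask)
  s2 <- uniform_field(6, cfg$grid, mask = cfg$mask)
  b1 <- decade_mortality_bands(base$pm25, s1, drv, mort, co, "2031-2040")
  b2 <- decade_mortality_bands(base$pm25, s2, drv, mort, co, "2031-2040")
  expect_lte(b1$low, b1$central$total)
  expect_lte(b1$central$total, b1$high)
  expect_gt(b2$high - b2$low, b1$high - b1$low)
  # joint band contains the exposure-only band
  lo_exp <- decade_mortality(field_map2(base$pm25, s1,
                                        function(m, s) pmax(m - s, 0)),
                             drv, mort, co, "2031-2040")$total
  hi_exp <- decade_mortality(field_map2(base$pm25, s1, `+`), drv, mort, co,
                             "2031-2040")$total
  expect_lte(b1$low, lo_exp)
  expect_gte(b1$high, hi_exp)
  # quadrature mode stays ordered
  bq <- decade_mortality_bands(base$pm25, s1, drv, mort, co, "2031-2040",
                               mode = "quadrature")
  expect_lte(bq$low, bq$central$total)
  expect_gte(bq$high, bq$central$total)
})

test_that("crude rate is invariant under uniform population scaling", {
  cfg <- small_config()
  base <- generate_baseline_fields(cfg)
  drv <- generate_scenario_drivers(cfg, "SSP4")
  mort <- generate_baseline_mortality(cfg)
  co <- default_ier_coefficients()
  d <- "2061-2070"
  r1 <- decade_mortality(base$pm25, drv, mort, co, d)
  drv2 <- drv
  drv2$population[[d]] <- field_map(drv$population[[d]], function(v) 2 * v)
  drv2$pop_total[[d]] <- 2 * drv$pop_total[[d]]
  r2 <- decade_mortality(base$pm25, drv2, mort, co, d)
  expect_equal(r2$total, 2 * r1$total, tolerance = 1e-12)
  expect_equal(crude_rate(r2, drv2, d), crude_rate(r1, drv, d),
               tolerance = 1e-12)
  drv2$pop_total[[d]] <- 0
  expect_error(crude_rate(r2, drv2, d), "non-positive")
})

test_that("frozen demography and GDP reproduce the baseline burden", {
  cfg <- small_config()
  base <- generate_baseline_fields(cfg)
  drv <- generate_scenario_drivers(cfg, "SSP1")
  mort <- generate_baseline_mortality(cfg)
  co <- default_ier_coefficients()
  ref <- baseline_burden(base$pm25, drv, mort, co)
  same <- decade_mortality(base$pm25, drv, mort, co, "2051-2060",
                           population = drv$population[["baseline"]],
                           age_fractions = drv$age_fractions["baseline", ],
                           gdp_growth = 1)
  expect_equal(same$total, ref$total, tolerance = 1e-12)
})
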