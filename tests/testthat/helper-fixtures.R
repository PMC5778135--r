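# Shared fixture builders.  Tests run on deliberately small domains; the
# statistical structure (trend, noise, hotspot, pathway shapes) matches
# the full-scale defaults.

small_config <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(
    seed = seed,
    lat_min = 10, lat_max = 20, lon_min = 70, lon_max = 80,
    resolution = 1,
    n_models = 4,
    hotspot = list(lat = 15, lon = 75, radius = 2, amplitude = 30),
    noise_sd = 0.1)
  do.call(synthetic_config, utils::modifyList(defaults, args))
}

# scenario trend / meteorology lists shaped for the 18-pentad calendar
flat_trends <- function(rcp45 = 1, rcp85 = 1) {
  list(rcp45 = rep(rcp45, 18), rcp85 = rep(rcp85, 18))
}
flat_met <- function(rcp45 = 0, rcp85 = 0) {
  list(rcp45 = rep(rcp45, 18), rcp85 = rep(rcp85, 18))
}

uniform_field <- function(value, grid, units = "ug m-3", mask = NULL) {
  gridded_field(matrix(value, grid$nlat, grid$nlon), grid, units, mask)
}

# drivers with hand-set population/age structure on an existing template
override_drivers <- function(drv, decade, population = NULL,
                             age_fractions = NULL, pop_total = NULL) {
  if (!is.null(population)) drv$population[[decade]] <- population
  if (!is.null(age_fractions)) drv$age_fractions[decade, ] <- age_fractions
  if (!is.null(pop_total)) drv$pop_total[[decade]] <- pop_total
  drv
}
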