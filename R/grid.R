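# Grid and field primitives shared by every pipeline stage.

#' Define a regular latitude/longitude grid
#'
#' All rasters in the pipeline live on one regular cell-centred grid.
#' Values are stored as matrices with rows indexing latitude (south to
#' north) and columns indexing longitude (west to east).
#'
#' @param lat_min,lat_max,lon_min,lon_max bounding box edges in degrees.
#' @param resolution cell size in degrees; must divide both extents exactly.
#' @return an object of class `grid_spec` with cell-centre coordinate
#'   vectors `lat` and `lon`.
#' @export
grid_spec <- function(lat_min = 6.5, lat_max = 37.5,
                      lon_min = 67.5, lon_max = 97.5,
                      resolution = 0.5) {
  if (!is.numeric(resolution) || length(resolution) != 1 || resolution <= 0)
    stop("configuration error: resolution must be a positive number")
  if (lat_max <= lat_min || lon_max <= lon_min)
    stop("configuration error: degenerate bounding box")
  nlat <- (lat_max - lat_min) / resolution
  nlon <- (lon_max - lon_min) / resolution
  if (abs(nlat - round(nlat)) > 1e-8 || abs(nlon - round(nlon)) > 1e-8)
    stop("configuration error: resolution does not divide the bounding box exactly")
  nlat <- as.integer(round(nlat)); nlon <- as.integer(round(nlon))
  structure(list(
    lat_min = lat_min, lat_max = lat_max,
    lon_min = lon_min, lon_max = lon_max,
    resolution = resolution, nlat = nlat, nlon = nlon,
    lat = lat_min + resolution * (seq_len(nlat) - 0.5),
    lon = lon_min + resolution * (seq_len(nlon) - 0.5)
  ), class = "grid_spec")
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a[c("lat_min", "lat_max", "lon_min", "lon_max", "resolution")],
                   b[c("lat_min", "lat_max", "lon_min", "lon_max", "resolution")],
                   tolerance = 1e-10))
}

#' Construct a gridded field
#'
#' @param values numeric matrix `nlat x nlon` (south-to-north rows).
#' @param grid a [grid_spec()].
#' @param units physical units string (mandatory; validated on IO).
#' @param mask logical land mask of the same shape; `TRUE` = land.
#' @return object of class `gridded_field`.
#' @export
gridded_field <- function(values, grid, units, mask = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  values <- as.matrix(values)
  if (!all(dim(values) == c(grid$nlat, grid$nlon)))
    stop("field dimensions do not match the grid (", grid$nlat, " x ", grid$nlon, ")")
  if (missing(units) || is.null(units) || !nzchar(units))
    stop("format error: missing mandatory 'units' attribute")
  if (is.null(mask)) mask <- matrix(TRUE, grid$nlat, grid$nlon)
  mask <- matrix(as.logical(mask), grid$nlat, grid$nlon)
  if (!any(mask)) stop("configuration error: empty land mask")
  structure(list(values = values, grid = grid, units = units, mask = mask),
            class = "gridded_field")
}

#' @export
print.gridded_field <- function(x, ...) {
  cat(sprintf("<gridded_field %dx%d [%s], %d land cells, land mean %.4g>\n",
              x$grid$nlat, x$grid$nlon, x$units, sum(x$mask),
              land_mean(x)))
  invisible(x)
}

check_compatible <- function(a, b) {
  stopifnot(inherits(a, "gridded_field"), inherits(b, "gridded_field"))
  if (!same_grid(a$grid, b$grid))
    stop("grid mismatch: fields are not on the same grid")
  if (!identical(a$mask, b$mask))
    stop("grid mismatch: fields do not share a land mask")
  invisible(TRUE)
}

#' Cell-wise arithmetic between compatible fields
#'
#' @param a,b `gridded_field`s on an identical grid and mask.
#' @param f binary function applied cell-wise.
#' @param units units of the result (defaults to `a$units`).
#' @return a `gridded_field`.
#' @export
field_map2 <- function(a, b, f, units = a$units) {
  check_compatible(a, b)
  gridded_field(f(a$values, b$values), a$grid, units, a$mask)
}

#' Transform one field cell-wise
#' @param a a `gridded_field`.
#' @param f unary function.
#' @param units result units.
#' @export
field_map <- function(a, f, units = a$units) {
  gridded_field(f(a$values), a$grid, units, a$mask)
}

#' Area-weighted national mean over land
#'
#' National averages are weighted by `cos(latitude)` so each cell counts in
#' proportion to its physical area.
#'
#' @param field a `gridded_field`.
#' @return scalar land mean.
#' @export
land_mean <- function(field) {
  w <- cos(field$grid$lat * pi / 180)
  wm <- matrix(w, field$grid$nlat, field$grid$nlon) * field$mask
  sum(field$values * wm) / sum(wm)
}

#' Procedural land mask for the synthetic study domain
#'
#' A deterministic smooth blob inscribed in the bounding box, standing in
#' for a national landmass.  Depends only on the grid, never on the seed,
#' so every generated raster shares it.
#'
#' @param grid a [grid_spec()].
#' @return logical matrix, `TRUE` on land.
#' @export
default_land_mask <- function(grid) {
  u <- (grid$lat - (grid$lat_min + grid$lat_max) / 2) / ((grid$lat_max - grid$lat_min) / 2)
  v <- (grid$lon - (grid$lon_min + grid$lon_max) / 2) / ((grid$lon_max - grid$lon_min) / 2)
  U <- matrix(u, grid$nlat, grid$nlon)
  V <- matrix(v, grid$nlat, grid$nlon, byrow = TRUE)
  th <- atan2(V, U)
  r2 <- U^2 + V^2
  m <- r2 <= (0.95 + 0.12 * sin(3 * th) + 0.08 * cos(5 * th))^2
  if (!any(m)) m <- matrix(TRUE, grid$nlat, grid$nlon)
  m
}

#' Partition the domain into rectangular administrative zones
#'
#' Zones ("states") carry baseline mortality rates and GDP.  The bounding
#' box is cut into a `k x k` lattice; each land cell belongs to exactly one
#' zone.
#'
#' @param grid a [grid_spec()].
#' @param k number of zone rows/columns (default 4, i.e. 16 zones).
#' @return integer matrix of zone ids (`NA` off-land is not applied here;
#'   combine with a mask downstream).
#' @export
zone_partition <- function(grid, k = 4) {
  stopifnot(k >= 1)
  li <- pmin(k, 1L + floor(k * (grid$lat - grid$lat_min) / (grid$lat_max - grid$lat_min)))
  lj <- pmin(k, 1L + floor(k * (grid$lon - grid$lon_min) / (grid$lon_max - grid$lon_min)))
  outer(li, lj, function(i, j) as.integer((i - 1L) * k + j))
}

# Smoothed standard-normal random surface used for spatial structure in the
# generator.  Gaussian kernel smoothing with reflecting edges; the result is
# re-standardised to mean 0, sd 1 over the whole matrix.
smooth_random_field <- function(nlat, nlon, length_scale = 4) {
  z <- matrix(stats::rnorm(nlat * nlon), nlat, nlon)
  if (length_scale > 0) {
    half <- max(1L, as.integer(ceiling(2 * length_scale)))
    k1 <- stats::dnorm(seq(-half, half), sd = length_scale)
    k1 <- k1 / sum(k1)
    pad_smooth <- function(m, kern, along_rows) {
      if (!along_rows) m <- t(m)
      h <- (length(kern) - 1L) %/% 2L
      idx <- c(rev(seq_len(h)), seq_len(nrow(m)), nrow(m) + 1L - rev(seq_len(h)))
      mp <- m[pmin(pmax(idx, 1L), nrow(m)), , drop = FALSE]
      out <- apply(mp, 2, function(col) stats::filter(col, kern, sides = 2))
      out <- out[(h + 1L):(h + nrow(m)), , drop = FALSE]
      if (!along_rows) out <- t(out)
      out
    }
    z <- pad_smooth(z, k1, TRUE)
    z <- pad_smooth(z, k1, FALSE)
  }
  (z - mean(z)) / stats::sd(z)
}

#' Bilinear downscaling of a coarse field to a finer grid
#'
#' Statistical downscaling of native-resolution model output to the common
#' analysis grid: bilinear interpolation of cell-centre values, treating the
#' quantity as an intensity (no area re-weighting).  A nearest-neighbour
#' variant is available.
#'
#' @param field coarse `gridded_field`.
#' @param target_grid a [grid_spec()] whose cell centres must fall inside
#'   the coarse cell-centre hull.
#' @param method `"bilinear"` (default) or `"nearest"`.
#' @param mask optional logical mask for the result; defaults to all-land.
#' @return `gridded_field` on `target_grid`.
#' @export
downscale <- function(field, target_grid, method = c("bilinear", "nearest"),
                      mask = NULL) {
  method <- match.arg(method)
  src <- field$grid
  if (min(target_grid$lat) < min(src$lat) - 1e-9 ||
      max(target_grid$lat) > max(src$lat) + 1e-9 ||
      min(target_grid$lon) < min(src$lon) - 1e-9 ||
      max(target_grid$lon) > max(src$lon) + 1e-9)
    stop("target grid extends beyond the coverage of the coarse field")
  interp1 <- function(coord, src_coord) {
    i <- findInterval(coord, src_coord, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), length(src_coord) - 1L)
    w <- (coord - src_coord[i]) / (src_coord[i + 1L] - src_coord[i])
    list(i = i, w = pmin(pmax(w, 0), 1))
  }
  a <- interp1(target_grid$lat, src$lat)
  b <- interp1(target_grid$lon, src$lon)
  V <- field$values
  if (method == "nearest") {
    ri <- ifelse(a$w < 0.5, a$i, a$i + 1L)
    cj <- ifelse(b$w < 0.5, b$i, b$i + 1L)
    out <- V[ri, cj, drop = FALSE]
  } else {
    wa <- matrix(a$w, target_grid$nlat, target_grid$nlon)
    wb <- matrix(b$w, target_grid$nlat, target_grid$nlon, byrow = TRUE)
    out <- V[a$i,     b$i,      drop = FALSE] * (1 - wa) * (1 - wb) +
           V[a$i + 1, b$i,      drop = FALSE] * wa       * (1 - wb) +
           V[a$i,     b$i + 1,  drop = FALSE] * (1 - wa) * wb +
           V[a$i + 1, b$i + 1,  drop = FALSE] * wa       * wb
  }
  gridded_field(out, target_grid, field$units, mask)
}
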