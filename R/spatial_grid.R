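#' Regular longitude/latitude grid specification
#'
#' @param resolution cell size in degrees (square cells).
#' @param bounds numeric `c(lon_min, lon_max, lat_min, lat_max)` in
#'   degrees; must be tiled exactly by `resolution` (within 1e-8 of a
#'   whole number of cells).
#' @param earth_radius sphere radius in km (default 6371).
#'
#' @return An object of class `grid_spec` with cell counts `nx`, `ny`
#'   and cell-center vectors `lon`, `lat`.
#' @examples
#' grid_spec(2.5, c(-80, -45, -20, 10))
#' @export
grid_spec <- function(resolution, bounds, earth_radius = 6371) {
  stopifnot(is.numeric(resolution), length(resolution) == 1, resolution > 0,
            length(bounds) == 4, earth_radius > 0)
  if (bounds[1] >= bounds[2] || bounds[3] >= bounds[4]) {
    stop("bounds must be ordered (lon_min < lon_max, lat_min < lat_max)",
         call. = FALSE)
  }
  nx <- (bounds[2] - bounds[1]) / resolution
  ny <- (bounds[4] - bounds[3]) / resolution
  if (abs(nx - round(nx)) > 1e-8 || abs(ny - round(ny)) > 1e-8) {
    stop("bounds are not an integer number of cells at this resolution",
         call. = FALSE)
  }
  nx <- as.integer(round(nx)); ny <- as.integer(round(ny))
  structure(list(resolution = resolution, bounds = as.numeric(bounds),
                 earth_radius = earth_radius, nx = nx, ny = ny,
                 lon = bounds[1] + (seq_len(nx) - 0.5) * resolution,
                 lat = bounds[3] + (seq_len(ny) - 0.5) * resolution),
            class = "grid_spec")
}

# Spherical band area R^2 * dlambda * (sin(phi2) - sin(phi1)), km^2,
# for one cell of width res_lon degrees between latitudes lat1 < lat2.
.band_area_km2 <- function(lat1, lat2, res_lon, radius = 6371) {
  radius^2 * (res_lon * pi / 180) *
    (sin(pmin(lat2, 90) * pi / 180) - sin(pmax(lat1, -90) * pi / 180))
}

#' Spherical cell areas of a grid
#'
#' Each cell's area is the exact spherical quadrilateral area
#' `R^2 * d(lambda) * (sin(phi_2) - sin(phi_1))`: longitude-independent,
#' shrinking toward the poles with the cosine of latitude.
#'
#' @param grid a [grid_spec()].
#' @return Numeric matrix `[nx, ny]` of areas in km^2.
#' @examples
#' g <- grid_spec(90, c(-180, 180, -90, 90))
#' sum(cell_areas(g)) / (4 * pi * 6371^2)  # == 1
#' @export
cell_areas <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  band <- .band_area_km2(grid$lat - grid$resolution / 2,
                         grid$lat + grid$resolution / 2,
                         grid$resolution, grid$earth_radius)
  matrix(band, nrow = grid$nx, ncol = grid$ny, byrow = TRUE)
}

#' Gridded windthrow counts and densities
#'
#' Counts events per grid cell (half-open membership: a point on a
#' shared edge belongs to the cell to its east/north) and converts to a
#' density in events per 10,000 km^2.
#'
#' @param events an [event_set()].
#' @param grid a [grid_spec()]; all events must fall within its bounds.
#' @return A list with `counts` and `density` matrices `[nx, ny]`, the
#'   cell `areas`, and the `grid`.
#' @export
grid_density_map <- function(events, grid) {
  stopifnot(inherits(events, "event_set"), inherits(grid, "grid_spec"))
  b <- grid$bounds
  out_of_bounds <- which(events$lon < b[1] | events$lon >= b[2] |
                         events$lat < b[3] | events$lat >= b[4])
  if (length(out_of_bounds)) {
    stop(sprintf("out-of-bounds events at indices: %s",
                 paste(out_of_bounds, collapse = ", ")), call. = FALSE)
  }
  ix <- floor((events$lon - b[1]) / grid$resolution) + 1L
  iy <- floor((events$lat - b[3]) / grid$resolution) + 1L
  counts <- matrix(0L, grid$nx, grid$ny)
  for (k in seq_len(nrow(events))) {
    counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  }
  areas <- cell_areas(grid)
  list(counts = counts, density = counts / areas * 1e4,
       areas = areas, grid = grid)
}

#' Percentile aggregation of a fine field onto a coarse grid
#'
#' Summarises each coarse cell by the q-th percentile of the fine cells
#' whose centers it contains (linear interpolation between order
#' statistics, the default quantile definition of [stats::quantile()]).
#' Used for display-scale maps, e.g. a 2.5-degree 90th-percentile CAPE
#' map from a 0.25-degree field.
#'
#' @param field a [cape_field()] (resolution at most `grid$resolution`).
#' @param grid a coarse [grid_spec()].
#' @param q percentile in `[0, 100]` (default 90).
#' @return A [cape_field()] on the coarse grid; coarse cells containing
#'   no fine values are `NA`.
#' @export
aggregate_percentile <- function(field, grid, q = 90) {
  stopifnot(inherits(field, "cape_field"), inherits(grid, "grid_spec"),
            q >= 0, q <= 100)
  fine_res <- if (length(field$lon) > 1) diff(field$lon)[1] else grid$resolution
  if (fine_res > grid$resolution + 1e-9) {
    stop("fine field resolution exceeds the coarse grid resolution",
         call. = FALSE)
  }
  b <- grid$bounds
  cc <- expand.grid(lon = field$lon, lat = field$lat)
  inside <- cc$lon >= b[1] & cc$lon < b[2] & cc$lat >= b[3] & cc$lat < b[4]
  ix <- floor((cc$lon - b[1]) / grid$resolution) + 1L
  iy <- floor((cc$lat - b[3]) / grid$resolution) + 1L
  vals <- as.vector(field$values)
  vals[!as.vector(field$mask)] <- NA
  out <- matrix(NA_real_, grid$nx, grid$ny)
  idx <- (iy - 1L) * grid$nx + ix
  for (cell in unique(idx[inside])) {
    v <- vals[inside & idx == cell]
    v <- v[!is.na(v)]
    if (length(v)) out[cell] <- unname(stats::quantile(v, q / 100, type = 7))
  }
  cape_field(out, grid$lon, grid$lat, cell_areas(grid),
             provenance = sprintf("p%g-aggregate of %s", q, field$provenance))
}
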