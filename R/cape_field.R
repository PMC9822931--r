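#' Georeferenced CAPE raster
#'
#' Container for a raster of convective available potential energy
#' (CAPE, J kg^-1) on a regular longitude/latitude grid, together with
#' per-cell areas and an in-region mask. This is the common currency of
#' the package: the density model is fitted against one, projections
#' scale one, and the synthetic generator produces them.
#'
#' @param values numeric matrix of CAPE values (J kg^-1), dimension
#'   `length(lon) x length(lat)`; `NA` marks missing cells.
#' @param lon,lat numeric vectors of cell-center coordinates in degrees,
#'   strictly increasing and equally spaced.
#' @param cell_areas numeric matrix of cell areas in km^2, same
#'   dimension as `values`. Computed from `lat` via spherical band
#'   areas when omitted (see [cell_areas()]).
#' @param mask logical matrix flagging in-region cells; defaults to all
#'   `TRUE` (a rectangular region).
#' @param provenance free-text label describing where the field came
#'   from, e.g. `"reanalysis-current"` or `"scaled-future"`.
#'
#' @return An object of class `cape_field`: a list with elements
#'   `values`, `lon`, `lat`, `cell_areas`, `mask`, `provenance`.
#' @examples
#' f <- cape_field(matrix(500, 4, 3), lon = seq(-70, -67), lat = seq(-3, -1))
#' f
#' @export
cape_field <- function(values, lon, lat, cell_areas = NULL, mask = NULL,
                       provenance = "unspecified") {
  values <- as.matrix(values)
  stopifnot(is.numeric(lon), is.numeric(lat))
  if (nrow(values) != length(lon) || ncol(values) != length(lat)) {
    stop("`values` must be a length(lon) x length(lat) matrix", call. = FALSE)
  }
  .check_regular_axis(lon, "lon")
  .check_regular_axis(lat, "lat")
  if (any(values < 0, na.rm = TRUE)) {
    stop("CAPE values must be >= 0 or NA", call. = FALSE)
  }
  if (is.null(cell_areas)) {
    res_lon <- if (length(lon) > 1) diff(lon)[1] else 1
    res_lat <- if (length(lat) > 1) diff(lat)[1] else 1
    band <- .band_area_km2(lat - res_lat / 2, lat + res_lat / 2, res_lon)
    cell_areas <- matrix(band, nrow = length(lon), ncol = length(lat),
                         byrow = TRUE)
  }
  cell_areas <- as.matrix(cell_areas)
  if (!all(dim(cell_areas) == dim(values))) {
    stop("`cell_areas` dimension must match `values`", call. = FALSE)
  }
  if (any(!is.finite(cell_areas)) || any(cell_areas <= 0)) {
    stop("cell areas must be finite and > 0", call. = FALSE)
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(values), ncol(values))
  mask <- as.matrix(mask)
  if (!all(dim(mask) == dim(values)) || !is.logical(mask)) {
    stop("`mask` must be a logical matrix matching `values`", call. = FALSE)
  }
  structure(
    list(values = values, lon = as.numeric(lon), lat = as.numeric(lat),
         cell_areas = cell_areas, mask = mask,
         provenance = as.character(provenance)[1]),
    class = "cape_field"
  )
}

.check_regular_axis <- function(x, name) {
  if (anyNA(x)) stop(sprintf("`%s` contains NA", name), call. = FALSE)
  if (length(x) > 1) {
    d <- diff(x)
    if (any(d <= 0)) {
      stop(sprintf("`%s` must be strictly increasing", name), call. = FALSE)
    }
    if (diff(range(d)) > 1e-6 * max(abs(d))) {
      stop(sprintf("`%s` must be equally spaced", name), call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.cape_field <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf(
    "<cape_field> %d x %d cells, lon [%g, %g], lat [%g, %g]\n",
    length(x$lon), length(x$lat), min(x$lon), max(x$lon),
    min(x$lat), max(x$lat)))
  cat(sprintf("  CAPE range: %.1f to %.1f J/kg (%d masked-in cells)\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(x$mask)))
  cat(sprintf("  region area: %.0f km2; provenance: %s\n",
              sum(x$cell_areas[x$mask]), x$provenance))
  invisible(x)
}

#' Windthrow event point set
#'
#' Holds the locations of observed (or simulated) windthrow events,
#' with optional per-event size and occurrence year.
#'
#' @param lon,lat numeric vectors of event coordinates in degrees.
#' @param size_m2 optional numeric vector of event areas (m^2).
#' @param year optional integer vector of occurrence years.
#'
#' @return An object of class `event_set`: a data.frame with columns
#'   `lon`, `lat` and any provided attributes; `nrow()` is the event
#'   count.
#' @examples
#' ev <- event_set(lon = c(-65.2, -66.0), lat = c(-3.1, -2.5))
#' nrow(ev)
#' @export
event_set <- function(lon, lat, size_m2 = NULL, year = NULL) {
  stopifnot(is.numeric(lon), is.numeric(lat), length(lon) == length(lat))
  if (anyNA(lon) || anyNA(lat)) stop("event coordinates contain NA", call. = FALSE)
  out <- data.frame(lon = as.numeric(lon), lat = as.numeric(lat))
  if (!is.null(size_m2)) {
    stopifnot(length(size_m2) == length(lon))
    out$size_m2 <- as.numeric(size_m2)
  }
  if (!is.null(year)) {
    stopifnot(length(year) == length(lon))
    out$year <- as.integer(year)
  }
  class(out) <- c("event_set", "data.frame")
  out
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("<event_set> %d events, lon [%g, %g], lat [%g, %g]\n",
              nrow(x),
              if (nrow(x)) min(x$lon) else NA, if (nrow(x)) max(x$lon) else NA,
              if (nrow(x)) min(x$lat) else NA, if (nrow(x)) max(x$lat) else NA))
  invisible(x)
}

# Cell-edge vectors for a regular-axis field (centers -> edges).
.axis_edges <- function(centers) {
  res <- if (length(centers) > 1) diff(centers)[1] else 1
  c(centers - res / 2, centers[length(centers)] + res / 2)
}
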