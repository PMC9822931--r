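# Plain-text serialisation for every container the pipeline exchanges:
# long-format CSV for rasters, CSV/GeoJSON for event points, JSON for
# fitted models and projection summaries.

#' Write / read a CAPE raster as long-format CSV
#'
#' Columns `lon, lat, cape, area_km2, mask`, one row per cell.
#' The reader reconstructs the regular grid from the unique sorted
#' coordinates; round-trip preserves values to full precision.
#'
#' @param field a [cape_field()].
#' @param path file path.
#' @return `write_cape_field()` returns `path` invisibly;
#'   `read_cape_field()` returns a [cape_field()].
#' @export
write_cape_field <- function(field, path) {
  stopifnot(inherits(field, "cape_field"))
  df <- data.frame(lon = rep(field$lon, times = length(field$lat)),
                   lat = rep(field$lat, each = length(field$lon)),
                   cape = as.vector(field$values),
                   area_km2 = as.vector(field$cell_areas),
                   mask = as.vector(field$mask))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cape_field
#' @param provenance label attached to the field on read.
#' @export
read_cape_field <- function(path, provenance = "file") {
  df <- utils::read.csv(path)
  need <- c("lon", "lat", "cape", "area_km2", "mask")
  if (!all(need %in% names(df))) {
    stop(sprintf("raster CSV must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  lon <- sort(unique(df$lon))
  lat <- sort(unique(df$lat))
  idx <- match(paste(df$lon, df$lat), paste(rep(lon, times = length(lat)),
                                            rep(lat, each = length(lon))))
  put <- function(x, default) {
    m <- matrix(default, length(lon), length(lat)); m[idx] <- x; m
  }
  cape_field(put(df$cape, NA_real_), lon, lat,
             cell_areas = put(df$area_km2, NA_real_),
             mask = put(as.logical(df$mask), FALSE),
             provenance = provenance)
}

#' Write / read windthrow event points as CSV
#'
#' Columns `lon, lat` plus any of `size_m2`, `year` present.
#'
#' @param events an [event_set()].
#' @param path file path.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_set"))
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("lon", "lat") %in% names(df))) {
    stop("event CSV must have `lon` and `lat` columns", call. = FALSE)
  }
  event_set(df$lon, df$lat,
            size_m2 = if ("size_m2" %in% names(df)) df$size_m2,
            year = if ("year" %in% names(df)) df$year)
}

#' Read windthrow event points from GeoJSON
#'
#' Accepts a FeatureCollection of Point features (properties `size_m2`
#' and `year` are picked up when present) or a bare geometry.
#'
#' @param path GeoJSON file path.
#' @return An [event_set()].
#' @export
read_events_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- switch(gj$type %||% "",
                  FeatureCollection = gj$features,
                  Feature = list(gj),
                  stop("GeoJSON must be a Feature(Collection) of points",
                       call. = FALSE))
  coords <- lapply(feats, function(f) unlist(f$geometry$coordinates))
  if (any(vapply(feats, function(f) f$geometry$type, "") != "Point")) {
    stop("only Point geometries are supported", call. = FALSE)
  }
  getp <- function(key) {
    vapply(feats, function(f) {
      v <- f$properties[[key]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
  }
  sizes <- getp("size_m2"); years <- getp("year")
  event_set(lon = vapply(coords, `[`, numeric(1), 1),
            lat = vapply(coords, `[`, numeric(1), 2),
            size_m2 = if (!all(is.na(sizes))) sizes,
            year = if (!all(is.na(years))) years)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a fitted density model as JSON
#'
#' Serialises edges (the unbounded upper edge is stored as the string
#' `"Inf"`), counts, areas, densities, bootstrap SDs and threshold.
#'
#' @param model a `windthrow_density_model`.
#' @param path file path.
#' @param provenance free-text label stored alongside the model.
#' @export
write_density_model <- function(model, path, provenance = "windcape-fit") {
  stopifnot(inherits(model, "windthrow_density_model"))
  obj <- list(
    provenance = provenance,
    bin_edges = c(model$bin_edges[-length(model$bin_edges)], "Inf"),
    bin_counts = model$bin_counts,
    bin_areas = model$bin_areas,
    bin_density = model$bin_density,
    bootstrap_sd = model$bootstrap_sd,
    threshold = if (is.na(model$threshold)) NULL else model$threshold)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_density_model
#' @export
read_density_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- suppressWarnings(as.numeric(obj$bin_edges))
  edges[length(edges)] <- Inf
  density_model(edges, obj$bin_counts, obj$bin_areas,
                threshold = obj$threshold %||% NA_real_,
                bootstrap_sd = obj$bootstrap_sd)
}

#' Write an ensemble projection summary
#'
#' `write_projection_json()` keeps full precision;
#' `write_projection_csv()` writes the integer-rounded report table
#' (see [projection_table()]).
#'
#' @param summary an [ensemble_summary()].
#' @param path file path.
#' @export
write_projection_json <- function(summary, path) {
  stopifnot(inherits(summary, "ensemble_summary"))
  jsonlite::write_json(
    list(per_model = summary$per_model,
         mean_area_increase = summary$mean_area_increase,
         sd_area_increase = summary$sd_area_increase,
         mean_density_increase = summary$mean_density_increase,
         sd_density_increase = summary$sd_density_increase),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_projection_json
#' @export
write_projection_csv <- function(summary, path) {
  utils::write.csv(projection_table(summary), path, row.names = FALSE)
  invisible(path)
}

#' Write a density map (counts and densities) as CSV
#'
#' @param map result of [grid_density_map()].
#' @param path file path.
#' @export
write_density_map <- function(map, path) {
  g <- map$grid
  df <- data.frame(lon = rep(g$lon, times = g$ny),
                   lat = rep(g$lat, each = g$nx),
                   count = as.vector(map$counts),
                   density = as.vector(map$density),
                   area_km2 = as.vector(map$areas))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a single atmospheric sounding from CSV
#'
#' Columns `pressure` (Pa, descending), `temperature` (K) and
#' optionally `humidity` (specific humidity, kg kg^-1). The surface
#' state is supplied separately.
#'
#' @param path CSV file path.
#' @param surface_pressure,surface_temperature,surface_humidity the
#'   parcel source state (Pa, K, kg kg^-1).
#' @return An [atmospheric_profile()].
#' @export
read_sounding <- function(path, surface_pressure, surface_temperature,
                          surface_humidity) {
  df <- utils::read.csv(path)
  if (!all(c("pressure", "temperature") %in% names(df))) {
    stop("sounding CSV needs `pressure` and `temperature` columns",
         call. = FALSE)
  }
  atmospheric_profile(df$pressure, df$temperature,
                      env_humidity = if ("humidity" %in% names(df)) df$humidity,
                      surface_pressure = surface_pressure,
                      surface_temperature = surface_temperature,
                      surface_humidity = surface_humidity)
}
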