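# co-registration check shared by the projection operations
.check_aligned <- function(a, b) {
  if (!isTRUE(all.equal(a$lon, b$lon)) || !isTRUE(all.equal(a$lat, b$lat))) {
    stop("alignment: fields are not co-registered", call. = FALSE)
  }
  invisible(TRUE)
}

#' Fractional CAPE change between two ESM climatologies
#'
#' Per-cell `(future - current) / current`, the delta-change factor
#' later applied to the observational baseline. Cells whose current
#' CAPE falls below `floor` are flagged missing instead of divided, to
#' guard against near-zero denominators.
#'
#' @param current_cmip,future_cmip co-registered [cape_field()]s of an
#'   ESM's current and future period-mean CAPE.
#' @param floor minimum current CAPE (J kg^-1) for a defined ratio
#'   (default 1).
#' @return An object of class `delta_field`: the fractional change
#'   matrix with the grid coordinates.
#' @export
delta_cape <- function(current_cmip, future_cmip, floor = 1) {
  stopifnot(inherits(current_cmip, "cape_field"),
            inherits(future_cmip, "cape_field"))
  .check_aligned(current_cmip, future_cmip)
  cur <- current_cmip$values
  fut <- future_cmip$values
  delta <- ifelse(!is.na(cur) & !is.na(fut) & cur >= floor,
                  (fut - cur) / cur, NA_real_)
  structure(list(values = delta, lon = current_cmip$lon,
                 lat = current_cmip$lat),
            class = "delta_field")
}

#' Scale a baseline CAPE field by a fractional delta
#'
#' The delta-change step: the future field on the observational grid is
#' `(1 + delta) * baseline`, cell by cell, so each ESM's projected
#' relative change is applied to the reanalysis climatology rather than
#' comparing incompatible absolute CAPE products.
#'
#' @param delta a `delta_field` from [delta_cape()], co-registered with
#'   the baseline (regrid beforehand if grids differ).
#' @param era5_current baseline [cape_field()] (e.g. reanalysis mean
#'   afternoon CAPE).
#' @return A [cape_field()] with provenance `"scaled-future"`; cells
#'   with missing delta are missing.
#' @export
scale_future_cape <- function(delta, era5_current) {
  stopifnot(inherits(delta, "delta_field"),
            inherits(era5_current, "cape_field"))
  .check_aligned(delta, era5_current)
  if (any(delta$values < -1, na.rm = TRUE)) {
    stop("negative-CAPE: delta below -1 would produce negative CAPE",
         call. = FALSE)
  }
  vals <- (1 + delta$values) * era5_current$values
  cape_field(vals, era5_current$lon, era5_current$lat,
             era5_current$cell_areas, era5_current$mask,
             provenance = "scaled-future")
}

#' Storm-favorable area of a CAPE field
#'
#' Total area (km^2) of in-region cells whose CAPE strictly exceeds the
#' threshold; cells exactly at the threshold do not count.
#'
#' @param field a [cape_field()].
#' @param threshold CAPE cutoff, J kg^-1.
#' @return Area in km^2.
#' @export
favorable_area <- function(field, threshold) {
  stopifnot(inherits(field, "cape_field"), is.finite(threshold))
  ok <- field$mask & !is.na(field$values)
  if (!any(ok)) stop("empty-field: no valid in-region cells", call. = FALSE)
  sum(field$cell_areas[ok & field$values > threshold])
}

#' Percentage increase in storm-favorable area
#'
#' `100 * (area_future - area_current) / area_current`, with each area
#' from [favorable_area()] at the same threshold.
#'
#' @param current,future co-registered [cape_field()]s.
#' @param threshold CAPE cutoff, J kg^-1.
#' @return Percentage increase (can be negative).
#' @export
favorable_area_increase <- function(current, future, threshold) {
  .check_aligned(current, future)
  a_cur <- favorable_area(current, threshold)
  a_fut <- favorable_area(future, threshold)
  if (a_cur == 0) {
    stop("undefined-increase: current favorable area is zero", call. = FALSE)
  }
  100 * (a_fut - a_cur) / a_cur
}

#' Projected percentage increase in windthrow events
#'
#' The expected total number of events under a CAPE field is the sum
#' over cells of the model's density at that cell's CAPE times the
#' cell's area (per 10,000 km^2). The projection compares this total on
#' the current and the scaled-future field:
#' `100 * (N_future - N_current) / N_current`. Both totals use the
#' model's prediction (not the observed event count) so current and
#' future are computed identically, and only cells valid in both
#' fields enter either total.
#'
#' @param model a `windthrow_density_model`.
#' @param current,future co-registered [cape_field()]s.
#' @return Percentage increase in the expected event total.
#' @export
project_density_increase <- function(model, current, future) {
  stopifnot(inherits(model, "windthrow_density_model"))
  .check_aligned(current, future)
  ok <- current$mask & future$mask &
    !is.na(current$values) & !is.na(future$values)
  if (!any(ok)) stop("empty-field: no jointly valid cells", call. = FALSE)
  n_cur <- sum(predict_density(model, current$values[ok]) *
                 current$cell_areas[ok] / 1e4)
  n_fut <- sum(predict_density(model, future$values[ok]) *
                 future$cell_areas[ok] / 1e4)
  if (n_cur == 0) {
    stop("undefined-increase: current expected event total is zero",
         call. = FALSE)
  }
  100 * (n_fut - n_cur) / n_cur
}

#' Full delta-change projection for one ESM
#'
#' Chains [delta_cape()], [scale_future_cape()],
#' [favorable_area_increase()] and [project_density_increase()] for a
#' single model against the observational baseline.
#'
#' @param model_name label for the ESM.
#' @param current_cmip,future_cmip the ESM's period-mean CAPE fields.
#' @param baseline the observational baseline [cape_field()],
#'   co-registered with the ESM fields.
#' @param density_model a fitted `windthrow_density_model`.
#' @param threshold storm-favorable cutoff, J kg^-1; defaults to the
#'   density model's.
#' @param floor denominator guard passed to [delta_cape()].
#' @return A list of class `projection_result`: `model_name`,
#'   `delta_field`, `scaled_future`, favorable areas (km^2) and the two
#'   percentage increases.
#' @export
project_model <- function(model_name, current_cmip, future_cmip, baseline,
                          density_model, threshold = density_model$threshold,
                          floor = 1) {
  delta <- delta_cape(current_cmip, future_cmip, floor = floor)
  scaled <- scale_future_cape(delta, baseline)
  structure(
    list(model_name = model_name,
         delta_field = delta,
         scaled_future = scaled,
         favorable_area_current = favorable_area(baseline, threshold),
         favorable_area_future = favorable_area(scaled, threshold),
         area_increase_pct = favorable_area_increase(baseline, scaled,
                                                     threshold),
         density_increase_pct = project_density_increase(density_model,
                                                         baseline, scaled)),
    class = "projection_result")
}

#' Ensemble mean and spread of projected increases
#'
#' @param results list of `projection_result` objects (one per ESM).
#' @return A list of class `ensemble_summary`: `per_model` data.frame
#'   (model, area-increase %, density-increase %) at full precision,
#'   plus ensemble means and sample (n-1) standard deviations. Round
#'   only at report time (see [projection_table()]).
#' @export
ensemble_summary <- function(results) {
  if (length(results) == 0) {
    stop("empty-ensemble: no projection results", call. = FALSE)
  }
  stopifnot(all(vapply(results, inherits, logical(1), "projection_result")))
  per_model <- data.frame(
    model = vapply(results, `[[`, character(1), "model_name"),
    area_increase_pct = vapply(results, `[[`, numeric(1),
                               "area_increase_pct"),
    density_increase_pct = vapply(results, `[[`, numeric(1),
                                  "density_increase_pct"))
  structure(
    list(per_model = per_model,
         mean_area_increase = mean(per_model$area_increase_pct),
         sd_area_increase = if (nrow(per_model) > 1)
           stats::sd(per_model$area_increase_pct) else NA_real_,
         mean_density_increase = mean(per_model$density_increase_pct),
         sd_density_increase = if (nrow(per_model) > 1)
           stats::sd(per_model$density_increase_pct) else NA_real_),
    class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("<ensemble_summary> %d models\n", nrow(x$per_model)))
  cat(sprintf("  favorable-area increase: %.1f%% (SD %.1f)\n",
              x$mean_area_increase, x$sd_area_increase))
  cat(sprintf("  windthrow-density increase: %.1f%% (SD %.1f)\n",
              x$mean_density_increase, x$sd_density_increase))
  invisible(x)
}

#' Report table of ensemble projections
#'
#' Per-model and ensemble rows with percentages rounded to the nearest
#' integer — rounding happens only here, at report time.
#'
#' @param summary an [ensemble_summary()].
#' @return A data.frame with columns `model`, `area_increase_pct`,
#'   `density_increase_pct`, ending in `Ensemble Mean` and
#'   `One standard deviation` rows.
#' @export
projection_table <- function(summary) {
  stopifnot(inherits(summary, "ensemble_summary"))
  pm <- summary$per_model
  rbind(
    data.frame(model = pm$model,
               area_increase_pct = round(pm$area_increase_pct),
               density_increase_pct = round(pm$density_increase_pct)),
    data.frame(model = c("Ensemble Mean", "One standard deviation"),
               area_increase_pct = round(c(summary$mean_area_increase,
                                           summary$sd_area_increase)),
               density_increase_pct = round(c(summary$mean_density_increase,
                                              summary$sd_density_increase))))
}
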