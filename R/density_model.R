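#' Sample CAPE at event locations
#'
#' Returns, for each event, the CAPE of the grid cell containing it
#' (nearest cell-center rule on a regular grid), in event order.
#'
#' @param field a [cape_field()].
#' @param events an [event_set()]; every event must fall inside the
#'   field's masked extent.
#' @return Numeric vector of per-event CAPE values (J kg^-1).
#' @export
sample_cape_at_points <- function(field, events) {
  stopifnot(inherits(field, "cape_field"), inherits(events, "event_set"))
  ex <- .axis_edges(field$lon)
  ey <- .axis_edges(field$lat)
  ix <- findInterval(events$lon, ex, rightmost.closed = FALSE)
  iy <- findInterval(events$lat, ey, rightmost.closed = FALSE)
  bad <- ix < 1 | ix > length(field$lon) | iy < 1 | iy > length(field$lat)
  ok <- !bad
  idx <- rep(NA_integer_, nrow(events))
  idx[ok] <- (iy[ok] - 1L) * length(field$lon) + ix[ok]
  bad[ok] <- !field$mask[idx[ok]] | is.na(field$values[idx[ok]])
  if (any(bad)) {
    stop(sprintf("out-of-region events at indices: %s",
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  field$values[idx]
}

#' Construct a windthrow-density look-up model directly
#'
#' Builds the step-function model from explicit bin edges, counts and
#' areas — e.g. when reconstructing a published table rather than
#' fitting from events. [fit_density_model()] is the usual entry point.
#'
#' @param bin_edges numeric vector of length `n_bins + 1`; first edge 0,
#'   last `Inf`, strictly increasing.
#' @param bin_counts events per bin.
#' @param bin_areas km^2 of region per bin (all positive).
#' @param threshold optional storm-favorable CAPE cutoff, J kg^-1.
#' @param bootstrap_sd optional per-bin density SDs.
#' @return An object of class `windthrow_density_model` with the bins,
#'   densities in events per 10,000 km^2, and total counts/areas.
#' @export
density_model <- function(bin_edges, bin_counts, bin_areas,
                          threshold = NA_real_, bootstrap_sd = NULL) {
  n_bins <- length(bin_edges) - 1
  stopifnot(n_bins >= 1, length(bin_counts) == n_bins,
            length(bin_areas) == n_bins)
  if (any(diff(bin_edges) <= 0)) {
    stop("bin edges must be strictly increasing", call. = FALSE)
  }
  if (bin_edges[1] != 0 || !is.infinite(bin_edges[n_bins + 1])) {
    stop("outer edges must be 0 and Inf", call. = FALSE)
  }
  if (any(bin_areas <= 0)) stop("bin areas must be > 0", call. = FALSE)
  structure(
    list(bin_edges = as.numeric(bin_edges),
         bin_counts = as.numeric(bin_counts),
         bin_areas = as.numeric(bin_areas),
         bin_density = as.numeric(bin_counts) / as.numeric(bin_areas) * 1e4,
         bootstrap_sd = bootstrap_sd,
         threshold = threshold,
         n_events = sum(bin_counts),
         total_area = sum(bin_areas)),
    class = "windthrow_density_model")
}

#' @export
print.windthrow_density_model <- function(x, ...) {
  n <- length(x$bin_counts)
  cat(sprintf("<windthrow_density_model> %d equal-count CAPE bins, %d events\n",
              n, round(x$n_events)))
  edges <- formatC(x$bin_edges, format = "fg", digits = 5)
  for (k in seq_len(n)) {
    cat(sprintf("  [%s, %s): %4d events on %10.0f km2 -> %6.2f per 10^4 km2%s\n",
                edges[k], edges[k + 1], round(x$bin_counts[k]),
                x$bin_areas[k], x$bin_density[k],
                if (!is.null(x$bootstrap_sd))
                  sprintf(" (SD %.2f)", x$bootstrap_sd[k]) else ""))
  }
  if (!is.na(x$threshold)) {
    cat(sprintf("  storm-favorable threshold: %.0f J/kg\n", x$threshold))
  }
  invisible(x)
}

#' Fit the equal-count binned windthrow-density model
#'
#' Sorts the per-event CAPE values and splits them into `n_bins`
#' equal-count groups (sizes differing by at most one; when the event
#' count is not divisible, the larger groups come first). Interior bin
#' edges are placed at the midpoint between the last event of one group
#' and the first of the next, and the outer edges are extended to 0 and
#' +Inf, under the assumption that windthrow density is similar for
#' neighbouring CAPE values and does not keep rising beyond the
#' observed range. Each bin's area is the summed area of in-region
#' cells whose CAPE falls in it; density is events per 10,000 km^2.
#'
#' Ties: events with identical CAPE straddling a group boundary cannot
#' be separated by any edge; they are kept with their sorted-order
#' group for the stored counts, and a warning reports the discrepancy
#' against edge-membership counts.
#'
#' @param event_capes per-event CAPE values, e.g. from
#'   [sample_cape_at_points()].
#' @param field the [cape_field()] supplying the region's cells.
#' @param n_bins number of equal-count bins (default 6).
#' @param threshold storm-favorable cutoff: `"auto"` (default) applies
#'   [favorable_threshold()]; or a fixed value in J kg^-1 (the
#'   published analysis uses 1023).
#' @return A `windthrow_density_model` (see [density_model()]).
#' @examples
#' set.seed(1)
#' f <- cape_field(matrix(runif(400, 100, 1500), 20, 20),
#'                 lon = seq(-70, -60.5, by = 0.5),
#'                 lat = seq(-10, -0.5, by = 0.5))
#' capes <- sample(f$values, 120, replace = TRUE)
#' fit_density_model(capes, f)
#' @export
fit_density_model <- function(event_capes, field, n_bins = 6,
                              threshold = "auto") {
  stopifnot(inherits(field, "cape_field"), n_bins >= 1)
  event_capes <- as.numeric(event_capes)
  if (anyNA(event_capes) || any(event_capes < 0)) {
    stop("event CAPE values must be non-negative and non-missing",
         call. = FALSE)
  }
  n <- length(event_capes)
  if (n < n_bins) {
    stop("underdetermined-model: fewer events than bins", call. = FALSE)
  }
  srt <- sort(event_capes)
  base <- n %/% n_bins
  sizes <- base + (seq_len(n_bins) <= n %% n_bins)
  cuts <- cumsum(sizes)[-n_bins]
  interior <- (srt[cuts] + srt[cuts + 1]) / 2
  if (any(diff(c(0, interior)) <= 0)) {
    stop("tie degeneracy: identical CAPE values collapse bin edges",
         call. = FALSE)
  }
  edges <- c(0, interior, Inf)
  member <- findInterval(event_capes, edges)
  counts_by_edge <- tabulate(member, nbins = n_bins)
  if (!all(counts_by_edge == sizes)) {
    warning(sprintf(
      "ties at bin edges: sorted-order counts (%s) differ from edge-membership counts (%s)",
      paste(sizes, collapse = ","), paste(counts_by_edge, collapse = ",")),
      call. = FALSE)
  }
  cells_ok <- field$mask & !is.na(field$values)
  cell_bin <- findInterval(field$values[cells_ok], edges)
  bin_areas <- vapply(seq_len(n_bins), function(k) {
    sum(field$cell_areas[cells_ok][cell_bin == k])
  }, numeric(1))
  if (any(bin_areas <= 0)) {
    stop("a bin covers zero region area; too few cells for this binning",
         call. = FALSE)
  }
  m <- density_model(edges, sizes, bin_areas)
  m$threshold <- if (identical(threshold, "auto")) {
    favorable_threshold(m)
  } else {
    as.numeric(threshold)
  }
  m
}

#' Predict windthrow density from CAPE
#'
#' Step-function look-up: returns the density of the bin containing
#' each CAPE value. Bins are left-closed/right-open; CAPE beyond the
#' largest observed value falls in the last (unbounded) bin, i.e. the
#' density is held constant rather than extrapolated upward.
#'
#' @param model a `windthrow_density_model`.
#' @param cape CAPE values, J kg^-1 (all `>= 0`).
#' @return Densities in events per 10,000 km^2, one per input value.
#' @export
predict_density <- function(model, cape) {
  stopifnot(inherits(model, "windthrow_density_model"))
  cape <- as.numeric(cape)
  out <- rep(NA_real_, length(cape))
  ok <- !is.na(cape)
  if (any(cape[ok] < 0)) stop("CAPE must be >= 0", call. = FALSE)
  out[ok] <- model$bin_density[findInterval(cape[ok], model$bin_edges)]
  out
}

#' Bootstrap standard deviation of per-bin densities
#'
#' Resamples the events with replacement `n_boot` times, recounts them
#' against the FIXED bin edges of the fitted model, recomputes the
#' per-bin density for each replicate, and returns the per-bin sample
#' SD across replicates. Edges are not refitted per replicate, so the
#' SDs describe the per-bin density estimates of the original binning.
#'
#' @param event_capes the per-event CAPE values the model was fitted to.
#' @param model a `windthrow_density_model`.
#' @param n_boot number of bootstrap replicates (default 10000).
#' @param seed integer RNG seed (required, for reproducibility).
#' @return Numeric vector of per-bin density SDs (events per
#'   10,000 km^2).
#' @export
bootstrap_density_sd <- function(event_capes, model, n_boot = 10000, seed) {
  stopifnot(inherits(model, "windthrow_density_model"))
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (n_boot < 2) stop("invalid-replicates: n_boot must be >= 2", call. = FALSE)
  event_capes <- as.numeric(event_capes)
  n <- length(event_capes)
  n_bins <- length(model$bin_counts)
  set.seed(as.integer(seed))
  chunk <- 500L
  dens <- matrix(NA_real_, n_boot, n_bins)
  done <- 0L
  while (done < n_boot) {
    m <- min(chunk, n_boot - done)
    draws <- matrix(event_capes[sample.int(n, n * m, replace = TRUE)], n, m)
    bins <- matrix(findInterval(draws, model$bin_edges), n, m)
    cnt <- apply(bins, 2, tabulate, nbins = n_bins)
    dens[done + seq_len(m), ] <- t(cnt / model$bin_areas * 1e4)
    done <- done + m
  }
  apply(dens, 2, stats::sd)
}

#' Storm-favorable CAPE threshold
#'
#' Selects the interior bin edge that maximizes the contrast between
#' the aggregate density above and below it: the edge `e` maximizing
#' `(events above / area above) / (events below / area below)`. When
#' the binned densities are flat there is no meaningful split; a
#' warning is issued and the lowest interior edge returned.
#'
#' @param model a `windthrow_density_model`.
#' @return The threshold in J kg^-1 (one of the interior bin edges).
#' @export
favorable_threshold <- function(model) {
  stopifnot(inherits(model, "windthrow_density_model"))
  n_bins <- length(model$bin_counts)
  if (n_bins < 2) stop("need at least 2 bins", call. = FALSE)
  interior <- model$bin_edges[2:n_bins]
  ratios <- vapply(seq_len(n_bins - 1), function(j) {
    below <- seq_len(j); above <- (j + 1):n_bins
    (sum(model$bin_counts[above]) / sum(model$bin_areas[above])) /
      (sum(model$bin_counts[below]) / sum(model$bin_areas[below]))
  }, numeric(1))
  if (diff(range(model$bin_density)) <=
      1e-12 * max(abs(model$bin_density), 1)) {
    warning("no-threshold: binned density is flat; returning lowest interior edge",
            call. = FALSE)
    return(interior[1])
  }
  interior[which.max(ratios)]
}

#' Favorable/non-favorable windthrow density ratio
#'
#' The fold difference in windthrow density between storm-favorable
#' (CAPE above the threshold) and non-favorable environments:
#' `(events above / area above) / (events below / area below)`, with
#' events and areas aggregated from the model's bins split at the
#' threshold. A threshold interior to a finite bin splits that bin's
#' counts and area linearly over its CAPE range; a threshold interior
#' to the unbounded last bin is rejected.
#'
#' @param model a `windthrow_density_model`.
#' @param threshold CAPE cutoff, J kg^-1; defaults to the model's.
#' @return The fold ratio (dimensionless).
#' @export
density_ratio <- function(model, threshold = model$threshold) {
  stopifnot(inherits(model, "windthrow_density_model"))
  if (is.na(threshold) || threshold <= 0) {
    stop("threshold must be a positive CAPE value", call. = FALSE)
  }
  e <- model$bin_edges
  n_bins <- length(model$bin_counts)
  if (threshold > max(e[is.finite(e)])) {
    stop("threshold lies inside the unbounded last bin", call. = FALSE)
  }
  lo <- e[-length(e)]; hi <- e[-1]
  frac_below <- ifelse(hi <= threshold, 1,
                ifelse(lo >= threshold, 0, (threshold - lo) / (hi - lo)))
  ev_below <- sum(model$bin_counts * frac_below)
  ar_below <- sum(model$bin_areas * frac_below)
  ev_above <- model$n_events - ev_below
  ar_above <- model$total_area - ar_below
  if (ev_below == 0 || ar_below == 0 || ar_above == 0) {
    stop("undefined-ratio: zero events or area on one side of the threshold",
         call. = FALSE)
  }
  (ev_above / ar_above) / (ev_below / ar_below)
}
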