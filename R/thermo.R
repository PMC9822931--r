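# Thermodynamic constants (SI). Constant latent heat; condensate loading
# ignored, consistent with pseudo-adiabatic removal of condensate.
.const <- list(
  Rd  = 287.04,    # dry-air gas constant, J kg-1 K-1
  Rv  = 461.5,     # water-vapour gas constant, J kg-1 K-1
  cp  = 1005.7,    # dry-air isobaric heat capacity, J kg-1 K-1
  Lv  = 2.501e6,   # latent heat of vaporisation, J kg-1
  eps = 287.04 / 461.5
)

#' CAPE computation configuration
#'
#' Controls the discrete pressure levels of the buoyancy sum, the level
#' spacing, the saturation vapour-pressure scheme, and how zero
#' buoyancy is treated by the step function.
#'
#' @param dp level spacing in Pa (default 10 kPa).
#' @param levels target pressure levels in Pa, descending; default
#'   100 kPa down to 10 kPa in steps of `dp`.
#' @param saturation_formula saturation vapour-pressure scheme; only
#'   `"bolton"` (empirical exponential fit over liquid water) is
#'   currently implemented. The slot exists so sensitivity tests can
#'   plug in alternatives.
#' @param zero_buoyancy_counts logical; if `FALSE` (default) a level
#'   with exactly zero buoyancy contributes nothing (strict step
#'   function). `TRUE` includes it — numerically identical since the
#'   term is zero, kept for explicitness.
#' @param ascent_dp internal pressure step (Pa) of the pseudo-adiabatic
#'   ascent integration (classical fourth-order Runge-Kutta); 500 Pa is
#'   far finer than any `dp` used for the buoyancy sum.
#'
#' @return An object of class `cape_config`.
#' @examples
#' cape_config()           # the 10-level default
#' cape_config(dp = 5000)  # 19 levels, 100 kPa to 10 kPa by 5 kPa
#' @export
cape_config <- function(dp = 1e4, levels = NULL,
                        saturation_formula = "bolton",
                        zero_buoyancy_counts = FALSE,
                        ascent_dp = 500) {
  stopifnot(is.numeric(dp), length(dp) == 1, dp > 0, ascent_dp > 0)
  if (is.null(levels)) levels <- seq(1e5, 1e4, by = -dp)
  levels <- sort(as.numeric(levels), decreasing = TRUE)
  if (length(levels) < 2) stop("need at least 2 levels", call. = FALSE)
  if (max(abs(diff(levels) + dp)) > 1e-6 * dp) {
    stop("`levels` must be spaced by `dp`", call. = FALSE)
  }
  saturation_formula <- match.arg(saturation_formula, "bolton")
  structure(list(dp = dp, levels = levels,
                 saturation_formula = saturation_formula,
                 zero_buoyancy_counts = isTRUE(zero_buoyancy_counts),
                 ascent_dp = ascent_dp),
            class = "cape_config")
}

#' Environmental sounding for parcel CAPE
#'
#' The environmental state a near-surface parcel is lifted through:
#' temperatures (and optionally specific humidity) on pressure levels,
#' plus the surface state that defines the parcel source.
#'
#' @param pressure_levels pressures in Pa, strictly decreasing from the
#'   surface upward.
#' @param env_temperature environmental temperature (K) at each level.
#' @param env_humidity optional environmental specific humidity
#'   (kg kg^-1) at each level; when omitted the environmental density
#'   uses dry air (no virtual-temperature correction).
#' @param surface_pressure surface pressure, Pa.
#' @param surface_temperature surface air temperature, K.
#' @param surface_humidity surface specific humidity, kg kg^-1.
#'
#' @return An object of class `atmospheric_profile`.
#' @examples
#' p <- seq(1e5, 1e4, by = -1e4)
#' atmospheric_profile(p, 300 - 50 * log(1e5 / p),
#'                     surface_pressure = 1.005e5,
#'                     surface_temperature = 301, surface_humidity = 0.017)
#' @export
atmospheric_profile <- function(pressure_levels, env_temperature,
                                env_humidity = NULL,
                                surface_pressure, surface_temperature,
                                surface_humidity) {
  pressure_levels <- as.numeric(pressure_levels)
  env_temperature <- as.numeric(env_temperature)
  if (length(pressure_levels) != length(env_temperature)) {
    stop("level and temperature vectors differ in length", call. = FALSE)
  }
  if (any(!is.finite(pressure_levels)) || any(!is.finite(env_temperature)) ||
      !is.finite(surface_pressure) || !is.finite(surface_temperature) ||
      !is.finite(surface_humidity)) {
    stop("invalid-input: non-finite profile values", call. = FALSE)
  }
  if (any(diff(pressure_levels) >= 0)) {
    stop("pressure_levels must be strictly decreasing", call. = FALSE)
  }
  if (any(env_temperature <= 0) || surface_temperature <= 0) {
    stop("temperatures must be > 0 K", call. = FALSE)
  }
  hums <- c(surface_humidity, env_humidity)
  if (any(hums < 0) || any(hums >= 0.1)) {
    stop("specific humidities must lie in [0, 0.1)", call. = FALSE)
  }
  if (!is.null(env_humidity)) {
    env_humidity <- as.numeric(env_humidity)
    stopifnot(length(env_humidity) == length(pressure_levels))
  }
  structure(list(pressure_levels = pressure_levels,
                 env_temperature = env_temperature,
                 env_humidity = env_humidity,
                 surface_pressure = as.numeric(surface_pressure),
                 surface_temperature = as.numeric(surface_temperature),
                 surface_humidity = as.numeric(surface_humidity)),
            class = "atmospheric_profile")
}

# Bolton-type saturation vapour pressure over liquid water, Pa.
.sat_vapor_pressure <- function(t_k) {
  611.2 * exp(17.67 * (t_k - 273.15) / (t_k - 273.15 + 243.5))
}

# saturation mixing ratio (kg kg-1); guarded against es approaching p
.sat_mixing_ratio <- function(p, t_k) {
  es <- pmin(.sat_vapor_pressure(t_k), 0.9 * p)
  .const$eps * es / (p - es)
}

.q_to_r <- function(q) q / (1 - q)          # specific humidity -> mixing ratio

# virtual temperature from temperature and vapour mixing ratio
.virtual_temp <- function(t_k, r) t_k * (1 + r / .const$eps) / (1 + r)

# Lifting condensation level of the surface parcel: Bolton's empirical
# LCL temperature, then the dry adiabat gives the LCL pressure.
.lcl <- function(ps, tas, r_sfc) {
  if (r_sfc <= 0) return(list(p = 0, t = NA_real_))  # never saturates
  e <- ps * r_sfc / (.const$eps + r_sfc)             # vapour pressure, Pa
  e_hpa <- max(e / 100, 1e-12)
  t_lcl <- 2840 / (3.5 * log(tas) - log(e_hpa) - 4.805) + 55
  t_lcl <- min(t_lcl, tas)
  kappa <- .const$Rd / .const$cp
  p_lcl <- ps * (t_lcl / tas)^(1 / kappa)
  list(p = p_lcl, t = t_lcl)
}

# dT/dp on the pseudo-adiabat (saturated ascent, condensate removed).
.pseudo_dTdp <- function(p, t_k) {
  rs <- .sat_mixing_ratio(p, t_k)
  with(.const,
       (1 / p) * (Rd * t_k + Lv * rs) /
         (cp + Lv^2 * rs * eps / (Rd * t_k^2)))
}

# RK4 integration of the pseudo-adiabat from (p0, t0) down to pressure
# p1 < p0 with steps no coarser than `h_max` Pa. Returns temperature at p1.
.pseudo_ascend <- function(p0, t0, p1, h_max) {
  if (p1 >= p0) return(t0)
  n <- ceiling((p0 - p1) / h_max)
  h <- (p1 - p0) / n
  t_k <- t0
  p <- p0
  for (i in seq_len(n)) {
    k1 <- .pseudo_dTdp(p, t_k)
    k2 <- .pseudo_dTdp(p + h / 2, t_k + h * k1 / 2)
    k3 <- .pseudo_dTdp(p + h / 2, t_k + h * k2 / 2)
    k4 <- .pseudo_dTdp(p + h, t_k + h * k3)
    t_k <- t_k + h * (k1 + 2 * k2 + 2 * k3 + k4) / 6
    p <- p0 + i * h
  }
  t_k
}

# Parcel temperature and vapour mixing ratio at a set of pressures
# (descending), lifting from the surface state. One integration pass.
.parcel_states <- function(ps, tas, q_sfc, pressures, ascent_dp) {
  kappa <- .const$Rd / .const$cp
  r_sfc <- .q_to_r(q_sfc)
  lcl <- .lcl(ps, tas, r_sfc)
  t_out <- numeric(length(pressures))
  r_out <- numeric(length(pressures))
  p_prev <- lcl$p
  t_prev <- lcl$t
  for (i in seq_along(pressures)) {
    p <- pressures[i]
    if (p >= lcl$p) {                       # unsaturated: dry adiabat
      t_out[i] <- tas * (p / ps)^kappa
      r_out[i] <- r_sfc
    } else {                                # saturated: pseudo-adiabat
      t_prev <- .pseudo_ascend(p_prev, t_prev, p, ascent_dp)
      p_prev <- p
      t_out[i] <- t_prev
      r_out[i] <- .sat_mixing_ratio(p, t_prev)
    }
  }
  list(temperature = t_out, mixing_ratio = r_out)
}

# Environmental virtual temperature interpolated to target pressures,
# linear in log-pressure. Targets outside the sounding's range get NA.
.env_virtual_temp <- function(profile, pressures) {
  lp_env <- log(profile$pressure_levels)
  t_i <- stats::approx(lp_env, profile$env_temperature, xout = log(pressures),
                       rule = 1)$y
  if (!is.null(profile$env_humidity)) {
    q_i <- stats::approx(lp_env, profile$env_humidity, xout = log(pressures),
                         rule = 1)$y
    .virtual_temp(t_i, .q_to_r(q_i))
  } else {
    t_i
  }
}

#' Lift the near-surface parcel to a pressure level
#'
#' Takes the surface parcel up a dry adiabat to its lifting
#' condensation level and then pseudo-adiabatically (condensate removed
#' on formation, no entrainment) to `level_pressure`, and returns its
#' thermodynamic state there. The parcel density uses the virtual
#' temperature of the (possibly saturated) parcel.
#'
#' @param profile an [atmospheric_profile()].
#' @param level_pressure target pressure, Pa.
#' @param config a [cape_config()].
#'
#' @return A list of class `parcel_state` with `pressure`,
#'   `temperature` (K), `vapor_mixing` (kg kg^-1), `density`
#'   (kg m^-3), `buoyancy_term` (m^3 kg^-1, the specific-volume excess
#'   over the environment, `NA` when the environment is undefined
#'   there), `saturated`, and `below_ground` (`TRUE` when
#'   `level_pressure` exceeds the surface pressure; such levels are
#'   excluded from the CAPE sum).
#' @seealso [compute_cape()]
#' @export
lift_parcel <- function(profile, level_pressure, config = cape_config()) {
  stopifnot(inherits(profile, "atmospheric_profile"),
            inherits(config, "cape_config"))
  if (!is.finite(level_pressure) || level_pressure <= 0) {
    stop("invalid-input: level_pressure must be finite and > 0", call. = FALSE)
  }
  if (level_pressure > profile$surface_pressure) {
    return(structure(list(pressure = level_pressure, temperature = NA_real_,
                          vapor_mixing = NA_real_, density = NA_real_,
                          buoyancy_term = NA_real_, saturated = NA,
                          below_ground = TRUE),
                     class = "parcel_state"))
  }
  st <- .parcel_states(profile$surface_pressure, profile$surface_temperature,
                       profile$surface_humidity, level_pressure,
                       config$ascent_dp)
  tv <- .virtual_temp(st$temperature, st$mixing_ratio)
  rho <- level_pressure / (.const$Rd * tv)
  tv_e <- .env_virtual_temp(profile, level_pressure)
  b <- if (is.na(tv_e)) NA_real_ else {
    1 / rho - .const$Rd * tv_e / level_pressure  # 1/rho - 1/rho_e
  }
  lcl_p <- .lcl(profile$surface_pressure, profile$surface_temperature,
                .q_to_r(profile$surface_humidity))$p
  structure(list(pressure = level_pressure, temperature = st$temperature,
                 vapor_mixing = st$mixing_ratio, density = rho,
                 buoyancy_term = b, saturated = level_pressure < lcl_p,
                 below_ground = FALSE),
            class = "parcel_state")
}

#' Nondilute near-surface-parcel CAPE by discrete buoyancy sum
#'
#' CAPE is the sum over discrete pressure levels of
#' `dp * H(b_i) * b_i`, where `b_i = 1/rho_i - 1/rho_e,i` is the
#' specific-volume difference between the lifted parcel (density
#' `rho_i`) and the environment (`rho_e,i`), `H` is the Heaviside step
#' function (only positively buoyant levels contribute), and `dp` is
#' the level spacing. With the default configuration the sum runs over
#' ten levels from 100 kPa to 10 kPa with `dp` = 10 kPa.
#'
#' Levels below ground (pressure exceeding the surface pressure) and
#' levels outside the sounding's pressure range are excluded from the
#' sum; at least two usable levels must remain.
#'
#' @inheritParams lift_parcel
#' @return CAPE in J kg^-1 (a non-negative scalar).
#' @examples
#' prof <- atmospheric_profile(
#'   pressure_levels = seq(1e5, 1e4, by = -5e3),
#'   env_temperature = 298 * (seq(1e5, 1e4, by = -5e3) / 1e5)^0.19,
#'   surface_pressure = 1e5, surface_temperature = 302,
#'   surface_humidity = 0.018)
#' compute_cape(prof)
#' @export
compute_cape <- function(profile, config = cape_config()) {
  stopifnot(inherits(profile, "atmospheric_profile"),
            inherits(config, "cape_config"))
  lv <- config$levels
  usable <- lv <= profile$surface_pressure
  tv_e <- rep(NA_real_, length(lv))
  tv_e[usable] <- .env_virtual_temp(profile, lv[usable])
  usable <- usable & !is.na(tv_e)
  if (sum(usable) < 2) {
    stop("insufficient-profile: fewer than 2 usable levels", call. = FALSE)
  }
  p_use <- lv[usable]
  st <- .parcel_states(profile$surface_pressure, profile$surface_temperature,
                       profile$surface_humidity, p_use, config$ascent_dp)
  tv_p <- .virtual_temp(st$temperature, st$mixing_ratio)
  b <- (.const$Rd / p_use) * (tv_p - tv_e[usable])   # 1/rho_i - 1/rho_e,i
  pos <- if (config$zero_buoyancy_counts) b >= 0 else b > 0
  sum(config$dp * b[pos])
}

#' Mean-afternoon CAPE climatology from hourly fields
#'
#' Averages a sequence of timestamped hourly CAPE rasters over a fixed
#' set of UTC hours (default 17:00-23:00, the local Amazon afternoon)
#' and an optional range of years, cell by cell.
#'
#' @param fields list of [cape_field()] objects on one common grid.
#' @param times `POSIXct` vector (UTC) of the same length as `fields`.
#' @param hours_utc integer hours to keep (default `17:23`).
#' @param years optional integer vector of years to keep.
#'
#' @return A [cape_field()] of per-cell means over exactly the selected
#'   hours; cells missing in every selected field stay `NA`.
#' @export
afternoon_mean_cape <- function(fields, times, hours_utc = 17:23,
                                years = NULL) {
  stopifnot(is.list(fields), length(fields) == length(times))
  if (!inherits(times, "POSIXct")) stop("`times` must be POSIXct", call. = FALSE)
  lt <- as.POSIXlt(times, tz = "UTC")
  keep <- lt$hour %in% hours_utc
  if (!is.null(years)) keep <- keep & (lt$year + 1900L) %in% years
  if (!any(keep)) stop("empty-selection: no timestamps match", call. = FALSE)
  sel <- fields[keep]
  ref <- sel[[1]]
  for (f in sel) {
    if (!identical(f$lon, ref$lon) || !identical(f$lat, ref$lat)) {
      stop("alignment: fields are not on one grid", call. = FALSE)
    }
  }
  acc <- array(0, dim(ref$values))
  cnt <- array(0L, dim(ref$values))
  for (f in sel) {
    ok <- !is.na(f$values)
    acc[ok] <- acc[ok] + f$values[ok]
    cnt <- cnt + ok
  }
  mean_v <- ifelse(cnt > 0, acc / cnt, NA_real_)
  cape_field(mean_v, ref$lon, ref$lat, ref$cell_areas, ref$mask,
             provenance = "afternoon-mean")
}

#' Daily CAPE fields from ESM surface and profile output
#'
#' Applies [compute_cape()] cell by cell and day by day to
#' CMIP-style daily output: surface temperature (`tas`, K), surface
#' specific humidity (`huss`, kg kg^-1), surface pressure (`ps`, Pa)
#' and temperature on standard pressure levels (`ta`, K).
#'
#' @param tas,huss,ps numeric matrices `[n_cell, n_day]`.
#' @param ta numeric array `[n_cell, n_day, n_level]`.
#' @param plev pressures (Pa) of `ta`'s levels, strictly decreasing.
#' @param hus optional array like `ta` of environmental specific
#'   humidity; omitted means a dry environmental density.
#' @param config a [cape_config()].
#'
#' @return Numeric matrix `[n_cell, n_day]` of daily CAPE (J kg^-1).
#'   Average over day subsets to form period climatologies (e.g. a
#'   current 1990-2015 and a future 2070-2099 mean).
#' @export
daily_cape_from_esm <- function(tas, huss, ps, ta, plev, hus = NULL,
                                config = cape_config()) {
  tas <- as.matrix(tas); huss <- as.matrix(huss); ps <- as.matrix(ps)
  d <- dim(tas)
  if (!all(dim(huss) == d) || !all(dim(ps) == d) ||
      length(dim(ta)) != 3 || !all(dim(ta)[1:2] == d) ||
      dim(ta)[3] != length(plev) ||
      (!is.null(hus) && !all(dim(hus) == dim(ta)))) {
    stop("alignment: field dimensions or level count mismatch", call. = FALSE)
  }
  out <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      prof <- atmospheric_profile(
        pressure_levels = plev, env_temperature = ta[i, j, ],
        env_humidity = if (is.null(hus)) NULL else hus[i, j, ],
        surface_pressure = ps[i, j], surface_temperature = tas[i, j],
        surface_humidity = huss[i, j])
      out[i, j] <- compute_cape(prof, config)
    }
  }
  out
}

#' Period-mean CAPE climatology from daily values
#'
#' @param daily matrix `[n_cell, n_day]` as returned by
#'   [daily_cape_from_esm()]; cells are column-major over the grid.
#' @param lon,lat grid cell-center coordinates (`n_cell ==
#'   length(lon) * length(lat)`).
#' @param days optional integer subset of day columns (e.g. a period).
#' @param provenance label for the resulting field.
#' @return A [cape_field()] of per-cell means.
#' @export
cape_climatology <- function(daily, lon, lat, days = NULL,
                             provenance = "esm-period-mean") {
  if (is.null(days)) days <- seq_len(ncol(daily))
  m <- rowMeans(daily[, days, drop = FALSE])
  cape_field(matrix(m, length(lon), length(lat)), lon, lat,
             provenance = provenance)
}
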