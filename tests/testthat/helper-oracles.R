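# Independent oracles used across the suite. They share the package's
# thermodynamic constants and saturation formula (the quantities under
# test are the ascent and the buoyancy sum, not the constants) but
# follow different numerical routes: saturation is detected
# incrementally during a fine Euler march instead of via a closed-form
# LCL, and integration is first-order Euler instead of Runge-Kutta.

.o_const <- list(Rd = 287.04, Rv = 461.5, cp = 1005.7, Lv = 2.501e6,
                 eps = 287.04 / 461.5)

.o_es <- function(t_k) 611.2 * exp(17.67 * (t_k - 273.15) / (t_k - 273.15 + 243.5))

.o_rs <- function(p, t_k) {
  es <- min(.o_es(t_k), 0.9 * p)
  .o_const$eps * es / (p - es)
}

.o_dTdp <- function(p, t_k) {
  rs <- .o_rs(p, t_k)
  with(.o_const,
       (1 / p) * (Rd * t_k + Lv * rs) / (cp + Lv^2 * rs * eps / (Rd * t_k^2)))
}

# Fine-step Euler lift of the surface parcel to every pressure in
# `p_targets` (descending). Saturation onset is detected where the
# dry-adiabat mixing ratio first exceeds saturation during the march.
# Returns temperature and vapour mixing ratio at each target.
oracle_lift <- function(ps, tas, huss, p_targets, dp = 100) {
  kappa <- .o_const$Rd / .o_const$cp
  r0 <- huss / (1 - huss)
  t_cur <- tas
  p_cur <- ps
  saturated <- FALSE
  t_out <- numeric(length(p_targets))
  r_out <- numeric(length(p_targets))
  for (k in seq_along(p_targets)) {
    pt <- p_targets[k]
    while (p_cur - pt > 1e-9) {
      step <- min(dp, p_cur - pt)
      if (!saturated) {
        t_try <- tas * ((p_cur - step) / ps)^kappa
        if (r0 > 0 && .o_rs(p_cur - step, t_try) <= r0) {
          saturated <- TRUE  # crossed the LCL within this step
        } else {
          t_cur <- t_try
        }
      }
      if (saturated) t_cur <- t_cur - step * .o_dTdp(p_cur, t_cur)
      p_cur <- p_cur - step
    }
    t_out[k] <- t_cur
    r_out[k] <- if (saturated) .o_rs(pt, t_cur) else r0
  }
  list(temperature = t_out, mixing_ratio = r_out)
}

# Brute-force buoyancy sum at arbitrary level spacing `dp_sum`, using
# the Euler-lift parcel and log-pressure interpolation of the
# environmental (virtual) temperature.
oracle_cape <- function(profile, dp_sum, ascent_dp = 100) {
  levels <- seq(1e5, 1e4, by = -dp_sum)
  levels <- levels[levels <= profile$surface_pressure]
  st <- oracle_lift(profile$surface_pressure, profile$surface_temperature,
                    profile$surface_humidity, levels, dp = ascent_dp)
  tv_p <- st$temperature * (1 + st$mixing_ratio / .o_const$eps) /
    (1 + st$mixing_ratio)
  t_e <- approx(log(profile$pressure_levels), profile$env_temperature,
                xout = log(levels), rule = 1)$y
  tv_e <- if (is.null(profile$env_humidity)) t_e else {
    q_e <- approx(log(profile$pressure_levels), profile$env_humidity,
                  xout = log(levels), rule = 1)$y
    r_e <- q_e / (1 - q_e)
    t_e * (1 + r_e / .o_const$eps) / (1 + r_e)
  }
  b <- (.o_const$Rd / levels) * (tv_p - tv_e)
  keep <- !is.na(b) & b > 0
  sum(dp_sum * b[keep])
}

# Standard idealized unstable sounding: hydrostatic 6.5 K/km lapse
# from 298 K at 100 kPa, warm moist surface parcel.
unstable_profile <- function(tas = 302, huss = 0.018, t0 = 298,
                             ps = 1e5, dp = 1e3) {
  p <- seq(1e5, 1e4, by = -dp)
  atmospheric_profile(p, t0 * (p / 1e5)^(287.04 * 0.0065 / 9.80665),
                      surface_pressure = ps, surface_temperature = tas,
                      surface_humidity = huss)
}

# Small synthetic field on a coarse grid for fast model tests.
small_field <- function(seed = 1, nx = 30, ny = 24, res = 0.5) {
  sc <- synthetic_scenario(
    seed = seed,
    grid = grid_spec(res, c(-70, -70 + nx * res, -10, -10 + ny * res)),
    correlation_length = 1.5)
  make_cape_field(sc)
}
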