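mk_field <- function(vals, lon = seq(-70, -65.5, by = 0.5),
                     lat = seq(-5, -1.5, by = 0.5), ...) {
  cape_field(matrix(vals, length(lon), length(lat)), lon, lat, ...)
}

test_that("delta change is the per-cell fractional difference", {
  lon <- seq(-70, -65.5, by = 0.5); lat <- seq(-5, -1.5, by = 0.5)
  set.seed(41)
  cur <- mk_field(runif(80, 200, 1500), lon, lat)
  expect_true(all(delta_cape(cur, cur)$values == 0))

  one <- mk_field(500, lon, lat)
  one$values[2, 3] <- 500
  fut <- mk_field(630, lon, lat)
  expect_equal(delta_cape(one, fut)$values[2, 3], 0.26)

  fut2 <- mk_field(runif(80, 100, 2500), lon, lat)
  d <- delta_cape(cur, fut2)
  loop <- matrix(NA_real_, 10, 8)
  for (i in 1:10) for (j in 1:8) {
    loop[i, j] <- (fut2$values[i, j] - cur$values[i, j]) / cur$values[i, j]
  }
  expect_equal(d$values, loop)

  # near-zero current CAPE is masked, not divided
  low <- cur; low$values[1, 1] <- 0.2
  expect_true(is.na(delta_cape(low, fut2)$values[1, 1]))
  # misaligned grids refuse to combine
  other <- cape_field(matrix(500, 3, 3), lon = 1:3, lat = 1:3)
  expect_error(delta_cape(cur, other), "alignment")
})

test_that("delta scaling multiplies the baseline grid-wise", {
  set.seed(42)
  base <- mk_field(runif(80, 100, 1500))
  d0 <- delta_cape(base, base)
  expect_equal(scale_future_cape(d0, base)$values, base$values)

  d1 <- d0; d1$values[] <- 1
  expect_equal(scale_future_cape(d1, base)$values, 2 * base$values)

  dh <- d0; dh$values[] <- runif(80, -0.3, 0.8)
  expect_equal(scale_future_cape(dh, base)$values,
               (1 + dh$values) * base$values)
  expect_equal(scale_future_cape(dh, base)$provenance, "scaled-future")

  dneg <- d0; dneg$values[3, 3] <- -1.2
  expect_error(scale_future_cape(dneg, base), "negative-CAPE")
})

test_that("favorable area uses a strict threshold over in-region cells", {
  base <- mk_field(500)
  expect_equal(favorable_area(base, 1023), 0)
  expect_equal(favorable_area(base, 499), sum(base$cell_areas))

  set.seed(43)
  rnd <- mk_field(runif(80, 0, 2000))
  thr <- 1023
  loop <- 0
  for (i in 1:10) for (j in 1:8) {
    if (rnd$values[i, j] > thr) loop <- loop + rnd$cell_areas[i, j]
  }
  expect_equal(favorable_area(rnd, thr), loop)

  # a cell exactly at the threshold is excluded
  at <- mk_field(1023)
  expect_equal(favorable_area(at, 1023), 0)

  empty <- mk_field(NA_real_)
  expect_error(favorable_area(empty, 1023), "empty-field")
})

test_that("favorable-area increase follows the area ratio", {
  set.seed(44)
  cur <- mk_field(runif(80, 500, 1500))
  expect_equal(favorable_area_increase(cur, cur, 1023), 0)

  # construct a future whose favorable area is exactly double
  thr <- as.numeric(stats::quantile(cur$values, 0.8))  # top 20% favorable
  fav_cur <- cur$values > thr
  fut <- cur
  # promote just enough additional cells to double the favorable area
  areas <- cur$cell_areas
  target <- sum(areas[fav_cur])
  cand <- order(cur$values, decreasing = TRUE)
  cand <- cand[!fav_cur[cand]]
  extra <- cand[cumsum(areas[cand]) <= target + 1e-9]
  # same-latitude cells have equal areas, so an exact doubling needs the
  # cumulative area to land exactly; adjust target set until it does
  expect_true(abs(sum(areas[extra]) - target) / target < 0.25)
  fut$values[extra] <- thr * 2
  inc <- favorable_area_increase(cur, fut, thr)
  expect_equal(inc, 100 * sum(areas[extra]) / target)

  low <- mk_field(10)
  expect_error(favorable_area_increase(low, cur, 1023), "undefined-increase")
})

test_that("projected event totals follow the density model", {
  m <- density_model(c(0, 1000, Inf), bin_counts = c(10, 20),
                     bin_areas = c(1e5, 1e5))  # densities d and 2d
  cur <- mk_field(500)    # all area in bin 1
  expect_equal(project_density_increase(m, cur, cur), 0)
  fut <- mk_field(1500)   # all area shifted to bin 2
  expect_equal(project_density_increase(m, cur, fut), 100)

  # planted heterogeneous future vs a per-cell accumulation
  set.seed(45)
  cur2 <- mk_field(runif(80, 100, 1400))
  fut2 <- mk_field(pmin(cur2$values * runif(80, 1, 1.6), 4999))
  inc <- project_density_increase(m, cur2, fut2)
  n_cur <- sum(predict_density(m, cur2$values) * cur2$cell_areas) / 1e4
  n_fut <- sum(predict_density(m, fut2$values) * fut2$cell_areas) / 1e4
  expect_equal(inc, 100 * (n_fut - n_cur) / n_cur)
})

test_that("identity chain: zero delta propagates to zero increases", {
  set.seed(46)
  base <- mk_field(runif(80, 100, 1500))
  m <- density_model(c(0, 700, Inf), c(30, 60), c(2e5, 1e5))
  d0 <- delta_cape(base, base)
  scaled <- scale_future_cape(d0, base)
  expect_equal(favorable_area_increase(base, scaled, 700), 0)
  expect_equal(project_density_increase(m, base, scaled), 0)
})

test_that("pointwise-larger deltas never shrink area or event totals", {
  set.seed(47)
  base <- mk_field(runif(80, 100, 1500))
  m <- density_model(c(0, 400, 900, Inf), c(10, 30, 60), c(2e5, 1e5, 5e4))
  d_small <- delta_cape(base, base); d_small$values[] <- runif(80, 0, 0.3)
  d_large <- d_small; d_large$values <- d_small$values + runif(80, 0, 0.3)
  f_small <- scale_future_cape(d_small, base)
  f_large <- scale_future_cape(d_large, base)
  for (thr in c(400, 900, 1200)) {
    expect_gte(favorable_area(f_large, thr), favorable_area(f_small, thr))
  }
  expect_gte(project_density_increase(m, base, f_large),
             project_density_increase(m, base, f_small))
})

test_that("percentage increases are invariant to a uniform area rescale", {
  set.seed(48)
  base <- mk_field(runif(80, 100, 1500))
  fut <- mk_field(base$values * 1.4)
  m <- density_model(c(0, 700, Inf), c(30, 60), c(2e5, 1e5))
  base2 <- cape_field(base$values, base$lon, base$lat,
                      cell_areas = base$cell_areas * 7, mask = base$mask)
  fut2 <- cape_field(fut$values, fut$lon, fut$lat,
                     cell_areas = fut$cell_areas * 7, mask = fut$mask)
  expect_equal(favorable_area_increase(base, fut, 700),
               favorable_area_increase(base2, fut2, 700))
  expect_equal(project_density_increase(m, base, fut),
               project_density_increase(m, base2, fut2))
})

test_that("ensemble summary gives means and sample SDs across models", {
  set.seed(49)
  base <- mk_field(runif(80, 300, 1400))
  m <- density_model(c(0, 700, Inf), c(30, 60), c(2e5, 1e5))
  mk_res <- function(name, delta) {
    fut <- cape_field(base$values * (1 + delta), base$lon, base$lat,
                      base$cell_areas, base$mask)
    project_model(name, base, fut, base, m, threshold = 700)
  }
  # identical members: SD exactly 0
  same <- ensemble_summary(list(mk_res("a", 0.2), mk_res("b", 0.2)))
  expect_equal(same$sd_area_increase, 0)
  expect_equal(same$sd_density_increase, 0)

  # hand-built results with increases 40% and 60%
  r1 <- mk_res("x", 0.1); r1$area_increase_pct <- 40
  r2 <- mk_res("y", 0.1); r2$area_increase_pct <- 60
  s <- ensemble_summary(list(r1, r2))
  expect_equal(s$mean_area_increase, 50)
  expect_equal(s$sd_area_increase, sd(c(40, 60)))
  expect_equal(s$sd_area_increase, 14.14, tolerance = 1e-3)

  # ten members vs direct mean/sd arithmetic
  deltas <- runif(10, 0.05, 0.5)
  res <- lapply(seq_along(deltas), function(i)
    mk_res(sprintf("m%02d", i), deltas[i]))
  s10 <- ensemble_summary(res)
  vals <- vapply(res, `[[`, numeric(1), "area_increase_pct")
  expect_equal(s10$mean_area_increase, mean(vals))
  expect_equal(s10$sd_area_increase, sd(vals))

  expect_error(ensemble_summary(list()), "empty-ensemble")

  # report table rounds to integers and appends ensemble rows
  tab <- projection_table(s10)
  expect_equal(nrow(tab), 12)
  expect_true(all(tab$area_increase_pct == round(tab$area_increase_pct)))
  expect_equal(tab$model[11:12], c("Ensemble Mean", "One standard deviation"))
})
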