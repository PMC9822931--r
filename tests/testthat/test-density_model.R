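test_that("point sampling returns containing-cell values in event order", {
  f <- small_field(seed = 3)
  # events exactly at cell centers pick up those cells' values
  ev <- event_set(lon = f$lon[c(2, 9)], lat = f$lat[c(4, 11)])
  expect_equal(sample_cape_at_points(f, ev),
               c(f$values[2, 4], f$values[9, 11]))

  # constant field: every event gets the constant
  fc <- cape_field(matrix(321, 10, 10), lon = f$lon[1:10], lat = f$lat[1:10])
  set.seed(5)
  evc <- event_set(lon = runif(20, min(fc$lon), max(fc$lon)),
                   lat = runif(20, min(fc$lat), max(fc$lat)))
  expect_true(all(sample_cape_at_points(fc, evc) == 321))

  # 50 random points vs a brute-force containment search
  set.seed(6)
  ev50 <- event_set(lon = runif(50, min(f$lon) - 0.24, max(f$lon) + 0.24),
                    lat = runif(50, min(f$lat) - 0.24, max(f$lat) + 0.24))
  res <- if (length(f$lon) > 1) diff(f$lon)[1] else 1
  brute <- sapply(seq_len(50), function(k) {
    i <- which(abs(f$lon - ev50$lon[k]) <= res / 2)[1]
    j <- which(abs(f$lat - ev50$lat[k]) <= res / 2)[1]
    f$values[i, j]
  })
  expect_equal(sample_cape_at_points(f, ev50), brute)

  # out-of-region points are reported by index
  bad <- event_set(lon = c(f$lon[1], 100), lat = c(f$lat[1], 0))
  expect_error(sample_cape_at_points(f, bad), "out-of-region.*2")
})

test_that("equal-count fitting splits events into near-equal bins", {
  f <- small_field(seed = 4)
  # exact division: 12 events, 6 bins, 2 each
  set.seed(7)
  capes12 <- sample(as.vector(f$values), 12)
  m12 <- fit_density_model(capes12, f)
  expect_equal(m12$bin_counts, rep(2, 6))

  # non-divisible: counts differ by at most one and conserve the total
  capes100 <- sample(as.vector(f$values), 100)
  m100 <- fit_density_model(capes100, f)
  expect_equal(sum(m100$bin_counts), 100)
  expect_lte(max(m100$bin_counts) - min(m100$bin_counts), 1)

  # outer edges extended; areas partition the region; densities consistent
  expect_identical(m100$bin_edges[1], 0)
  expect_true(is.infinite(m100$bin_edges[7]))
  expect_equal(sum(m100$bin_areas), sum(f$cell_areas[f$mask]))
  expect_equal(m100$bin_density, m100$bin_counts / m100$bin_areas * 1e4)

  # membership by the fitted edges reproduces the counts (distinct values)
  member <- findInterval(capes100, m100$bin_edges)
  expect_equal(tabulate(member, 6), m100$bin_counts)

  expect_error(fit_density_model(capes12[1:5], f), "underdetermined-model")
})

test_that("tied CAPE values at a group boundary trigger a tie warning", {
  f <- small_field(seed = 8)
  capes <- c(200, 200, 200, 300, 400, 500, 600, 700, 800, 900, 950, 990)
  expect_warning(fit_density_model(capes, f, n_bins = 6), "ties")

  # ties so pervasive that edges collapse entirely are rejected
  expect_error(
    suppressWarnings(fit_density_model(rep(c(200, 300), 6), small_field(8),
                                       n_bins = 6)),
    "tie degeneracy")
})

test_that("density prediction is a bounded step function on [0, Inf)", {
  m <- density_model(c(0, 400, 900, Inf), bin_counts = c(10, 20, 60),
                     bin_areas = c(5e5, 3e5, 2e5))
  # extensions: below the observed range and far above it
  expect_equal(predict_density(m, 0), m$bin_density[1])
  expect_equal(predict_density(m, 1e6), m$bin_density[3])
  # a value exactly on an interior edge belongs to the upper bin
  expect_equal(predict_density(m, 400), m$bin_density[2])
  expect_equal(predict_density(m, 900), m$bin_density[3])
  # piecewise-constant and bounded by the bin densities
  x <- seq(0, 5000, by = 13)
  y <- predict_density(m, x)
  expect_true(all(y %in% m$bin_density))
  expect_error(predict_density(m, -5), ">= 0")
})

test_that("bootstrap SDs are seed-reproducible and match the binomial form", {
  f <- small_field(seed = 9)
  set.seed(10)
  capes <- sample(as.vector(f$values), 400)
  m <- fit_density_model(capes, f)
  sd1 <- bootstrap_density_sd(capes, m, n_boot = 400, seed = 123)
  sd2 <- bootstrap_density_sd(capes, m, n_boot = 400, seed = 123)
  expect_identical(sd1, sd2)
  expect_error(bootstrap_density_sd(capes, m, n_boot = 1, seed = 1),
               "invalid-replicates")

  # all events in one bin: resampling cannot move them, SD is exactly 0
  m1 <- density_model(c(0, 1e4, Inf), bin_counts = c(8, 0),
                      bin_areas = c(1e5, 1e5))
  sd_one <- bootstrap_density_sd(rep(50, 8), m1, n_boot = 200, seed = 4)
  expect_identical(sd_one, c(0, 0))
})

test_that("threshold selection maximizes the aggregate density contrast", {
  # two bins: the single interior edge is the only candidate
  m2 <- density_model(c(0, 700, Inf), c(10, 80), c(1e5, 1e5))
  expect_equal(favorable_threshold(m2), 700)

  # (1,1,1,8,8,8) over equal areas: the edge between bins 3 and 4
  m6 <- density_model(c(0, 1:5 * 200, Inf),
                      bin_counts = c(1, 1, 1, 8, 8, 8) * 10,
                      bin_areas = rep(1e5, 6))
  expect_equal(favorable_threshold(m6), 600)

  # flat density: warning, lowest interior edge
  mf <- density_model(c(0, 1:5 * 200, Inf), rep(10, 6), rep(1e5, 6))
  expect_warning(thr <- favorable_threshold(mf), "no-threshold")
  expect_equal(thr, 200)
})

test_that("threshold recovery from a planted step intensity", {
  sc <- synthetic_scenario(
    seed = 31, grid = grid_spec(0.25, c(-70, -58, -10, 0)),
    intensity_fn = function(cape) ifelse(cape > 800, 4, 0.5))
  f <- make_cape_field(sc)
  ev <- simulate_windthrows(f, sc$intensity_fn, seed = 32)
  capes <- sample_cape_at_points(f, ev)
  m <- suppressWarnings(fit_density_model(capes, f))
  # recovered within one (first-bin) width of the planted change point
  width <- diff(m$bin_edges)[2]
  expect_lt(abs(m$threshold - 800), max(width, m$bin_edges[2]))
})

test_that("density ratio aggregates bins split at the threshold", {
  # homogeneous model: ratio is exactly 1
  mf <- density_model(c(0, 1:5 * 200, Inf), rep(10, 6), rep(1e5, 6))
  expect_equal(density_ratio(mf, 600), 1.0)

  # two-class construction with densities 4 and 1 (per 1e4 km2)
  m2 <- density_model(c(0, 500, Inf), bin_counts = c(4, 3),
                      bin_areas = c(1e4, 3e4))
  expect_equal(density_ratio(m2, 500), 1 / 4)
  m2b <- density_model(c(0, 500, Inf), bin_counts = c(3, 4),
                       bin_areas = c(3e4, 1e4))
  expect_equal(density_ratio(m2b, 500), 4.0)

  # a threshold interior to a finite bin splits it linearly
  expect_equal(density_ratio(mf, 300), 1.0)
  # errors: nothing below, or threshold in the unbounded bin
  expect_error(density_ratio(density_model(c(0, 500, Inf), c(0, 7),
                                           c(1e4, 1e4)), 500),
               "undefined-ratio")
  expect_error(density_ratio(m2, 5000), "unbounded")
})

test_that("fitted densities are unbiased for a planted step intensity", {
  # parameter-recovery property: across replicate Poisson simulations the
  # fitted per-bin density stays within 3 binomial-ish SE of the truth
  sc <- synthetic_scenario(
    seed = 51, grid = grid_spec(0.5, c(-70, -55, -10, 2)),
    intensity_fn = function(cape) ifelse(cape > 1023, 2.8, 0.35))
  f <- make_cape_field(sc)
  n_rep <- 30
  ok <- logical(0)
  for (r in seq_len(n_rep)) {
    ev <- simulate_windthrows(f, sc$intensity_fn, seed = 1000 + r)
    if (nrow(ev) < 60) next
    capes <- sample_cape_at_points(f, ev)
    m <- suppressWarnings(fit_density_model(capes, f))
    # analytic truth per fitted bin: expected events from the planted
    # intensity over exactly the cells that fall in that bin
    cells <- f$mask & !is.na(f$values)
    bin_of <- findInterval(f$values[cells], m$bin_edges)
    lam_cell <- sc$intensity_fn(f$values[cells]) * f$cell_areas[cells] / 1e4
    for (k in 1:6) {
      exp_count <- sum(lam_cell[bin_of == k])
      truth_dens <- exp_count / m$bin_areas[k] * 1e4
      se <- sqrt(exp_count) / m$bin_areas[k] * 1e4
      ok <- c(ok, abs(m$bin_density[k] - truth_dens) <= 3 * se)
    }
  }
  expect_gt(mean(ok), 0.95)
})
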