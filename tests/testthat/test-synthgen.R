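test_that("snow is binary, 1 far above the front and 0 far behind it", {
  cfg <- snow_front_config(noise_p = 0)
  snow <- make_snow_series(cfg)
  expect_true(all(snow$values %in% c(0, 1)))
  k <- cfg$melt_steepness
  L1 <- front_latitude(cfg, cfg$dates[1])
  above <- which.min(abs(snow$lat - (L1 + 10 / k)))
  expect_equal(unname(snow$values[above, 1, 1]), 1)
  # same cell after the front has moved 10/k degrees past it
  lat_cell <- snow$lat[above]
  t_past <- which(front_latitude(cfg) > lat_cell + 10 / k)[1]
  expect_equal(unname(snow$values[above, 1, t_past]), 0)
})

test_that("column snow fraction at the front matches a direct cell count", {
  cfg <- snow_front_config(noise_p = 0)
  snow <- make_snow_series(cfg)
  for (k in c(10, 40, 80)) {
    L <- front_latitude(cfg, cfg$dates[k])
    frac_sim <- mean(snow$values[, 1, k])
    frac_direct <- mean(snow$lat >= L)   # cells at/above the front
    expect_equal(frac_sim, frac_direct,
                 tolerance = 1.5 / length(snow$lat))
  }
})

test_that("deterministic melt never re-freezes", {
  cfg <- snow_front_config(noise_p = 0)
  snow <- make_snow_series(cfg)
  diffs <- apply(snow$values, c(1, 2), function(v) max(diff(v)))
  expect_true(all(diffs <= 0))
})

test_that("rasters and tracks are bit-identical under the same seed", {
  cfg <- snow_front_config(noise_p = 0.05, seed = 99)
  expect_identical(make_snow_series(cfg), make_snow_series(cfg))
  env1 <- make_env_fields(cfg, noise_sd = c(temp = 1, ndvi = 0.05, wind = 2))
  env2 <- make_env_fields(cfg, noise_sd = c(temp = 1, ndvi = 0.05, wind = 2))
  expect_identical(env1, env2)
  land <- tiny_landscape(ndays = 20)
  ac <- agent_config(n_individuals = 2, n_steps = 10, beta = c(snow = -1),
                     seed = 5)
  s1 <- simulate_agents(ac, land$series, land$cfg)
  s2 <- simulate_agents(ac, land$series, land$cfg)
  expect_identical(s1$tracks, s2$tracks)
  expect_identical(s1$strata, s2$strata)
})

test_that("temperature warms with date, NDVI stays in [-1, 1], mean wind is exact", {
  cfg <- snow_front_config()
  env <- make_env_fields(cfg, wind_mean = c(5, 0),
                         noise_sd = c(temp = 0, ndvi = 0, wind = 0))
  tm <- env$temp$values
  expect_true(all(tm[, , 10] > tm[, , 1]))
  expect_true(all(env$ndvi$values >= -1 & env$ndvi$values <= 1))
  expect_true(all(env$wind_u$values == 5))
  expect_true(all(env$wind_v$values == 0))
  # noisy NDVI still clipped
  env2 <- make_env_fields(cfg, ndvi0 = 0.9, noise_sd = c(ndvi = 1))
  expect_true(all(env2$ndvi$values >= -1 & env2$ndvi$values <= 1))
})

test_that("zero coefficients give uniform choice over candidate rank", {
  land <- tiny_landscape(ndays = 40)
  ac <- agent_config(n_individuals = 30, n_steps = 38,
                     beta = c(snow = 0, wind_support = 0, crosswind = 0),
                     K = 10, seed = 11)
  sim <- simulate_agents(ac, land$series, land$cfg)
  ch <- sim$strata$candidate[sim$strata$case == 1]
  n_dec <- length(ch)
  expect_gte(n_dec, 1000)
  freq <- tabulate(ch, 10) / n_dec
  # binomial error band around 1/10
  se <- sqrt(0.1 * 0.9 / n_dec)
  expect_true(all(abs(freq - 0.1) < 4 * se))
})

test_that("strong snow avoidance picks a snow-free candidate almost always", {
  land <- tiny_landscape(ndays = 40)
  ac <- agent_config(n_individuals = 20, n_steps = 38, coupling = "ON_FRONT",
                     beta = c(snow = -10), seed = 3)
  sim <- simulate_agents(ac, land$series, land$cfg)
  st <- sim$strata
  per <- split(st, st$stratum)
  mixed <- Filter(function(d) any(d$snow == 0) && any(d$snow == 1), per)
  expect_gt(length(mixed), 50)
  chose_free <- vapply(mixed, function(d) d$snow[d$case == 1] == 0, logical(1))
  expect_gt(mean(chose_free), 0.99)
})

test_that("selection strength matches an independent softmax re-simulation", {
  land <- tiny_landscape(ndays = 40)
  ac <- agent_config(n_individuals = 55, n_steps = 38, coupling = "ON_FRONT",
                     beta = c(snow = -1.5), seed = 21)
  sim <- simulate_agents(ac, land$series, land$cfg)
  st <- sim$strata
  expect_gte(length(unique(st$stratum)), 2000)
  obs_diff <- mean(st$snow[st$case == 1]) - mean(st$snow)
  expect_lt(obs_diff, 0)
  # closed-form expectation of the same softmax on the same candidate sets
  s <- as.integer(factor(st$stratum))
  w <- exp(-1.5 * st$snow)
  p <- as.numeric(w / rowsum(w, s)[s])
  exp_chosen <- sum(st$snow * p) / length(unique(s))
  exp_diff <- exp_chosen - mean(st$snow)
  # Monte-Carlo SE of the mean chosen-snow value
  se <- stats::sd(st$snow[st$case == 1]) / sqrt(length(unique(s)))
  expect_lt(abs(obs_diff - exp_diff), 4 * se)
})

test_that("front coupling orders snow occupancy AHEAD > ON_FRONT > BEHIND", {
  land <- tiny_landscape(ndays = 40)
  occ <- vapply(c("AHEAD", "ON_FRONT", "BEHIND"), function(m) {
    ac <- agent_config(n_individuals = 10, n_steps = 38, coupling = m,
                       beta = c(snow = 0), seed = 8)
    sim <- suppressWarnings(simulate_agents(ac, land$series, land$cfg))
    ch <- sim$strata[sim$strata$case == 1, ]
    mean(ch$snow)
  }, numeric(1))
  expect_true(occ["AHEAD"] > occ["ON_FRONT"])
  expect_true(occ["ON_FRONT"] > occ["BEHIND"])
})

test_that("neighbourhood snow occupancy respects its radius parameter", {
  cfg <- snow_front_config(noise_p = 0)
  snow <- make_snow_series(cfg)
  L <- front_latitude(cfg, cfg$dates[10])
  pts <- data.frame(lon = 20, lat = c(L + 3, L - 3, L),
                    date = cfg$dates[10])
  # radius 0 is the plain nearest-cell annotation
  expect_equal(occupied_snow_fraction(pts, snow, 0),
               as.numeric(annotate_points(pts, snow, quiet = TRUE)))
  occ <- occupied_snow_fraction(pts, snow, radius_km = 60)
  expect_equal(occ[1], 1)              # deep in snow
  expect_equal(occ[2], 0)              # well behind the front
  expect_equal(occ[3], 0.5, tolerance = 0.3)  # straddling the front
})

test_that("candidate distances keep the configured exponential kernel", {
  # wide grid so that the off-grid redraw rule (which preserves the
  # kernel only away from edges) never bites
  cfg <- snow_front_config(
    lon_min = 0, lon_max = 60, lat_min = 45, lat_max = 80, cell_deg = 1,
    dates = seq(as.Date("2016-04-01"), by = "day", length.out = 40),
    front_lat0 = 57, front_speed = 0.2, seed = 2)
  series <- list(snow = make_snow_series(cfg))
  ac <- agent_config(n_individuals = 20, n_steps = 38, step_mean_km = 50,
                     beta = c(snow = 0), seed = 13)
  sim <- simulate_agents(ac, series, cfg)
  d <- sim$strata$dist_km
  expect_gte(length(d), 5000)
  ks <- suppressWarnings(stats::ks.test(d, "pexp", 1 / 50))
  expect_gt(ks$p.value, 0.01)
})
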