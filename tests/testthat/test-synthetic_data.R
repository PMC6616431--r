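test_that("scenario config validates its invariants", {
  expect_error(scenario_config(epochs = c(1990, 1990, 2000)),
               "strictly increasing")
  expect_error(scenario_config(conversion_intensity = 1.4), "\\[0, 1\\]")
  expect_error(scenario_config(n_county = 1), "two counties")
  bad <- diag(6); bad[1, 1] <- 0.5
  expect_error(scenario_config(transitions = rep(list(bad), 5)),
               "sum to 1")
})

test_that("identity transitions reproduce the initial map at every epoch", {
  cfg <- small_config(transitions = rep(list(diag(6)), 5))
  lulc <- generate_lulc_series(cfg, seed = 1)
  for (k in 2:6) expect_identical(lulc[[k]]$codes, lulc[[1]]$codes)
})

test_that("certain conversion empties farmland after the GGP start", {
  cfg <- small_config(conversion_intensity = 1, conversion_grass_frac = 0,
                      conversion_gradient = 0, conversion_decay = 1,
                      baseline_churn = 0, reclamation = 0)
  lulc <- generate_lulc_series(cfg, seed = 2)
  yrs <- vapply(lulc, function(g) g$year, numeric(1))
  for (k in which(yrs > 2000))
    expect_equal(sum(lulc[[k]]$codes == 1L), 0)
  expect_gt(sum(lulc[[which(yrs == 2000)]]$codes == 1L), 0)
})

test_that("conversion fraction matches the binomial expectation", {
  # 0.3 conversion probability, uniform in space, one interval
  cfg <- scenario_config(nrow = 100, ncol = 100, n_county = 4,
                         conversion_intensity = 0.3,
                         conversion_gradient = 0, conversion_decay = 1,
                         baseline_churn = 0, reclamation = 0)
  lulc <- generate_lulc_series(cfg, seed = 3)
  yrs <- vapply(lulc, function(g) g$year, numeric(1))
  k <- which(yrs == 2000)
  farm <- lulc[[k]]$codes == 1L
  n_farm <- sum(farm)
  expect_gt(n_farm, 1000)
  converted <- farm & matrix(lulc[[k + 1L]]$codes %in% c(2L, 3L), 100)
  phat <- sum(converted) / n_farm
  se <- sqrt(0.3 * 0.7 / n_farm)
  expect_lt(abs(phat - 0.3), 3 * se)
})

test_that("restored-area totals equal the generator's conversion log", {
  cfg <- small_config()
  lulc <- generate_lulc_series(cfg, seed = 4)
  zones <- attr(lulc, "zones")
  log <- attr(lulc, "conversion_log")
  for (k in 1:5) {
    ra <- restored_area(lulc[[k]], lulc[[k + 1]], zones)
    lg <- log[log$from_year == cfg$epochs[k], ]
    expect_equal(ra$restored_km2, lg$restored_km2[match(ra$zone, lg$zone)])
  }
})

test_that("lulc generation is deterministic given the seed", {
  cfg <- small_config()
  a <- generate_lulc_series(cfg, seed = 9)
  b <- generate_lulc_series(cfg, seed = 9)
  expect_identical(a, b)
  s1 <- generate_scenario(small_config(), seed = 7)
  s2 <- generate_scenario(small_config(), seed = 7)
  expect_identical(s1, s2)
})

test_that("noise-free NDVI yields an exactly linear regional series", {
  cfg <- small_config(ndvi_noise_sd = 0, ndvi_pixel_sd = 0,
                      ndvi_slope1 = 0.003, ndvi_slope2 = 0.003)
  st <- generate_ndvi_stack(cfg, seed = 1)
  nd <- ndvi_series(st, scenario_zones(cfg))
  reg <- nd[nd$zone == "region", ]
  slopes <- diff(reg$ndvi)
  expect_equal(slopes, rep(0.003, 25), tolerance = 1e-10)
})

test_that("NDVI values stay within [-1, 1] even under extreme settings", {
  cfg <- small_config(ndvi_base = 0.9, ndvi_pixel_sd = 0.5,
                      ndvi_noise_sd = 0.3)
  st <- generate_ndvi_stack(cfg, seed = 2)
  rng <- range(unlist(lapply(st$data, range)))
  expect_gte(rng[1], -1)
  expect_lte(rng[2], 1)
})

test_that("climate fields have the configured moments and respect bounds", {
  # zero spread: constant fields at the configured means
  cfg0 <- small_config(pre_sd = 0, tmp_sd = 0)
  cl0 <- generate_climate(cfg0, seed = 1)
  expect_true(all(cl0$pre == 1000) && all(cl0$tmp == 20))
  # CLT check on independent cells (no smoothing)
  cfg <- scenario_config(nrow = 100, ncol = 100, pre_sd = 50,
                         climate_smooth = 0)
  cl <- generate_climate(cfg, seed = 2)
  expect_lt(abs(mean(cl$pre) - 1000), 3 * 50 / sqrt(1e4))
  # negative precipitation clipped to zero
  cfgn <- small_config(pre_mean = 10, pre_sd = 200)
  cln <- generate_climate(cfgn, seed = 3)
  expect_gte(min(cln$pre), 0)
  expect_gt(mean(cln$pre == 0), 0)
  # smoothing induces positive neighbour correlation
  cfs <- scenario_config(nrow = 60, ncol = 60, climate_smooth = 2)
  cls <- generate_climate(cfs, seed = 4)
  x <- cls$tmp
  expect_gt(cor(as.vector(x[-1, ]), as.vector(x[-60, ])), 0.3)
})

test_that("county tables follow the west-to-east population gradient", {
  ct <- generate_county_tables(small_config(pop_gradient = 0.8))
  dens <- ct$counties$pop_1990 / ct$counties$area_km2
  west <- dens[which.min(ct$counties$east_frac)]
  east <- dens[which.max(ct$counties$east_frac)]
  expect_gt(west, east)
  # gradient 0: equal densities
  ct0 <- generate_county_tables(small_config(pop_gradient = 0))
  d0 <- ct0$counties$pop_1990 / ct0$counties$area_km2
  expect_equal(max(d0) - min(d0), 0, tolerance = 1e-9)
  # the default county count of the full scenario
  ct54 <- generate_county_tables(scenario_config())
  expect_equal(nrow(ct54$counties), 54)
})

test_that("expert matrices are reciprocal and consistency tracks noise", {
  w <- c(0.20, 0.10, 0.24, 0.09, 0.05, 0.22, 0.10)
  clean <- generate_expert_matrices(5, w, noise = 0, seed = 1)
  for (m in clean) {
    expect_equal(m * t(m), matrix(1, 7, 7), tolerance = 1e-12)
    expect_lt(ahp_weights(m)$cr, 1e-8)
  }
  noisy <- generate_expert_matrices(20, w, noise = 0.8, seed = 2)
  crs <- vapply(noisy, function(m) ahp_weights(m)$cr, numeric(1))
  expect_gt(sum(crs > 0.1), 0)   # screening path is exercised
  for (m in noisy) expect_equal(m * t(m), matrix(1, 7, 7),
                                tolerance = 1e-12)
})
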