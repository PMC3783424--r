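test_that("the EOS-80 polynomial reproduces the UNESCO check values", {
  expect_equal(sigma_theta(35, 25), 23.34306, tolerance = 1e-3)
  expect_equal(sigma_theta(35, 5), 27.67547, tolerance = 1e-3)
  expect_equal(sigma_theta(35, 0), 28.10630, tolerance = 1e-3)
})

test_that("density responds with the physical signs and range checks fire", {
  expect_gt(sigma_theta(35, 10), sigma_theta(35, 20))  # thermal expansion
  expect_gt(sigma_theta(36, 15), sigma_theta(35, 15))  # haline contraction
  expect_error(sigma_theta(35, 45), "temperature")
  expect_error(sigma_theta(50, 15), "salinity")
  expect_error(sigma_theta(35, NA), "non-finite")
  expect_error(sigma_theta(35, 15, pressure = 10), "surface-referenced")
  # adapter hook replaces the equation of state
  expect_equal(sigma_theta(35, 15, eos = function(s, t) 1026), 26)
})

test_that("1-m level interpolation is linear in T/S and computes density at levels", {
  lev <- interpolate_levels(c(4, 8), c(16, 12), c(35.5, 35.3))
  expect_equal(lev$depth_m, 1:8)
  expect_equal(lev$temp_c[6], 14)            # midpoint -> arithmetic mean
  expect_equal(lev$temp_c[4], 16)            # level at a bin depth
  expect_equal(lev$temp_c[1], 16)            # above first bin: its value
  expect_equal(lev$sigma_theta[6], sigma_theta(35.4, 14), tolerance = 1e-12)
  # monotone T,S: level density bracketed by bin densities
  s_lo <- sigma_theta(35.5, 16); s_hi <- sigma_theta(35.3, 12)
  expect_true(all(lev$sigma_theta >= min(s_lo, s_hi) - 1e-9 &
                  lev$sigma_theta <= max(s_lo, s_hi) + 1e-9))
  expect_error(interpolate_levels(4, 16, 35.5), "single-bin")
  expect_error(interpolate_levels(c(8, 4), c(12, 16), c(35.3, 35.5)),
               "strictly increasing")
})

test_that("a 0.01 kg/m3-per-metre density ramp puts the mixed layer at 17 m", {
  # sigma rises 0.01 per m below the 4-m reference: delta = 0.125 first
  # reached at 4 + 13 = 17 m (0.13 >= 0.125)
  z <- 1:60
  sig <- 26 + pmax(0, z - 4) * 0.01
  lev <- data.frame(depth_m = z, sigma_theta = sig)
  expect_equal(mixed_layer_depth(lev, delta = 0.125, surface_ref_depth = 4),
               17)
})

test_that("fully mixed columns return the deepest level and shallow casts error", {
  lev <- data.frame(depth_m = 1:50, sigma_theta = rep(26.2, 50))
  expect_equal(mixed_layer_depth(lev), 50)
  lev3 <- data.frame(depth_m = 1:3, sigma_theta = rep(26, 3))
  expect_error(mixed_layer_depth(lev3), "shallower")
})

test_that("a density step at the 30/31-m interface yields MLD 31 m", {
  sig <- c(rep(25.0, 30), rep(25.5, 30))
  lev <- data.frame(depth_m = 1:60, sigma_theta = sig)
  expect_equal(mixed_layer_depth(lev), 31)
})

test_that("thermocline intensity is the maximum per-metre temperature change", {
  iso <- data.frame(depth_m = 1:20, temp_c = rep(15, 20))
  expect_equal(thermocline_intensity(iso), 0)
  lin <- data.frame(depth_m = 1:20, temp_c = 18 - 0.1 * (1:20))
  expect_equal(thermocline_intensity(lin), 0.1, tolerance = 1e-9)
  # synthetic band of slope 0.8 C/m between 10 and 15 m
  t <- c(rep(18, 10), 18 - 0.8 * (1:5), rep(14, 5))
  band <- data.frame(depth_m = 1:20, temp_c = t)
  expect_equal(thermocline_intensity(band), 0.8, tolerance = 1e-9)
})

test_that("benthic values come from the deepest level and thickness closes the column", {
  lev <- interpolate_levels(c(4, 40, 80), c(18, 14, 13), c(35.8, 35.4, 35.3))
  bt <- benthic_and_transition(lev, mld = 30)
  expect_equal(bt$benthic_temp, 13)
  expect_equal(bt$benthic_sal, 35.3)
  expect_equal(bt$transition_thickness, 50)
  expect_equal(bt$transition_thickness + 30, max(lev$depth_m))  # identity
  expect_equal(benthic_and_transition(lev, mld = 80)$transition_thickness, 0)
})

test_that("upwelled-water classification uses strict threshold boundaries", {
  expect_true(classify_upwelled(16.0, 35.5, 26.5))
  expect_false(classify_upwelled(17.0, 35.5, 26.5))  # T boundary strict
  expect_false(classify_upwelled(16.0, 35.7, 26.5))  # salinity too high
  expect_false(classify_upwelled(16.0, 35.6, 26.5))  # S boundary strict
  expect_false(classify_upwelled(16.0, 35.5, 26.0))  # sigma boundary strict
})

test_that("profile summaries carry MLD, thermocline, benthic and month per cast", {
  ocfg <- ocean_config()
  loc <- data.frame(t = as.POSIXct("2010-02-05", tz = "UTC") + 0:3 * 86400,
                    lon = 135 + 0:3 / 10, lat = rep(-35, 4),
                    bottom_m = rep(85, 4))
  sim <- simulate_ctd_profiles(loc, ocfg, seed = 8)
  ws <- summarize_profiles(sim$profiles)
  expect_equal(nrow(ws), 4)
  expect_true(all(ws$month == 2))
  expect_true(all(ws$mld_m > 0 & ws$mld_m <= 85))
  expect_true(all(ws$transition_thickness >= 0))
  expect_true(all(abs(ws$mld_m - sim$truth$true_mld_m) <= 1))
})

test_that("IDW gridding is exact at samples, symmetric between pairs, and matches brute force", {
  gs <- raster_grid(matrix(0, 6, 6), 0, 0, 1, crs = "planar_km")
  lon <- c(1.5, 4.5); lat <- c(3.5, 3.5); val <- c(10, 20)
  f <- monthly_field(lon, lat, val, gs, power = 2, max_dist = 100)
  # cell centred on a sample takes its value
  expect_equal(f$values[3, 2], 10)
  expect_equal(f$values[3, 5], 20)
  # cell equidistant from both samples averages them
  expect_equal(f$values[3, 3] + f$values[3, 4], 30, tolerance = 1e-9)
  expect_equal(f$values[6, 3] + f$values[6, 4], 30, tolerance = 1e-9)
  # brute-force oracle at an arbitrary cell (row 1, col 1): centre (0.5, 5.5)
  d <- sqrt((0.5 - lon)^2 + (5.5 - lat)^2)
  w <- 1 / d^2
  expect_equal(f$values[1, 1], sum(w * val) / sum(w), tolerance = 1e-12)
  # out-of-range cells become missing
  f2 <- monthly_field(1.5, 3.5, 10, gs, max_dist = 1)
  expect_true(is.na(f2$values[1, 6]))
})

test_that("covariate extraction returns one row per point with constant-field sanity", {
  bathy <- raster_grid(matrix(50, 10, 10), 134, -36, 0.2)
  slope <- raster_grid(matrix(1.5, 10, 10), 134, -36, 0.2)
  fld <- raster_grid(matrix(13, 10, 10), 134, -36, 0.2)
  pts <- data.frame(lon = runif(20, 134.5, 135.5),
                    lat = runif(20, -35.5, -34.5),
                    month = rep(c(1, 2), 10))
  cov <- extract_covariates(pts, list(benthic_temp = list("1" = fld,
                                                          "2" = fld)),
                            bathymetry = bathy, slope = slope)
  expect_equal(nrow(cov), 20)
  expect_true(all(cov$depth_m == 50))
  expect_true(all(cov$slope_deg == 1.5))
  expect_true(all(cov$benthic_temp == 13))
  # a point outside the grids produces NA with a warning, not an error
  pts2 <- rbind(pts, data.frame(lon = 150, lat = -35, month = 1))
  expect_warning(cov2 <- extract_covariates(pts2, bathymetry = bathy),
                 "outside")
  expect_true(is.na(cov2$depth_m[21]))
})

test_that("mixed layer depth deepens with ocean depth in the upwelling season", {
  # deeper casts cap the simulated MLD less often -> positive relationship
  ocfg <- ocean_config(mld_by_month = rep(40, 12), mld_jitter_m = 6)
  set.seed(40)
  bottoms <- runif(80, 20, 100)
  loc <- data.frame(t = as.POSIXct("2010-01-15", tz = "UTC") + 1:80 * 3600,
                    lon = 135, lat = -35, bottom_m = bottoms)
  sim <- simulate_ctd_profiles(loc, ocfg, seed = 12)
  ws <- summarize_profiles(sim$profiles)
  reg <- ols_regress(ws$mld_m, bottoms)
  expect_gt(reg$slope, 0)
  expect_lt(reg$p, 0.01)
})
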