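fixes_df <- function(t_h, lon, lat, lc = "3", wet = TRUE,
                     animal_id = "a1") {
  data.frame(animal_id = animal_id, t = t_utc(t_h), lon = lon, lat = lat,
             lc = lc, wet = wet, stringsAsFactors = FALSE)
}

test_that("LC-Z removal drops exactly the unclassified fixes, order preserved", {
  f <- fixes_df(0:5, 135 + (0:5) / 100, rep(-34.5, 6),
                lc = c("3", "Z", "B", "Z", "1", "0"))
  out <- drop_unclassified(f)
  expect_equal(nrow(out), 4)
  expect_identical(out$lc, c("3", "B", "1", "0"))
  expect_equal(nrow(drop_unclassified(f[f$lc == "Z", ])), 0)
  expect_identical(drop_unclassified(f[f$lc != "Z", ]),
                   f[f$lc != "Z", ])
})

test_that("duplicate timestamps keep the better location class, ties keep the first", {
  f <- fixes_df(c(0, 0, 1, 1, 2), 135 + (1:5) / 100, rep(-34.5, 5),
                lc = c("B", "2", "1", "1", "0"))
  out <- dedup_fixes(f)
  expect_equal(nrow(out), 3)
  expect_identical(out$lc, c("2", "1", "0"))
  expect_equal(out$lon[2], 135.03)  # first of the tied pair
  expect_false(any(duplicated(out$t)))
})

test_that("a 100-km spike between slow neighbours is removed by the speed filter", {
  # neighbours move ~2 km/h; the middle fix jumps ~100 km in 1 h
  f <- fixes_df(0:4, c(135, 135.02, 136.1, 135.06, 135.08), rep(-34.5, 5))
  out <- speed_filter(f, vmax = 2.0)
  expect_equal(nrow(out), 4)
  expect_false(136.1 %in% out$lon)
})

test_that("a stationary track passes the speed filter unchanged", {
  f <- fixes_df(0:9, rep(135, 10), rep(-34.5, 10))
  expect_identical(speed_filter(f), f)
  expect_warning(speed_filter(f[1:2, ]), "fewer than 3")
})

test_that("speed filter output survives an exhaustive post-hoc rms rescan and is idempotent", {
  set.seed(12)
  n <- 120
  lon <- 135 + cumsum(rnorm(n, 0, 0.01))
  lat <- -34.5 + cumsum(rnorm(n, 0, 0.01))
  spike <- sample(2:(n - 1), 8)
  lon[spike] <- lon[spike] + runif(8, 0.5, 1.5)
  f <- fixes_df(0:(n - 1) * 2, lon, lat)
  out <- speed_filter(f, vmax = 2.0)
  # independent rescan: no remaining fix may have rms adjacent speed > vmax
  xy <- project_local(out$lon, out$lat, c(median(out$lon), median(out$lat)))
  th <- as.numeric(out$t) / 3600
  sp <- sqrt(diff(xy$x)^2 + diff(xy$y)^2) / diff(th)
  m <- length(sp)
  rms <- sqrt((sp[-m]^2 + sp[-1]^2) / 2)
  expect_true(all(c(sp[1], rms, sp[m]) <= 2.0 * 3.6 + 1e-9))
  expect_identical(speed_filter(out, vmax = 2.0), out)
})

test_that("linear interpolation of collinear fixes lands on the line at the exact 2-h grid", {
  f <- fixes_df(c(0, 4, 8), c(135, 135.2, 135.4), c(-34.5, -34.3, -34.1))
  tr <- interpolate_track(f, dt = 2, mode = "linear")
  expect_identical(tr$t, t_utc(seq(0, 8, by = 2)))
  expect_equal(tr$lon, seq(135, 135.4, by = 0.1), tolerance = 1e-6)
  expect_equal(tr$lat, seq(-34.5, -34.1, by = 0.1), tolerance = 1e-6)
})

test_that("state-space smoothing beats the raw fixes against truth on a noisy simulation", {
  out <- simulate_tracks(sim_config(seed = 3, n_trips = 3))
  f <- dedup_fixes(drop_unclassified(out$fixes))
  f <- speed_filter(f)
  tr <- interpolate_track(f, dt = 2, mode = "ctcrw")
  expect_identical(attr(tr, "mode"), "ctcrw")
  origin <- attr(tr, "origin")
  truth_xy <- project_local(out$truth$lon, out$truth$lat, origin)
  truth_at <- function(times) {
    i <- match(as.numeric(times), as.numeric(out$truth$t))
    list(x = truth_xy$x[i], y = truth_xy$y[i], ok = !is.na(i))
  }
  tt <- truth_at(tr$t)
  rmse_sm <- sqrt(mean((tr$x[tt$ok] - tt$x[tt$ok])^2 +
                       (tr$y[tt$ok] - tt$y[tt$ok])^2))
  fix_xy <- project_local(f$lon, f$lat, origin)
  tf <- truth_at(f$t)
  rmse_raw <- sqrt(mean((fix_xy$x[tf$ok] - tf$x[tf$ok])^2 +
                        (fix_xy$y[tf$ok] - tf$y[tf$ok])^2))
  expect_lt(rmse_sm, rmse_raw)
})

test_that("the 6-h trip rule is strict: 8-h run is one trip, 4-h and exactly-6-h runs none", {
  wet8 <- data.frame(t = t_utc(0:8), wet = c(rep(TRUE, 9)))
  expect_equal(nrow(segment_trips(wet8, min_trip = 6)), 1)
  wet4 <- data.frame(t = t_utc(0:4), wet = rep(TRUE, 5))
  expect_equal(nrow(segment_trips(wet4, min_trip = 6)), 0)
  wet6 <- data.frame(t = t_utc(0:6), wet = rep(TRUE, 7))
  expect_equal(nrow(segment_trips(wet6, min_trip = 6)), 0)  # strictly >
})

test_that("wet runs of 5, 7 and 9 hours yield exactly two trips with raw-fix boundaries", {
  runs <- c(rep(TRUE, 6), FALSE, rep(TRUE, 8), FALSE, rep(TRUE, 10))
  # hourly fixes: runs last 5, 7 and 9 h
  f <- data.frame(t = t_utc(seq_along(runs) - 1), wet = runs)
  tr <- segment_trips(f, min_trip = 6)
  expect_equal(nrow(tr), 2)
  expect_equal(tr$duration_h, c(7, 9))
  expect_identical(tr$start_t[1], f$t[8])   # first wet fix of the 7-h run
  expect_identical(tr$end_t[1], f$t[15])    # last wet fix of that run
})

test_that("no trip shorter than the rule is ever emitted from random wet/dry strings", {
  set.seed(31)
  for (k in 1:20) {
    wet <- runif(60) < 0.6
    f <- data.frame(t = t_utc(0:59), wet = wet)
    tr <- segment_trips(f, min_trip = 6)
    if (nrow(tr)) {
      expect_true(all(tr$duration_h > 6))
      expect_true(all(diff(as.numeric(tr$start_t)) > 0))
      # every trip window is fully wet
      for (i in seq_len(nrow(tr))) {
        inside <- f$t >= tr$start_t[i] & f$t <= tr$end_t[i]
        expect_true(all(f$wet[inside]))
      }
    }
  }
  all_dry <- data.frame(t = t_utc(0:20), wet = rep(FALSE, 21))
  expect_equal(nrow(segment_trips(all_dry)), 0)
})

test_that("trip metrics follow the closed form and are reversal-invariant", {
  # two fixes one degree apart on the equator, 12 h apart
  p <- data.frame(t = t_utc(c(0, 12)), lon = c(0, 1), lat = c(0, 0))
  m <- trip_metrics(p)
  expect_equal(m$distance_km, 111.19, tolerance = 1e-3)
  expect_equal(m$duration_d, 0.5)
  expect_equal(m$speed_kmh, m$distance_km / 12)
  stay <- data.frame(t = t_utc(c(0, 10)), lon = c(135, 135),
                     lat = c(-34, -34))
  expect_equal(trip_metrics(stay)$distance_km, 0)
  set.seed(8)
  q <- data.frame(t = t_utc(0:10 * 2), lon = 135 + cumsum(rnorm(11, 0, 0.05)),
                  lat = -34.5 + cumsum(rnorm(11, 0, 0.05)))
  rev_q <- q[11:1, ]; rev_q$t <- q$t
  expect_equal(trip_metrics(q)$distance_km, trip_metrics(rev_q)$distance_km)
  expect_error(trip_metrics(q[1, ]), "single-position")
})

test_that("trip counts are recovered from low-error simulations", {
  for (seed in 1:5) {
    scales <- argos_error_scale_km
    scales[] <- pmin(scales, 1)  # class errors <= 1 km
    out <- simulate_tracks(sim_config(seed = seed, n_trips = 5,
                                      class_error_scale = scales))
    f <- dedup_fixes(drop_unclassified(out$fixes))
    f <- speed_filter(f)
    tr <- segment_trips(f, min_trip = 6)
    expect_equal(nrow(tr), attr(out$truth, "n_trips"))
  }
})

test_that("an animal duplicated across the cohort has zero standard error", {
  one <- data.frame(animal_id = c("a", "b"), n_trips = c(20, 20),
                    mean_distance_km = c(150, 150),
                    mean_duration_d = c(3, 3))
  cs <- cohort_summary(one)
  expect_true(all(cs$grand$se == 0))
  expect_error(cohort_summary(one[1, , drop = FALSE]), "2 animals")
})

test_that("per-animal trip summary collapses a trip table to the cohort shape", {
  trips <- data.frame(animal_id = c("a", "a", "b"),
                      distance_km = c(100, 200, 50),
                      duration_d = c(2, 4, 1))
  pa <- per_animal_trip_summary(trips)
  expect_equal(pa$n_trips, c(2, 1))
  expect_equal(pa$mean_distance_km, c(150, 50))
  expect_equal(pa$mean_duration_d, c(3, 1))
})
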