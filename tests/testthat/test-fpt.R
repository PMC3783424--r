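test_that("rediscretization marks points at exact equal spacing with linear time", {
  # straight 10-km track at 1 km/h
  tr <- data.frame(x = seq(0, 10, by = 2), y = 0, t = t_utc(seq(0, 10, 2)))
  p <- rediscretize(tr, step = 1)
  expect_equal(nrow(p), 11)
  expect_equal(sqrt(diff(p$x)^2 + diff(p$y)^2), rep(1, 10),
               tolerance = 1e-9)
  # constant speed -> equal time increments
  expect_equal(as.numeric(diff(p$t), units = "hours"), rep(1, 10),
               tolerance = 1e-9)
  expect_error(rediscretize(tr[1, , drop = FALSE]), "at least 2")
  expect_error(rediscretize(data.frame(x = c(0, 0.1), y = 0,
                                       t = t_utc(0:1)), step = 1),
               "shorter than one step")
})

test_that("rediscretized points are exactly one step apart with monotone time", {
  set.seed(14)
  for (k in 1:5) {
    n <- 40
    tr <- data.frame(x = cumsum(rnorm(n, 0, 2)), y = cumsum(rnorm(n, 0, 2)),
                     t = t_utc(0:(n - 1)))
    p <- rediscretize(tr, step = 1)
    expect_equal(sqrt(diff(p$x)^2 + diff(p$y)^2), rep(1, nrow(p) - 1),
                 tolerance = 1e-9)
    expect_true(all(diff(as.numeric(p$t)) > 0))
    # every placed point lies on the original polyline: its distance to the
    # nearest source segment is ~0
    seg_dist <- function(px, py) {
      min(vapply(seq_len(n - 1), function(i) {
        dx <- tr$x[i + 1] - tr$x[i]; dy <- tr$y[i + 1] - tr$y[i]
        u <- ((px - tr$x[i]) * dx + (py - tr$y[i]) * dy) / (dx^2 + dy^2)
        u <- min(max(u, 0), 1)
        sqrt((tr$x[i] + u * dx - px)^2 + (tr$y[i] + u * dy - py)^2)
      }, numeric(1)))
    }
    for (i in seq(1, nrow(p), length.out = 10))
      expect_lt(seg_dist(p$x[round(i)], p$y[round(i)]), 1e-8)
  }
})

test_that("rediscretization of a gently curving track covers its length within one step", {
  # small heading changes: corner cutting is negligible, so the step count
  # accounts for the whole path length to within one step
  set.seed(15)
  heading <- cumsum(rnorm(60, 0, 0.05))
  tr <- data.frame(x = cumsum(c(0, 2 * cos(heading))),
                   y = cumsum(c(0, 2 * sin(heading))),
                   t = t_utc(0:60))
  len <- sum(sqrt(diff(tr$x)^2 + diff(tr$y)^2))
  p <- rediscretize(tr, step = 1)
  expect_lte(len - (nrow(p) - 1), 1.05)
  expect_gte(len - (nrow(p) - 1), 0)
})

test_that("FPT on a straight constant-speed line is 2r/v at interior points", {
  p <- make_path(0:20, rep(0, 21), 0:20)  # 1 km/h
  f <- first_passage_time(p, r = 2)
  # interior points far from the ends: forward 2 h + backward 2 h
  expect_equal(f[5:16], rep(4, 12), tolerance = 1e-9)
  expect_true(is.na(f[1]))   # no backward exit
  expect_true(is.na(f[21]))
  expect_error(first_passage_time(p, r = 0), "radius")
})

test_that("FPT is non-decreasing in the radius at every defined point", {
  p <- random_walk_path(150, seed = 4)
  f1 <- first_passage_time(p, 1)
  f3 <- first_passage_time(p, 3)
  ok <- !is.na(f1) & !is.na(f3)
  expect_true(any(ok))
  expect_true(all(f1[ok] <= f3[ok] + 1e-9))
})

test_that("FPT matches the numeric root-finding oracle on seeded random walks", {
  for (seed in 1:3) {
    p <- random_walk_path(120, seed = seed)
    for (r in c(0.8, 2.5)) {
      got <- first_passage_time(p, r)
      want <- oracle_fpt(p, r)
      expect_identical(is.na(got), is.na(want))
      ok <- !is.na(got)
      expect_lt(max(abs(got[ok] - want[ok])), 1e-6)
    }
  }
})

test_that("FPT is invariant to planar translation and rotation", {
  p <- random_walk_path(100, seed = 9)
  f <- first_passage_time(p, 2)
  sh <- p; sh$x <- p$x + 500; sh$y <- p$y - 200
  expect_equal(first_passage_time(sh, 2), f, tolerance = 1e-9)
  th <- 0.7
  ro <- p
  ro$x <- cos(th) * p$x - sin(th) * p$y
  ro$y <- sin(th) * p$x + cos(th) * p$y
  expect_equal(first_passage_time(ro, 2), f, tolerance = 1e-9)
})

test_that("maximum daily step length sums within-UTC-day path lengths", {
  # 30 h at 1 km/h: day 1 covers 24 km, day 2 covers 6 km
  p <- make_path(0:30, rep(0, 31), 0:30)
  expect_equal(max_daily_step(p), 24, tolerance = 1e-9)
})

test_that("variance of log FPT is invariant to uniform time rescaling", {
  p <- random_walk_path(200, seed = 2)
  prof1 <- ars_scale(p, r_min = 0.5, r_max = 10, n_radii = 15)
  p2 <- p
  p2$t <- p$t[1] + 2 * (as.numeric(p$t) - as.numeric(p$t[1]))  # double speed
  prof2 <- ars_scale(p2, r_min = 0.5, r_max = 10, n_radii = 15)
  ok <- !is.na(prof1$varlog) & !is.na(prof2$varlog)
  expect_equal(prof1$varlog[ok], prof2$varlog[ok], tolerance = 1e-6)
  expect_equal(prof1$ars_radius, prof2$ars_radius)
})

test_that("a straight constant-speed track is flagged non-informative", {
  p <- make_path(seq(0, 60, by = 1), rep(0, 61), 0:60)
  prof <- ars_scale(p, r_min = 0.5, r_max = 10, n_radii = 10)
  expect_lt(prof$varlog_max, 0.01)
  expect_false(prof$informative)
})

test_that("ARS labelling flags the q-quantile and reports runs as segments", {
  f <- c(NA, 1, 1, 1, 1, 10, 10, 1, 10, NA)
  lab <- label_ars(f, q = 0.75)
  expect_identical(lab$ars, c(NA, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE,
                              FALSE, TRUE, NA))
  expect_equal(lab$segments$start, c(6, 9))
  expect_equal(lab$segments$end, c(7, 9))
  # q = 0 flags everything defined; q = 1 only the maximum
  expect_true(all(label_ars(f, q = 0)$ars[!is.na(f)]))
  expect_equal(sum(label_ars(c(1, 2, 3), q = 1)$ars), 1)
  expect_error(label_ars(c(NA_real_, NA_real_)), "missing")
})

test_that("high-FPT labels recover the simulated foraging patches", {
  # truth = patch membership of each path point (inside a 5-km patch)
  cfg <- clean_sim_config(seed = 2, n_trips = 6, trip_hours = 40)
  out <- simulate_tracks(cfg)
  truth <- out$truth[out$truth$state != "haulout", ]
  path <- rediscretize(data.frame(x = truth$x, y = truth$y, t = truth$t),
                       step = 1)
  prof <- ars_scale(path, r_min = 0.5, n_radii = 30)
  lab <- label_ars(prof$fpt[, which.min(abs(prof$radii - prof$ars_radius))],
                   q = 0.75)
  centers <- lapply(cfg$patch_centers, function(p) {
    xy <- project_local(p[1], p[2], cfg$colony)
    c(xy$x, xy$y)
  })
  in_patch <- Reduce(`|`, lapply(centers, function(ctr) {
    sqrt((path$x - ctr[1])^2 + (path$y - ctr[2])^2) <= cfg$patch_radius
  }))
  ok <- !is.na(lab$ars)
  sens <- mean(lab$ars[ok & in_patch])
  spec <- mean(!lab$ars[ok & !in_patch])
  expect_gte((sens + spec) / 2, 0.75)  # balanced accuracy
  expect_gte(sens, 0.70)
})
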