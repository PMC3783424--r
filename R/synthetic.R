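# Synthetic-data generators. Every input the pipeline consumes can be
# simulated with the statistical structure the analysis assumes, plus
# ground-truth records for parameter-recovery tests. All generators are
# pure functions of (config, seed): each draws from its own seed stream
# (fixed offsets) so adding one generator never shifts another's output.

.ARGOS_CLASSES <- c("3", "2", "1", "0", "A", "B", "Z")

#' Default per-class ARGOS location-error scales (km)
#'
#' Student-t (df = 5) error scales by location class, used both by the
#' track simulator and as the observation-noise table for track
#' interpolation and Brownian-bridge location error. Class Z carries the
#' gross-outlier scale.
#' @export
argos_error_scale_km <- c("3" = 0.25, "2" = 0.5, "1" = 1.0, "0" = 2.5,
                          "A" = 3.0, "B" = 5.0, "Z" = 50)

#' Simulation configuration for a synthetic central-place forager
#'
#' Defaults describe one adult male sea lion on the South Australian shelf:
#' foraging trips of ~3.6 d alternating with haulouts, directed travel legs
#' to offshore patches, area-restricted search (ARS) inside the patches, and
#' ARGOS-class observation error on every fix.
#'
#' @param seed integer seed; fixed seed implies byte-identical output.
#' @param colony c(lon, lat) of the haulout colony.
#' @param n_trips number of foraging trips.
#' @param patch_centers list of c(lon, lat) ARS patch centres.
#' @param patch_radius km, radius of each ARS patch.
#' @param travel_speed km/h on directed legs.
#' @param ars_speed km/h during ARS.
#' @param fix_interval h between fixes.
#' @param argos_class_mix named proportions over classes 3,2,1,0,A,B,Z.
#' @param class_error_scale named km scales per class (Student-t, df 5).
#' @param haulout_hours h hauled out between trips.
#' @param trip_hours h per trip (travel out + ARS + travel back).
#' @param animal_id id string for the simulated animal.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       colony = c(135.0, -34.5),
                       n_trips = 28,
                       patch_centers = list(c(135.3, -34.95),
                                            c(134.7, -34.9)),
                       patch_radius = 5,
                       travel_speed = 5,
                       ars_speed = 1,
                       fix_interval = 2,
                       argos_class_mix = c("3" = 0.08, "2" = 0.14, "1" = 0.18,
                                           "0" = 0.20, "A" = 0.20, "B" = 0.18,
                                           "Z" = 0.02),
                       class_error_scale = argos_error_scale_km,
                       haulout_hours = 36,
                       trip_hours = 86,
                       animal_id = "sim1") {
  if (abs(sum(argos_class_mix) - 1) > 1e-8)
    stop("argos_class_mix must sum to 1", call. = FALSE)
  if (travel_speed <= 0 || ars_speed <= 0)
    stop("speeds must be > 0", call. = FALSE)
  if (n_trips > 0 && length(patch_centers) == 0)
    stop("n_trips > 0 requires at least one patch center", call. = FALSE)
  structure(list(seed = seed, colony = colony, n_trips = n_trips,
                 patch_centers = patch_centers, patch_radius = patch_radius,
                 travel_speed = travel_speed, ars_speed = ars_speed,
                 fix_interval = fix_interval,
                 argos_class_mix = argos_class_mix,
                 class_error_scale = class_error_scale,
                 haulout_hours = haulout_hours, trip_hours = trip_hours,
                 animal_id = animal_id),
            class = "sim_config")
}

#' Simulate an ARGOS-observed central-place foraging track
#'
#' Alternates haulout (dry, at the colony) and trip (wet) phases. Each trip
#' is a correlated random walk: a directed outbound leg (low turning-angle
#' variance) to a patch centre, an ARS phase (high turning, low speed,
#' reflected back towards the centre at the patch edge), and a directed
#' return leg. Fixes are the true positions plus Student-t (df = 5)
#' observation error scaled by the sampled ARGOS class; class Z plays the
#' gross-outlier role.
#'
#' @param cfg a [sim_config()].
#' @return list with `fixes` (data.frame: animal_id, t (POSIXct UTC), lon,
#'   lat, lc, wet) and `truth` (data.frame: t, lon, lat, x, y, state
#'   ("haulout"/"travel"/"ars"), trip). `truth` also carries attributes
#'   `ars_dwell_frac` (planned ARS share of trip time) and `n_trips`.
#' @export
simulate_tracks <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  dt <- cfg$fix_interval
  colony_xy <- c(0, 0)
  patches <- lapply(cfg$patch_centers, function(p) {
    xy <- project_local(p[1], p[2], cfg$colony)
    c(xy$x, xy$y)
  })
  t0 <- as.POSIXct("2009-12-01 00:00:00", tz = "UTC")

  xs <- ys <- numeric(0); state <- character(0); trip_id <- integer(0)
  tt <- numeric(0)  # hours since t0
  now <- 0
  emit <- function(x, y, st, tr, t_h) {
    xs <<- c(xs, x); ys <<- c(ys, y); state <<- c(state, st)
    trip_id <<- c(trip_id, tr); tt <<- c(tt, t_h)
  }
  travel_time <- function(p) 2 * sqrt(sum((p - colony_xy)^2)) /
    cfg$travel_speed
  for (k in seq_len(max(1, cfg$n_trips))) {
    # haulout phase before each trip
    n_dry <- max(1, round(cfg$haulout_hours / dt))
    for (j in seq_len(n_dry)) { emit(0, 0, "haulout", 0L, now); now <- now + dt }
    if (cfg$n_trips == 0) break
    patch <- patches[[((k - 1) %% length(patches)) + 1]]
    ars_hours <- cfg$trip_hours - travel_time(patch)
    if (ars_hours <= 0)
      stop("trip_hours too short to reach the patch and return",
           call. = FALSE)
    pos <- c(0, 0); heading <- atan2(patch[2], patch[1])
    # outbound
    while (sqrt(sum((pos - patch)^2)) > cfg$patch_radius) {
      bearing <- atan2(patch[2] - pos[2], patch[1] - pos[1]) +
        rnorm(1, 0, 10 * pi / 180)
      step <- min(cfg$travel_speed * dt, sqrt(sum((pos - patch)^2)))
      pos <- pos + step * c(cos(bearing), sin(bearing))
      heading <- bearing
      emit(pos[1], pos[2], "travel", k, now); now <- now + dt
    }
    # ARS inside the patch
    n_ars <- max(1, round(ars_hours / dt))
    for (j in seq_len(n_ars)) {
      heading <- heading + rnorm(1, 0, 120 * pi / 180)
      cand <- pos + cfg$ars_speed * dt * c(cos(heading), sin(heading))
      if (sqrt(sum((cand - patch)^2)) > cfg$patch_radius) {
        heading <- atan2(patch[2] - pos[2], patch[1] - pos[1])
        cand <- pos + cfg$ars_speed * dt * c(cos(heading), sin(heading))
      }
      pos <- cand
      emit(pos[1], pos[2], "ars", k, now); now <- now + dt
    }
    # return leg
    while (sqrt(sum(pos^2)) > cfg$travel_speed * dt) {
      bearing <- atan2(-pos[2], -pos[1]) + rnorm(1, 0, 10 * pi / 180)
      pos <- pos + cfg$travel_speed * dt * c(cos(bearing), sin(bearing))
      emit(pos[1], pos[2], "travel", k, now); now <- now + dt
    }
    pos <- colony_xy
    emit(pos[1], pos[2], "travel", k, now); now <- now + dt
  }

  ll <- unproject_local(xs, ys, cfg$colony)
  truth <- data.frame(t = t0 + tt * 3600, lon = ll$lon, lat = ll$lat,
                      x = xs, y = ys, state = state, trip = trip_id)
  plan_dwell <- 1 - travel_time(patches[[1]]) / cfg$trip_hours
  attr(truth, "ars_dwell_frac") <- plan_dwell
  attr(truth, "n_trips") <- cfg$n_trips

  n <- nrow(truth)
  lc <- sample(.ARGOS_CLASSES, n, replace = TRUE, prob = cfg$argos_class_mix)
  scale <- cfg$class_error_scale[lc]
  ex <- rt(n, df = 5) * scale
  ey <- rt(n, df = 5) * scale
  oll <- unproject_local(xs + ex, ys + ey, cfg$colony)
  fixes <- data.frame(animal_id = cfg$animal_id, t = truth$t,
                      lon = oll$lon, lat = oll$lat, lc = lc,
                      wet = state != "haulout",
                      stringsAsFactors = FALSE)
  list(fixes = fixes, truth = truth)
}

#' Simulate a shelf bathymetry grid
#'
#' Depth (positive metres below the surface) ramps from ~0 m at a coastline
#' north of the colony down to `shelf_depth`, with a steeper slope-break
#' band beyond `break_km` offshore and optional smooth seeded noise
#' (sum of random low-frequency sinusoids).
#'
#' @param cfg a [sim_config()] (seed and colony are used).
#' @param cell_deg grid cell size, degrees.
#' @param half_extent_deg half-width of the grid around the colony, degrees.
#' @param shelf_depth m depth at the shelf edge.
#' @param shelf_km offshore distance over which the shelf ramp runs.
#' @param break_km offshore distance where the slope break starts.
#' @param break_grad m per km in the slope-break band.
#' @param noise_amp m, amplitude of the smooth noise (0 disables).
#' @param coast_offset_km coastline's distance north of the colony.
#' @return a lon/lat [raster_grid()] of depth in m (positive down).
#' @export
simulate_bathymetry <- function(cfg, cell_deg = 0.02, half_extent_deg = 1.2,
                                shelf_depth = 120, shelf_km = 80,
                                break_km = 80, break_grad = 12,
                                noise_amp = 3, coast_offset_km = 15) {
  set.seed(cfg$seed + 1000003L)
  lon0 <- cfg$colony[1]; lat0 <- cfg$colony[2]
  xll <- lon0 - half_extent_deg; yll <- lat0 - half_extent_deg
  nc <- nr <- ceiling(2 * half_extent_deg / cell_deg)
  lon_c <- xll + (seq_len(nc) - 0.5) * cell_deg
  lat_c <- yll + (nr - seq_len(nr) + 0.5) * cell_deg  # row 1 = north
  km_per_deg <- pi / 180 * EARTH_RADIUS_KM
  # offshore distance (km) south of the coastline
  coast_lat <- lat0 + coast_offset_km / km_per_deg
  off_km <- (coast_lat - lat_c) * km_per_deg
  depth1 <- pmax(0, pmin(off_km, shelf_km)) / shelf_km * shelf_depth +
    pmax(0, off_km - break_km) * break_grad
  z <- matrix(depth1, nr, nc)  # constant along rows (east-west)
  if (noise_amp > 0) {
    ph <- runif(6, 0, 2 * pi); fr <- runif(6, 0.5, 2.5)
    lonm <- matrix(lon_c, nr, nc, byrow = TRUE)
    latm <- matrix(lat_c, nr, nc)
    nz <- 0
    for (i in 1:3) nz <- nz + sin(2 * pi * fr[i] * lonm + ph[i])
    for (i in 4:6) nz <- nz + sin(2 * pi * fr[i] * latm + ph[i])
    z <- z + noise_amp * nz / 3
    z[off_km <= 0, ] <- 0
  }
  raster_grid(z, xll, yll, cell_deg)
}

#' Ocean configuration for the CTD simulator
#'
#' Defaults give a seasonal cycle on the South Australian shelf: warm fresh
#' surface water, an upwelling season (Dec-Mar) in which the deep layer is
#' the cold dense upwelled plume (T < 17, sigma-theta > 26, S < 35.6), and
#' warmer, saltier non-plume deep water otherwise.
#'
#' @param mld_by_month numeric(12), mean mixed layer depth (m) per month.
#' @param t_surf_by_month,s_surf_by_month numeric(12), surface T (deg C)
#'   and S (psu) per calendar month.
#' @param t_deep_upwelled,s_deep_upwelled deep endpoint during upwelling.
#' @param t_deep_other,s_deep_other deep endpoint outside upwelling.
#' @param upwelling_months integer months of the upwelling season.
#' @param thermocline_m thickness of the transition band (m).
#' @param bin_m depth-bin spacing of the emitted profiles (m).
#' @param noise_t,noise_s sensor noise sd for T and S.
#' @param mld_jitter_m sd of per-profile MLD jitter (m).
#' @return list of class `ocean_config`.
#' @export
ocean_config <- function(mld_by_month = c(55, 50, 45, 40, 45, 50,
                                          55, 55, 55, 55, 55, 55) * 0.6,
                         t_surf_by_month = c(19, 19.5, 19, 18, 17.5, 16.5,
                                             15.5, 15, 15.5, 16.5, 17.5, 18.5),
                         s_surf_by_month = rep(35.8, 12),
                         t_deep_upwelled = 13, s_deep_upwelled = 35.3,
                         t_deep_other = 17.5, s_deep_other = 35.7,
                         upwelling_months = c(12, 1, 2, 3),
                         thermocline_m = 8, bin_m = 1,
                         noise_t = 0.01, noise_s = 0.005,
                         mld_jitter_m = 3) {
  structure(as.list(environment()), class = "ocean_config")
}

#' Simulate CTD profiles along a track
#'
#' One profile per input location. The water column is piecewise: a mixed
#' layer of uniform T/S (hence uniform sigma-theta), a square-root-shaped
#' transition to the deep endpoint over `thermocline_m` (steep immediately
#' below the mixed layer, so the density threshold criterion is met within
#' ~1 m of the true interface), and the deep layer down to the sea floor.
#' During `upwelling_months` the deep endpoint is the upwelled plume
#' signature. Truth records the threshold-criterion MLD of the noiseless
#' column, computed analytically from the generator's own T/S functions.
#'
#' @param locations data.frame with columns `t` (POSIXct), `lon`, `lat` and
#'   `bottom_m` (sea-floor depth, m); one profile is emitted per row.
#' @param ocfg an [ocean_config()].
#' @param seed integer seed for sensor noise and MLD jitter.
#' @param animal_id id carried onto the profiles.
#' @return list with `profiles` (long data.frame: profile_id, animal_id, t,
#'   lon, lat, depth_m, temp_c, sal_psu) and `truth` (per profile: true MLD
#'   under the 0.125 kg m-3 / 4-m criterion, deep-layer upwelled flag,
#'   month).
#' @export
simulate_ctd_profiles <- function(locations, ocfg, seed = 1,
                                  animal_id = "sim1") {
  stopifnot(inherits(ocfg, "ocean_config"))
  set.seed(seed + 2000003L)
  keep <- locations$bottom_m >= 4
  locations <- locations[keep, , drop = FALSE]
  n <- nrow(locations)
  month <- as.integer(format(locations$t, "%m"))
  out <- vector("list", n)
  truth <- data.frame(profile_id = seq_len(n), month = month,
                      true_mld_m = rep(NA_real_, n),
                      upwelled_deep = rep(FALSE, n))
  for (i in seq_len(n)) {
    bottom <- floor(locations$bottom_m[i])
    up <- month[i] %in% ocfg$upwelling_months
    ts <- ocfg$t_surf_by_month[month[i]]
    ss <- ocfg$s_surf_by_month[month[i]]
    td <- if (up) ocfg$t_deep_upwelled else ocfg$t_deep_other
    sd_ <- if (up) ocfg$s_deep_upwelled else ocfg$s_deep_other
    mld <- ocfg$mld_by_month[month[i]] + rnorm(1, 0, ocfg$mld_jitter_m)
    mld <- min(max(6, mld), bottom - 2)
    frac <- function(z) {
      f <- pmin(1, pmax(0, (z - mld) / ocfg$thermocline_m))
      sqrt(f)
    }
    col_t <- function(z) ts + (td - ts) * frac(z)
    col_s <- function(z) ss + (sd_ - ss) * frac(z)
    # truth MLD: threshold criterion applied to the noiseless column
    zlev <- seq(1, bottom)
    sig <- sigma_theta(col_s(zlev), col_t(zlev))
    ref <- sig[match(4, zlev)]
    hit <- which(zlev > 4 & sig - ref >= 0.125)
    truth$true_mld_m[i] <- if (length(hit)) zlev[hit[1]] else max(zlev)
    truth$upwelled_deep[i] <- up
    zb <- seq(4, bottom, by = ocfg$bin_m)
    if (length(zb) < 2 || max(zb) < 4) next
    out[[i]] <- data.frame(
      profile_id = i, animal_id = animal_id, t = locations$t[i],
      lon = locations$lon[i], lat = locations$lat[i],
      depth_m = zb,
      temp_c = col_t(zb) + rnorm(length(zb), 0, ocfg$noise_t),
      sal_psu = col_s(zb) + rnorm(length(zb), 0, ocfg$noise_s))
  }
  list(profiles = do.call(rbind, out), truth = truth)
}

#' Simulate a seasonal-AR whisker isotope series
#'
#' Draws from the multiplicative seasonal first-order autoregression
#' x_t = mu + phi (x_{t-1} - mu) + phi_s (x_{t-s} - mu)
#'        - phi phi_s (x_{t-1-s} - mu) + eps_t,
#' the model class that describes whisker delta-13C / delta-15N series.
#' A burn-in of 10 seasonal periods is discarded.
#'
#' @param n number of segments (months) to return.
#' @param mu series mean (per mil).
#' @param phi regular AR(1) coefficient, |phi| < 1.
#' @param phi_s seasonal AR coefficient, |phi_s| < 1.
#' @param s seasonal period in months (>= 2 if phi_s != 0).
#' @param sigma_eps innovation sd (per mil).
#' @param seed integer seed.
#' @return list with `series` (numeric, length n, newest value last) and
#'   `truth` (the generating parameters).
#' @export
simulate_isotope_series <- function(n, mu, phi, phi_s, s, sigma_eps,
                                    seed = 1) {
  if (abs(phi) >= 1 || abs(phi_s) >= 1)
    stop("nonstationary parameters: |phi| and |phi_s| must be < 1",
         call. = FALSE)
  if (phi_s != 0 && s < 2) stop("seasonal period s must be >= 2",
                                call. = FALSE)
  set.seed(seed)
  s_eff <- max(2, s)
  burn <- 10 * s_eff
  ntot <- n + burn
  x <- numeric(ntot)
  lag <- function(v, k, i) if (i - k >= 1) v[i - k] else 0
  for (i in seq_len(ntot)) {
    x[i] <- phi * lag(x, 1, i) + phi_s * lag(x, s_eff, i) -
      phi * phi_s * lag(x, s_eff + 1, i) + rnorm(1, 0, sigma_eps)
  }
  series <- mu + x[(burn + 1):ntot]
  list(series = series,
       truth = list(mu = mu, phi = phi, phi_s = phi_s, s = s,
                    sigma_eps = sigma_eps))
}
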