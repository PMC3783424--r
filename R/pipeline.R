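# End-to-end pipeline: simulate -> filter -> interpolate -> trips -> FPT ->
# UD -> oceanography -> covariates -> CPH -> isotopes, every stage writing
# its CSV/ASC/GeoJSON artifact plus a JSON run manifest.

#' Pipeline configuration
#'
#' Tunable constants of the whole pipeline. Movement/oceanography defaults
#' are the analysis constants (2 m/s speed filter, >6 h trips, 2-h
#' interpolation, 1-km FPT steps from 0.5 km, 0.125 kg m-3 / 4-m MLD
#' criterion, upwelling thresholds 17 degC / 26 kg m-3 / 35.6, 3 mm/month
#' whisker growth, 50/95% UD levels); the simulation block is sized as a
#' small demonstration colony so the full pipeline runs in minutes.
#'
#' @param n_animals simulated animals.
#' @param n_trips trips per animal.
#' @param trip_hours,haulout_hours trip phase durations, h.
#' @param vmax speed-filter bound, m/s.
#' @param min_trip_h minimum at-sea duration of a trip, h.
#' @param dt_h interpolation grid spacing, h.
#' @param interp_mode "ctcrw" or "linear".
#' @param fpt_rmin_km,fpt_n_radii,ars_quantile FPT sweep controls.
#' @param delta_sigma,surface_ref_m MLD criterion.
#' @param idw_power,idw_max_dist_km,field_cell_deg monthly-field gridding.
#' @param r_max correlation-screen threshold.
#' @param ud_cell_km UD grid cell size.
#' @param profile_every emit one CTD profile per this many at-sea positions.
#' @param whisker_segments segments per simulated whisker.
#' @param sarima_seasons seasonal periods swept during isotope model
#'   selection.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_animals = 2, n_trips = 4, trip_hours = 40,
                            haulout_hours = 24,
                            vmax = 2.0, min_trip_h = 6, dt_h = 2,
                            interp_mode = "ctcrw",
                            fpt_rmin_km = 0.5, fpt_n_radii = 30,
                            ars_quantile = 0.75,
                            delta_sigma = 0.125, surface_ref_m = 4,
                            idw_power = 2, idw_max_dist_km = 100,
                            field_cell_deg = 0.1,
                            r_max = 0.7, ud_cell_km = 1,
                            profile_every = 4, whisker_segments = 48,
                            sarima_seasons = c(6, 12)) {
  structure(as.list(environment()), class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full pipeline on a simulated colony
#'
#' Executes every stage in order and writes each stage's artifact under
#' `out_dir`. Re-running with the same config and seed yields byte-identical
#' artifacts.
#'
#' @param config a [pipeline_config()].
#' @param seed integer master seed.
#' @param out_dir output directory (created if missing).
#' @return (invisibly) a list of the main in-memory results.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 42,
                         out_dir = "results/pipeline") {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(out_dir, ...)

  ## -- simulate ------------------------------------------------------------
  sims <- .stage("simulate", {
    lapply(seq_len(config$n_animals), function(i) {
      cfg <- sim_config(seed = seed + i,
                        colony = c(135.0 + 0.4 * (i - 1), -34.5),
                        n_trips = config$n_trips,
                        trip_hours = config$trip_hours,
                        haulout_hours = config$haulout_hours,
                        patch_centers = list(c(135.0 + 0.4 * (i - 1) + 0.15,
                                               -34.75)),
                        animal_id = sprintf("sim%02d", i))
      simulate_tracks(cfg)
    })
  })
  all_fixes <- do.call(rbind, lapply(sims, `[[`, "fixes"))
  write_fixes_csv(all_fixes, pth("fixes.csv"))

  bathy <- .stage("bathymetry", {
    g <- simulate_bathymetry(sim_config(seed = seed), half_extent_deg = 1.5)
    write_esri_ascii(g, pth("bathymetry.asc"))
    g
  })
  slope <- .stage("slope", {
    s <- grid_slope(bathy)
    write_esri_ascii(s, pth("slope.asc"))
    s
  })

  ## -- filter / interpolate / trips ---------------------------------------
  tracks <- .stage("tracks", lapply(sims, function(sm) {
    f <- drop_unclassified(sm$fixes)
    f <- dedup_fixes(f)
    f <- speed_filter(f, vmax = config$vmax)
    ip <- interpolate_track(f, dt = config$dt_h, mode = config$interp_mode)
    ip$wet <- f$wet[findInterval(as.numeric(ip$t), as.numeric(f$t),
                                 rightmost.closed = FALSE)]
    list(animal_id = sm$fixes$animal_id[1], fixes = f, interp = ip,
         truth = sm$truth)
  }))

  trips <- .stage("trips", {
    rows <- list()
    for (tr in tracks) {
      w <- segment_trips(tr$fixes, min_trip = config$min_trip_h)
      for (i in seq_len(nrow(w))) {
        pos <- tr$interp[tr$interp$t >= w$start_t[i] &
                           tr$interp$t <= w$end_t[i], ]
        if (nrow(pos) < 2) next
        m <- trip_metrics(pos)
        rows[[length(rows) + 1]] <- data.frame(
          animal_id = tr$animal_id, trip = w$trip[i],
          start_t = w$start_t[i], end_t = w$end_t[i],
          duration_d = m$duration_d, distance_km = m$distance_km,
          speed_kmh = m$speed_kmh)
      }
    }
    tt <- do.call(rbind, rows)
    out <- tt; out$start_t <- .fmt_utc(out$start_t)
    out$end_t <- .fmt_utc(out$end_t)
    utils::write.csv(out, pth("trips.csv"), row.names = FALSE, quote = FALSE)
    tt
  })

  ## -- FPT / ARS -----------------------------------------------------------
  fpt_res <- .stage("fpt", {
    ars_rows <- list(); point_rows <- list()
    for (tr in tracks) {
      paths <- list()
      w <- segment_trips(tr$fixes, min_trip = config$min_trip_h)
      for (i in seq_len(nrow(w))) {
        pos <- tr$interp[tr$interp$t >= w$start_t[i] &
                           tr$interp$t <= w$end_t[i], ]
        p <- tryCatch(rediscretize(pos), error = function(e) NULL)
        if (!is.null(p) && nrow(p) >= 5) paths[[length(paths) + 1]] <-
            list(trip = w$trip[i], path = p)
      }
      if (!length(paths)) next
      rmax <- 2 * max(vapply(paths, function(pp) max_daily_step(pp$path),
                             numeric(1)))
      radii <- exp(seq(log(config$fpt_rmin_km), log(rmax),
                       length.out = config$fpt_n_radii))
      fpt_all <- lapply(paths, function(pp)
        vapply(radii, function(r) first_passage_time(pp$path, r),
               numeric(nrow(pp$path))))
      pooled <- do.call(rbind, fpt_all)
      varlog <- apply(pooled, 2, function(col) {
        v <- col[!is.na(col) & col > 0]
        if (length(v) < 20) NA_real_ else stats::var(log(v))
      })
      if (all(is.na(varlog))) next
      peak <- which(varlog == max(varlog, na.rm = TRUE))[1]
      ars_r <- radii[peak]
      ars_rows[[length(ars_rows) + 1]] <- data.frame(
        animal_id = tr$animal_id, ars_radius_km = ars_r,
        varlog_max = varlog[peak])
      for (k in seq_along(paths)) {
        pp <- paths[[k]]
        fr <- fpt_all[[k]][, peak]
        ll <- unproject_local(pp$path$x, pp$path$y,
                              attr(tr$interp, "origin"))
        point_rows[[length(point_rows) + 1]] <- data.frame(
          animal_id = tr$animal_id, trip = pp$trip,
          point = seq_len(nrow(pp$path)), lon = ll$lon, lat = ll$lat,
          timestamp = .fmt_utc(pp$path$t), radius_km = ars_r, fpt_h = fr)
      }
    }
    ars_tab <- do.call(rbind, ars_rows)
    pts <- do.call(rbind, point_rows)
    utils::write.csv(ars_tab, pth("ars_summary.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(pts, pth("fpt_points.csv"), row.names = FALSE,
                     quote = FALSE)
    list(ars = ars_tab, points = pts)
  })

  ## -- BBMM UD -------------------------------------------------------------
  ud_res <- .stage("ud", {
    rows <- list()
    for (tr in tracks) {
      w <- segment_trips(tr$fixes, min_trip = config$min_trip_h)
      for (i in seq_len(nrow(w))) {
        pos <- tr$interp[tr$interp$t >= w$start_t[i] &
                           tr$interp$t <= w$end_t[i], ]
        if (nrow(pos) < 5) next
        s2 <- estimate_bm_variance(pos, loc_error = 0.1)
        ud <- bbmm_ud(pos, s2, loc_error = 0.1,
                      cellsize = config$ud_cell_km)
        rows[[length(rows) + 1]] <- data.frame(
          animal_id = tr$animal_id, trip = w$trip[i], sigma2_m = s2,
          ud50_km2 = ud$area50, ud95_km2 = ud$area95)
        if (i == 1) {
          write_esri_ascii(ud$grid, pth(sprintf("ud_%s_trip1.asc",
                                                tr$animal_id)))
          write_ud_contours_geojson(ud, attr(tr$interp, "origin"),
                                    pth(sprintf("ud_%s_trip1.geojson",
                                                tr$animal_id)))
        }
      }
    }
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, pth("ud_areas.csv"), row.names = FALSE,
                     quote = FALSE)
    tab
  })

  ## -- oceanography --------------------------------------------------------
  ocean <- .stage("ocean", {
    ocfg <- ocean_config()
    profs <- list(); truths <- list()
    for (ai in seq_along(tracks)) {
      tr <- tracks[[ai]]
      at_sea <- tr$interp[which(tr$interp$wet),]
      locs <- at_sea[seq(1, nrow(at_sea), by = config$profile_every), ]
      locs$bottom_m <- pmax(6, sample_grid(bathy, locs$lon, locs$lat))
      sim <- simulate_ctd_profiles(locs, ocfg, seed = seed + 100 + ai,
                                   animal_id = tr$animal_id)
      sim$profiles$profile_id <- paste0(tr$animal_id, "_",
                                        sim$profiles$profile_id)
      profs[[ai]] <- sim$profiles; truths[[ai]] <- sim$truth
    }
    profiles <- do.call(rbind, profs)
    write_ctd_csv(profiles, pth("ctd_profiles.csv"))
    wc <- summarize_profiles(profiles, delta = config$delta_sigma,
                             surface_ref_depth = config$surface_ref_m)
    out <- wc; out$t <- .fmt_utc(out$t)
    utils::write.csv(out, pth("water_column.csv"), row.names = FALSE,
                     quote = FALSE)
    # monthly benthic-temperature and MLD fields
    gspec <- raster_grid(matrix(0, ceiling(2.4 / config$field_cell_deg),
                                ceiling(3 / config$field_cell_deg)),
                         xll = 133.8, yll = -35.7,
                         cellsize = config$field_cell_deg)
    fields <- list(benthic_temp = list(), mld_m = list(),
                   benthic_sal = list(), transition_thickness = list(),
                   thermocline_intensity = list())
    for (m in sort(unique(wc$month))) {
      sub <- wc[wc$month == m, ]
      for (v in names(fields)) {
        fields[[v]][[as.character(m)]] <- monthly_field(
          sub$lon, sub$lat, sub[[v]], gspec, power = config$idw_power,
          max_dist = config$idw_max_dist_km)
      }
      write_esri_ascii(fields$benthic_temp[[as.character(m)]],
                       pth(sprintf("benthic_temp_m%02d.asc", m)))
    }
    list(profiles = profiles, wc = wc, fields = fields)
  })

  ## -- covariates + CPH ----------------------------------------------------
  habitat <- .stage("habitat", {
    pts <- fpt_res$points
    pts$month <- as.integer(substr(pts$timestamp, 6, 7))
    cov <- extract_covariates(pts, monthly_fields = ocean$fields,
                              bathymetry = bathy, slope = slope)
    utils::write.csv(cov, pth("covariates.csv"), row.names = FALSE,
                     quote = FALSE)
    sel_rows <- list()
    for (a in unique(cov$animal_id)) {
      sub <- cov[cov$animal_id == a & !is.na(cov$fpt_h) & cov$fpt_h > 0, ]
      sub <- sub[stats::complete.cases(sub[, c("depth_m", "slope_deg")]), ]
      if (nrow(sub) < 30) next
      sel <- tryCatch(
        cox_select(sub$fpt_h,
                   data.frame(depth_m = sub$depth_m,
                              slope_deg = sub$slope_deg,
                              mld_m = sub$mld_m),
                   cluster = sub$trip, r_max = config$r_max),
        error = function(e) NULL)
      if (is.null(sel)) next
      tb <- sel$table; tb$animal_id <- a
      sel_rows[[length(sel_rows) + 1]] <- tb
    }
    cph_tab <- do.call(rbind, sel_rows)
    utils::write.csv(cph_tab, pth("cph_models.csv"), row.names = FALSE,
                     quote = FALSE)
    list(covariates = cov, cph = cph_tab)
  })

  ## -- isotopes ------------------------------------------------------------
  iso <- .stage("isotopes", {
    rows <- list(); summ <- list(); series <- list()
    for (ai in seq_along(tracks)) {
      a <- tracks[[ai]]$animal_id
      c13 <- simulate_isotope_series(config$whisker_segments, mu = -16,
                                     phi = 0.4, phi_s = 0.6, s = 12,
                                     sigma_eps = 0.25,
                                     seed = seed + 200 + ai)
      n15 <- simulate_isotope_series(config$whisker_segments, mu = 16,
                                     phi = 0.5, phi_s = 0, s = 12,
                                     sigma_eps = 0.2,
                                     seed = seed + 300 + ai)
      # series are oldest-first; segment 1 (base) is the newest growth
      rows[[ai]] <- data.frame(animal_id = a,
                               segment_index = seq_len(config$whisker_segments),
                               d13C = rev(c13$series), d15N = rev(n15$series))
      series[[a]] <- c13$series
      s13 <- isotope_summary(c13$series); s15 <- isotope_summary(n15$series)
      summ[[ai]] <- data.frame(animal_id = a,
                               d13C_mean = s13$mean, d13C_var = s13$variance,
                               d13C_min = s13$min, d13C_max = s13$max,
                               d15N_mean = s15$mean, d15N_var = s15$variance,
                               d15N_min = s15$min, d15N_max = s15$max)
    }
    whisker <- do.call(rbind, rows)
    write_whisker_csv(whisker, pth("whisker.csv"))
    summary_tab <- do.call(rbind, summ)
    utils::write.csv(summary_tab, pth("isotope_summary.csv"),
                     row.names = FALSE, quote = FALSE)
    cmp <- compare_individuals(series)
    sel <- sarima_select(series[[1]], p = 0:1, q = 0:1, d = 0, P = 0:1,
                         D = 0, Q = 0, seasons = config$sarima_seasons)
    utils::write.csv(sel$table, pth("sarima_models.csv"), row.names = FALSE,
                     quote = FALSE)
    list(whisker = whisker, summary = summary_tab, compare = cmp,
         sarima = sel)
  })

  ## -- manifest ------------------------------------------------------------
  .stage("manifest", {
    files <- sort(list.files(out_dir))
    manifest <- list(
      package = "aslforage",
      version = as.character(utils::packageVersion("aslforage")),
      seed = seed,
      config = unclass(config),
      artifacts = files)
    jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  })

  invisible(list(trips = trips, fpt = fpt_res, ud = ud_res, ocean = ocean,
                 habitat = habitat, isotopes = iso, out_dir = out_dir))
}
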