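# Water-column descriptors from CTD casts: potential density anomaly,
# mixed layer depth, thermocline intensity, benthic values, upwelled-water
# classification, and monthly gridded fields for covariate extraction.

#' Potential density anomaly of seawater at surface pressure (EOS-80)
#'
#' sigma-theta = rho(S, T, p = 0) - 1000 kg m-3 via the UNESCO 1983
#' (EOS-80) one-atmosphere international equation of state, implemented
#' in-repo and verified against the published check values. At the surface
#' reference pressure, potential and in-situ temperature coincide, so `temp`
#' is used directly; for the shelf depths handled here (< 150 m) the
#' adiabatic correction is far below the 0.125 kg m-3 mixed-layer
#' threshold. The `eos` argument is an adapter hook: any function
#' `f(sal, temp)` returning density (kg m-3) can be swapped in (e.g. a
#' TEOS-10 implementation).
#'
#' @param sal practical salinity (psu), within `[2, 42]`.
#' @param temp temperature (deg C), within `[-2, 40]`.
#' @param pressure dbar; must be 0 (surface reference) for the built-in
#'   polynomial.
#' @param eos optional replacement equation of state `f(sal, temp)`.
#' @return sigma-theta in kg m-3.
#' @export
sigma_theta <- function(sal, temp, pressure = 0, eos = NULL) {
  if (any(!is.finite(sal)) || any(!is.finite(temp)))
    stop("non-finite T/S input", call. = FALSE)
  if (any(temp < -2 | temp > 40)) stop("temperature outside [-2, 40] C",
                                       call. = FALSE)
  if (any(sal < 2 | sal > 42)) stop("salinity outside [2, 42]",
                                    call. = FALSE)
  if (!is.null(eos)) return(eos(sal, temp) - 1000)
  if (any(pressure != 0))
    stop("built-in EOS-80 polynomial is surface-referenced (pressure = 0)",
         call. = FALSE)
  t <- temp; s <- sal
  rho_w <- 999.842594 + 6.793952e-2 * t - 9.095290e-3 * t^2 +
    1.001685e-4 * t^3 - 1.120083e-6 * t^4 + 6.536332e-9 * t^5
  a <- 8.24493e-1 - 4.0899e-3 * t + 7.6438e-5 * t^2 -
    8.2467e-7 * t^3 + 5.3875e-9 * t^4
  b <- -5.72466e-3 + 1.0227e-4 * t - 1.6546e-6 * t^2
  c0 <- 4.8314e-4
  rho_w + a * s + b * s^1.5 + c0 * s^2 - 1000
}

#' Interpolate a CTD cast to 1-m levels
#'
#' T and S are linearly interpolated to integer-metre depths from 1 m to the
#' deepest bin (levels above the shallowest bin take its value); sigma-theta
#' is then computed at each level from the interpolated T and S, never
#' interpolated from per-bin densities.
#'
#' @param depth_m increasing depth bins (m).
#' @param temp_c,sal_psu per-bin temperature and salinity.
#' @return data.frame with `depth_m` (1..deepest), `temp_c`, `sal_psu`,
#'   `sigma_theta`.
#' @export
interpolate_levels <- function(depth_m, temp_c, sal_psu) {
  if (length(depth_m) < 2) stop("single-bin profile", call. = FALSE)
  if (is.unsorted(depth_m, strictly = TRUE))
    stop("depth bins must be strictly increasing", call. = FALSE)
  z <- seq_len(floor(max(depth_m)))
  tt <- approx(depth_m, temp_c, xout = z, rule = 2)$y
  ss <- approx(depth_m, sal_psu, xout = z, rule = 2)$y
  data.frame(depth_m = z, temp_c = tt, sal_psu = ss,
             sigma_theta = sigma_theta(ss, tt))
}

#' Mixed layer depth by the density-threshold criterion
#'
#' MLD is the shallowest 1-m level below the surface reference depth where
#' sigma-theta exceeds the reference value (at `surface_ref_depth`, the
#' bottom of the first transmitted depth bin) by at least `delta`. If no
#' level qualifies the column is fully mixed and MLD equals the deepest
#' level.
#'
#' @param levels data.frame from [interpolate_levels()].
#' @param delta density threshold, kg m-3.
#' @param surface_ref_depth reference depth, m.
#' @return MLD in m.
#' @export
mixed_layer_depth <- function(levels, delta = 0.125, surface_ref_depth = 4) {
  if (max(levels$depth_m) < surface_ref_depth)
    stop("profile shallower than the surface reference depth",
         call. = FALSE)
  ref <- levels$sigma_theta[match(surface_ref_depth, levels$depth_m)]
  below <- levels$depth_m > surface_ref_depth
  hit <- which(below & levels$sigma_theta - ref >= delta)
  if (length(hit)) levels$depth_m[hit[1]] else max(levels$depth_m)
}

#' Thermocline intensity
#'
#' Maximum absolute change in temperature per metre over consecutive
#' 1-m levels, deg C per m.
#'
#' @param levels data.frame from [interpolate_levels()].
#' @return deg C per m.
#' @export
thermocline_intensity <- function(levels) {
  if (nrow(levels) < 2) stop("need at least two levels", call. = FALSE)
  max(abs(diff(levels$temp_c)) / diff(levels$depth_m))
}

#' Benthic values and transition layer thickness
#'
#' Benthic T and S are taken from the deepest level (the maximum depth bin
#' stands in for the sea floor); transition layer thickness is the distance
#' from the bottom of the mixed layer to the sea floor.
#'
#' @param levels data.frame from [interpolate_levels()].
#' @param mld mixed layer depth (m), from [mixed_layer_depth()].
#' @return list with `benthic_temp`, `benthic_sal`, `transition_thickness`.
#' @export
benthic_and_transition <- function(levels, mld) {
  i <- which.max(levels$depth_m)
  list(benthic_temp = levels$temp_c[i],
       benthic_sal = levels$sal_psu[i],
       transition_thickness = levels$depth_m[i] - mld)
}

#' Classify water as upwelled
#'
#' Study-region threshold criteria for upwelled water, all strict:
#' T < 17 deg C, sigma-theta > 26 kg m-3, salinity < 35.6.
#'
#' @param temp deg C.
#' @param sal practical salinity.
#' @param sigma sigma-theta, kg m-3.
#' @return logical.
#' @export
classify_upwelled <- function(temp, sal, sigma) {
  temp < 17 & sigma > 26 & sal < 35.6
}

#' Summarize one CTD profile
#'
#' Runs the full water-column chain on one cast: 1-m levels, MLD,
#' thermocline intensity, benthic values, transition thickness, and the
#' upwelled flag evaluated on the benthic level.
#'
#' @param depth_m,temp_c,sal_psu the cast's bins.
#' @param delta,surface_ref_depth MLD criterion, see [mixed_layer_depth()].
#' @return one-row data.frame (WaterColumnSummary).
#' @export
summarize_profile <- function(depth_m, temp_c, sal_psu,
                              delta = 0.125, surface_ref_depth = 4) {
  lev <- interpolate_levels(depth_m, temp_c, sal_psu)
  mld <- mixed_layer_depth(lev, delta, surface_ref_depth)
  bt <- benthic_and_transition(lev, mld)
  i <- which.max(lev$depth_m)
  data.frame(mld_m = mld,
             thermocline_intensity = thermocline_intensity(lev),
             benthic_temp = bt$benthic_temp,
             benthic_sal = bt$benthic_sal,
             transition_thickness = bt$transition_thickness,
             upwelled = classify_upwelled(bt$benthic_temp, bt$benthic_sal,
                                          lev$sigma_theta[i]))
}

#' Summarize a set of CTD profiles
#'
#' @param profiles long data.frame (profile_id, t, lon, lat, depth_m,
#'   temp_c, sal_psu), as read by [read_ctd_csv()] or produced by
#'   [simulate_ctd_profiles()].
#' @param ... passed to [summarize_profile()].
#' @return data.frame, one row per profile, with id/time/location columns
#'   plus the water-column summary and calendar `month`.
#' @export
summarize_profiles <- function(profiles, ...) {
  ids <- unique(profiles$profile_id)
  rows <- lapply(ids, function(id) {
    p <- profiles[profiles$profile_id == id, ]
    p <- p[order(p$depth_m), ]
    cbind(data.frame(profile_id = id, t = p$t[1], lon = p$lon[1],
                     lat = p$lat[1],
                     month = as.integer(format(p$t[1], "%m"))),
          summarize_profile(p$depth_m, p$temp_c, p$sal_psu, ...))
  })
  do.call(rbind, rows)
}

#' Monthly inverse-distance-weighted field
#'
#' Grids point samples onto a raster by inverse-distance weighting: each
#' cell takes the IDW mean of the samples within `max_dist` km of its
#' centre; cells with no sample in range are nodata. Distances are
#' great-circle for lon/lat grids, Euclidean for planar grids.
#'
#' @param lon,lat,value sample locations and values.
#' @param grid_spec a [raster_grid()] giving the target geometry (values
#'   ignored).
#' @param power IDW exponent.
#' @param max_dist search radius, km.
#' @return a [raster_grid()] with the interpolated field.
#' @export
monthly_field <- function(lon, lat, value, grid_spec, power = 2,
                          max_dist = 100) {
  if (length(value) < 1) stop("no samples", call. = FALSE)
  g <- grid_spec
  out <- matrix(NA_real_, g$nrows, g$ncols)
  xc <- .grid_xc(g, seq_len(g$ncols))
  yc <- .grid_yc(g, seq_len(g$nrows))
  for (i in seq_len(g$nrows)) {
    for (j in seq_len(g$ncols)) {
      d <- if (g$crs == "lonlat") haversine_km(xc[j], yc[i], lon, lat)
           else sqrt((xc[j] - lon)^2 + (yc[i] - lat)^2)
      keep <- d <= max_dist
      if (!any(keep)) next
      if (any(d[keep] < 1e-9)) { out[i, j] <- value[keep][which.min(d[keep])]
      } else {
        w <- 1 / d[keep]^power
        out[i, j] <- sum(w * value[keep]) / sum(w)
      }
    }
  }
  raster_grid(out, g$xll, g$yll, g$cellsize, g$nodata, crs = g$crs,
              origin = g$origin)
}

#' Extract environmental covariates at FPT locations
#'
#' One row per input point: static depth and slope (bilinear sample of the
#' DEM-derived grids) and the monthly dynamic fields matched on calendar
#' month. Points outside a field get `NA` in that column with a warning.
#'
#' @param points data.frame with `lon`, `lat`, `month` and any id columns
#'   (carried through).
#' @param monthly_fields named list: `monthly_fields[[var]][[month]]` is a
#'   [raster_grid()] (months as character keys).
#' @param bathymetry,slope static [raster_grid()]s (may be NULL).
#' @return `points` with one extra column per variable.
#' @export
extract_covariates <- function(points, monthly_fields = list(),
                               bathymetry = NULL, slope = NULL) {
  n <- nrow(points)
  safe_sample <- function(grid, lon, lat) {
    vapply(seq_along(lon), function(k) {
      tryCatch(sample_grid(grid, lon[k], lat[k]),
               error = function(e) NA_real_)
    }, numeric(1))
  }
  out <- points
  if (!is.null(bathymetry))
    out$depth_m <- safe_sample(bathymetry, points$lon, points$lat)
  if (!is.null(slope))
    out$slope_deg <- safe_sample(slope, points$lon, points$lat)
  for (var in names(monthly_fields)) {
    col <- rep(NA_real_, n)
    for (m in unique(points$month)) {
      gm <- monthly_fields[[var]][[as.character(m)]]
      if (is.null(gm)) next
      idx <- which(points$month == m)
      col[idx] <- safe_sample(gm, points$lon[idx], points$lat[idx])
    }
    out[[var]] <- col
  }
  miss <- vapply(seq_len(n), function(i) anyNA(out[i, setdiff(names(out),
                                                  names(points))]),
                 logical(1))
  if (any(miss))
    warning(sum(miss), " point(s) fell outside one or more fields; ",
            "missing values emitted", call. = FALSE)
  out
}
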