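# Readers/writers for the pipeline's file dialects. All CSVs are plain
# comma-separated with a header row; timestamps are ISO-8601 UTC
# ("YYYY-MM-DDTHH:MM:SSZ"); coordinates decimal degrees WGS84.

.parse_utc <- function(x, file, col) {
  t <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  t2 <- as.POSIXct(x, format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
  t[is.na(t)] <- t2[is.na(t)]
  if (anyNA(t)) {
    bad <- which(is.na(t))[1]
    stop(sprintf("%s: malformed timestamp in column '%s' at data row %d: '%s'",
                 file, col, bad, x[bad]), call. = FALSE)
  }
  t
}

.fmt_utc <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

.require_cols <- function(df, cols, file) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s): %s", file,
                 paste(miss, collapse = ", ")), call. = FALSE)
}

#' Read ARGOS fixes CSV
#'
#' Columns: animal_id, timestamp (ISO-8601 UTC), lon, lat, lc (ARGOS class
#' 3/2/1/0/A/B/Z), wet (TRUE/FALSE).
#' @param path file path.
#' @return data.frame with `t` as POSIXct UTC.
#' @export
read_fixes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(lc = "character"))
  .require_cols(df, c("animal_id", "timestamp", "lon", "lat", "lc", "wet"),
                path)
  bad_lc <- which(!df$lc %in% .ARGOS_CLASSES)
  if (length(bad_lc))
    stop(sprintf("%s: invalid location class at data row %d: '%s'", path,
                 bad_lc[1], df$lc[bad_lc[1]]), call. = FALSE)
  data.frame(animal_id = df$animal_id,
             t = .parse_utc(df$timestamp, path, "timestamp"),
             lon = df$lon, lat = df$lat, lc = df$lc,
             wet = as.logical(df$wet), stringsAsFactors = FALSE)
}

#' Write ARGOS fixes CSV
#' @param fixes data.frame as returned by [read_fixes_csv()].
#' @param path output path.
#' @export
write_fixes_csv <- function(fixes, path) {
  utils::write.csv(data.frame(animal_id = fixes$animal_id,
                              timestamp = .fmt_utc(fixes$t),
                              lon = fixes$lon, lat = fixes$lat,
                              lc = fixes$lc, wet = fixes$wet),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read CTD profiles CSV (long format)
#'
#' Columns: profile_id, animal_id, timestamp, lon, lat, depth_m, temp_c,
#' sal_psu.
#' @param path file path.
#' @return data.frame with `t` as POSIXct UTC.
#' @export
read_ctd_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("profile_id", "animal_id", "timestamp", "lon", "lat",
                      "depth_m", "temp_c", "sal_psu"), path)
  data.frame(profile_id = df$profile_id, animal_id = df$animal_id,
             t = .parse_utc(df$timestamp, path, "timestamp"),
             lon = df$lon, lat = df$lat, depth_m = df$depth_m,
             temp_c = df$temp_c, sal_psu = df$sal_psu,
             stringsAsFactors = FALSE)
}

#' Write CTD profiles CSV
#' @param profiles long data.frame.
#' @param path output path.
#' @export
write_ctd_csv <- function(profiles, path) {
  utils::write.csv(data.frame(profile_id = profiles$profile_id,
                              animal_id = profiles$animal_id,
                              timestamp = .fmt_utc(profiles$t),
                              lon = profiles$lon, lat = profiles$lat,
                              depth_m = profiles$depth_m,
                              temp_c = profiles$temp_c,
                              sal_psu = profiles$sal_psu),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read whisker isotope CSV
#'
#' Columns: animal_id, segment_index (1 = base), d13C, d15N.
#' @param path file path.
#' @return data.frame.
#' @export
read_whisker_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("animal_id", "segment_index", "d13C", "d15N"), path)
  df
}

#' Write whisker isotope CSV
#' @param whisker data.frame with animal_id, segment_index, d13C, d15N.
#' @param path output path.
#' @export
write_whisker_csv <- function(whisker, path) {
  utils::write.csv(whisker[, c("animal_id", "segment_index", "d13C",
                               "d15N")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write UD contour polygons as GeoJSON
#'
#' Extracts the density contour enclosing each probability level (smallest
#' set of cells whose mass reaches the level) from a planar UD grid and
#' writes the rings as GeoJSON polygons in lon/lat.
#'
#' @param ud a `ud_result` from [bbmm_ud()].
#' @param origin c(lon, lat) projection origin of the UD's planar grid.
#' @param path output path.
#' @param levels probability levels.
#' @export
write_ud_contours_geojson <- function(ud, origin, path,
                                      levels = c(0.5, 0.95)) {
  g <- ud$grid
  xc <- .grid_xc(g, seq_len(g$ncols))
  yc_desc <- .grid_yc(g, seq_len(g$nrows))     # row 1 = top
  z <- t(g$values[rev(seq_len(g$nrows)), , drop = FALSE])  # [x, y asc]
  yc <- rev(yc_desc)
  m <- sort(as.vector(g$values), decreasing = TRUE)
  cum <- cumsum(m)
  feats <- list()
  for (lev in levels) {
    k <- which(cum >= lev - 1e-12)[1]
    thr <- m[k]
    cl <- grDevices::contourLines(xc, yc, z, levels = thr)
    coords <- lapply(cl, function(ring) {
      ll <- unproject_local(ring$x, ring$y, origin)
      ring_xy <- cbind(ll$lon, ll$lat)
      if (!all(ring_xy[1, ] == ring_xy[nrow(ring_xy), ]))
        ring_xy <- rbind(ring_xy, ring_xy[1, ])
      lapply(seq_len(nrow(ring_xy)), function(i) as.numeric(ring_xy[i, ]))
    })
    feats[[length(feats) + 1]] <- list(
      type = "Feature",
      properties = list(level = lev),
      geometry = list(type = "Polygon", coordinates = coords))
  }
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Missing keys take the [pipeline_config()] defaults.
#' @param path YAML file.
#' @return a `pipeline_config` list.
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}
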