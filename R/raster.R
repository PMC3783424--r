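# Minimal raster container + ESRI ASCII grid I/O, slope and sampling.
# Grids are cell-centre registered, row-major from the top (north) row,
# lower-left corner given by (xll, yll) as in the ESRI ASCII convention.

#' Construct a raster grid
#'
#' @param values numeric matrix, `nrows` x `ncols`, row 1 = northernmost row.
#' @param xll,yll lower-left corner of the grid (degrees, or km for planar
#'   grids; units are the caller's).
#' @param cellsize cell edge length, same units as `xll`/`yll`.
#' @param nodata sentinel for missing cells (stored as `NA` internally).
#' @param crs either `"lonlat"` (default) or `"planar_km"`; planar grids
#'   carry their projection `origin` (lon, lat) so they can be georeferenced.
#' @param origin projection origin for planar grids.
#' @return object of class `raster_grid`.
#' @export
raster_grid <- function(values, xll, yll, cellsize, nodata = -9999,
                        crs = c("lonlat", "planar_km"), origin = NULL) {
  crs <- match.arg(crs)
  if (!is.matrix(values)) stop("values must be a matrix", call. = FALSE)
  if (cellsize <= 0) stop("cellsize must be > 0", call. = FALSE)
  structure(list(values = values, ncols = ncol(values), nrows = nrow(values),
                 xll = xll, yll = yll, cellsize = cellsize, nodata = nodata,
                 crs = crs, origin = origin),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid: %d x %d cells, cellsize %g (%s), xll %g, yll %g\n",
              x$nrows, x$ncols, x$cellsize, x$crs, x$xll, x$yll))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  values in [%g, %g], %d NA cells\n", rng[1], rng[2],
              sum(is.na(x$values))))
  invisible(x)
}

# x coordinate of cell-centre column j (1-based), y of row i (row 1 = top)
.grid_xc <- function(g, j) g$xll + (j - 0.5) * g$cellsize
.grid_yc <- function(g, i) g$yll + (g$nrows - i + 0.5) * g$cellsize

#' Read an ESRI ASCII grid (.asc)
#'
#' Header keys NCOLS/NROWS/XLLCORNER/YLLCORNER/CELLSIZE/NODATA_VALUE
#' (case-insensitive); values row-major from the north row. NODATA cells
#' become `NA`.
#'
#' @param path file path.
#' @return a [raster_grid()].
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("missing ESRI ASCII header keys: ",
         paste(setdiff(need, names(hdr)), collapse = ", "), call. = FALSE)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop(sprintf("expected %d values, found %d",
                 hdr$ncols * hdr$nrows, length(vals)), call. = FALSE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  raster_grid(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, nodata)
}

#' Write an ESRI ASCII grid (.asc)
#'
#' Bit-exact round-trip of header values; `NA` cells written as the grid's
#' nodata sentinel.
#'
#' @param grid a [raster_grid()].
#' @param path output path.
#' @export
write_esri_ascii <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("NCOLS %d", grid$ncols),
    sprintf("NROWS %d", grid$nrows),
    sprintf("XLLCORNER %.10g", grid$xll),
    sprintf("YLLCORNER %.10g", grid$yll),
    sprintf("CELLSIZE %.10g", grid$cellsize),
    sprintf("NODATA_VALUE %.10g", grid$nodata)), con)
  m <- grid$values
  m[is.na(m)] <- grid$nodata
  writeLines(apply(m, 1, function(r) paste(format(r, trim = TRUE,
                                                  digits = 10),
                                           collapse = " ")), con)
  invisible(path)
}

#' Bilinear sampling of a grid at points
#'
#' Interpolates the four surrounding cell centres; outside the outermost
#' ring of centres the value collapses to the nearest edge cell (points must
#' still lie within the grid extent). `NA` (nodata) in any contributing cell
#' propagates.
#'
#' @param grid a [raster_grid()].
#' @param x,y point coordinates in the grid's units (lon/lat or planar km).
#' @return numeric vector of sampled values.
#' @export
sample_grid <- function(grid, x, y) {
  xmax <- grid$xll + grid$ncols * grid$cellsize
  ymax <- grid$yll + grid$nrows * grid$cellsize
  if (any(x < grid$xll | x > xmax | y < grid$yll | y > ymax))
    stop("point outside grid extent", call. = FALSE)
  # fractional column/row in cell-centre coordinates
  fc <- (x - grid$xll) / grid$cellsize + 0.5   # 1 at first centre
  fr <- (ymax - y) / grid$cellsize + 0.5       # 1 at top centre
  j0 <- pmin(pmax(floor(fc), 1), grid$ncols - 1)
  i0 <- pmin(pmax(floor(fr), 1), grid$nrows - 1)
  if (grid$ncols == 1) j0 <- rep(1, length(x))
  if (grid$nrows == 1) i0 <- rep(1, length(x))
  tx <- pmin(pmax(fc - j0, 0), 1)
  ty <- pmin(pmax(fr - i0, 0), 1)
  v <- grid$values
  j1 <- pmin(j0 + 1, grid$ncols); i1 <- pmin(i0 + 1, grid$nrows)
  v00 <- v[cbind(i0, j0)]; v01 <- v[cbind(i0, j1)]
  v10 <- v[cbind(i1, j0)]; v11 <- v[cbind(i1, j1)]
  (1 - ty) * ((1 - tx) * v00 + tx * v01) + ty * ((1 - tx) * v10 + tx * v11)
}

#' Slope of a DEM by Horn's method
#'
#' 3x3 finite-difference slope in degrees. For lon/lat grids the cell size
#' is converted to metres at the grid-centre latitude (east-west spacing
#' scaled by cos(lat)); planar-km grids use 1000 m per km. Edge cells are
#' nodata.
#'
#' @param dem a [raster_grid()] of elevations/depths in metres.
#' @return a [raster_grid()] of slope in degrees, `[0, 90)`.
#' @export
grid_slope <- function(dem) {
  if (dem$nrows < 3 || dem$ncols < 3)
    stop("grid smaller than 3x3", call. = FALSE)
  if (dem$crs == "lonlat") {
    lat_c <- dem$yll + dem$nrows * dem$cellsize / 2
    dy_m <- dem$cellsize * (pi / 180) * EARTH_RADIUS_KM * 1000
    dx_m <- dy_m * cos(lat_c * pi / 180)
  } else {
    dx_m <- dy_m <- dem$cellsize * 1000
  }
  z <- dem$values
  nr <- dem$nrows; nc <- dem$ncols
  out <- matrix(NA_real_, nr, nc)
  # shifted sub-matrices: a b c / d e f / g h i around each interior cell
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  a <- z[ri - 1, ci - 1]; b <- z[ri - 1, ci]; cc <- z[ri - 1, ci + 1]
  d <- z[ri, ci - 1];                        f <- z[ri, ci + 1]
  g <- z[ri + 1, ci - 1]; h <- z[ri + 1, ci]; ii <- z[ri + 1, ci + 1]
  dzdx <- ((cc + 2 * f + ii) - (a + 2 * d + g)) / (8 * dx_m)
  dzdy <- ((a + 2 * b + cc) - (g + 2 * h + ii)) / (8 * dy_m)
  out[ri, ci] <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  raster_grid(out, dem$xll, dem$yll, dem$cellsize, dem$nodata,
              crs = dem$crs, origin = dem$origin)
}
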