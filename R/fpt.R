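# First-passage-time analysis: 1-km rediscretization of tracks, FPT over a
# radius sweep, the ARS scale as the variance-of-log-FPT peak, and labelling
# of high-FPT (inferred foraging) locations.

#' Rediscretize a track to equal step lengths
#'
#' Classical track rediscretization: starting at the first position, walk
#' the piecewise-linear projected track and place the next point where the
#' straight-line (Euclidean) distance from the previous placed point first
#' equals `step` km, located exactly by segment-circle intersection. The
#' time at each point is linearly interpolated within its source segment.
#' FPT is always computed on this path, never on raw fixes.
#'
#' @param track data.frame with planar `x`, `y` (km) and `t` (POSIXct), as
#'   produced by [interpolate_track()].
#' @param step spacing, km.
#' @return data.frame of class `discrete_path` with `x`, `y` (km), `t`;
#'   consecutive point spacing is exactly `step` km (the leftover tail of
#'   the track shorter than one step is dropped).
#' @export
rediscretize <- function(track, step = 1) {
  if (nrow(track) < 2) stop("need at least 2 positions", call. = FALSE)
  x <- track$x; y <- track$y
  t_h <- as.numeric(track$t - track$t[1], units = "hours")
  n <- length(x)
  if (sum(sqrt(diff(x)^2 + diff(y)^2)) < step)
    stop("path shorter than one step", call. = FALSE)
  ox <- x[1]; oy <- y[1]; ot <- t_h[1]
  # current position lies on segment j at fraction s
  j <- 1L; s <- 0
  out_x <- ox; out_y <- oy; out_t <- ot
  repeat {
    placed <- FALSE
    # scan segments from the current one until the circle of radius `step`
    # around the last placed point is crossed
    k <- j
    while (k < n) {
      ex <- x[k + 1]; ey <- y[k + 1]
      if (sqrt((ex - ox)^2 + (ey - oy)^2) >= step) {
        s0 <- if (k == j) s else 0
        # crossing fraction within [s0, 1] of segment k
        f <- .cross_frac(c(x[k] + s0 * (x[k + 1] - x[k]),
                           y[k] + s0 * (y[k + 1] - y[k])),
                         c(ex, ey), c(ox, oy), step)
        s_new <- s0 + f * (1 - s0)
        ox <- x[k] + s_new * (x[k + 1] - x[k])
        oy <- y[k] + s_new * (y[k + 1] - y[k])
        ot <- t_h[k] + s_new * (t_h[k + 1] - t_h[k])
        j <- k; s <- s_new
        out_x <- c(out_x, ox); out_y <- c(out_y, oy); out_t <- c(out_t, ot)
        placed <- TRUE
        break
      }
      k <- k + 1L
    }
    if (!placed) break
  }
  out <- data.frame(x = out_x, y = out_y,
                    t = track$t[1] + (out_t - t_h[1]) * 3600)
  class(out) <- c("discrete_path", class(out))
  out
}

# crossing fraction s in [0,1] along segment p1->p2 where distance from c
# first equals r (entering from inside: |p1-c| <= r < |p2-c|)
.cross_frac <- function(p1, p2, cen, r) {
  d <- p2 - p1; f <- p1 - cen
  a <- sum(d * d); b <- 2 * sum(f * d); cc <- sum(f * f) - r^2
  disc <- b^2 - 4 * a * cc
  if (disc < 0) disc <- 0
  s <- (-b + sqrt(disc)) / (2 * a)   # larger root = outward crossing
  min(max(s, 0), 1)
}

#' First passage time across a circle of radius r
#'
#' For each path point, FPT is the time between the backward and forward
#' first exits from the circle of radius `r` centred on that point; exit
#' instants are located exactly by segment-circle intersection. Points whose
#' forward or backward walk reaches the end of the path before crossing get
#' `NA` (missing, not an error).
#'
#' @param path a [rediscretize()]d path.
#' @param r radius, km.
#' @return numeric vector of FPT in hours, one per path point.
#' @export
first_passage_time <- function(path, r) {
  if (r <= 0) stop("radius must be > 0", call. = FALSE)
  n <- nrow(path)
  x <- path$x; y <- path$y
  t_h <- as.numeric(path$t - path$t[1], units = "hours")
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    # forward exit
    if (i == n) next
    df <- sqrt((x[(i + 1):n] - x[i])^2 + (y[(i + 1):n] - y[i])^2)
    kf <- which(df > r)[1]
    if (is.na(kf)) next
    k <- i + kf                     # first index beyond r
    s <- .cross_frac(c(x[k - 1], y[k - 1]), c(x[k], y[k]),
                     c(x[i], y[i]), r)
    t_fwd <- t_h[k - 1] + s * (t_h[k] - t_h[k - 1])
    # backward exit
    if (i == 1) next
    db <- sqrt((x[(i - 1):1] - x[i])^2 + (y[(i - 1):1] - y[i])^2)
    kb <- which(db > r)[1]
    if (is.na(kb)) next
    k <- i - kb                     # first index beyond r going backward
    s <- .cross_frac(c(x[k + 1], y[k + 1]), c(x[k], y[k]),
                     c(x[i], y[i]), r)
    t_bwd <- t_h[k + 1] + s * (t_h[k] - t_h[k + 1])
    out[i] <- t_fwd - t_bwd
  }
  out
}

#' Maximum daily step length of a path
#'
#' Max over calendar (UTC) days of the summed within-day path length, km;
#' sets the upper end of the FPT radius sweep.
#'
#' @param path a [rediscretize()]d path.
#' @return km.
#' @export
max_daily_step <- function(path) {
  n <- nrow(path)
  seg <- sqrt(diff(path$x)^2 + diff(path$y)^2)
  day <- format(path$t[-n], "%Y-%m-%d")
  max(tapply(seg, day, sum))
}

#' ARS scale from the variance of log FPT
#'
#' Computes FPT over a log-spaced radius sweep from `r_min` to `r_max`
#' (default twice the maximum daily step length), takes the variance across
#' path points of ln FPT at each radius (points undefined at a radius are
#' excluded from that radius's variance), and returns the radius of the
#' variance peak as the ARS patch scale. Ties take the smallest radius; a
#' peak below 0.01 is flagged non-informative (straight, constant-speed
#' movement).
#'
#' @param path a [rediscretize()]d path.
#' @param r_min minimum radius, km.
#' @param r_max maximum radius, km; `NULL` = 2 x [max_daily_step()].
#' @param n_radii number of radii in the sweep.
#' @param min_defined minimum number of defined FPT values a radius needs to
#'   enter the sweep.
#' @return list of class `fpt_profile`: `radii`, `fpt` (points x radii
#'   matrix, h), `varlog`, `ars_radius` (km), `varlog_max`, `informative`.
#' @export
ars_scale <- function(path, r_min = 0.5, r_max = NULL, n_radii = 50,
                      min_defined = 20) {
  if (is.null(r_max)) r_max <- 2 * max_daily_step(path)
  radii <- exp(seq(log(r_min), log(r_max), length.out = n_radii))
  fpt <- vapply(radii, function(r) first_passage_time(path, r),
                numeric(nrow(path)))
  varlog <- apply(fpt, 2, function(col) {
    v <- col[!is.na(col) & col > 0]
    if (length(v) < min_defined) NA_real_ else stats::var(log(v))
  })
  if (all(is.na(varlog)))
    stop("no radius has enough defined FPT values", call. = FALSE)
  peak <- which(varlog == max(varlog, na.rm = TRUE))[1]  # ties: smallest r
  structure(list(radii = radii, fpt = fpt, varlog = varlog,
                 ars_radius = radii[peak],
                 varlog_max = varlog[peak],
                 informative = varlog[peak] >= 0.01),
            class = "fpt_profile")
}

#' Label ARS points by high FPT
#'
#' Points whose FPT at the ARS radius reaches the `q`-quantile of the
#' defined FPT values are flagged as area-restricted search; runs of flagged
#' points are reported as segments.
#'
#' @param fpt_at_r numeric FPT (h) per path point at the chosen radius.
#' @param q quantile threshold in `[0, 1]`.
#' @return list with `ars` (logical per point, `NA` where FPT missing) and
#'   `segments` (data.frame: start, end indices of flagged runs).
#' @export
label_ars <- function(fpt_at_r, q = 0.75) {
  def <- !is.na(fpt_at_r)
  if (!any(def)) stop("all FPT values missing", call. = FALSE)
  thr <- stats::quantile(fpt_at_r[def], q, names = FALSE)
  flag <- ifelse(def, fpt_at_r >= thr, NA)
  r <- rle(ifelse(is.na(flag), FALSE, flag))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  seg <- data.frame(start = starts[r$values], end = ends[r$values])
  list(ars = flag, segments = seg)
}
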