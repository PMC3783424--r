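# Cleaning raw ARGOS fixes, trip segmentation and trip/cohort summaries.

.LC_RANK <- c("3" = 1, "2" = 2, "1" = 3, "0" = 4, "A" = 5, "B" = 6, "Z" = 7)

#' Drop unclassified (LC-Z) locations
#'
#' @param fixes data.frame with at least column `lc`.
#' @return `fixes` without LC-Z rows, order preserved.
#' @export
drop_unclassified <- function(fixes) {
  fixes[fixes$lc != "Z", , drop = FALSE]
}

#' De-duplicate fixes sharing a timestamp
#'
#' Keeps the fix with the better (lower-error) location class; ties keep the
#' first occurrence. Output is strictly increasing in time per animal.
#'
#' @param fixes data.frame with `animal_id`, `t`, `lc`.
#' @return de-duplicated fixes.
#' @export
dedup_fixes <- function(fixes) {
  o <- order(fixes$animal_id, fixes$t, .LC_RANK[as.character(fixes$lc)])
  f <- fixes[o, , drop = FALSE]
  dup <- duplicated(data.frame(f$animal_id, f$t))
  f[!dup, , drop = FALSE]
}

# adjacent-speed rms per fix given km coordinates and hours
.rms_speeds <- function(x, y, t_h) {
  n <- length(x)
  sp <- sqrt(diff(x)^2 + diff(y)^2) / diff(t_h)  # km/h between consecutive
  prev <- c(NA, sp); nxt <- c(sp, NA)
  rms <- sqrt((prev^2 + nxt^2) / 2)
  rms[1] <- nxt[1]; rms[n] <- prev[n]            # endpoints: single speed
  rms
}

#' McConnell swim-speed filter
#'
#' Iterative removal of implausibly fast fixes: each interior fix is scored
#' by the root-mean-square of its two adjacent great-circle speeds
#' (endpoints by their single adjacent speed); while any score exceeds
#' `vmax` the worst fix is removed and scores recomputed. The result is
#' idempotent and guaranteed to contain no fix whose adjacent-speed rms
#' exceeds `vmax`.
#'
#' @param fixes data.frame with `t` (POSIXct), `lon`, `lat`, time-ordered.
#' @param vmax speed bound, m/s.
#' @return filtered fixes.
#' @export
speed_filter <- function(fixes, vmax = 2.0) {
  if (nrow(fixes) < 3) {
    warning("fewer than 3 fixes; returned unchanged", call. = FALSE)
    return(fixes)
  }
  vmax_kmh <- vmax * 3.6
  origin <- c(stats::median(fixes$lon), stats::median(fixes$lat))
  xy <- project_local(fixes$lon, fixes$lat, origin)
  keep <- rep(TRUE, nrow(fixes))
  t_h <- as.numeric(fixes$t) / 3600
  repeat {
    idx <- which(keep)
    if (length(idx) < 2) break
    rms <- .rms_speeds(xy$x[idx], xy$y[idx], t_h[idx])
    bad <- which(rms > vmax_kmh)
    if (!length(bad)) break
    worst <- bad[which.max(rms[bad])]
    keep[idx[worst]] <- FALSE
  }
  fixes[keep, , drop = FALSE]
}

#' Segment a wet/dry fix stream into foraging trips
#'
#' Maximal runs of wet fixes longer than `min_trip` hours become trips
#' (strictly greater than, so a run of exactly `min_trip` h is excluded).
#' Boundaries are the raw timestamps of the first and last wet fix of the
#' run. Dry records and short wet runs are excluded. An all-dry stream
#' yields an empty list.
#'
#' @param fixes data.frame with `t` (POSIXct) and logical `wet`,
#'   time-ordered.
#' @param min_trip minimum at-sea duration, h.
#' @return data.frame of trip windows: `trip`, `start_t`, `end_t`,
#'   `duration_h`.
#' @export
segment_trips <- function(fixes, min_trip = 6) {
  r <- rle(fixes$wet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- list(); k <- 0
  for (i in seq_along(r$values)) {
    if (!isTRUE(r$values[i])) next
    t1 <- fixes$t[starts[i]]; t2 <- fixes$t[ends[i]]
    dur <- as.numeric(difftime(t2, t1, units = "hours"))
    if (dur > min_trip) {
      k <- k + 1
      out[[k]] <- data.frame(trip = k, start_t = t1, end_t = t2,
                             duration_h = dur)
    }
  }
  if (!k) return(data.frame(trip = integer(), start_t = as.POSIXct(character(), tz = "UTC"),
                            end_t = as.POSIXct(character(), tz = "UTC"),
                            duration_h = numeric()))
  do.call(rbind, out)
}

#' Trip metrics: duration, distance and transit speed
#'
#' Distance is the summed great-circle distance over consecutive positions
#' (km), duration in days, speed = distance / (24 * duration) km/h.
#'
#' @param positions data.frame with `t`, `lon`, `lat` for one trip,
#'   time-ordered.
#' @return list with `duration_d`, `distance_km`, `speed_kmh`.
#' @export
trip_metrics <- function(positions) {
  n <- nrow(positions)
  if (n < 2) stop("single-position trip", call. = FALSE)
  dist <- sum(haversine_km(positions$lon[-n], positions$lat[-n],
                           positions$lon[-1], positions$lat[-1]))
  dur_d <- as.numeric(difftime(positions$t[n], positions$t[1],
                               units = "days"))
  list(duration_d = dur_d, distance_km = dist,
       speed_kmh = dist / (24 * dur_d))
}

#' Cohort summary across animals
#'
#' Per-animal means of trip distance, duration and (optionally) dive depth
#' plus trip counts; grand statistics are the unweighted mean over animals
#' with SE = sample SD across animals / sqrt(n animals).
#'
#' @param per_animal data.frame with one row per animal: columns `animal_id`,
#'   `n_trips`, `mean_distance_km`, `mean_duration_d` and optionally
#'   `mean_dive_depth_m` (and any other per-animal means). Use
#'   [per_animal_trip_summary()] to build it from trip tables.
#' @return list with `per_animal` (as given) and `grand` (data.frame:
#'   variable, mean, se, n_animals).
#' @export
cohort_summary <- function(per_animal) {
  if (nrow(per_animal) < 2) stop("need at least 2 animals", call. = FALSE)
  vars <- setdiff(names(per_animal), "animal_id")
  grand <- do.call(rbind, lapply(vars, function(v) {
    x <- per_animal[[v]]
    data.frame(variable = v, mean = mean(x),
               se = stats::sd(x) / sqrt(length(x)),
               n_animals = length(x))
  }))
  list(per_animal = per_animal, grand = grand)
}

#' Per-animal trip summary
#'
#' Collapses a trip table (one row per trip) to one row per animal, the
#' shape [cohort_summary()] consumes.
#'
#' @param trips data.frame with `animal_id`, `distance_km`, `duration_d`
#'   and optionally `dive_depth_m`.
#' @return data.frame, one row per animal.
#' @export
per_animal_trip_summary <- function(trips) {
  ids <- unique(trips$animal_id)
  do.call(rbind, lapply(ids, function(a) {
    tr <- trips[trips$animal_id == a, ]
    out <- data.frame(animal_id = a, n_trips = nrow(tr),
                      mean_distance_km = mean(tr$distance_km),
                      mean_duration_d = mean(tr$duration_d))
    if ("dive_depth_m" %in% names(tr))
      out$mean_dive_depth_m <- mean(tr$dive_depth_m)
    out
  }))
}
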