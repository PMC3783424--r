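# Shared fixtures and independent oracles used across the suite.

t_utc <- function(h) as.POSIXct("2010-01-01 00:00:00", tz = "UTC") + h * 3600

# a discrete path from planar coordinates and times in hours
make_path <- function(x, y, t_h) {
  p <- data.frame(x = x, y = y, t = t_utc(t_h))
  class(p) <- c("discrete_path", class(p))
  p
}

# planar random-walk path: n points, 1-h spacing, N(0, step_sd) increments
random_walk_path <- function(n, seed, step_sd = 1) {
  set.seed(seed)
  make_path(cumsum(c(0, rnorm(n - 1, 0, step_sd))),
            cumsum(c(0, rnorm(n - 1, 0, step_sd))),
            0:(n - 1))
}

# Independent FPT oracle: scans every segment and finds the circle crossing
# by numeric root-finding on the distance function (vs the package's
# closed-form quadratic).
oracle_fpt <- function(path, r) {
  n <- nrow(path)
  x <- path$x; y <- path$y
  t_h <- as.numeric(path$t - path$t[1], units = "hours")
  dist_at <- function(j, s, i) {
    px <- x[j] + s * (x[j + 1] - x[j]); py <- y[j] + s * (y[j + 1] - y[j])
    sqrt((px - x[i])^2 + (py - y[i])^2)
  }
  cross_time <- function(i, idx) {
    # idx: ordered vertex indices walking away from i
    for (k in seq_along(idx)[-1]) {
      a <- idx[k - 1]; b <- idx[k]
      if (sqrt((x[b] - x[i])^2 + (y[b] - y[i])^2) > r) {
        j <- min(a, b); forward <- b > a
        f <- function(s) dist_at(j, s, i) - r
        s_lo <- if (forward) 0 else 1
        root <- uniroot(f, sort(c(s_lo, if (forward) 1 else 0)),
                        tol = 1e-13)$root
        return(t_h[j] + root * (t_h[j + 1] - t_h[j]))
      }
    }
    NA_real_
  }
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tf <- if (i < n) cross_time(i, i:n) else NA
    tb <- if (i > 1) cross_time(i, i:1) else NA
    out[i] <- tf - tb
  }
  out
}

# brute-force Horn slope at one interior cell (independent of grid_slope's
# vectorised shifts)
oracle_horn_cell <- function(z, i, j, dx_m, dy_m) {
  a <- z[i - 1, j - 1]; b <- z[i - 1, j]; cc <- z[i - 1, j + 1]
  d <- z[i, j - 1]; f <- z[i, j + 1]
  g <- z[i + 1, j - 1]; h <- z[i + 1, j]; ii <- z[i + 1, j + 1]
  dzdx <- ((cc + 2 * f + ii) - (a + 2 * d + g)) / (8 * dx_m)
  dzdy <- ((a + 2 * b + cc) - (g + 2 * h + ii)) / (8 * dy_m)
  atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
}

# error-free simulation config for movement-method tests
clean_sim_config <- function(seed, n_trips = 4, ...) {
  sim_config(seed = seed, n_trips = n_trips,
             class_error_scale = stats::setNames(rep(0, 7),
                                                 c("3", "2", "1", "0",
                                                   "A", "B", "Z")),
             ...)
}

# simulated planar Brownian motion track, dt = 1 h
bm_track <- function(n, sigma2, seed) {
  set.seed(seed)
  make_path(cumsum(c(0, rnorm(n - 1, 0, sqrt(sigma2)))),
            cumsum(c(0, rnorm(n - 1, 0, sqrt(sigma2)))),
            0:(n - 1))
}

# analytic synthetic CTD cast: uniform mixed layer to mld, then a linear
# sigma-theta increase of `grad` per metre (via temperature)
step_levels <- function(mld, bottom, sigma_jump = 0.5) {
  z <- seq_len(bottom)
  temp <- ifelse(z <= mld, 18, 13)
  sal <- rep(35.5, bottom)
  data.frame(depth_m = z, temp_c = temp, sal_psu = sal,
             sigma_theta = sigma_theta(sal, temp))
}
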