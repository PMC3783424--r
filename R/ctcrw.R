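# Track interpolation to a regular time grid. Two modes: a continuous-time
# correlated random walk (CTCRW: integrated Ornstein-Uhlenbeck velocity)
# fitted by maximum likelihood and smoothed with a Kalman filter/smoother,
# and a piecewise-linear fallback. Both run on planar km coordinates from a
# local azimuthal-equidistant projection and emit the same record shape.

# state transition and innovation covariance of the CTCRW over dt hours
.ctcrw_TQ <- function(beta, sigma2, dt) {
  e1 <- exp(-beta * dt); e2 <- exp(-2 * beta * dt)
  Tm <- matrix(c(1, 0, (1 - e1) / beta, e1), 2, 2)
  qxx <- sigma2 / beta^2 *
    (dt - 2 * (1 - e1) / beta + (1 - e2) / (2 * beta))
  qxv <- sigma2 / (2 * beta^2) * (1 - 2 * e1 + e2)
  qvv <- sigma2 / (2 * beta) * (1 - e2)
  Qm <- matrix(c(qxx, qxv, qxv, qvv), 2, 2)
  list(T = Tm, Q = Qm)
}

# Kalman filter (+ optional RTS smoother) for one axis.
# times: hours (sorted); y: observations (NA = prediction-only epoch);
# tau2: per-epoch observation variance. Returns loglik and smoothed means.
.ctcrw_kalman <- function(times, y, tau2, beta, sigma2, smooth = FALSE) {
  n <- length(times)
  H <- matrix(c(1, 0), 1, 2)
  a <- c(y[which(!is.na(y))[1]], 0)
  P <- diag(c(100^2, 25))
  ll <- 0
  if (smooth) {
    at_f <- matrix(0, n, 2); Pt_f <- array(0, c(n, 2, 2))
    at_p <- matrix(0, n, 2); Pt_p <- array(0, c(n, 2, 2))
    Tt <- array(0, c(n, 2, 2))
  }
  for (i in seq_len(n)) {
    if (i > 1) {
      dt <- times[i] - times[i - 1]
      if (dt > 0) {
        tq <- .ctcrw_TQ(beta, sigma2, dt)
        a <- as.vector(tq$T %*% a)
        P <- tq$T %*% P %*% t(tq$T) + tq$Q
        if (smooth) Tt[i, , ] <- tq$T
      } else if (smooth) Tt[i, , ] <- diag(2)
    }
    if (smooth) { at_p[i, ] <- a; Pt_p[i, , ] <- P }
    if (!is.na(y[i])) {
      f <- P[1, 1] + tau2[i]
      v <- y[i] - a[1]
      ll <- ll - 0.5 * (log(2 * pi * f) + v^2 / f)
      K <- P[, 1] / f
      a <- a + K * v
      P <- P - outer(K, K) * f
    }
    if (smooth) { at_f[i, ] <- a; Pt_f[i, , ] <- P }
  }
  out <- list(loglik = ll)
  if (smooth) {
    sm <- at_f
    Ps <- Pt_f[n, , ]
    for (i in (n - 1):1) {
      Pp <- Pt_p[i + 1, , ]
      J <- Pt_f[i, , ] %*% t(Tt[i + 1, , ]) %*% solve(Pp + diag(1e-10, 2))
      sm[i, ] <- at_f[i, ] + as.vector(J %*% (sm[i + 1, ] - at_p[i + 1, ]))
      Ps <- Pt_f[i, , ] + J %*% (Ps - Pp) %*% t(J)
    }
    out$smoothed <- sm
  }
  out
}

#' Interpolate a filtered track to a regular time grid
#'
#' Mode `"ctcrw"` fits a continuous-time correlated random walk (position +
#' Ornstein-Uhlenbeck velocity) by maximum likelihood over (beta, sigma)
#' with ARGOS-class-dependent observation noise, then predicts positions at
#' the exact `dt`-hour grid spanning the fixes with a Kalman
#' filter/smoother. Mode `"linear"` is a great-circle piecewise-linear
#' fallback (also used automatically if the CTCRW optimiser fails).
#'
#' @param fixes data.frame with `t` (POSIXct), `lon`, `lat` and (for ctcrw)
#'   `lc`; time-ordered, speed-filtered.
#' @param dt grid spacing, h.
#' @param mode `"ctcrw"` or `"linear"`.
#' @param class_error_scale named km observation-noise scale per ARGOS
#'   class.
#' @return data.frame with `t` (exactly t0, t0+dt, ...), `lon`, `lat`, and
#'   the planar `x`, `y` (km) in the projection used; attribute `mode`
#'   records the mode actually applied, `origin` the projection origin.
#' @export
interpolate_track <- function(fixes, dt = 2, mode = c("ctcrw", "linear"),
                              class_error_scale = argos_error_scale_km) {
  mode <- match.arg(mode)
  if (nrow(fixes) < 2) stop("need at least 2 fixes", call. = FALSE)
  origin <- c(stats::median(fixes$lon), stats::median(fixes$lat))
  xy <- project_local(fixes$lon, fixes$lat, origin)
  t_h <- as.numeric(fixes$t - fixes$t[1], units = "hours")
  grid_h <- seq(0, max(t_h), by = dt)
  applied <- mode
  gx <- gy <- NULL
  if (mode == "ctcrw") {
    tau <- if ("lc" %in% names(fixes))
      pmax(class_error_scale[as.character(fixes$lc)], 0.05)
    else rep(0.5, nrow(fixes))
    res <- tryCatch(
      .fit_ctcrw(t_h, xy$x, xy$y, tau^2, grid_h),
      error = function(e) NULL)
    if (is.null(res) || anyNA(res$x) || anyNA(res$y)) {
      applied <- "linear"
    } else { gx <- res$x; gy <- res$y }
  }
  if (is.null(gx)) {
    gx <- approx(t_h, xy$x, xout = grid_h, rule = 2)$y
    gy <- approx(t_h, xy$y, xout = grid_h, rule = 2)$y
  }
  if (any(!is.finite(gx)) || any(!is.finite(gy)))
    stop("non-finite interpolated positions (degenerate segment)",
         call. = FALSE)
  ll <- unproject_local(gx, gy, origin)
  out <- data.frame(t = fixes$t[1] + grid_h * 3600, lon = ll$lon,
                    lat = ll$lat, x = gx, y = gy)
  attr(out, "mode") <- applied
  attr(out, "origin") <- origin
  out
}

.fit_ctcrw <- function(t_h, x, y, tau2, grid_h) {
  nll <- function(p) {
    beta <- exp(p[1]); sigma2 <- exp(p[2])
    if (!is.finite(beta) || beta < 1e-6 || beta > 1e3) return(1e10)
    l <- .ctcrw_kalman(t_h, x, tau2, beta, sigma2)$loglik +
      .ctcrw_kalman(t_h, y, tau2, beta, sigma2)$loglik
    if (!is.finite(l)) 1e10 else -l
  }
  sp <- sqrt(diff(x)^2 + diff(y)^2) / pmax(diff(t_h), 1e-6)
  start <- c(log(0.5), log(max(stats::var(sp), 0.1)))
  opt <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 300))
  beta <- exp(opt$par[1]); sigma2 <- exp(opt$par[2])
  # merge observation epochs with prediction epochs
  all_t <- sort(unique(c(t_h, grid_h)))
  yi <- match(all_t, t_h)
  yx <- ifelse(is.na(yi), NA, x[yi])
  yy <- ifelse(is.na(yi), NA, y[yi])
  tt2 <- ifelse(is.na(yi), 1, tau2[yi])
  smx <- .ctcrw_kalman(all_t, yx, tt2, beta, sigma2, smooth = TRUE)$smoothed
  smy <- .ctcrw_kalman(all_t, yy, tt2, beta, sigma2, smooth = TRUE)$smoothed
  gi <- match(grid_h, all_t)
  list(x = smx[gi, 1], y = smy[gi, 1], beta = beta, sigma2 = sigma2)
}
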