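# Seasonal ARIMA fitting with Box-Jenkins selection and Ljung-Box
# validation for whisker isotope series. Estimation delegates to
# stats::arima with method "CSS-ML" -- conditional sum of squares for
# starting values followed by exact Gaussian maximum likelihood through the
# Kalman state-space recursion -- which is precisely the estimator this
# module requires. Selection (BIC over the order space) and the portmanteau
# validation are implemented here.

#' Fit one SARIMA(p,d,q)(P,D,Q)_s model
#'
#' Regular differencing d times and seasonal differencing D times, then
#' multiplicative seasonal ARMA by CSS starting values + exact ML
#' (`stats::arima`, method "CSS-ML"). BIC uses the effective length of the
#' differenced series: `BIC = -2 loglik + k ln(n - d - D s)` with k = number
#' of estimated parameters including the innovation variance. A Ljung-Box
#' portmanteau test of the residuals (df reduced by the number of fitted
#' ARMA parameters) is attached.
#'
#' @param series numeric time series (oldest first).
#' @param order c(p, d, q).
#' @param seasonal c(P, D, Q).
#' @param s seasonal period (months); required >= 2 when any seasonal order
#'   is positive.
#' @param lb_lags lags for the Ljung-Box test (default min(10, n/5)).
#' @return list of class `sarima_fit`: `order`, `seasonal`, `s`, `coef`,
#'   `sigma2`, `loglik`, `bic`, `ljung_box` (Q, df, p), `residuals`,
#'   `n_eff`.
#' @export
sarima_fit <- function(series, order = c(1, 0, 0), seasonal = c(0, 0, 0),
                       s = 12, lb_lags = NULL) {
  n <- length(series)
  k_arma <- order[1] + order[3] + seasonal[1] + seasonal[3]
  n_eff <- n - order[2] - seasonal[2] * s
  if (n_eff < 10 + k_arma)
    stop("series too short for the requested orders", call. = FALSE)
  if (any(seasonal > 0) && s < 2)
    stop("seasonal orders need s >= 2", call. = FALSE)
  fit <- stats::arima(series, order = order,
                      seasonal = list(order = seasonal, period = s),
                      method = "CSS-ML")
  # enforce stationarity (AR polys) and invertibility (MA polys)
  check_roots <- function(coefs, prefix, sign) {
    cf <- coefs[grep(paste0("^", prefix, "[0-9]+$"), names(coefs))]
    if (length(cf) && any(abs(polyroot(c(1, sign * cf))) < 1 + 1e-8))
      stop("non-stationary/non-invertible optimum", call. = FALSE)
  }
  check_roots(fit$coef, "ar", -1); check_roots(fit$coef, "sar", -1)
  check_roots(fit$coef, "ma", 1); check_roots(fit$coef, "sma", 1)
  k <- length(fit$coef) + 1   # + innovation variance
  bic <- -2 * fit$loglik + k * log(n_eff)
  res <- as.numeric(stats::residuals(fit))
  if (is.null(lb_lags)) lb_lags <- min(10, floor(n / 5))
  lb <- if (lb_lags > k_arma)
    ljung_box(res, lags = lb_lags, fitted_params = k_arma)
  else list(Q = NA_real_, df = NA_real_, p = NA_real_)
  structure(list(order = order, seasonal = seasonal, s = s,
                 coef = fit$coef, sigma2 = fit$sigma2,
                 loglik = as.numeric(fit$loglik), bic = bic,
                 ljung_box = lb, residuals = res, n_eff = n_eff),
            class = "sarima_fit")
}

#' @export
print.sarima_fit <- function(x, ...) {
  cat(sprintf("SARIMA(%d,%d,%d)(%d,%d,%d)_%d  loglik %.3f  BIC %.3f\n",
              x$order[1], x$order[2], x$order[3],
              x$seasonal[1], x$seasonal[2], x$seasonal[3], x$s,
              x$loglik, x$bic))
  if (length(x$coef)) print(round(x$coef, 4))
  cat(sprintf("Ljung-Box Q = %.3f (df %s, p = %.3g)\n", x$ljung_box$Q,
              x$ljung_box$df, x$ljung_box$p))
  invisible(x)
}

#' Box-Jenkins SARIMA selection by BIC
#'
#' Fits every model in the order space (skipping candidates that fail to
#' converge or are non-stationary), selects the minimum-BIC fit, and
#' attaches its Ljung-Box validation. Aseasonal candidates
#' (P = D = Q = 0) are fitted once, not once per period.
#'
#' @param series numeric series, length >= 18 (about a year and a half of
#'   monthly whisker segments).
#' @param p,d,q vectors of regular orders to sweep.
#' @param P,D,Q vectors of seasonal orders to sweep.
#' @param seasons seasonal periods to sweep.
#' @return list with `best` (a `sarima_fit`) and `table` (one row per
#'   converged candidate, sorted by BIC ascending).
#' @export
sarima_select <- function(series, p = 0:2, d = 0:1, q = 0:2,
                          P = 0:1, D = 0:1, Q = 0:1,
                          seasons = c(3, 4, 6, 12)) {
  if (length(series) < 18)
    stop("series shorter than 18 observations", call. = FALSE)
  grid <- expand.grid(p = p, d = d, q = q, P = P, D = D, Q = Q,
                      s = seasons)
  aseasonal <- grid$P == 0 & grid$D == 0 & grid$Q == 0
  grid <- grid[!aseasonal | grid$s == seasons[1], ]
  fits <- list(); rows <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    fit <- tryCatch(
      suppressWarnings(sarima_fit(series, order = c(g$p, g$d, g$q),
                                  seasonal = c(g$P, g$D, g$Q), s = g$s)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$bic)) next
    fits[[length(fits) + 1]] <- fit
    rows[[length(rows) + 1]] <- data.frame(
      p = g$p, d = g$d, q = g$q, P = g$P, D = g$D, Q = g$Q,
      s = if (g$P == 0 && g$D == 0 && g$Q == 0) 0L else g$s,
      k = length(fit$coef) + 1, loglik = fit$loglik, bic = fit$bic,
      ljung_box_q = fit$ljung_box$Q, ljung_box_p = fit$ljung_box$p)
  }
  if (!length(fits)) stop("no SARIMA candidate converged", call. = FALSE)
  tab <- do.call(rbind, rows)
  o <- order(tab$bic)
  tab <- tab[o, ]; rownames(tab) <- NULL
  list(best = fits[[o[1]]], table = tab)
}

#' Ljung-Box portmanteau test
#'
#' `Q = n (n + 2) sum_{j=1..lags} r_j^2 / (n - j)`; p-value from chi-square
#' with `lags - fitted_params` degrees of freedom.
#'
#' @param residuals model residuals.
#' @param lags number of autocorrelation lags.
#' @param fitted_params number of ARMA parameters estimated (reduces df).
#' @return list: `Q`, `df`, `p`.
#' @export
ljung_box <- function(residuals, lags = NULL, fitted_params = 0) {
  n <- length(residuals)
  if (is.null(lags)) lags <- min(10, floor(n / 5))
  if (lags <= fitted_params)
    stop("lags must exceed the number of fitted parameters", call. = FALSE)
  if (lags >= n) stop("lags must be < n", call. = FALSE)
  r <- stats::acf(residuals, lag.max = lags, plot = FALSE,
                  demean = TRUE)$acf[-1]
  Q <- n * (n + 2) * sum(r^2 / (n - seq_len(lags)))
  df <- lags - fitted_params
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE))
}
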