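# Cox proportional-hazards models of habitat residency. The hazard is the
# risk of leaving the FPT circle: h(t) = exp(beta' X) h0(t). All FPT spells
# are treated as observed events (the animal always eventually leaves the
# circle; spells that never close are missing upstream and excluded).
# Fitted from first principles: Newton-Raphson on the Breslow partial
# likelihood with a cluster-robust (sandwich) variance grouped by trip.

# Breslow partial likelihood, gradient and Hessian.
# times ascending; X n x p; beta p-vector. Returns list(ll, grad, hess,
# risk-set aggregates used by the residuals).
.cox_pl <- function(times, X, beta) {
  n <- length(times); p <- ncol(X)
  o <- order(times)
  Xo <- X[o, , drop = FALSE]; to <- times[o]
  eta <- as.vector(Xo %*% beta)
  w <- exp(eta)
  # reverse cumulative sums: S0_i = sum_{j >= i} w_j (risk set of t_(i))
  S0 <- rev(cumsum(rev(w)))
  S1 <- apply(Xo * w, 2, function(col) rev(cumsum(rev(col))))
  S1 <- matrix(S1, n, p)
  # ties (Breslow): risk-set sums evaluated at the first index of each tie
  first <- match(to, to)            # index of first occurrence of each time
  S0t <- S0[first]
  S1t <- S1[first, , drop = FALSE]
  ll <- sum(eta - log(S0t))
  xbar <- S1t / S0t
  grad <- colSums(Xo - xbar)
  hess <- matrix(0, p, p)
  # S2/S0 - xbar xbar' accumulated over events
  for (k in seq_len(p)) for (l in k:p) {
    S2kl <- rev(cumsum(rev(w * Xo[, k] * Xo[, l])))[first]
    v <- sum(S2kl / S0t - xbar[, k] * xbar[, l])
    hess[k, l] <- hess[l, k] <- -v
  }
  list(ll = ll, grad = grad, hess = hess, order = o, w = w, S0t = S0t,
       xbar = xbar, Xo = Xo, to = to, first = first)
}

#' Fit a Cox proportional-hazards model on FPT spells
#'
#' All spells are events (no censoring). Newton-Raphson maximization of the
#' Breslow partial likelihood; variance is the cluster-robust sandwich
#' grouped by `cluster` (typically the foraging trip), so per-trip
#' dependence of spells is reflected in the standard errors. An empty
#' covariate set fits the null model.
#'
#' @param times positive event (FPT) times, h.
#' @param covariates data.frame / matrix of numeric covariates (0 columns =
#'   null model).
#' @param cluster grouping vector for the robust variance (default: each
#'   observation its own cluster).
#' @param max_iter,tol Newton-Raphson controls.
#' @return list of class `cph_fit`: `coef`, `hr` (= exp(coef)), `se`
#'   (robust), `wald_p`, `loglik`, `loglik_null`, `n`, `n_events`, `aicc`,
#'   `terms`.
#' @export
cox_fit <- function(times, covariates, cluster = NULL,
                    max_iter = 50, tol = 1e-9) {
  if (any(times <= 0)) stop("all times must be > 0", call. = FALSE)
  X <- as.matrix(covariates)
  n <- length(times)
  if (is.null(cluster)) cluster <- seq_len(n)
  keep <- stats::complete.cases(X) & is.finite(times)
  X <- X[keep, , drop = FALSE]; times <- times[keep]
  cluster <- cluster[keep]; n <- length(times)
  ll_null <- .cox_pl(times, matrix(0, n, 1), 0)$ll
  # zero-variance covariates carry no partial-likelihood information:
  # their coefficient is identically 0
  if (ncol(X) > 0) {
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    const <- apply(X, 2, function(col) stats::var(col) == 0)
    const_terms <- colnames(X)[const]
    X <- X[, !const, drop = FALSE]
  } else const_terms <- character(0)
  p <- ncol(X)
  pad_const <- function(fit) {
    if (!length(const_terms)) return(fit)
    z <- stats::setNames(rep(0, length(const_terms)), const_terms)
    fit$coef <- c(fit$coef, z)
    fit$hr <- c(fit$hr, exp(z))
    fit$se <- c(fit$se, stats::setNames(rep(Inf, length(const_terms)),
                                        const_terms))
    fit$wald_p <- c(fit$wald_p, stats::setNames(rep(1, length(const_terms)),
                                                const_terms))
    fit$terms <- c(fit$terms, const_terms)
    fit
  }
  if (p == 0) {
    fit <- list(coef = numeric(0), hr = numeric(0), se = numeric(0),
                wald_p = numeric(0), loglik = ll_null, loglik_null = ll_null,
                n = n, n_events = n, aicc = aicc(ll_null, 0, n),
                terms = character(0))
    class(fit) <- "cph_fit"
    return(pad_const(fit))
  }
  beta <- rep(0, p)
  pl <- .cox_pl(times, X, beta)
  for (it in seq_len(max_iter)) {
    step <- tryCatch(solve(pl$hess, pl$grad),
                     error = function(e) stop("singular information matrix",
                                              call. = FALSE))
    new_beta <- beta - step
    new_pl <- .cox_pl(times, X, new_beta)
    halv <- 0
    while (new_pl$ll < pl$ll && halv < 20) {  # step halving
      new_beta <- (beta + new_beta) / 2
      new_pl <- .cox_pl(times, X, new_beta)
      halv <- halv + 1
    }
    beta <- new_beta; pl <- new_pl
    if (any(abs(beta) > 20))
      stop("divergent coefficients (complete separation?)", call. = FALSE)
    if (sqrt(sum(pl$grad^2)) < tol) break
    if (it == max_iter)
      stop(sprintf("no convergence in %d iterations (|grad| = %.3g)",
                   max_iter, sqrt(sum(pl$grad^2))), call. = FALSE)
  }
  info <- -pl$hess
  # score residuals per subject (Breslow, all events):
  # U_j = (x_j - xbar(t_j)) - exp(eta_j) [x_j A(t_j) - B(t_j)]
  # A = cumsum over event times of d_k / S0_k, B likewise of d_k xbar_k/S0_k
  ut <- unique(pl$to)
  d_k <- as.vector(table(factor(pl$to, levels = ut)))
  ki <- match(pl$to, ut)            # event-time group of each subject
  S0u <- pl$S0t[match(ut, pl$to)]
  xbaru <- pl$xbar[match(ut, pl$to), , drop = FALSE]
  A <- cumsum(d_k / S0u)
  B <- apply(xbaru * (d_k / S0u), 2, cumsum)
  B <- matrix(B, length(ut), p)
  U <- (pl$Xo - pl$xbar) -
    pl$w * (pl$Xo * A[ki] - B[ki, , drop = FALSE])
  cl_o <- cluster[pl$order]
  Ug <- rowsum(U, group = cl_o)
  Vi <- solve(info)
  V <- Vi %*% crossprod(as.matrix(Ug)) %*% Vi
  se <- sqrt(diag(V))
  z <- beta / se
  terms <- colnames(X)
  if (is.null(terms)) terms <- paste0("x", seq_len(p))
  fit <- list(coef = stats::setNames(beta, terms),
              hr = stats::setNames(exp(beta), terms),
              se = stats::setNames(se, terms),
              wald_p = stats::setNames(2 * stats::pnorm(-abs(z)), terms),
              loglik = pl$ll, loglik_null = ll_null,
              n = n, n_events = n, aicc = aicc(pl$ll, p, n),
              terms = terms)
  class(fit) <- "cph_fit"
  pad_const(fit)
}

#' @export
print.cph_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit: %d events, loglik %.3f, AICc %.3f\n",
              x$n_events, x$loglik, x$aicc))
  if (length(x$coef)) {
    print(data.frame(coef = x$coef, hr = x$hr, robust_se = x$se,
                     p = x$wald_p))
  } else cat("  (null model)\n")
  invisible(x)
}

#' AICc: Akaike information criterion corrected for sample size
#'
#' `AICc = -2 loglik + 2k + 2k(k+1)/(n - k - 1)`. For Cox models `n` is the
#' number of events.
#'
#' @param loglik log-likelihood at the optimum.
#' @param k number of estimated parameters.
#' @param n effective sample size (> k + 1).
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("n must exceed k + 1", call. = FALSE)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Screen covariates by pairwise Pearson correlation
#'
#' Returns every subset of covariates containing no pair with
#' `|r| > r_max` (complete-case Pearson correlation). Zero-variance
#' covariates are excluded with a warning. The empty subset (null model) is
#' not included; model-selection helpers add it themselves.
#'
#' @param covariates data.frame of numeric covariates.
#' @param r_max correlation threshold.
#' @return list with `subsets` (list of character vectors) and `cor`
#'   (correlation matrix of the retained covariates).
#' @export
pearson_screen <- function(covariates, r_max = 0.7) {
  X <- as.data.frame(covariates)
  if (ncol(X) < 2) stop("need at least 2 covariates", call. = FALSE)
  v <- vapply(X, function(col) stats::var(col, na.rm = TRUE), numeric(1))
  if (any(v == 0 | !is.finite(v))) {
    warning("zero-variance covariate(s) excluded: ",
            paste(names(X)[v == 0 | !is.finite(v)], collapse = ", "),
            call. = FALSE)
    X <- X[, v > 0 & is.finite(v), drop = FALSE]
  }
  cm <- stats::cor(X, use = "pairwise.complete.obs")
  nm <- names(X)
  ok_pair <- abs(cm) <= r_max
  subsets <- list()
  for (size in seq_along(nm)) {
    for (comb in utils::combn(nm, size, simplify = FALSE)) {
      idx <- match(comb, nm)
      if (all(ok_pair[idx, idx][upper.tri(diag(length(idx)))]) ||
          length(idx) == 1)
        subsets[[length(subsets) + 1]] <- comb
    }
  }
  list(subsets = subsets, cor = cm)
}

#' Fit and rank Cox models over admissible covariate subsets
#'
#' Candidates are the null model, the main-effects model of every
#' admissible subset from [pearson_screen()], and, for subsets of two or
#' more covariates, each single pairwise interaction added to its subset's
#' main effects. Models are ranked by AICc (n = events); candidates whose
#' terms all have Wald p > 0.05 are flagged `no_sig_term`. Candidates that
#' fail to fit are skipped with a message.
#'
#' @param times positive FPT spell durations, h.
#' @param covariates data.frame of numeric covariates.
#' @param cluster grouping for the robust variance (e.g. trip id).
#' @param r_max correlation threshold for [pearson_screen()].
#' @return list with `best` (a `cph_fit`), `table` (one row per candidate:
#'   terms, k, loglik, aicc, delta_aicc, no_sig_term), `fits` (all fits).
#' @export
cox_select <- function(times, covariates, cluster = NULL, r_max = 0.7) {
  scr <- pearson_screen(covariates, r_max)
  cands <- list(character(0))
  for (s in scr$subsets) {
    cands[[length(cands) + 1]] <- s
    if (length(s) >= 2) {
      for (pr in utils::combn(s, 2, simplify = FALSE))
        cands[[length(cands) + 1]] <- c(s, paste(pr, collapse = ":"))
    }
  }
  fits <- list(); rows <- list()
  for (ci in seq_along(cands)) {
    terms <- cands[[ci]]
    Xc <- matrix(numeric(0), length(times), 0)
    if (length(terms)) {
      cols <- lapply(terms, function(tm) {
        if (grepl(":", tm, fixed = TRUE)) {
          pr <- strsplit(tm, ":", fixed = TRUE)[[1]]
          covariates[[pr[1]]] * covariates[[pr[2]]]
        } else covariates[[tm]]
      })
      Xc <- do.call(cbind, cols)
      colnames(Xc) <- terms
    }
    fit <- tryCatch(cox_fit(times, Xc, cluster),
                    error = function(e) {
                      message("candidate {", paste(terms, collapse = ", "),
                              "} skipped: ", conditionMessage(e))
                      NULL
                    })
    if (is.null(fit)) next
    fits[[length(fits) + 1]] <- fit
    rows[[length(rows) + 1]] <- data.frame(
      terms = if (length(terms)) paste(terms, collapse = " + ") else "(null)",
      k = length(fit$coef), loglik = fit$loglik, aicc = fit$aicc,
      no_sig_term = length(fit$coef) > 0 && all(fit$wald_p > 0.05))
  }
  tab <- do.call(rbind, rows)
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  o <- order(tab$aicc)
  tab <- tab[o, ]; fits <- fits[o]
  rownames(tab) <- NULL
  list(best = fits[[1]], table = tab, fits = fits)
}
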