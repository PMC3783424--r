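# Classic-test helpers behind the module surface: OLS regression with an
# F-test of the slope (the benthic-diver screen), Kruskal-Wallis and
# Bartlett comparisons. All delegate to base R's implementations.

#' Simple linear regression with F-test of the slope
#'
#' Used for the benthic-diving screen (maximum dive depth regressed on mean
#' water depth; `benthic = TRUE` when R^2 exceeds `benthic_r2`) and the
#' MLD-vs-depth checks.
#'
#' @param y,x response and predictor.
#' @param benthic_r2 R^2 threshold for the benthic flag.
#' @return list: `slope`, `intercept`, `F`, `r_squared`, `p`, `benthic`.
#' @export
ols_regress <- function(y, x, benthic_r2 = 0.75) {
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  if (stats::var(x) == 0) stop("zero-variance predictor", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  Fv <- unname(sm$fstatistic[1])
  pv <- stats::pf(Fv, sm$fstatistic[2], sm$fstatistic[3], lower.tail = FALSE)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       F = Fv, r_squared = sm$r.squared, p = pv,
       benthic = sm$r.squared > benthic_r2)
}

#' Kruskal-Wallis rank test across groups
#'
#' Rank-based H with tie correction, p from chi-square with k - 1 df.
#' A degenerate input where every value is identical returns H = 0, p = 1.
#'
#' @param groups list of numeric vectors.
#' @return list: `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 1))
    stop("every group needs >= 1 value", call. = FALSE)
  all_v <- unlist(groups)
  if (length(unique(all_v)) == 1)
    return(list(H = 0, df = length(groups) - 1, p = 1))
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Bartlett test of homogeneity of variances
#'
#' @param groups list of numeric vectors, each with n >= 2 and positive
#'   variance (the statistic is undefined otherwise).
#' @return list: `K`, `df`, `p`.
#' @export
bartlett_test <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2)) stop("every group needs n >= 2", call. = FALSE)
  vs <- vapply(groups, stats::var, numeric(1))
  if (any(vs == 0)) stop("zero-variance group: statistic undefined",
                         call. = FALSE)
  bt <- stats::bartlett.test(groups)
  list(K = unname(bt$statistic), df = unname(bt$parameter), p = bt$p.value)
}
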