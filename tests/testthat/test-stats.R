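# direct Breslow partial-likelihood recomputation for the grid oracle
breslow_pl <- function(times, x, beta) {
  o <- order(times)
  x <- x[o]; times <- times[o]
  eta <- beta * x
  sum(vapply(seq_along(times), function(i) {
    risk <- which(times >= times[i])
    eta[i] - log(sum(exp(eta[risk])))
  }, numeric(1)))
}

test_that("two-group exponential spells with rate ratio 2 recover beta = ln 2", {
  set.seed(11)
  n <- 2000
  x <- rep(c(0, 1), each = n / 2)
  times <- rexp(n, rate = exp(log(2) * x))
  fit <- cox_fit(times, data.frame(group = x))
  expect_gte(unname(fit$coef["group"]), log(2) - 0.1)
  expect_lte(unname(fit$coef["group"]), log(2) + 0.1)
  expect_equal(unname(fit$hr["group"]), exp(unname(fit$coef["group"])))
  expect_lt(unname(fit$wald_p["group"]), 1e-6)
})

test_that("a five-spell fit matches a 2001-point grid search of the partial likelihood", {
  times <- c(1.3, 2.7, 0.6, 4.1, 3.3)
  x <- c(1, 0, 1, 0, 1)
  fit <- cox_fit(times, data.frame(x = x))
  grid <- seq(-5, 5, length.out = 2001)
  pl <- vapply(grid, breslow_pl, numeric(1), times = times, x = x)
  expect_lt(abs(unname(fit$coef["x"]) - grid[which.max(pl)]), 1e-3 + 0.005)
  # and the fitted likelihood is at least the grid's best
  expect_gte(fit$loglik, max(pl) - 1e-9)
})

test_that("a constant covariate gets coefficient 0 and the null likelihood", {
  set.seed(2)
  times <- rexp(30)
  fit <- cox_fit(times, data.frame(c0 = rep(2, 30)))
  expect_equal(unname(fit$coef["c0"]), 0)
  expect_equal(fit$loglik, fit$loglik_null)
  expect_equal(unname(fit$wald_p["c0"]), 1)
})

test_that("the score vanishes at the optimum and beats beta = 0", {
  set.seed(19)
  n <- 200
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  times <- rexp(n, rate = exp(0.5 * X$a))
  fit <- cox_fit(times, X)
  pl_hat <- aslforage:::.cox_pl(times, as.matrix(X), fit$coef[c("a", "b")])
  expect_lt(sqrt(sum(pl_hat$grad^2)), 1e-6)
  expect_gte(fit$loglik, aslforage:::.cox_pl(times, as.matrix(X),
                                             c(0, 0))$ll)
})

test_that("the hand-rolled Cox fit agrees with survival::coxph", {
  skip_if_not_installed("survival")
  set.seed(23)
  n <- 300
  X <- data.frame(depth = rnorm(n, 60, 15), slope = rnorm(n, 2, 1))
  cl <- rep(1:30, each = 10)
  times <- rexp(n, rate = exp(0.01 * X$depth - 0.2 * X$slope))
  fit <- cox_fit(times, X, cluster = cl)
  ref <- survival::coxph(survival::Surv(times, rep(1, n)) ~ depth + slope +
                           survival::cluster(cl),
                         data = X, ties = "breslow")
  expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(ref$var))), tolerance = 1e-6)
  expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-8)
})

test_that("separated data raise a divergence error and bad times are rejected", {
  times <- c(1, 2, 3, 10, 11, 12)
  x <- c(1, 1, 1, 0, 0, 0)  # perfectly orders the spells
  expect_error(cox_fit(times, data.frame(x = x)), "divergent")
  expect_error(cox_fit(c(-1, 2), data.frame(x = c(0, 1))), "> 0")
})

test_that("AICc follows its formula and exceeds AIC for k > 0", {
  expect_equal(aicc(-100, 0, 50), 200)
  expect_equal(aicc(-100, 2, 50), 204.2553191, tolerance = 1e-6)
  expect_gt(aicc(-100, 2, 50), -2 * (-100) + 2 * 2)
  expect_error(aicc(-100, 5, 6), "exceed")
})

test_that("the correlation screen never pairs collinear covariates", {
  set.seed(5)
  a <- rnorm(100)
  cov <- data.frame(a = a, b = a + rnorm(100, 0, 1e-6), c = rnorm(100))
  scr <- pearson_screen(cov, r_max = 0.7)
  expect_equal(scr$cor["a", "b"], 1, tolerance = 1e-6)
  both <- vapply(scr$subsets, function(s) all(c("a", "b") %in% s),
                 logical(1))
  expect_false(any(both))
  # independent covariates: the full set is admissible
  set.seed(6)
  ind <- as.data.frame(matrix(rnorm(500 * 3), 500, 3))
  names(ind) <- c("u", "v", "w")
  scr2 <- pearson_screen(ind, r_max = 0.7)
  expect_true(any(vapply(scr2$subsets, function(s) length(s) == 3,
                         logical(1))))
  cov$z <- 1
  expect_warning(pearson_screen(cov, 0.7), "zero-variance")
})

test_that("model selection puts the active covariate in the top model", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 300
    X <- data.frame(active = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
    times <- rexp(n, rate = exp(0.8 * X$active))
    sel <- cox_select(times, X, cluster = seq_len(n))
    expect_true("active" %in% sel$best$terms)
  }
})

test_that("with pure-noise covariates the null model stays competitive", {
  hits <- 0
  for (seed in 1:5) {
    set.seed(100 + seed)
    n <- 200
    X <- data.frame(n1 = rnorm(n), n2 = rnorm(n))
    times <- rexp(n)
    sel <- cox_select(times, X)
    d_null <- sel$table$delta_aicc[sel$table$terms == "(null)"]
    if (d_null <= 2) hits <- hits + 1
  }
  expect_gte(hits, 3)
})

test_that("selection output is ordered by AICc and reproducible under row shuffling", {
  set.seed(42)
  n <- 150
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  times <- rexp(n, rate = exp(0.5 * X$a))
  sel <- cox_select(times, X)
  expect_true(!is.unsorted(sel$table$aicc))
  expect_equal(sel$table$delta_aicc[1], 0)
  perm <- sample(n)
  sel2 <- cox_select(times[perm], X[perm, ], cluster = NULL)
  expect_equal(sel$table$aicc, sel2$table$aicc, tolerance = 1e-8)
})

test_that("OLS recovers exact fits and flags benthic-style relationships", {
  x <- 1:20
  r <- ols_regress(2 * x, x)
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_true(r$benthic)
  set.seed(4)
  r2 <- ols_regress(rnorm(1000), rnorm(1000))
  expect_lt(r2$r_squared, 0.01)
  expect_false(r2$benthic)
  # F and p match a textbook recomputation
  set.seed(13)
  xx <- rnorm(40); yy <- 1 + 0.5 * xx + rnorm(40)
  r3 <- ols_regress(yy, xx)
  fit <- lm(yy ~ xx)
  ssr <- sum((fitted(fit) - mean(yy))^2); sse <- sum(resid(fit)^2)
  Fv <- ssr / (sse / 38)
  expect_equal(r3$F, Fv, tolerance = 1e-9)
  expect_equal(r3$p, pf(Fv, 1, 38, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(ols_regress(1:5, rep(1, 5)), "zero-variance")
})

test_that("Kruskal-Wallis matches the hand-ranked example and degenerate input", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$H, 3.857143, tolerance = 1e-5)
  expect_equal(kw$df, 1)
  same <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)
  # identical distributions: no signal
  set.seed(9)
  v <- rnorm(100)
  kw2 <- kruskal_wallis(split(v, rep(1:2, 50)))
  expect_gt(kw2$p, 0.05)
})

test_that("Kruskal-Wallis holds its nominal type-I error on null simulations", {
  set.seed(77)
  rej <- mean(replicate(2000, {
    kruskal_wallis(list(rnorm(20), rnorm(20), rnorm(20)))$p < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("Bartlett's test separates unequal variances and rejects degenerate groups", {
  set.seed(5)
  eq <- bartlett_test(list(rnorm(200), rnorm(200), rnorm(200)))
  expect_gt(eq$p, 0.001)
  uneq <- bartlett_test(list(rnorm(50, sd = 1), rnorm(50, sd = 10)))
  expect_lt(uneq$p, 0.001)
  g <- rnorm(30)
  expect_equal(bartlett_test(list(g, g))$K, 0, tolerance = 1e-10)
  expect_error(bartlett_test(list(rep(1, 5), rnorm(5))), "zero-variance")
  expect_error(bartlett_test(list(1, rnorm(5))), "n >= 2")
})
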