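make_fd_rows <- function(n = 150, pref = 6, seed = 13, ...) {
  d <- generate_panel(small_config(n = n, pref = pref, seed = seed, ...))
  eb <- compute_ebsmr_table(d$panel, d$rates)
  build_first_difference(eb, d$resources)
}

test_that("first differencing produces log and plain differences", {
  rows <- make_fd_rows(n = 80, pref = 4)
  expect_equal(nrow(rows), 80 * 2 * 4)
  expect_true(all(is.finite(rows$dy)))

  # hand-built resource table: PHN per 100k doubling gives d_ln_phn = ln 2
  res <- data.frame(
    municipality_id = rep(1:2, each = 2),
    prefecture_id = 1,
    period = rep(c("2010", "2015"), 2),
    population = c(1000, 1000, 2000, 2000),
    population_base = c(1000, 1000, 2000, 2000),
    phn_all_per100k = c(20, 40, 30, 30),
    phn_ft_per100k = c(18, 36, 30, 30),
    phn_pt_per100k = c(2, 4, 1e-9, 1e-9),
    physicians_per100k = c(100, 110, 90, 90),
    clinics_per100k = c(70, 70, 60, 60),
    hospitals_per100k = c(7, 6, 8, 8),
    welfare_per100k = c(9, 10, 12, 12))
  eb <- data.frame(
    municipality_id = rep(1:2, each = 2), prefecture_id = 1,
    sex = "male", cause = "all_causes",
    period = rep(c("2010", "2015"), 2),
    ebsmr = c(100, 95, 102, 102))
  rows2 <- build_first_difference(eb, res)
  r1 <- rows2[rows2$municipality_id == 1, ]
  expect_equal(r1$d_ln_phn, log(2))
  expect_equal(r1$dy, -5)
  expect_equal(r1$d_physicians, 10)
  r2 <- rows2[rows2$municipality_id == 2, ]
  expect_equal(r2$d_ln_phn, 0)
  expect_equal(r2$dy, 0)
  expect_equal(r2$d_hospitals, 0)
})

test_that("zero PHN density errors by default, offsets on request", {
  res <- data.frame(
    municipality_id = rep(1:3, each = 2), prefecture_id = 1,
    period = rep(c("2010", "2015"), 3),
    population = 1000, population_base = 1000,
    phn_all_per100k = c(0, 10, 20, 30, 15, 25),
    phn_ft_per100k = 10, phn_pt_per100k = 1,
    physicians_per100k = 100, clinics_per100k = 70,
    hospitals_per100k = 7, welfare_per100k = 9)
  eb <- data.frame(
    municipality_id = rep(1:3, each = 2), prefecture_id = 1,
    sex = "male", cause = "all_causes",
    period = rep(c("2010", "2015"), 3), ebsmr = 100)
  expect_error(build_first_difference(eb, res), "zero phn_all_per100k")
  expect_warning(rows <- build_first_difference(eb, res,
                                                zero_phn = "offset"),
                 "continuity offset")
  expect_true(all(is.finite(rows$d_ln_phn)))
})

test_that("mixed model reduces to OLS when the group variance is zero", {
  set.seed(101)
  n <- 400; g <- rep(1:8, each = 50)
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  y <- X %*% c(1.5, -0.7) + rnorm(n)          # no group effect
  fit <- fit_lmm_ml(y, X, g)
  ols <- solve(crossprod(X), crossprod(X, y))
  expect_lt(max(abs(fit$coefficients$estimate - drop(ols))), 1e-6)
  expect_lt(fit$sigma2_u, 1e-6)
})

test_that("mixed model matches the GLS solution with true variance components", {
  set.seed(202)
  n <- 1600; n_g <- 47
  g <- sort(rep_len(1:n_g, n))
  X <- cbind(phn = rnorm(n), pop = rnorm(n), z = rnorm(n))
  beta <- c(-1, 0.5, 0)
  s2u <- 4; s2e <- 25
  u <- rnorm(n_g, 0, sqrt(s2u))
  y <- drop(X %*% beta) + u[g] + rnorm(n, 0, sqrt(s2e))
  fit <- fit_lmm_ml(y, X, g)
  # GLS with the TRUE variance components (Woodbury per group)
  V_inv_y <- numeric(n); V_inv_X <- matrix(0, n, 3)
  for (gg in unique(g)) {
    idx <- which(g == gg); m <- length(idx)
    Vi <- diag(m) / s2e - matrix(s2u / (s2e * (s2e + m * s2u)), m, m)
    V_inv_y[idx] <- Vi %*% y[idx]
    V_inv_X[idx, ] <- Vi %*% X[idx, ]
  }
  gls <- solve(t(X) %*% V_inv_X, t(X) %*% V_inv_y)
  gls_se <- sqrt(diag(solve(t(X) %*% V_inv_X)))
  expect_true(all(abs(fit$coefficients$estimate - drop(gls)) <= 3 * gls_se))
  # sampling error of a variance component over 47 groups is ~sqrt(2/47)
  expect_lt(abs(fit$sigma2_u - s2u) / s2u, 3 * sqrt(2 / 47))
  expect_lt(abs(fit$sigma2_e - s2e) / s2e, 0.1)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * (3 + 2))
})

test_that("mixed model likelihood dominates the no-random-effect fit", {
  rows <- make_fd_rows(n = 100, pref = 5, seed = 8)
  r <- rows[rows$sex == "female" & rows$cause == "heart_disease", ]
  X <- as.matrix(r[, c("d_ln_phn", "d_ln_pop")])
  f1 <- fit_lmm_ml(r$dy, X, r$prefecture_id)
  f0 <- fit_lm_no_re(r$dy, X)
  expect_gte(f1$loglik, f0$loglik - 1e-6)
})

test_that("singleton groups reduce the mixed model to OLS coefficients", {
  set.seed(303)
  n <- 60
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- drop(X %*% c(2, -1)) + rnorm(n)
  fit <- fit_lmm_ml(y, X, groups = seq_len(n))
  ols <- solve(crossprod(X), crossprod(X, y))
  expect_lt(max(abs(fit$coefficients$estimate - drop(ols))), 1e-6)
})

test_that("an exact linear fit does not crash the mixed model", {
  set.seed(404)
  n <- 80
  X <- cbind(a = rnorm(n))
  y <- drop(X %*% 3)
  fit <- fit_lmm_ml(y, X, groups = rep(1:4, each = 20))
  expect_equal(fit$coefficients$estimate, 3, tolerance = 1e-6)
})

test_that("rank-deficient designs are rejected", {
  set.seed(5)
  x <- rnorm(30)
  X <- cbind(x, 2 * x)
  expect_error(fit_lmm_ml(rnorm(30), X, rep(1:3, 10)), "rank")
})

test_that("first-difference and fixed-effects estimators coincide", {
  set.seed(606)
  n_m <- 200
  unit <- rep(seq_len(n_m), each = 2)
  X2 <- cbind(phn = rnorm(2 * n_m), pop = rnorm(2 * n_m))
  y2 <- 0.5 * X2[, 1] - 1.2 * X2[, 2] + rep(rnorm(n_m, 0, 2), each = 2) +
    rnorm(2 * n_m)
  res <- first_difference_equals_fixed_effects(y2, X2, unit)
  expect_lt(res$max_abs_diff, 1e-8)

  # 3-municipality hand oracle, single covariate
  unit3 <- c(1, 1, 2, 2, 3, 3)
  x3 <- c(1, 3, 2, 2.5, 0, 4)
  y3 <- c(10, 14, 8, 9, 5, 13)
  dy <- c(4, 1, 8); dx <- c(2, 0.5, 4)
  hand <- sum(dx * dy) / sum(dx^2)
  res3 <- first_difference_equals_fixed_effects(y3, cbind(x = x3), unit3)
  expect_equal(unname(res3$beta_fd), hand)
  expect_equal(unname(res3$beta_fe), hand)

  # a covariate with no within variation breaks both estimators identically
  Xc <- cbind(z = rep(rnorm(n_m), each = 2))
  expect_error(first_difference_equals_fixed_effects(y2, Xc, unit), "rank")
  expect_error(
    first_difference_equals_fixed_effects(y2[1:3], X2[1:3, ], c(1, 1, 2)),
    "two periods")
})

test_that("no-intercept simple regression matches the normal equations", {
  x <- c(1, 2, 3, 4)
  expect_equal(simple_regression_no_intercept(2 * x, x)$slope, 2)
  expect_lt(simple_regression_no_intercept(2 * x, x)$p, 1e-10)
  xo <- c(1, -1, 1, -1); yo <- c(1, 1, -1, -1)   # orthogonal
  expect_equal(simple_regression_no_intercept(yo, xo)$slope, 0)
  set.seed(9)
  x <- rnorm(50); y <- rnorm(50)
  f <- simple_regression_no_intercept(y, x)
  expect_equal(f$slope, sum(x * y) / sum(x^2))
  lm_fit <- summary(lm(y ~ 0 + x))
  expect_equal(f$se, lm_fit$coefficients[1, 2])
  expect_equal(f$p, lm_fit$coefficients[1, 4])
  expect_error(simple_regression_no_intercept(y, rep(0, 50)), "zero")
})

test_that("VIFs follow the 1/(1-R^2) closed form", {
  n <- 40
  u <- scale(stats::poly(seq_len(n), 1))[, 1]
  v <- scale(residuals(lm(rnorm(n) ~ u)))[, 1]
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  x1 <- u
  x2 <- 0.6 * u + 0.8 * v          # exact sample correlation 0.6
  out <- vif(cbind(x1, x2))
  expect_equal(unname(out), c(1 / (1 - 0.36), 1 / (1 - 0.36)),
               tolerance = 1e-10)
  # orthogonal centered columns: VIF 1
  out1 <- vif(cbind(u, v))
  expect_equal(unname(out1), c(1, 1), tolerance = 1e-10)
  # duplicated column: infinite VIF
  expect_true(all(is.infinite(vif(cbind(x1, x1)))))
})

test_that("BH q-values match the step-up definition", {
  expect_equal(bh_qvalues(0.05), 0.05)
  expect_equal(bh_qvalues(rep(1, 5)), rep(1, 5))
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(14)
  for (i in 1:20) {
    p <- runif(sample(3:30, 1))^2
    q <- bh_qvalues(p)
    expect_equal(q, bh_oracle(p))
    # monotone in sorted-p order, permutation-consistent
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    perm <- sample(seq_along(p))
    expect_equal(bh_qvalues(p[perm]), q[perm])
  }
  expect_error(bh_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Cohen's d uses the pooled standard deviation", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  a <- c(8, 12, 10, 8, 12); b <- a - 2          # means 10 vs 8, both sd 2
  expect_equal(sd(a), 2)
  expect_equal(cohens_d(a, b), 1)
  set.seed(15)
  x <- rnorm(13, 2); y <- rnorm(29)
  sp <- sqrt((12 * var(x) + 28 * var(y)) / 40)
  expect_equal(cohens_d(x, y), (mean(x) - mean(y)) / sp)
  expect_warning(dd <- cohens_d(c(1, 1), c(2, 2)), "undefined")
  expect_true(is.nan(dd))
})

test_that("stratified fits partition the rows and recover local effects", {
  rows <- make_fd_rows(n = 200, pref = 8, seed = 33)
  r <- rows[rows$sex == "male" & rows$cause == "all_causes", ]
  fits <- stratified_fits(r, c("d_ln_phn", "d_ln_pop"),
                          baseline_field = "baseline_pop",
                          threshold = 10000)
  expect_equal(fits$low$stratum_n + fits$high$stratum_n, nrow(r))
  # threshold at the minimum: everything in one stratum
  expect_warning(
    one <- stratified_fits(r, c("d_ln_phn", "d_ln_pop"),
                           baseline_field = "baseline_pop",
                           threshold = min(r$baseline_pop)),
    "empty stratum")
  expect_equal(one$high$stratum_n, nrow(r))

  # an effect present only above the threshold is recovered only there
  set.seed(44)
  n <- 600
  sim <- data.frame(prefecture_id = rep(1:10, each = 60),
                    baseline_pop = rep(c(5000, 50000), each = 300),
                    d_ln_phn = rnorm(n), d_ln_pop = rnorm(n))
  eff <- ifelse(sim$baseline_pop >= 10000, -3, 0)
  sim$dy <- eff * sim$d_ln_phn + rnorm(n)
  f2 <- stratified_fits(sim, c("d_ln_phn", "d_ln_pop"),
                        baseline_field = "baseline_pop", threshold = 10000)
  est <- function(f) f$coefficients$estimate[f$coefficients$term ==
                                               "d_ln_phn"]
  p_of <- function(f) f$coefficients$p[f$coefficients$term == "d_ln_phn"]
  expect_lt(p_of(f2$high), 0.001)
  expect_lt(abs(est(f2$high) - (-3)), 0.5)
  expect_gt(p_of(f2$low), 0.01)
})
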