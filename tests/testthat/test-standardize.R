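test_that("expected deaths accumulate population times rate over the window", {
  expect_equal(expected_deaths(c(a = 1000), c(a = 0.01), years = 1), 10)
  expect_equal(
    expected_deaths(c(a1 = 1000, a2 = 500, a3 = 2000),
                    c(a1 = 0.001, a2 = 0.01, a3 = 0.05), years = 5),
    530)
  expect_warning(e0 <- expected_deaths(c(a = 0, b = 0), c(a = 0.1, b = 0.2)),
                 "all-zero")
  expect_equal(e0, 0)
  expect_error(expected_deaths(c(a = 10), c(b = 0.1)), "mismatch")
})

test_that("raw SMR is 100 o/e and rejects non-positive e", {
  expect_equal(raw_smr(7, 7), 100)
  expect_equal(raw_smr(0, 3), 0)
  expect_equal(raw_smr(12, 8), 150)
  expect_error(raw_smr(1, 0), "positive")
  expect_error(raw_smr(-1, 5), "non-negative")
})

test_that("moment estimator matches hand evaluation on a toy set", {
  o <- c(5, 20, 10); e <- c(10, 10, 10)
  pr <- fit_gamma_prior_moments(o, e)
  m <- 35 / 30
  v <- sum(e * (o / e - m)^2) / sum(e) - m / mean(e)
  expect_equal(pr$mean, m)
  expect_equal(pr$vhat, v)
  expect_equal(pr$rate, m / v)
  expect_equal(pr$shape, m^2 / v)
  expect_equal(pr$shape, 5)            # hand-computed: m^2 / 0.272222
  expect_equal(pr$rate, 30 / 7)
  expect_false(pr$degenerate)
})

test_that("zero between-area variance yields a degenerate prior", {
  pr <- fit_gamma_prior_moments(o = c(4, 9, 25), e = c(4, 9, 25))
  expect_true(pr$degenerate)
  expect_equal(pr$mean, 1)
  expect_lt(pr$vhat, 0)
  eb <- eb_posterior_smr(c(4, 9), c(4, 9), pr)
  expect_equal(eb$ebsmr, c(100, 100))
})

test_that("moment estimator recovers simulated gamma hyperparameters", {
  set.seed(2024)
  n <- 2000
  theta <- rgamma(n, shape = 4, rate = 4)     # mean 1, variance 0.25
  e <- runif(n, 50, 500)
  o <- rpois(n, e * theta)
  pr <- fit_gamma_prior_moments(o, e)
  expect_lt(abs(pr$mean - 1), 0.02)
  expect_lt(abs(pr$vhat - 0.25) / 0.25, 0.15)
})

test_that("prior fitting requires at least two areas with positive e", {
  expect_error(fit_gamma_prior_moments(5, 5), "insufficient")
  expect_error(fit_gamma_prior_moments(c(1, 2), c(1, 0)), "positive")
})

test_that("EB posterior mean has the conjugate closed form", {
  pr <- list(shape = 10, rate = 10, mean = 1, degenerate = FALSE)
  expect_equal(eb_posterior_smr(5, 5, pr)$ebsmr, 100)
  # large-e limit recovers the raw SMR
  big <- eb_posterior_smr(1.5e6, 1e6, pr)
  expect_lt(abs(big$ebsmr - 150), 0.1)
  expect_error(eb_posterior_smr(-1, 5, pr), "non-negative")
})

test_that("EB posterior matches numerical integration on random cases", {
  set.seed(7)
  for (i in 1:100) {
    alpha <- runif(1, 0.5, 50)
    nu <- runif(1, 0.5, 50)
    e <- runif(1, 0.5, 400)
    o <- rpois(1, e * rgamma(1, alpha, nu))
    pr <- list(shape = alpha, rate = nu, mean = alpha / nu,
               degenerate = FALSE)
    got <- eb_posterior_smr(o, e, pr)$ebsmr / 100
    want <- eb_quadrature_oracle(o, e, alpha, nu)
    expect_lt(abs(got - want) / want, 1e-8)
  }
})

test_that("shrinkage stays between the raw SMR and the prior mean", {
  set.seed(11)
  for (i in 1:200) {
    alpha <- runif(1, 0.2, 30); nu <- runif(1, 0.2, 30)
    e <- runif(1, 0.1, 500); o <- rpois(1, e * 1.3)
    pr <- list(shape = alpha, rate = nu, mean = alpha / nu,
               degenerate = FALSE)
    eb <- eb_posterior_smr(o, e, pr)
    lo <- min(eb$smr_raw, 100 * pr$mean) - 1e-9
    hi <- max(eb$smr_raw, 100 * pr$mean) + 1e-9
    expect_gte(eb$ebsmr, lo)
    expect_lte(eb$ebsmr, hi)
  }
})

test_that("shrinkage towards the prior decreases as e grows", {
  pr <- list(shape = 8, rate = 8, mean = 1, degenerate = FALSE)
  ratio <- 1.4
  es <- c(1, 5, 20, 100, 1000, 1e5)
  gaps <- vapply(es, function(e) {
    eb <- eb_posterior_smr(ratio * e, e, pr)
    abs(eb$ebsmr - eb$smr_raw)
  }, numeric(1))
  expect_true(all(diff(gaps) <= 1e-9))
})

test_that("EBSMR table is calibrated and less dispersed than raw SMRs", {
  d <- generate_panel(null_config(n = 400))
  eb <- compute_ebsmr_table(d$panel, d$rates)
  sub <- eb[eb$sex == "male" & eb$cause == "all_causes" &
              eb$period == "2010", ]
  mc_se <- sd(sub$smr_raw) / sqrt(nrow(sub))
  expect_lt(abs(mean(sub$ebsmr) - 100), 3 * mc_se + 1e-6)
  # shrinkage reduces dispersion in every cell of a structured panel
  d2 <- generate_panel(small_config(n = 200, pref = 8,
                                    prior_shape = 10, prior_rate = 10))
  eb2 <- compute_ebsmr_table(d2$panel, d2$rates)
  for (cl in split(eb2, interaction(eb2$sex, eb2$cause, eb2$period))) {
    expect_lt(var(cl$ebsmr), var(cl$smr_raw))
  }
})

test_that("a single-period panel is handled without error", {
  d <- generate_panel(small_config(n = 60, pref = 3, periods = "2010"))
  eb <- compute_ebsmr_table(d$panel, d$rates)
  expect_setequal(unique(eb$period), "2010")
  expect_equal(nrow(eb), nrow(d$panel))
})

test_that("weighted mean of EBSMRs approaches the group mean under full shrinkage", {
  set.seed(3)
  e <- runif(300, 10, 200)
  o <- rpois(300, e * rgamma(300, 6, 6))
  m <- sum(o) / sum(e)
  pr <- list(shape = 1e9 * m, rate = 1e9, mean = m, degenerate = FALSE)
  eb <- eb_posterior_smr(o, e, pr)
  wmean <- sum(e * eb$ebsmr / 100) / sum(e)
  expect_lt(abs(wmean - m), 1e-4)
})

test_that("small prefecture groups fall back to the national prior", {
  d <- generate_panel(small_config(n = 40, pref = 20, seed = 5))
  # 2 municipalities per prefecture: below the default minimum of 5
  eb <- compute_ebsmr_table(d$panel, d$rates)
  expect_true(all(eb$prior_fallback))
  eb2 <- compute_ebsmr_table(d$panel, d$rates, min_group = 2)
  expect_false(any(eb2$prior_fallback))
})
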