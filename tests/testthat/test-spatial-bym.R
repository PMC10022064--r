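test_that("ICAR log-density matches the dense quadratic-form oracle", {
  g3 <- adjacency_graph(data.frame(from = c(1, 2), to = c(2, 3)), n = 3)
  expect_equal(icar_log_density(c(5, 5, 5), g3, tau = 2), 0)
  expect_equal(icar_log_density(c(1, 0, -1), g3, tau = 1), -1)
  set.seed(18)
  for (i in 1:10) {
    n <- sample(5:25, 1)
    edges <- geometric_adjacency(n, radius = 0.6)
    g <- adjacency_graph(edges, n = n)
    phi <- rnorm(n)
    tau <- runif(1, 0.1, 5)
    expect_equal(icar_log_density(phi, g, tau),
                 icar_quadratic_oracle(phi, edges, n, tau))
  }
  expect_error(icar_log_density(1:2, g3), "length")
})

test_that("ICAR density is invariant to per-component constants", {
  e2 <- rbind(grid_adjacency(9), grid_adjacency(9) + 9L)
  g <- adjacency_graph(e2, n = 18)
  expect_equal(g$n_components, 2L)
  set.seed(19)
  phi <- rnorm(18)
  shifted <- phi + rep(c(3, -7), each = 9)
  expect_equal(icar_log_density(phi, g, 1.3),
               icar_log_density(shifted, g, 1.3))
})

test_that("adjacency graph validates and summarises the edge list", {
  expect_error(adjacency_graph(data.frame(from = 1, to = 1)), "self-loops")
  g <- adjacency_graph(data.frame(from = c(1, 1, 2), to = c(2, 2, 1)), n = 3)
  expect_equal(nrow(g$edges), 1L)          # duplicates collapse
  expect_equal(g$degree, c(1L, 1L, 0L))
  expect_equal(g$isolated, 3L)
  expect_equal(g$n_components, 2L)
})

test_that("quantile credible intervals follow the stated conventions", {
  expect_equal(quantile_ci(rep(2.5, 200)), c(2.5, 2.5))
  set.seed(20)
  z <- rnorm(1e6)
  ci <- quantile_ci(z, 0.95)
  expect_lt(abs(ci[1] + 1.959964), 0.01)
  expect_lt(abs(ci[2] - 1.959964), 0.01)
  x <- runif(150)
  expect_equal(quantile_ci(x, 1), range(x))
  expect_error(quantile_ci(rnorm(50)), "100 draws")
})

test_that("split R-hat flags non-converged chains and matches its formula", {
  set.seed(21)
  good <- matrix(rnorm(4000), ncol = 4)
  expect_lt(abs(rhat(good) - 1), 0.01)
  bad <- cbind(rnorm(500, -10), rnorm(500, 10))
  expect_gt(rhat(bad), 1.5)
  expect_error(rhat(matrix(rnorm(100), ncol = 1)), "2 chains")

  # direct evaluation of the split formula on a fixture
  m <- matrix(rnorm(400), ncol = 2)
  sp <- cbind(m[1:100, ], m[101:200, ])
  n <- 100
  B <- n * var(colMeans(sp))
  W <- mean(apply(sp, 2, var))
  expect_equal(rhat(m), sqrt(((n - 1) / n * W + B / n) / W))
})

test_that("effective sample size is near n for white noise, small for sticky chains", {
  set.seed(22)
  iid <- matrix(rnorm(4000), ncol = 4)
  expect_gt(ess(iid), 2000)
  ar <- matrix(0, 1000, 2)
  for (ch in 1:2) {
    x <- numeric(1000)
    for (t in 2:1000) x[t] <- 0.95 * x[t - 1] + rnorm(1, 0, 0.1)
    ar[, ch] <- x
  }
  expect_lt(ess(ar), 300)
})

test_that("PHN covariate split separates baseline and change", {
  d <- generate_panel(small_config(n = 60, pref = 3, seed = 51))
  eb <- compute_ebsmr_table(d$panel, d$rates)
  obs <- build_bym_data(eb, d$resources, "male", "all_causes")
  spec <- bym_model_spec(obs, chains = 2L, iter = 400L, warmup = 200L)
  sp2 <- split_phn_covariate(spec)
  expect_true(all(c("ln_phn_baseline", "ln_phn_change") %in%
                    sp2$covariates))
  expect_false("ln_phn" %in% sp2$covariates)
  ob2 <- sp2$obs
  first <- ob2$time == 0
  expect_equal(ob2$ln_phn_baseline[first], ob2$ln_phn[first])
  expect_true(all(ob2$ln_phn_change[first] == 0))
  second <- !first
  expect_equal(ob2$ln_phn_change[second],
               ob2$ln_phn[second] - ob2$ln_phn_baseline[second])

  # no change anywhere: change column identically zero
  res_const <- d$resources
  res_const$phn_all_per100k <- ave(res_const$phn_all_per100k,
                                   res_const$municipality_id)
  obs_c <- build_bym_data(eb, res_const, "male", "all_causes")
  sp_c <- split_phn_covariate(bym_model_spec(obs_c, chains = 2L,
                                             iter = 400L, warmup = 200L))
  expect_true(all(abs(sp_c$obs$ln_phn_change) < 1e-12))

  # doubling in one municipality shows as ln 2 in its second-period row
  res_d <- d$resources
  i2 <- res_d$municipality_id == 5 & res_d$period == "2015"
  i1 <- res_d$municipality_id == 5 & res_d$period == "2010"
  res_d$phn_all_per100k[i2] <- 2 * res_d$phn_all_per100k[i1]
  obs_d <- build_bym_data(eb, res_d, "male", "all_causes")
  sp_d <- split_phn_covariate(bym_model_spec(obs_d, chains = 2L,
                                             iter = 400L, warmup = 200L))
  chg <- sp_d$obs$ln_phn_change[sp_d$obs$municipality_id == 5 &
                                  sp_d$obs$time == 1]
  expect_equal(chg, log(2))
})

test_that("posterior matches ML Poisson regression when random effects are off", {
  d <- generate_panel(small_config(n = 150, pref = 6, seed = 61))
  eb <- compute_ebsmr_table(d$panel, d$rates)
  obs <- build_bym_data(eb, d$resources, "female", "malignant_neoplasms")
  g <- adjacency_graph(d$adjacency, n = 150)
  spec <- bym_model_spec(obs, include_spatial = FALSE,
                         include_hetero = FALSE,
                         chains = 4L, iter = 6000L, warmup = 3000L,
                         seed = 17)
  fit <- fit_bym(spec, g)
  X <- as.matrix(obs[, spec$covariates])
  mle <- coef(glm(obs$o ~ 0 + X + offset(log(obs$e)), family = poisson()))
  diff <- abs(fit$summary$mean - unname(mle))
  mc_err <- 4 * fit$summary$sd / sqrt(pmax(fit$summary$ess, 1)) +
    0.05 * fit$summary$sd
  expect_true(all(diff <= mc_err))
})

test_that("prior-only sampling reproduces the documented priors", {
  d <- generate_panel(small_config(n = 60, pref = 3, seed = 71))
  eb <- compute_ebsmr_table(d$panel, d$rates)
  obs <- build_bym_data(eb, d$resources, "male", "heart_disease")
  g <- adjacency_graph(d$adjacency, n = 60)
  spec <- bym_model_spec(obs, chains = 4L, iter = 5000L, warmup = 2000L,
                         seed = 23)
  fit <- fit_bym(spec, g, prior_only = TRUE)
  betas <- fit$summary[seq_along(spec$covariates), ]
  expect_true(all(abs(betas$mean) < 0.6))
  expect_true(all(abs(betas$sd - 5) < 0.6))
  seps <- fit$summary[fit$summary$parameter == "sigma_eps", ]
  expect_lt(abs(seps$mean - sqrt(2 / pi)), 0.08)   # half-normal(1) mean
})

test_that("coefficient draws rescale exactly with the covariate scaling", {
  d <- generate_panel(small_config(n = 80, pref = 4, seed = 81))
  eb <- compute_ebsmr_table(d$panel, d$rates)
  obs <- build_bym_data(eb, d$resources, "male", "all_causes")
  g <- adjacency_graph(d$adjacency, n = 80)
  covs <- c("ln_phn", "ln_pop", "time")
  spec1 <- bym_model_spec(obs, covariates = covs, prior_sd_beta = 5,
                          chains = 2L, iter = 800L, warmup = 400L,
                          seed = 97)
  obs2 <- obs
  obs2$ln_phn <- obs2$ln_phn / 1000
  spec2 <- bym_model_spec(obs2, covariates = covs,
                          prior_sd_beta = c(5000, 5, 5),
                          chains = 2L, iter = 800L, warmup = 400L,
                          seed = 97)
  f1 <- fit_bym(spec1, g)
  f2 <- fit_bym(spec2, g)
  expect_equal(f2$draws$beta[[1]][, 1], f1$draws$beta[[1]][, 1] * 1000)
  expect_equal(f2$draws$beta[[2]][, 2], f1$draws$beta[[2]][, 2])
  # reporting convention: scaled covariates are multiplied by 1000
  expect_equal(f1$summary$mean_reported[1], f1$summary$mean[1] * 1000)
  expect_equal(f1$summary$report_multiplier[1:3], c(1000, 1000, 1))
})

test_that("model specification validates its inputs", {
  d <- generate_panel(small_config(n = 40, pref = 2, seed = 91))
  eb <- compute_ebsmr_table(d$panel, d$rates)
  obs <- build_bym_data(eb, d$resources, "male", "all_causes")
  expect_error(bym_model_spec(obs, covariates = "nope"), "missing")
  bad <- obs; bad$e[1] <- 0
  expect_error(bym_model_spec(bad), "e > 0")
  bad2 <- obs; bad2$o[1] <- -1
  expect_error(bym_model_spec(bad2), "non-negative")
  bad3 <- obs; bad3$time[1] <- 2
  expect_error(bym_model_spec(bad3), "0/1")
  spec <- bym_model_spec(obs, chains = 2L, iter = 150L, warmup = 100L)
  g <- adjacency_graph(d$adjacency, n = 40)
  expect_error(fit_bym(spec, g), "100 post-warmup")
})
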