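#' Adjacency graph for the spatial model
#'
#' Wraps an undirected edge list into the structure the ICAR component needs:
#' node count, unique edges (no self-loops), per-node degree and connected
#' component labels. Isolated nodes are flagged; the ICAR density treats each
#' connected component separately.
#'
#' @param edges two-column data.frame or matrix of node indices (1-based).
#' @param n number of nodes (defaults to the largest index seen).
#' @return list of class \code{bym_graph}: n, edges (matrix), degree,
#'   component, n_components, isolated.
#' @export
adjacency_graph <- function(edges, n = max(edges)) {
  em <- as.matrix(edges)[, 1:2, drop = FALSE]
  storage.mode(em) <- "integer"
  if (any(em[, 1L] == em[, 2L])) stop("self-loops not allowed", call. = FALSE)
  em <- cbind(pmin(em[, 1L], em[, 2L]), pmax(em[, 1L], em[, 2L]))
  em <- unique(em)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(em))
  deg <- igraph::degree(g)
  comp <- igraph::components(g)$membership
  out <- list(n = n, edges = em, degree = as.integer(deg),
              component = as.integer(comp),
              n_components = max(comp),
              isolated = which(deg == 0L))
  class(out) <- "bym_graph"
  out
}

#' ICAR log-density (up to the normalizing constant)
#'
#' The intrinsic conditional autoregressive prior on a spatial field phi with
#' precision tau has improper joint density proportional to
#' \code{exp(-(tau/2) * sum_{i~j} (phi_i - phi_j)^2)} over unique edges;
#' the sum-to-zero constraint per connected component is enforced elsewhere
#' (soft constraint during sampling, exact projection when simulating).
#'
#' @param phi numeric vector indexed by graph nodes.
#' @param graph a \code{bym_graph}.
#' @param tau precision (> 0).
#' @return log-density up to an additive constant.
#' @export
icar_log_density <- function(phi, graph, tau = 1) {
  stopifnot(inherits(graph, "bym_graph"), tau > 0)
  if (length(phi) != graph$n) stop("phi length does not match graph",
                                   call. = FALSE)
  d <- phi[graph$edges[, 1L]] - phi[graph$edges[, 2L]]
  -(tau / 2) * sum(d^2)
}

#' Stacked observation table for the BYM model
#'
#' Builds the municipality x period observation table the spatial model
#' consumes for one sex x cause series: observed deaths, expected deaths, the
#' log-transformed PHN density and population, untransformed per-100k
#' resource counts, and a time dummy (0 for the first period, 1 for the
#' second).
#'
#' @param ebsmr_table output of [compute_ebsmr_table()] (supplies o and e).
#' @param resources resource table from [generate_panel()].
#' @param sex,cause the series to extract.
#' @return data.frame: municipality_id, period, time, o, e, ln_phn, ln_pop,
#'   physicians, clinics, hospitals, welfare.
#' @export
build_bym_data <- function(ebsmr_table, resources, sex, cause) {
  oe <- ebsmr_table[ebsmr_table$sex == sex & ebsmr_table$cause == cause,
                    c("municipality_id", "period", "o", "e")]
  if (nrow(oe) == 0L) stop("no rows for sex=", sex, " cause=", cause,
                           call. = FALSE)
  obs <- merge(oe, resources, by = c("municipality_id", "period"))
  periods <- sort(unique(obs$period))
  obs$time <- as.numeric(match(obs$period, periods) - 1L)
  out <- data.frame(
    municipality_id = obs$municipality_id,
    period = obs$period,
    time = obs$time,
    o = obs$o,
    e = obs$e,
    ln_phn = log(obs$phn_all_per100k),
    ln_pop = log(obs$population),
    physicians = obs$physicians_per100k,
    clinics = obs$clinics_per100k,
    hospitals = obs$hospitals_per100k,
    welfare = obs$welfare_per100k
  )
  out <- out[order(out$municipality_id, out$period), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' BYM model specification
#'
#' Collects the design for [fit_bym()]: the stacked observation table, the
#' covariate columns, the reporting convention (adjustment covariates other
#' than the time dummy are reported on a x1/1000 scale, i.e. the posterior
#' draws are multiplied by 1000), prior settings, and sampler settings.
#' The model is fitted on the natural covariate scale; \code{prior_sd_beta}
#' applies per natural-scale coefficient.
#'
#' @param obs observation table from [build_bym_data()] (needs columns
#'   municipality_id, o, e, time and the covariates).
#' @param covariates character vector of covariate column names (no
#'   intercept; the offset log(e) absorbs the level).
#' @param scaled_covariates covariates whose reported estimates use the
#'   1/1000 covariate scaling (default: all except \code{"time"}).
#' @param prior_sd_beta normal prior SD per coefficient (recycled).
#' @param include_spatial,include_hetero include the ICAR field / the
#'   unstructured heterogeneity.
#' @param chains,iter,warmup sampler settings (iter includes warmup).
#' @param soft_sum_sd_factor soft sum-to-zero: the mean constraint SD is
#'   \code{factor * component size}.
#' @param rhat_threshold,min_ess convergence flags.
#' @param seed integer seed.
#' @return list of class \code{bym_spec}.
#' @export
bym_model_spec <- function(obs,
                           covariates = c("ln_phn", "ln_pop", "physicians",
                                          "clinics", "hospitals", "welfare",
                                          "time"),
                           scaled_covariates = setdiff(covariates, "time"),
                           prior_sd_beta = 5,
                           include_spatial = TRUE,
                           include_hetero = TRUE,
                           chains = 4L, iter = 12000L, warmup = 4000L,
                           soft_sum_sd_factor = 0.001,
                           rhat_threshold = 1.05, min_ess = 400,
                           seed = 1L) {
  stopifnot(all(c("municipality_id", "o", "e") %in% names(obs)))
  miss <- setdiff(covariates, names(obs))
  if (length(miss) > 0) stop("missing covariates: ",
                             paste(miss, collapse = ", "), call. = FALSE)
  if (any(obs$e <= 0)) stop("offset requires e > 0", call. = FALSE)
  if (any(obs$o < 0) || any(obs$o != round(obs$o))) {
    stop("o must be non-negative integers", call. = FALSE)
  }
  if ("time" %in% covariates && !all(obs$time %in% c(0, 1))) {
    stop("time dummy must be 0/1", call. = FALSE)
  }
  spec <- list(
    obs = obs,
    covariates = covariates,
    report_multiplier = ifelse(covariates %in% scaled_covariates, 1000, 1),
    prior_sd_beta = rep_len(prior_sd_beta, length(covariates)),
    include_spatial = include_spatial,
    include_hetero = include_hetero,
    chains = as.integer(chains), iter = as.integer(iter),
    warmup = as.integer(warmup),
    soft_sum_sd_factor = soft_sum_sd_factor,
    rhat_threshold = rhat_threshold, min_ess = min_ess,
    seed = as.integer(seed)
  )
  class(spec) <- "bym_spec"
  spec
}

#' Split the PHN covariate into baseline and change
#'
#' Replaces the single \code{ln_phn} column by two: the baseline (first
#' period) log PHN density applied to both periods, and the between-period
#' difference of logs applied through the time dummy (zero in the first
#' period, the full change in the second). This is the study's second model
#' variant, separating the standing workforce from its change.
#'
#' @param spec a \code{bym_spec} whose obs carry \code{ln_phn} and both
#'   periods.
#' @return a new \code{bym_spec} with covariates \code{ln_phn_baseline} and
#'   \code{ln_phn_change} in place of \code{ln_phn}.
#' @export
split_phn_covariate <- function(spec) {
  stopifnot(inherits(spec, "bym_spec"))
  obs <- spec$obs
  if (!"ln_phn" %in% names(obs)) stop("obs lack ln_phn", call. = FALSE)
  periods <- sort(unique(obs$period))
  if (length(periods) != 2L) stop("missing baseline period", call. = FALSE)
  base <- obs[obs$period == periods[1L], c("municipality_id", "ln_phn")]
  names(base)[2L] <- "ln_phn_baseline"
  obs <- merge(obs, base, by = "municipality_id")
  chg <- obs$ln_phn - obs$ln_phn_baseline
  obs$ln_phn_change <- chg * obs$time +
    0 * (1 - obs$time)   # explicit: zero at baseline, full change after
  obs <- obs[order(obs$municipality_id, obs$period), , drop = FALSE]
  rownames(obs) <- NULL
  covs <- spec$covariates
  i <- match("ln_phn", covs)
  covs <- append(covs[-i], c("ln_phn_baseline", "ln_phn_change"), after = i - 1L)
  bym_model_spec(obs, covariates = covs,
                 scaled_covariates = setdiff(covs, "time"),
                 prior_sd_beta = spec$prior_sd_beta[1L],
                 include_spatial = spec$include_spatial,
                 include_hetero = spec$include_hetero,
                 chains = spec$chains, iter = spec$iter,
                 warmup = spec$warmup,
                 soft_sum_sd_factor = spec$soft_sum_sd_factor,
                 rhat_threshold = spec$rhat_threshold,
                 min_ess = spec$min_ess, seed = spec$seed)
}

#' Fit the BYM spatial Poisson model
#'
#' Full Bayesian inference for
#' \code{o_k ~ Poisson(mu_k)}, \code{log(mu_k) = log(e_k) + x_k beta +
#' phi_m(k) + eps_k}, with an intrinsic CAR prior on the per-municipality
#' spatial field phi (shared across periods; soft sum-to-zero per connected
#' component), iid normal heterogeneity eps per observation, independent
#' \code{N(0, prior_sd_beta)} priors on the coefficients and half-normal(1)
#' priors on the two scale parameters. Sampling is adaptive
#' Metropolis-within-Gibbs; convergence is summarised by split-chain R-hat
#' and effective sample size for every reported parameter.
#'
#' @param spec a \code{bym_spec}.
#' @param graph a \code{bym_graph} over the municipalities in
#'   \code{spec$obs} (node i = municipality id i).
#' @param prior_only sample from the priors alone (likelihood switched off);
#'   used for prior-predictive checks.
#' @param store_phi keep the full phi draws (needed for phi credible
#'   intervals; summaries are always available).
#' @return list of class \code{bym_fit}: \code{summary} (data.frame:
#'   parameter, mean, sd, q2.5, q97.5, rhat, ess, report_multiplier,
#'   mean_reported, q2.5_reported, q97.5_reported), \code{draws} (list of
#'   per-chain matrices for beta and scales), \code{phi_mean},
#'   \code{eps_mean}, \code{converged}, \code{settings}.
#' @export
fit_bym <- function(spec, graph, prior_only = FALSE, store_phi = FALSE) {
  stopifnot(inherits(spec, "bym_spec"), inherits(graph, "bym_graph"))
  obs <- spec$obs
  munis <- sort(unique(obs$municipality_id))
  if (length(munis) != graph$n || !all(munis == seq_len(graph$n))) {
    stop("municipality ids must be 1..n matching the graph", call. = FALSE)
  }
  X <- as.matrix(obs[, spec$covariates, drop = FALSE])
  if (graph$n_components > 1L) {
    message("adjacency graph has ", graph$n_components,
            " components; sum-to-zero applied per component")
  }
  n_keep <- spec$iter - spec$warmup
  if (n_keep < 100L) stop("need at least 100 post-warmup draws",
                          call. = FALSE)

  set.seed(spec$seed)
  chains <- vector("list", spec$chains)
  for (ch in seq_len(spec$chains)) {
    chains[[ch]] <- .bym_mcmc_chain(
      o = as.numeric(obs$o), log_e = log(obs$e), X = X,
      muni = as.integer(obs$municipality_id - 1L),
      edges = graph$edges - 1L,
      comp = as.integer(graph$component - 1L),
      prior_sd_beta = spec$prior_sd_beta,
      soft_sum_sd_factor = spec$soft_sum_sd_factor,
      include_spatial = spec$include_spatial,
      include_hetero = spec$include_hetero,
      use_likelihood = !prior_only,
      n_iter = spec$iter, n_warmup = spec$warmup,
      store_phi = store_phi)
  }

  pnames <- c(spec$covariates,
              if (spec$include_spatial) "sigma_phi",
              if (spec$include_hetero) "sigma_eps")
  get_param <- function(name) {
    sapply(chains, function(cc) {
      j <- match(name, spec$covariates)
      if (!is.na(j)) cc$beta[, j] else cc[[name]]
    })
  }
  mult <- c(spec$report_multiplier,
            if (spec$include_spatial) 1, if (spec$include_hetero) 1)
  rows <- lapply(seq_along(pnames), function(i) {
    dm <- get_param(pnames[i])        # n_keep x chains
    pooled <- as.numeric(dm)
    ci <- quantile_ci(pooled, 0.95)
    data.frame(parameter = pnames[i], mean = mean(pooled), sd = stats::sd(pooled),
               q2.5 = ci[1L], q50 = stats::median(pooled), q97.5 = ci[2L],
               rhat = rhat(dm), ess = ess(dm),
               report_multiplier = mult[i],
               mean_reported = mean(pooled) * mult[i],
               q2.5_reported = ci[1L] * mult[i],
               q97.5_reported = ci[2L] * mult[i])
  })
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  converged <- all(summary$rhat < spec$rhat_threshold) &&
    all(summary$ess >= spec$min_ess)

  phi_draws <- NULL
  if (store_phi && spec$include_spatial) {
    phi_draws <- lapply(chains, `[[`, "phi")
  }
  out <- list(
    summary = summary,
    draws = list(beta = lapply(chains, `[[`, "beta"),
                 sigma_phi = lapply(chains, `[[`, "sigma_phi"),
                 sigma_eps = lapply(chains, `[[`, "sigma_eps"),
                 lp = lapply(chains, `[[`, "lp"),
                 phi = phi_draws),
    phi_mean = rowMeans(sapply(chains, `[[`, "phi_mean")),
    eps_mean = rowMeans(sapply(chains, `[[`, "eps_mean")),
    converged = converged,
    settings = spec[c("covariates", "report_multiplier", "prior_sd_beta",
                      "include_spatial", "include_hetero", "chains", "iter",
                      "warmup", "soft_sum_sd_factor", "rhat_threshold",
                      "min_ess", "seed")]
  )
  class(out) <- "bym_fit"
  out
}

#' Quantile credible interval
#'
#' Central credible interval from empirical quantiles (type-7 convention);
#' for level 0.95 these are the 2.5\% and 97.5\% quantiles. Level 1 returns
#' the draw range.
#'
#' @param draws numeric vector (>= 100 draws).
#' @param level coverage level in (0, 1].
#' @return numeric vector c(low, high).
#' @export
quantile_ci <- function(draws, level = 0.95) {
  if (length(draws) < 100L) stop("need at least 100 draws", call. = FALSE)
  stopifnot(level > 0, level <= 1)
  a <- (1 - level) / 2
  unname(stats::quantile(draws, c(a, 1 - a), type = 7, names = FALSE))
}

#' Split-chain potential scale reduction (R-hat)
#'
#' Each chain is split in half; R-hat is computed from the between- and
#' within-half variances of the split chains:
#' \code{sqrt(((n-1)/n W + B/n) / W)}.
#'
#' @param draws matrix (iterations x chains) or list of equal-length chains.
#' @return R-hat statistic.
#' @export
rhat <- function(draws) {
  m <- as_chain_matrix(draws)
  if (ncol(m) < 2L) stop("need at least 2 chains", call. = FALSE)
  sp <- split_chains(m)
  n <- nrow(sp)
  mu <- colMeans(sp)
  B <- n * stats::var(mu)
  W <- mean(apply(sp, 2L, stats::var))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size
#'
#' Split-chain effective sample size using the autocorrelation sum truncated
#' by Geyer's initial positive sequence, combined across chains.
#'
#' @inheritParams rhat
#' @return effective sample size.
#' @export
ess <- function(draws) {
  m <- as_chain_matrix(draws)
  sp <- split_chains(m)
  n <- nrow(sp); k <- ncol(sp)
  mu <- colMeans(sp)
  W <- mean(apply(sp, 2L, stats::var))
  B <- if (k > 1L) n * stats::var(mu) else 0
  var_plus <- (n - 1) / n * W + B / n
  if (var_plus == 0) return(n * k)
  # mean autocovariance across split chains
  max_lag <- n - 1L
  acov <- matrix(0, max_lag + 1L, k)
  for (j in seq_len(k)) {
    x <- sp[, j] - mu[j]
    ac <- stats::acf(x, lag.max = max_lag, plot = FALSE, type = "covariance",
                     demean = FALSE)$acf[, 1L, 1L]
    acov[, j] <- ac
  }
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  # Geyer initial positive sequence on paired sums
  tau <- 1
  t <- 1L
  while (t + 1L <= length(rho) - 1L) {
    pair <- rho[t + 1L] + rho[t + 2L]
    if (!is.finite(pair) || pair <= 0) break
    tau <- tau + 2 * pair
    t <- t + 2L
  }
  max(1, n * k / tau)
}

as_chain_matrix <- function(draws) {
  if (is.list(draws)) {
    len <- unique(lengths(draws))
    if (length(len) != 1L) stop("chains must have equal length",
                                call. = FALSE)
    draws <- do.call(cbind, draws)
  }
  as.matrix(draws)
}

split_chains <- function(m) {
  n <- nrow(m)
  h <- n %/% 2L
  cbind(m[seq_len(h), , drop = FALSE],
        m[(n - h + 1L):n, , drop = FALSE])
}
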