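#' Generator configuration for synthetic municipality panels
#'
#' Builds the configuration object consumed by [generate_panel()]. Defaults
#' emulate the Japanese municipal panel the analysis targets: 1,601
#' municipalities in 47 prefectures observed at the 2010 and 2015 censuses,
#' log-normally distributed populations, a public-health-nurse (PHN) density
#' that decreases with population size, gamma-distributed municipal relative
#' risks clustered by prefecture, a spatially structured (intrinsic CAR) risk
#' field on a municipality adjacency graph, and a secular mortality decline
#' between the two periods. Death counts are pooled over five-year windows
#' centred on each census year.
#'
#' @param n_municipalities number of municipalities.
#' @param n_prefectures number of prefectures (contiguous blocks of the
#'   adjacency grid).
#' @param n_age_groups number of five-year age groups (default 18: 0-4 ... 85+).
#' @param periods character vector of two period labels.
#' @param period_years years of death counts pooled per period.
#' @param pop_lognormal_mu,pop_lognormal_sigma log-scale location and scale of
#'   the municipal population distribution. Defaults reproduce a natural-scale
#'   mean near 44,300 and SD near 57,700.
#' @param phn_intercept,phn_slope,phn_noise_sd parameters of
#'   \code{ln(PHN per 100k) = phn_intercept - phn_slope * ln(population) + noise};
#'   \code{phn_slope >= 0} encodes that small municipalities have more PHNs
#'   per capita.
#' @param true_beta named numeric vector of log-relative-risk effects per unit
#'   of the named covariate (covariates are centred before the effect is
#'   applied, so the panel stays calibrated to the reference level 100).
#'   Recognised names: \code{ln_phn}, \code{ln_pop}, \code{physicians},
#'   \code{clinics}, \code{hospitals}, \code{welfare}.
#' @param prior_shape,prior_rate gamma hyperparameters of the municipal
#'   relative-risk distribution; scalars or vectors of length
#'   \code{n_prefectures}.
#' @param pref_sd SD of the prefecture-level log-risk shift (clusters risks by
#'   prefecture).
#' @param spatial_sd marginal-scale SD of the ICAR spatial field (0 disables).
#' @param hetero_sd SD of unstructured log-risk noise per stratum-period.
#' @param time_effect log-scale secular change in mortality between the first
#'   and second period (negative = decline).
#' @param adjacency \code{"grid"} (default, guaranteed connected) or
#'   \code{"geometric"} (random geometric graph, may need densification).
#' @param sexes,causes labels of the sex and cause-of-death strata.
#' @param seed integer seed; a fixed seed makes the output byte-identical.
#'
#' @return A list of class \code{phn_generator_config}.
#' @seealso [default_config()], [generate_panel()]
#' @export
generator_config <- function(n_municipalities = 1601,
                             n_prefectures = 47,
                             n_age_groups = 18,
                             periods = c("2010", "2015"),
                             period_years = 5,
                             pop_lognormal_mu = 10.2025,
                             pop_lognormal_sigma = 0.9961,
                             phn_intercept = 8.7,
                             phn_slope = 0.5,
                             phn_noise_sd = 0.3,
                             true_beta = c(ln_phn = -0.05),
                             prior_shape = 70,
                             prior_rate = 70,
                             pref_sd = 0.05,
                             spatial_sd = 0.05,
                             hetero_sd = 0.03,
                             time_effect = -0.08,
                             adjacency = c("grid", "geometric"),
                             sexes = c("male", "female"),
                             causes = c("all_causes", "malignant_neoplasms",
                                        "heart_disease",
                                        "cerebrovascular_disease"),
                             seed = 1L) {
  adjacency <- match.arg(adjacency)
  cfg <- list(
    n_municipalities = as.integer(n_municipalities),
    n_prefectures = as.integer(n_prefectures),
    n_age_groups = as.integer(n_age_groups),
    periods = as.character(periods),
    period_years = period_years,
    pop_lognormal_mu = pop_lognormal_mu,
    pop_lognormal_sigma = pop_lognormal_sigma,
    phn_intercept = phn_intercept,
    phn_slope = phn_slope,
    phn_noise_sd = phn_noise_sd,
    true_beta = true_beta,
    prior_shape = prior_shape,
    prior_rate = prior_rate,
    pref_sd = pref_sd,
    spatial_sd = spatial_sd,
    hetero_sd = hetero_sd,
    time_effect = time_effect,
    adjacency = adjacency,
    sexes = as.character(sexes),
    causes = as.character(causes),
    seed = as.integer(seed)
  )
  class(cfg) <- "phn_generator_config"
  validate_generator_config(cfg)
  cfg
}

#' Default generator configuration
#'
#' The configuration whose generated panel matches the study's descriptive
#' magnitudes: 1,601 municipalities, 47 prefectures, periods 2010 and 2015,
#' populations with natural-scale mean near 44,300 and SD near 57,700, and
#' around 43 PHNs per 100,000 population overall (around 85 in municipalities
#' below 10,000 inhabitants).
#'
#' @param ... overrides passed to [generator_config()].
#' @return A \code{phn_generator_config}.
#' @export
default_config <- function(...) {
  generator_config(...)
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "phn_generator_config"))
  counts <- c(cfg$n_municipalities, cfg$n_prefectures, cfg$n_age_groups)
  if (any(counts < 1L)) {
    stop("invalid config: counts must be >= 1", call. = FALSE)
  }
  if (cfg$n_prefectures > cfg$n_municipalities) {
    stop("invalid config: more prefectures than municipalities", call. = FALSE)
  }
  if (cfg$pop_lognormal_sigma < 0 || !is.finite(cfg$pop_lognormal_mu)) {
    stop("invalid config: non-positive population parameters", call. = FALSE)
  }
  sds <- c(cfg$phn_noise_sd, cfg$pref_sd, cfg$spatial_sd, cfg$hetero_sd)
  if (any(sds < 0)) stop("invalid config: sds must be >= 0", call. = FALSE)
  if (cfg$phn_slope < 0) {
    stop("invalid config: phn_slope must be >= 0", call. = FALSE)
  }
  if (any(cfg$prior_shape < 0) || any(cfg$prior_rate < 0)) {
    stop("invalid config: gamma hyperparameters must be >= 0", call. = FALSE)
  }
  if (length(cfg$periods) < 1L) {
    stop("invalid config: at least one period required", call. = FALSE)
  }
  invisible(cfg)
}

#' Fixed national age pyramid
#'
#' One shared pyramid of five-year age-group proportions, shaped like an aged
#' national population (modal mass at late-middle age). Used for every
#' municipality; the study standardizes by age group but individual municipal
#' pyramids are not modelled.
#'
#' @param n_age_groups number of five-year groups (first is 0-4).
#' @param old_age_tilt optional log-linear tilt towards older groups
#'   (0 = none); positive values age the pyramid.
#' @return numeric vector of proportions summing to 1.
#' @export
age_pyramid <- function(n_age_groups = 18, old_age_tilt = 0) {
  base <- c(0.042, 0.044, 0.047, 0.048, 0.051, 0.058, 0.064, 0.073,
            0.080, 0.068, 0.060, 0.062, 0.078, 0.071, 0.055, 0.045,
            0.031, 0.023)
  if (n_age_groups <= length(base)) {
    p <- base[seq_len(n_age_groups)]
  } else {
    p <- c(base, rep(base[length(base)] / 2, n_age_groups - length(base)))
  }
  if (old_age_tilt != 0) {
    p <- p * exp(old_age_tilt * (seq_along(p) - 1) / (length(p) - 1))
  }
  p / sum(p)
}

# labels stay syntactic R names so panel columns survive a text round-trip
age_group_labels <- function(n_age_groups) {
  lo <- (seq_len(n_age_groups) - 1L) * 5L
  labs <- sprintf("%02d_%02d", lo, lo + 4L)
  labs[n_age_groups] <- sprintf("%02dup", lo[n_age_groups])
  labs
}

age_midpoints <- function(n_age_groups) {
  (seq_len(n_age_groups) - 1L) * 5 + 2.5
}

#' Reference age-specific mortality rate table
#'
#' Builds a synthetic base-year reference rate table (per person-year) by
#' five-year age group, sex and cause. Rates follow a Gompertz curve in age
#' with the level of each sex-cause schedule calibrated so that, under the
#' fixed national pyramid, the implied crude death rate matches a target of
#' the magnitude seen in Japanese municipal data (five-year pooled counts
#' around 3,200 per 100,000 for male all-cause mortality).
#'
#' @param config a \code{phn_generator_config}.
#' @param gompertz_b log-slope of mortality in age (per year).
#' @return data.frame with columns age_group, sex, cause, rate and attribute
#'   \code{base_year}.
#' @export
reference_rate_table <- function(config = default_config(),
                                 gompertz_b = 0.09) {
  # target crude annual rates (per person-year), by sex then cause
  targets <- list(
    male = c(all_causes = 0.00643, malignant_neoplasms = 0.00203,
             heart_disease = 0.00092, cerebrovascular_disease = 0.00064),
    female = c(all_causes = 0.00597, malignant_neoplasms = 0.00133,
               heart_disease = 0.00110, cerebrovascular_disease = 0.00071)
  )
  pyramid <- age_pyramid(config$n_age_groups)
  mids <- age_midpoints(config$n_age_groups)
  shape <- exp(gompertz_b * mids)
  denom <- sum(pyramid * shape)
  out <- expand.grid(age_group = age_group_labels(config$n_age_groups),
                     sex = config$sexes, cause = config$causes,
                     stringsAsFactors = FALSE)
  rate <- numeric(nrow(out))
  for (i in seq_len(nrow(out))) {
    sx <- out$sex[i]
    tgt <- if (sx %in% names(targets)) targets[[sx]] else targets[[1L]]
    cr <- if (out$cause[i] %in% names(tgt)) tgt[[out$cause[i]]] else
      mean(unlist(targets)) / 2
    k <- cr / denom
    a <- match(out$age_group[i], age_group_labels(config$n_age_groups))
    rate[i] <- k * shape[a]
  }
  out$rate <- rate
  attr(out, "base_year") <- config$periods[1L]
  out
}

#' Rectangular-grid adjacency over municipalities
#'
#' Arranges n nodes on a near-square grid and connects rook neighbours;
#' the result is always connected, as the intrinsic CAR prior requires.
#'
#' @param n number of nodes.
#' @return data.frame with columns \code{from}, \code{to} (from < to).
#' @export
grid_adjacency <- function(n) {
  stopifnot(n >= 1)
  nc <- max(1L, floor(sqrt(n)))
  row <- (seq_len(n) - 1L) %/% nc
  col <- (seq_len(n) - 1L) %% nc
  right <- which(col < nc - 1L & seq_len(n) + 1L <= n)
  down <- which(seq_len(n) + nc <= n)
  edges <- rbind(
    cbind(right, right + 1L),
    cbind(down, down + nc)
  )
  data.frame(from = as.integer(edges[, 1L]), to = as.integer(edges[, 2L]))
}

#' Random-geometric adjacency
#'
#' Uniform points in the unit square joined below a connection radius; edges
#' are added from a minimum spanning tree of the point distances when the raw
#' graph is disconnected, so the ICAR component is always well defined on one
#' component.
#'
#' @param n number of nodes.
#' @param radius connection radius (default scales as \code{sqrt(2/n)}).
#' @return data.frame with columns \code{from}, \code{to}.
#' @export
geometric_adjacency <- function(n, radius = sqrt(2 / n)) {
  xy <- cbind(stats::runif(n), stats::runif(n))
  d <- as.matrix(stats::dist(xy))
  adj <- d <= radius & upper.tri(d)
  idx <- which(adj, arr.ind = TRUE)
  edges <- data.frame(from = as.integer(idx[, 1L]), to = as.integer(idx[, 2L]))
  g <- igraph::graph_from_edgelist(as.matrix(edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  if (igraph::components(g)$no > 1L) {
    mst <- igraph::mst(igraph::graph_from_adjacency_matrix(
      d, mode = "undirected", weighted = TRUE))
    me <- igraph::as_edgelist(mst, names = FALSE)
    extra <- data.frame(from = pmin(me[, 1L], me[, 2L]),
                        to = pmax(me[, 1L], me[, 2L]))
    edges <- unique(rbind(edges, extra))
  }
  edges[order(edges$from, edges$to), , drop = FALSE]
}

#' Sample an intrinsic CAR field
#'
#' Draws one realization of the ICAR density exp(-(1/(2 sd^2))
#' sum_{i~j}(phi_i - phi_j)^2) restricted to the sum-to-zero subspace of each
#' connected component, via the eigen-decomposition of the graph Laplacian:
#' phi = sum_k v_k z_k sd / sqrt(lambda_k) over eigenpairs with lambda_k > 0.
#' Exact and reproducible under a fixed seed.
#'
#' @param edges two-column edge data.frame.
#' @param n number of nodes.
#' @param spatial_sd scale of the field (0 returns all zeros).
#' @return numeric vector of length n summing to zero per component.
#' @export
sample_icar_field <- function(edges, n, spatial_sd) {
  if (spatial_sd == 0 || n == 1L) return(numeric(n))
  L <- matrix(0, n, n)
  for (k in seq_len(nrow(edges))) {
    i <- edges$from[k]; j <- edges$to[k]
    L[i, j] <- L[i, j] - 1
    L[j, i] <- L[j, i] - 1
    L[i, i] <- L[i, i] + 1
    L[j, j] <- L[j, j] + 1
  }
  eg <- eigen(L, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  z <- stats::rnorm(sum(pos))
  drop(eg$vectors[, pos, drop = FALSE] %*%
         (z * spatial_sd / sqrt(eg$values[pos])))
}

# contiguous prefecture blocks along grid order, sizes as equal as possible
assign_prefectures <- function(n, n_pref) {
  sizes <- rep(n %/% n_pref, n_pref)
  extra <- n %% n_pref
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(n_pref), times = sizes)
}

#' Generate a synthetic municipality panel
#'
#' Simulates the full data structure the analysis consumes: a mortality panel
#' (one row per municipality x sex x cause x period carrying observed deaths
#' and age-group populations), a healthcare-resource table, an adjacency edge
#' list, a base-year reference rate table and a ground-truth record.
#'
#' The generative model: populations are log-normal; each municipality's
#' age structure follows the shared national pyramid; expected deaths are
#' \code{e = period_years * sum_a pop_a * rate_a}; the true relative risk is
#' \code{theta = r * exp(gamma_pref + sum_j beta_j (x_j - mean(x_j)) + phi +
#' eps + time_effect * t)} with \code{r ~ Gamma(shape, rate)} per stratum,
#' \code{phi} an ICAR field over the adjacency graph and \code{eps} white
#' noise; observed deaths are \code{o ~ Poisson(e * theta)}. PHN density
#' follows \code{ln(PHN per 100k) = phn_intercept - phn_slope ln(pop) +
#' noise}; all per-100k denominators use the first-period population in both
#' periods, matching the analysis convention.
#'
#' @param config a \code{phn_generator_config}.
#' @return list with elements \code{panel}, \code{resources},
#'   \code{adjacency}, \code{rates}, \code{truth}.
#' @export
generate_panel <- function(config = default_config()) {
  validate_generator_config(config)
  set.seed(config$seed)
  n <- config$n_municipalities
  n_age <- config$n_age_groups
  periods <- config$periods
  n_per <- length(periods)

  edges <- switch(config$adjacency,
                  grid = grid_adjacency(n),
                  geometric = geometric_adjacency(n))
  pref <- assign_prefectures(n, config$n_prefectures)

  pop1 <- stats::rlnorm(n, config$pop_lognormal_mu, config$pop_lognormal_sigma)
  pop_mult <- if (n_per > 1L) exp(stats::rnorm(n, -0.02, 0.02)) else NULL
  pop <- matrix(pop1, n, n_per)
  if (n_per > 1L) for (t in 2:n_per) pop[, t] <- pop[, t - 1L] * pop_mult

  pyramid <- age_pyramid(n_age)
  male_share <- 0.487

  # healthcare resources, per 100,000 of the first-period population
  ln_pop1 <- log(pop1)
  phn1 <- exp(config$phn_intercept - config$phn_slope * ln_pop1 +
                stats::rnorm(n, 0, config$phn_noise_sd))
  phn_change <- exp(stats::rnorm(n, 0.05, 0.25))
  part_frac <- stats::rbeta(n, 1.5, 45)
  phys1 <- exp(1.9 + 0.30 * ln_pop1 + stats::rnorm(n, 0, 0.45))
  clin1 <- exp(5.49 - 0.12 * ln_pop1 + stats::rnorm(n, 0, 0.35))
  hosp1 <- exp(2.78 - 0.08 * ln_pop1 + stats::rnorm(n, 0, 0.40))
  welf1 <- exp(6.39 - 0.42 * ln_pop1 + stats::rnorm(n, 0, 0.50))

  res_rows <- vector("list", n_per)
  for (t in seq_len(n_per)) {
    if (t == 1L) {
      phn <- phn1; phys <- phys1; clin <- clin1; hosp <- hosp1; welf <- welf1
      frac <- part_frac
    } else {
      phn <- phn1 * phn_change^(t - 1L)
      phys <- phys1 * exp(stats::rnorm(n, 0.02, 0.12))
      clin <- clin1 * exp(stats::rnorm(n, 0.00, 0.08))
      hosp <- hosp1 * exp(stats::rnorm(n, -0.04, 0.08))
      welf <- welf1 * exp(stats::rnorm(n, 0.12, 0.20))
      # part-time share drifts on the logit scale, so the full/part split
      # carries independent between-period variation
      frac <- stats::plogis(stats::qlogis(part_frac) +
                              stats::rnorm(n, 0, 0.4))
    }
    res_rows[[t]] <- data.frame(
      municipality_id = seq_len(n),
      prefecture_id = pref,
      period = periods[t],
      population = pop[, t],
      population_base = pop1,
      phn_all_per100k = phn,
      phn_ft_per100k = phn * (1 - frac),
      phn_pt_per100k = phn * frac,
      physicians_per100k = phys,
      clinics_per100k = clin,
      hospitals_per100k = hosp,
      welfare_per100k = welf
    )
  }
  resources <- do.call(rbind, res_rows)
  resources <- resources[order(resources$municipality_id,
                               resources$period), , drop = FALSE]
  rownames(resources) <- NULL

  rates <- reference_rate_table(config)

  # spatial and prefecture components of the true log relative risk
  phi <- sample_icar_field(edges, n, config$spatial_sd)
  gamma_pref <- if (config$pref_sd > 0)
    stats::rnorm(config$n_prefectures, 0, config$pref_sd) else
      numeric(config$n_prefectures)

  # covariate effects on log risk, applied to centred covariates
  covs <- function(t) {
    r <- res_rows[[t]]
    cbind(ln_phn = log(r$phn_all_per100k), ln_pop = log(r$population),
          physicians = r$physicians_per100k, clinics = r$clinics_per100k,
          hospitals = r$hospitals_per100k, welfare = r$welfare_per100k)
  }
  beta <- config$true_beta
  cov_means <- NULL
  lin <- matrix(0, n, n_per)
  if (length(beta) > 0) {
    allcov <- do.call(rbind, lapply(seq_len(n_per), covs))
    cov_means <- colMeans(allcov)
    for (t in seq_len(n_per)) {
      x <- covs(t)
      for (nm in names(beta)) {
        if (!nm %in% colnames(x)) {
          stop("unknown covariate in true_beta: ", nm, call. = FALSE)
        }
        lin[, t] <- lin[, t] + beta[[nm]] * (x[, nm] - cov_means[[nm]])
      }
    }
  }

  shape <- rep_len(config$prior_shape, config$n_prefectures)
  rate_g <- rep_len(config$prior_rate, config$n_prefectures)

  grid <- expand.grid(municipality_id = seq_len(n), sex = config$sexes,
                      cause = config$causes, stringsAsFactors = FALSE)
  n_strat <- nrow(grid)
  # base gamma relative risk per municipality x sex x cause
  r_base <- stats::rgamma(n_strat, shape = shape[pref[grid$municipality_id]],
                          rate = rate_g[pref[grid$municipality_id]])

  labs <- age_group_labels(n_age)
  rate_lookup <- array(rates$rate,
                       dim = c(n_age, length(config$sexes),
                               length(config$causes)),
                       dimnames = list(labs, config$sexes, config$causes))

  panel_rows <- vector("list", n_per)
  for (t in seq_len(n_per)) {
    m <- grid$municipality_id
    sex_share <- ifelse(grid$sex == "male", male_share, 1 - male_share)
    pop_age <- outer(pop[m, t] * sex_share, pyramid)   # n_strat x n_age
    rmat <- sapply(seq_len(n_age), function(a)
      rate_lookup[cbind(a, match(grid$sex, config$sexes),
                        match(grid$cause, config$causes))])
    e <- config$period_years * rowSums(pop_age * rmat)
    eps <- if (config$hetero_sd > 0)
      stats::rnorm(n_strat, 0, config$hetero_sd) else numeric(n_strat)
    theta <- r_base * exp(gamma_pref[pref[m]] + lin[m, t] + phi[m] + eps +
                            config$time_effect * (t - 1L))
    o <- stats::rpois(n_strat, e * theta)
    pa <- round(pop_age)
    colnames(pa) <- paste0("pop_", labs)
    panel_rows[[t]] <- cbind(
      data.frame(municipality_id = m, prefecture_id = pref[m],
                 sex = grid$sex, cause = grid$cause, period = periods[t],
                 o = o, theta_true = theta),
      as.data.frame(pa)
    )
  }
  panel <- do.call(rbind, panel_rows)
  theta_truth <- panel[, c("municipality_id", "sex", "cause", "period",
                           "theta_true")]
  names(theta_truth)[5L] <- "theta"
  panel$theta_true <- NULL
  panel <- panel[order(panel$municipality_id, panel$sex, panel$cause,
                       panel$period), , drop = FALSE]
  rownames(panel) <- NULL

  truth <- list(
    true_beta = beta,
    covariate_means = cov_means,
    theta = theta_truth,
    phi = phi,
    prefecture_effect = gamma_pref,
    prior_shape = shape,
    prior_rate = rate_g,
    config = config
  )

  list(panel = panel, resources = resources, adjacency = edges,
       rates = rates, truth = truth)
}
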