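#' Expected deaths by indirect standardization
#'
#' Applies reference age-specific mortality rates to an age-structured
#' population: \code{e = years * sum_a pop_a * rate_a}. Rates are per
#' person-year; \code{years} is the length of the pooling window (five years
#' of death counts per census period in this study).
#'
#' @param pop_by_age named numeric vector of person counts per age group.
#' @param rates named numeric vector of reference rates per person-year,
#'   covering every age group of \code{pop_by_age}.
#' @param years pooling window length in years (>= 1).
#' @return expected deaths (person-equivalents).
#' @export
expected_deaths <- function(pop_by_age, rates, years = 1) {
  stopifnot(years >= 1)
  if (is.null(names(pop_by_age)) || is.null(names(rates))) {
    if (length(pop_by_age) != length(rates)) {
      stop("age grouping mismatch between population and rates",
           call. = FALSE)
    }
    r <- rates
  } else {
    miss <- setdiff(names(pop_by_age), names(rates))
    if (length(miss) > 0) {
      stop("age grouping mismatch: no reference rate for ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    r <- rates[names(pop_by_age)]
  }
  if (any(pop_by_age < 0) || any(r < 0)) {
    stop("negative population or rate", call. = FALSE)
  }
  if (all(pop_by_age == 0)) {
    warning("all-zero population: expected deaths are 0")
    return(0)
  }
  years * sum(pop_by_age * r)
}

#' Raw standardized mortality ratio
#'
#' \code{100 * o / e}: observed over expected deaths on the conventional
#' x100 scale (the base-year national value is 100).
#'
#' @param o observed deaths (>= 0).
#' @param e expected deaths (> 0).
#' @return SMR on the x100 scale.
#' @export
raw_smr <- function(o, e) {
  if (any(e <= 0)) stop("expected deaths must be positive", call. = FALSE)
  if (any(o < 0)) stop("observed deaths must be non-negative", call. = FALSE)
  100 * o / e
}

#' Moment-estimated gamma prior for small-area relative risks
#'
#' Marshall's precision-weighted moment estimator for the Poisson-Gamma
#' model. With areas i holding observed deaths o_i and expected deaths e_i:
#' \deqn{\hat m = \sum o_i / \sum e_i}
#' \deqn{\hat v = \frac{\sum_i e_i (o_i/e_i - \hat m)^2}{\sum_i e_i}
#'   - \hat m / \bar e, \qquad \bar e = \sum e_i / n.}
#' If \eqn{\hat v > 0} the gamma prior has rate \eqn{\nu = \hat m/\hat v} and
#' shape \eqn{\alpha = \hat m^2/\hat v}; otherwise the between-area variance
#' is indistinguishable from Poisson noise and the prior is degenerate at the
#' group mean (complete shrinkage).
#'
#' @param o,e numeric vectors of observed and expected deaths (>= 2 areas,
#'   all e > 0).
#' @param label optional group label carried in the result.
#' @return list of class \code{gamma_prior}: shape, rate, mean, vhat,
#'   degenerate, n, label.
#' @export
fit_gamma_prior_moments <- function(o, e, label = NULL) {
  if (length(o) != length(e)) stop("o and e lengths differ", call. = FALSE)
  if (length(o) < 2L) {
    stop("insufficient data: need at least 2 areas to fit a prior",
         call. = FALSE)
  }
  if (any(e <= 0)) stop("all expected deaths must be positive", call. = FALSE)
  if (any(o < 0)) stop("observed deaths must be non-negative", call. = FALSE)
  m <- sum(o) / sum(e)
  ebar <- mean(e)
  v <- sum(e * (o / e - m)^2) / sum(e) - m / ebar
  if (v > 0) {
    prior <- list(shape = m^2 / v, rate = m / v, mean = m, vhat = v,
                  degenerate = FALSE, n = length(o), label = label)
  } else {
    prior <- list(shape = NA_real_, rate = NA_real_, mean = m, vhat = v,
                  degenerate = TRUE, n = length(o), label = label)
  }
  class(prior) <- "gamma_prior"
  prior
}

#' Empirical Bayes posterior-mean SMR
#'
#' Poisson likelihood o ~ Poisson(e * theta) with conjugate gamma prior
#' theta ~ Gamma(shape alpha, rate nu) gives posterior
#' Gamma(o + alpha, e + nu); the EBSMR is 100 times its mean,
#' \code{100 * (o + alpha) / (e + nu)}, equivalently the shrinkage form
#' \code{w * smr_raw + (1 - w) * 100 * m} with weight \code{w = e/(e + nu)}.
#' A degenerate prior shrinks completely to the group mean.
#'
#' @param o observed deaths (>= 0).
#' @param e expected deaths (> 0).
#' @param prior a \code{gamma_prior} from [fit_gamma_prior_moments()] (or a
#'   list with shape, rate, mean, degenerate).
#' @return list: smr_raw, ebsmr (both x100 scale), shrinkage_w, degenerate.
#' @export
eb_posterior_smr <- function(o, e, prior) {
  if (any(o < 0)) stop("observed deaths must be non-negative", call. = FALSE)
  if (any(e <= 0)) stop("expected deaths must be positive", call. = FALSE)
  smr <- 100 * o / e
  if (isTRUE(prior$degenerate)) {
    list(smr_raw = smr, ebsmr = rep_len(100 * prior$mean, length(o)),
         shrinkage_w = rep_len(0, length(o)), degenerate = TRUE)
  } else {
    stopifnot(prior$shape > 0, prior$rate > 0)
    w <- e / (e + prior$rate)
    list(smr_raw = smr, ebsmr = 100 * (o + prior$shape) / (e + prior$rate),
         shrinkage_w = w, degenerate = FALSE)
  }
}

#' EBSMR table for a municipality panel
#'
#' Computes expected deaths, raw SMRs and empirical Bayes SMRs for every
#' municipality x sex x cause x period stratum. The gamma prior is
#' moment-fitted within grouping x sex x cause x period (grouping defaults to
#' prefecture, mirroring a prior determined "from the distribution of SMRs
#' per prefecture"); groups smaller than \code{min_group} fall back to the
#' national pool for that sex x cause x period, and the fallback is recorded.
#' The same base-year reference rates are applied to both periods so EBSMRs
#' are longitudinally comparable.
#'
#' @param panel mortality panel as produced by [generate_panel()] (columns
#'   municipality_id, prefecture_id, sex, cause, period, o, pop_<age> ...).
#' @param rates reference rate table (age_group, sex, cause, rate).
#' @param period_years pooling window length in years.
#' @param grouping column name used to fit priors (default
#'   \code{"prefecture_id"}); \code{NULL} pools nationally.
#' @param min_group minimum areas per group before falling back to the
#'   national pool.
#' @return data.frame with columns municipality_id, prefecture_id, sex,
#'   cause, period, o, e, smr_raw, ebsmr, shrinkage_w, prior_shape,
#'   prior_rate, degenerate, prior_fallback.
#' @export
compute_ebsmr_table <- function(panel, rates, period_years = 5,
                                grouping = "prefecture_id", min_group = 5L) {
  pop_cols <- grep("^pop_", names(panel), value = TRUE)
  if (length(pop_cols) == 0L) stop("panel has no pop_<age> columns",
                                   call. = FALSE)
  age_labs <- sub("^pop_", "", pop_cols)
  miss <- setdiff(age_labs, unique(rates$age_group))
  if (length(miss) > 0) {
    stop("age grouping mismatch: no reference rate for ",
         paste(miss, collapse = ", "), call. = FALSE)
  }

  # expected deaths: vectorized over rows of the panel
  key <- interaction(rates$age_group, rates$sex, rates$cause, drop = FALSE)
  rate_map <- stats::setNames(rates$rate, as.character(key))
  e <- numeric(nrow(panel))
  popm <- as.matrix(panel[, pop_cols, drop = FALSE])
  for (a in seq_along(age_labs)) {
    k <- paste(age_labs[a], panel$sex, panel$cause, sep = ".")
    e <- e + popm[, a] * rate_map[k]
  }
  e <- period_years * e

  out <- panel[, c("municipality_id", "prefecture_id", "sex", "cause",
                   "period", "o")]
  out$e <- as.numeric(e)
  ok <- out$e > 0
  if (any(!ok)) {
    warning(sum(!ok), " strata with zero expected deaths excluded from EB ",
            "estimation")
    out <- out[ok, , drop = FALSE]
  }

  cell <- interaction(out$sex, out$cause, out$period, drop = TRUE)
  out$smr_raw <- 100 * out$o / out$e
  out$ebsmr <- NA_real_
  out$shrinkage_w <- NA_real_
  out$prior_shape <- NA_real_
  out$prior_rate <- NA_real_
  out$degenerate <- NA
  out$prior_fallback <- FALSE

  for (cl in levels(cell)) {
    rows <- which(cell == cl)
    national <- NULL
    grp <- if (is.null(grouping)) rep(1L, length(rows)) else
      out[[grouping]][rows]
    for (g in unique(grp)) {
      idx <- rows[grp == g]
      fallback <- length(idx) < min_group
      if (fallback) {
        if (is.null(national)) {
          national <- fit_gamma_prior_moments(out$o[rows], out$e[rows],
                                              label = paste0(cl, ":national"))
        }
        prior <- national
      } else {
        prior <- fit_gamma_prior_moments(out$o[idx], out$e[idx],
                                         label = paste0(cl, ":", g))
      }
      eb <- eb_posterior_smr(out$o[idx], out$e[idx], prior)
      out$ebsmr[idx] <- eb$ebsmr
      out$shrinkage_w[idx] <- eb$shrinkage_w
      out$prior_shape[idx] <- prior$shape
      out$prior_rate[idx] <- prior$rate
      out$degenerate[idx] <- prior$degenerate
      out$prior_fallback[idx] <- fallback
    }
  }
  rownames(out) <- NULL
  out
}
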