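#' Build first-differenced rows for the panel model
#'
#' Joins the EBSMR table to the resource table and, per municipality x sex x
#' cause, computes the change in EBSMR between the two periods (dy), the
#' difference of natural logs of PHN density and of population, and plain
#' differences of the other per-100k resource counts. Per-100k denominators
#' are taken as supplied (the resource table already uses the first-period
#' population for both periods). Baseline (first-period) population and
#' EBSMR are carried along for stratified analyses.
#'
#' @param ebsmr_table output of [compute_ebsmr_table()].
#' @param resources resource table from [generate_panel()].
#' @param zero_phn \code{"error"} (default) or \code{"offset"}: a PHN density
#'   of zero in either period is an error, or is replaced by the smallest
#'   positive observed value with a warning.
#' @return data.frame, one row per municipality x sex x cause: dy, d_ln_phn,
#'   d_ln_phn_ft, d_ln_phn_pt, d_ln_pop, d_physicians, d_clinics,
#'   d_hospitals, d_welfare, baseline_pop, baseline_ebsmr.
#' @export
build_first_difference <- function(ebsmr_table, resources,
                                   zero_phn = c("error", "offset")) {
  zero_phn <- match.arg(zero_phn)
  periods <- sort(unique(ebsmr_table$period))
  if (length(periods) != 2L) {
    stop("first differencing requires exactly two periods; found ",
         length(periods), call. = FALSE)
  }
  p1 <- periods[1L]; p2 <- periods[2L]

  logdiff <- function(x2, x1, what, ids) {
    zero <- which(x1 <= 0 | x2 <= 0)
    if (length(zero) > 0) {
      if (zero_phn == "error" && grepl("phn", what)) {
        stop("zero ", what, " in municipality ",
             paste(utils::head(ids[zero], 5L), collapse = ", "),
             "; set zero_phn = 'offset' to apply a continuity correction",
             call. = FALSE)
      }
      off <- min(c(x1[x1 > 0], x2[x2 > 0]))
      warning("zero ", what, " in ", length(zero),
              " municipalities; continuity offset ", signif(off, 3),
              " applied")
      x1 <- x1 + off; x2 <- x2 + off
    }
    log(x2) - log(x1)
  }

  r1 <- resources[resources$period == p1, , drop = FALSE]
  r2 <- resources[resources$period == p2, , drop = FALSE]
  r1 <- r1[order(r1$municipality_id), ]
  r2 <- r2[order(r2$municipality_id), ]
  stopifnot(identical(r1$municipality_id, r2$municipality_id))
  ids <- r1$municipality_id

  rd <- data.frame(
    municipality_id = ids,
    prefecture_id = r1$prefecture_id,
    d_ln_phn = logdiff(r2$phn_all_per100k, r1$phn_all_per100k,
                       "phn_all_per100k", ids),
    d_ln_phn_ft = logdiff(r2$phn_ft_per100k, r1$phn_ft_per100k,
                          "phn_ft_per100k", ids),
    d_ln_phn_pt = logdiff(r2$phn_pt_per100k, r1$phn_pt_per100k,
                          "phn_pt_per100k", ids),
    d_ln_pop = log(r2$population) - log(r1$population),
    d_physicians = r2$physicians_per100k - r1$physicians_per100k,
    d_clinics = r2$clinics_per100k - r1$clinics_per100k,
    d_hospitals = r2$hospitals_per100k - r1$hospitals_per100k,
    d_welfare = r2$welfare_per100k - r1$welfare_per100k,
    baseline_pop = r1$population
  )

  e1 <- ebsmr_table[ebsmr_table$period == p1,
                    c("municipality_id", "sex", "cause", "ebsmr")]
  e2 <- ebsmr_table[ebsmr_table$period == p2,
                    c("municipality_id", "sex", "cause", "ebsmr")]
  names(e1)[4L] <- "baseline_ebsmr"
  names(e2)[4L] <- "ebsmr_2"
  y <- merge(e1, e2, by = c("municipality_id", "sex", "cause"))
  y$dy <- y$ebsmr_2 - y$baseline_ebsmr
  y$ebsmr_2 <- NULL

  out <- merge(y, rd, by = "municipality_id")
  bad <- !stats::complete.cases(out) |
    !apply(out[, sapply(out, is.numeric), drop = FALSE], 1L,
           function(z) all(is.finite(z)))
  if (any(bad)) {
    warning(sum(bad), " rows with non-finite differences dropped")
    out <- out[!bad, , drop = FALSE]
  }
  out <- out[order(out$municipality_id, out$sex, out$cause), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' No-intercept linear mixed model by maximum likelihood
#'
#' Fits \code{y ~ 0 + X + (1 | group)} by full maximum likelihood (not REML):
#' a no-intercept linear model for the first-differenced outcome with a
#' single random-intercept variance component for the grouping factor
#' (prefecture). Coefficient inference uses Wald tests; by default the
#' reference distribution is standard normal, with a t reference on
#' \code{n - ncol(X)} degrees of freedom behind a flag. AIC counts the fixed
#' effects plus both variance components.
#'
#' @param y numeric outcome vector.
#' @param X numeric design matrix without an intercept column.
#' @param groups grouping factor (one random intercept).
#' @param wald_df \code{"normal"} (default) or \code{"residual"}.
#' @return list of class \code{lmm_fit}: coefficients (data.frame with
#'   estimate, se, statistic, p), sigma2_u, sigma2_e, loglik, aic, n,
#'   n_groups, converged, and the underlying \code{merMod} object.
#' @export
fit_lmm_ml <- function(y, X, groups, wald_df = c("normal", "residual")) {
  wald_df <- match.arg(wald_df)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  if (n <= ncol(X)) stop("need more observations than covariates",
                         call. = FALSE)
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  dat <- data.frame(.y = y, X, .g = factor(groups), check.names = FALSE)
  form <- stats::as.formula(paste(
    ".y ~ 0 +", paste0("`", colnames(X), "`", collapse = " + "),
    "+ (1 | .g)"))
  ctrl <- lme4::lmerControl(
    check.nobs.vs.nlev = "ignore", check.nobs.vs.nRE = "ignore",
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))
  fit <- suppressWarnings(
    lme4::lmer(form, data = dat, REML = FALSE, control = ctrl))
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  stat <- est / se
  p <- if (wald_df == "normal") 2 * stats::pnorm(-abs(stat)) else
    2 * stats::pt(-abs(stat), df = n - ncol(X))
  vc <- lme4::VarCorr(fit)
  sigma2_u <- as.numeric(vc$.g[1L, 1L])
  sigma2_e <- stats::sigma(fit)^2
  ll <- as.numeric(stats::logLik(fit))
  k <- ncol(X) + 2L   # fixed effects + two variance components
  conv <- length(fit@optinfo$conv$lme4) == 0L &&
    (is.null(fit@optinfo$conv$opt) || fit@optinfo$conv$opt == 0L)
  out <- list(
    coefficients = data.frame(term = names(est), estimate = as.numeric(est),
                              se = se, statistic = as.numeric(stat),
                              p = as.numeric(p), row.names = NULL),
    sigma2_u = sigma2_u, sigma2_e = sigma2_e,
    loglik = ll, aic = -2 * ll + 2 * k, n = n,
    n_groups = nlevels(dat$.g), converged = conv, model = fit)
  class(out) <- "lmm_fit"
  out
}

#' No-intercept least squares on the same design (no random effect)
#'
#' The comparison model without the prefecture random intercept, fitted by
#' maximum likelihood; its AIC is reported against the mixed model's.
#'
#' @inheritParams fit_lmm_ml
#' @return list: coefficients, sigma2_e, loglik, aic, n.
#' @export
fit_lm_no_re <- function(y, X, wald_df = c("normal", "residual")) {
  wald_df <- match.arg(wald_df)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  fit <- stats::lm(y ~ 0 + X)
  n <- length(y)
  est <- stats::coef(fit)
  sm <- summary(fit)
  se <- sm$coefficients[, 2L]
  stat <- est / se
  p <- if (wald_df == "normal") 2 * stats::pnorm(-abs(stat)) else
    2 * stats::pt(-abs(stat), df = n - ncol(X))
  rss <- sum(stats::resid(fit)^2)
  sigma2 <- rss / n                       # ML variance
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
  k <- ncol(X) + 1L
  list(coefficients = data.frame(term = colnames(X),
                                 estimate = as.numeric(est), se = se,
                                 statistic = as.numeric(stat),
                                 p = as.numeric(p), row.names = NULL),
       sigma2_e = sigma2, loglik = ll, aic = -2 * ll + 2 * k, n = n)
}

#' First-difference vs fixed-effects estimator identity
#'
#' With exactly two periods the no-intercept least-squares estimator on
#' first differences coincides numerically with the within (fixed-effects)
#' estimator on the stacked two-period data demeaned within municipality.
#' Computes both and reports the maximum absolute discrepancy.
#'
#' @param y2,X2 stacked outcome and design (2 rows per municipality).
#' @param unit vector of municipality ids aligning the stacked rows.
#' @return list: beta_fd, beta_fe, max_abs_diff.
#' @export
first_difference_equals_fixed_effects <- function(y2, X2, unit) {
  X2 <- as.matrix(X2)
  tab <- table(unit)
  if (any(tab != 2L)) {
    stop("unsupported design: every municipality needs exactly two periods",
         call. = FALSE)
  }
  u <- factor(unit)
  # within transformation
  ybar <- tapply(y2, u, mean)[u]
  Xbar <- apply(X2, 2L, function(col) tapply(col, u, mean)[u])
  yw <- y2 - ybar
  Xw <- X2 - Xbar
  if (qr(Xw)$rank < ncol(Xw)) {
    stop("design matrix is rank deficient after the within transformation",
         call. = FALSE)
  }
  beta_fe <- solve(crossprod(Xw), crossprod(Xw, yw))
  # first differences (second minus first occurrence per unit)
  first <- !duplicated(u)
  second <- duplicated(u)
  ord1 <- order(u[first]); ord2 <- order(u[second])
  dy <- y2[second][ord2] - y2[first][ord1]
  dX <- X2[second, , drop = FALSE][ord2, , drop = FALSE] -
    X2[first, , drop = FALSE][ord1, , drop = FALSE]
  beta_fd <- solve(crossprod(dX), crossprod(dX, dy))
  list(beta_fd = drop(beta_fd), beta_fe = drop(beta_fe),
       max_abs_diff = max(abs(beta_fd - beta_fe)))
}

#' No-intercept simple regression
#'
#' Bivariate regression through the origin: slope = sum(xy)/sum(x^2), with a
#' t test on n - 1 degrees of freedom.
#'
#' @param y,x numeric vectors.
#' @return list: slope, se, statistic, p, n.
#' @export
simple_regression_no_intercept <- function(y, x) {
  stopifnot(length(y) == length(x))
  sxx <- sum(x^2)
  if (sxx == 0) stop("x is identically zero", call. = FALSE)
  n <- length(x)
  slope <- sum(x * y) / sxx
  res <- y - slope * x
  se <- sqrt(sum(res^2) / (n - 1) / sxx)
  stat <- slope / se
  list(slope = slope, se = se, statistic = stat,
       p = 2 * stats::pt(-abs(stat), df = n - 1), n = n)
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j) where R^2_j is from regressing column j (with an
#' intercept) on the remaining columns. Exactly collinear columns are
#' returned as \code{Inf}.
#'
#' @param X numeric matrix with >= 2 columns.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("need at least 2 columns", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  out <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((X[, j] - mean(X[, j]))^2)
    if (ss_tot == 0) return(Inf)
    r2 <- 1 - ss_res / ss_tot
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1L))
  names(out) <- colnames(X)
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment,
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} n / j} clipped at 1, returned in the
#' input order.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return numeric vector of q-values.
#' @export
bh_qvalues <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Cohen's d with pooled standard deviation
#'
#' Standardized mean difference \code{(mean_a - mean_b) / s_pooled},
#' \code{s_pooled = sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a+n_b-2))}.
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @return Cohen's d; \code{NaN} with a warning when the pooled SD is zero.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("both groups need >= 2 values", call. = FALSE)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) {
    warning("pooled SD is zero: Cohen's d undefined")
    return(NaN)
  }
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Stratified mixed-model fits
#'
#' Splits the first-differenced rows at a threshold of a baseline field
#' (population 10,000 or baseline EBSMR 100 in the study design) and fits the
#' no-intercept mixed model independently in each stratum. Strata where the
#' mixed model fails fall back to the model without the random effect, with
#' the fallback recorded; empty strata are skipped with a warning.
#'
#' @param rows first-differenced rows from [build_first_difference()]
#'   (already restricted to one sex x cause series).
#' @param covariates character vector of covariate column names.
#' @param baseline_field column to stratify on (\code{"baseline_pop"} or
#'   \code{"baseline_ebsmr"}).
#' @param threshold cut point; strata are \code{< threshold} and
#'   \code{>= threshold}.
#' @param wald_df passed to [fit_lmm_ml()].
#' @return named list of fits (elements \code{low}, \code{high}), each with
#'   the stratum size and a \code{random_effect} flag.
#' @export
stratified_fits <- function(rows, covariates, baseline_field = "baseline_pop",
                            threshold = 10000, wald_df = "normal") {
  stopifnot(baseline_field %in% names(rows))
  strata <- list(low = rows[rows[[baseline_field]] < threshold, , drop = FALSE],
                 high = rows[rows[[baseline_field]] >= threshold, ,
                             drop = FALSE])
  out <- list()
  for (nm in names(strata)) {
    s <- strata[[nm]]
    if (nrow(s) == 0L) {
      warning("empty stratum '", nm, "' skipped")
      next
    }
    X <- as.matrix(s[, covariates, drop = FALSE])
    fit <- tryCatch(
      c(fit_lmm_ml(s$dy, X, s$prefecture_id, wald_df = wald_df),
        list(random_effect = TRUE)),
      error = function(err) {
        warning("mixed model failed in stratum '", nm,
                "'; refit without random effect (", conditionMessage(err), ")")
        c(fit_lm_no_re(s$dy, X, wald_df = wald_df),
          list(random_effect = FALSE))
      })
    fit$stratum <- nm
    fit$stratum_n <- nrow(s)
    out[[nm]] <- fit
  }
  out
}
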