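#' Study configuration
#'
#' Collects everything [run_study()] needs: the generator configuration (or
#' pre-built data), the sex and cause series to analyse, the model variants
#' to run, the study thresholds with their conventional values (population
#' size class 10,000; baseline EBSMR class 100; significance 0.05; q-value
#' reporting level 0.10; 1/1000 covariate scaling in the spatial model), and
#' sampler settings for the spatial model.
#'
#' @param generator a \code{phn_generator_config} (ignored when \code{data}
#'   is supplied).
#' @param data optional pre-built data list (elements panel, resources,
#'   adjacency, rates) as returned by [generate_panel()] or read from disk.
#' @param sexes,causes series to analyse (default: all in the data).
#' @param variants model variants to run; any of \code{"descriptive"},
#'   \code{"bivariate"}, \code{"adjusted"}, \code{"ftpt"},
#'   \code{"stratified"}, \code{"bym"}, \code{"bym_split"}.
#' @param pop_threshold population size-class boundary.
#' @param ebsmr_threshold baseline-EBSMR class boundary.
#' @param significance significance level for flags in the report.
#' @param q_report q-value reporting level.
#' @param min_group minimum prefecture group size for the EB prior.
#' @param bym list of sampler settings: chains, iter, warmup,
#'   prior_sd_beta.
#' @param seed master seed; per-fit seeds are derived from it.
#' @return list of class \code{phn_study_config}.
#' @export
study_config <- function(generator = default_config(),
                         data = NULL,
                         sexes = NULL, causes = NULL,
                         variants = c("descriptive", "bivariate", "adjusted",
                                      "ftpt", "stratified", "bym",
                                      "bym_split"),
                         pop_threshold = 10000,
                         ebsmr_threshold = 100,
                         significance = 0.05,
                         q_report = 0.10,
                         min_group = 5L,
                         bym = list(chains = 4L, iter = 3000L,
                                    warmup = 1500L, prior_sd_beta = 5),
                         seed = 1L) {
  stopifnot(pop_threshold > 0, ebsmr_threshold > 0, significance > 0,
            q_report > 0, length(variants) >= 1L)
  cfg <- list(generator = generator, data = data, sexes = sexes,
              causes = causes, variants = variants,
              pop_threshold = pop_threshold,
              ebsmr_threshold = ebsmr_threshold,
              significance = significance, q_report = q_report,
              min_group = as.integer(min_group),
              bym = utils::modifyList(list(chains = 4L, iter = 3000L,
                                           warmup = 1500L,
                                           prior_sd_beta = 5), bym),
              seed = as.integer(seed))
  class(cfg) <- "phn_study_config"
  cfg
}

#' Remove flagged municipalities
#'
#' Drops rows carrying any active exclusion flag (administrative exclusions
#' are modelled as boolean flag columns, by default every column whose name
#' starts with \code{exclude_}). Removal counts per flag are reported.
#'
#' @param panel data.frame.
#' @param flags flag column names; default all \code{exclude_*} columns.
#' @return the filtered panel (flag columns retained).
#' @export
filter_panel <- function(panel, flags = grep("^exclude_", names(panel),
                                             value = TRUE)) {
  if (length(flags) == 0L) return(panel)
  drop <- rep(FALSE, nrow(panel))
  for (f in flags) {
    active <- as.logical(panel[[f]]) %in% TRUE
    message(sum(active), " rows flagged by ", f)
    drop <- drop | active
  }
  out <- panel[!drop, , drop = FALSE]
  if (nrow(out) == 0L) warning("all rows excluded")
  rownames(out) <- NULL
  out
}

#' Descriptive table by municipality size class
#'
#' Means and SDs of baseline EBSMRs (per sex x cause) and healthcare
#' resources, overall and split at a baseline-population threshold, with
#' Cohen's d (small minus large class, pooled SD) per variable.
#'
#' @param ebsmr_table output of [compute_ebsmr_table()].
#' @param resources resource table.
#' @param pop_threshold size-class boundary (default 10,000).
#' @param period which period to describe (default the first).
#' @return data.frame: variable, mean_all, sd_all, n_small, mean_small,
#'   sd_small, n_large, mean_large, sd_large, cohens_d.
#' @export
describe_panel <- function(ebsmr_table, resources, pop_threshold = 10000,
                           period = NULL) {
  if (is.null(period)) period <- sort(unique(resources$period))[1L]
  res <- resources[resources$period == period, , drop = FALSE]
  res <- res[order(res$municipality_id), ]
  small <- res$population_base < pop_threshold
  vars <- list()
  eb <- ebsmr_table[ebsmr_table$period == period, , drop = FALSE]
  for (sx in unique(eb$sex)) for (cs in unique(eb$cause)) {
    v <- eb[eb$sex == sx & eb$cause == cs, ]
    v <- v[order(v$municipality_id), ]
    if (!identical(v$municipality_id, res$municipality_id)) {
      v <- v[match(res$municipality_id, v$municipality_id), ]
    }
    vars[[paste("ebsmr", sx, cs, sep = "_")]] <- v$ebsmr
  }
  for (rc in c("phn_all_per100k", "phn_ft_per100k", "phn_pt_per100k",
               "physicians_per100k", "clinics_per100k", "hospitals_per100k",
               "welfare_per100k", "population")) {
    vars[[rc]] <- res[[rc]]
  }
  rows <- lapply(names(vars), function(nm) {
    x <- vars[[nm]]
    a <- x[small]; b <- x[!small]
    d <- if (length(a) >= 2L && length(b) >= 2L)
      suppressWarnings(cohens_d(a, b)) else NA_real_
    if (length(a) < 2L || length(b) < 2L) {
      warning("size class with < 2 municipalities for ", nm,
              "; Cohen's d undefined")
    }
    data.frame(variable = nm, mean_all = mean(x), sd_all = stats::sd(x),
               n_small = length(a),
               mean_small = if (length(a)) mean(a) else NA_real_,
               sd_small = if (length(a) >= 2L) stats::sd(a) else NA_real_,
               n_large = length(b),
               mean_large = if (length(b)) mean(b) else NA_real_,
               sd_large = if (length(b) >= 2L) stats::sd(b) else NA_real_,
               cohens_d = d)
  })
  out <- do.call(rbind, rows)
  attr(out, "period") <- period
  attr(out, "pop_threshold") <- pop_threshold
  out
}

#' Change table by municipality size class
#'
#' Like [describe_panel()] but for between-period changes: EBSMR differences
#' and plain differences of resource densities (per-100k, baseline-population
#' denominator).
#'
#' @param rows output of [build_first_difference()] for all sex x cause.
#' @param resources resource table (for the resource changes).
#' @param pop_threshold size-class boundary.
#' @return data.frame like [describe_panel()].
#' @export
describe_changes <- function(rows, resources, pop_threshold = 10000) {
  periods <- sort(unique(resources$period))
  r1 <- resources[resources$period == periods[1L], ]
  r2 <- resources[resources$period == periods[2L], ]
  r1 <- r1[order(r1$municipality_id), ]
  r2 <- r2[order(r2$municipality_id), ]
  small <- r1$population_base < pop_threshold
  vars <- list()
  for (sx in unique(rows$sex)) for (cs in unique(rows$cause)) {
    v <- rows[rows$sex == sx & rows$cause == cs, ]
    v <- v[match(r1$municipality_id, v$municipality_id), ]
    vars[[paste("d_ebsmr", sx, cs, sep = "_")]] <- v$dy
  }
  for (rc in c("phn_all_per100k", "phn_ft_per100k", "phn_pt_per100k",
               "physicians_per100k", "clinics_per100k", "hospitals_per100k",
               "welfare_per100k", "population")) {
    vars[[paste0("d_", rc)]] <- r2[[rc]] - r1[[rc]]
  }
  rows_out <- lapply(names(vars), function(nm) {
    x <- vars[[nm]]
    a <- x[small]; b <- x[!small]
    d <- if (length(a) >= 2L && length(b) >= 2L)
      suppressWarnings(cohens_d(a, b)) else NA_real_
    data.frame(variable = nm, mean_all = mean(x, na.rm = TRUE),
               sd_all = stats::sd(x[!is.na(x)]),
               n_small = length(a), mean_small = mean(a, na.rm = TRUE),
               sd_small = stats::sd(a[!is.na(a)]),
               n_large = length(b), mean_large = mean(b, na.rm = TRUE),
               sd_large = stats::sd(b[!is.na(b)]), cohens_d = d)
  })
  do.call(rbind, rows_out)
}

adjusted_covariates <- list(
  all_phn = c("d_ln_phn", "d_ln_pop", "d_physicians", "d_clinics",
              "d_hospitals", "d_welfare"),
  ftpt = c("d_ln_phn_ft", "d_ln_phn_pt", "d_ln_pop", "d_physicians",
           "d_clinics", "d_hospitals", "d_welfare")
)

coef_rows <- function(fit, model, sex, cause, stratum = "all") {
  co <- fit$coefficients
  data.frame(model = model, sex = sex, cause = cause, stratum = stratum,
             term = co$term, estimate = co$estimate, se = co$se, p = co$p,
             aic = fit$aic, n = fit$n,
             converged = isTRUE(fit$converged) ||
               is.null(fit$converged),
             random_effect = !is.null(fit$sigma2_u),
             sigma2_u = if (!is.null(fit$sigma2_u)) fit$sigma2_u else
               NA_real_,
             row.names = NULL)
}

#' Run the full study
#'
#' Orchestrates the analysis end to end on synthetic (or supplied) data:
#' EBSMR computation, descriptive and change tables, bivariate no-intercept
#' regressions, adjusted first-difference mixed models (all-PHN and
#' full-time/part-time variants, with the no-random-effect AIC comparison and
#' VIFs), stratified analyses, Benjamini-Hochberg q-values over the cause
#' series, and the spatial BYM fits (single-PHN and baseline/change
#' variants). Every fitted model's n, convergence flag and seed are recorded
#' in the bundle manifest; with a fixed seed the bundle is reproducible.
#'
#' @param config a \code{phn_study_config}.
#' @return list of class \code{phn_report_bundle}: data (the input data
#'   list), ebsmr, descriptive, changes, bivariate, adjusted, vif,
#'   stratified, qvalues, bym, manifest, partial (character vector of failed
#'   stages, empty when complete).
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "phn_study_config"))
  variants <- config$variants
  partial <- character(0)

  data <- if (!is.null(config$data)) config$data else
    generate_panel(config$generator)
  panel <- filter_panel(data$panel)
  sexes <- if (!is.null(config$sexes)) config$sexes else unique(panel$sex)
  causes <- if (!is.null(config$causes)) config$causes else
    unique(panel$cause)
  panel <- panel[panel$sex %in% sexes & panel$cause %in% causes, ,
                 drop = FALSE]

  ebsmr <- compute_ebsmr_table(panel, data$rates,
                               period_years = if (!is.null(
                                 config$generator$period_years))
                                 config$generator$period_years else 5,
                               min_group = config$min_group)
  rows <- build_first_difference(ebsmr, data$resources)

  bundle <- list(data = data, ebsmr = ebsmr, first_difference = rows)

  if ("descriptive" %in% variants) {
    bundle$descriptive <- describe_panel(ebsmr, data$resources,
                                         config$pop_threshold)
    bundle$changes <- describe_changes(rows, data$resources,
                                       config$pop_threshold)
  }

  if ("bivariate" %in% variants) {
    out <- list()
    for (sx in sexes) for (cs in causes) {
      r <- rows[rows$sex == sx & rows$cause == cs, ]
      classes <- list(all = rep(TRUE, nrow(r)),
                      small = r$baseline_pop < config$pop_threshold,
                      large = r$baseline_pop >= config$pop_threshold)
      for (cl in names(classes)) {
        s <- r[classes[[cl]], ]
        if (nrow(s) < 3L) next
        f <- simple_regression_no_intercept(s$dy, s$d_ln_phn)
        out[[length(out) + 1L]] <- data.frame(
          sex = sx, cause = cs, class = cl, slope = f$slope, se = f$se,
          p = f$p, n = f$n)
      }
    }
    bundle$bivariate <- do.call(rbind, out)
  }

  model_variants <- intersect(c("adjusted", "ftpt"), variants)
  if (length(model_variants) > 0) {
    out <- list(); vifs <- list()
    for (mv in model_variants) {
      covs <- adjusted_covariates[[if (mv == "adjusted") "all_phn" else
        "ftpt"]]
      for (sx in sexes) for (cs in causes) {
        r <- rows[rows$sex == sx & rows$cause == cs, ]
        X <- as.matrix(r[, covs, drop = FALSE])
        fit <- tryCatch(fit_lmm_ml(r$dy, X, r$prefecture_id),
                        error = function(e) e)
        if (inherits(fit, "error")) {
          partial <- c(partial, paste("adjusted", mv, sx, cs))
          next
        }
        fit0 <- fit_lm_no_re(r$dy, X)
        cr <- coef_rows(fit, mv, sx, cs)
        cr$aic_no_re <- fit0$aic
        out[[length(out) + 1L]] <- cr
        if (mv == "adjusted") {
          v <- vif(X)
          vifs[[length(vifs) + 1L]] <- data.frame(
            sex = sx, cause = cs, term = names(v), vif = as.numeric(v))
        }
      }
    }
    bundle$adjusted <- do.call(rbind, out)
    if (length(vifs)) bundle$vif <- do.call(rbind, vifs)

    # q-values: BH over the cause series of the PHN change coefficient,
    # within sex x model family
    adj <- bundle$adjusted
    phn_terms <- c("d_ln_phn", "d_ln_phn_ft", "d_ln_phn_pt")
    qrows <- list()
    for (mv in unique(adj$model)) for (sx in unique(adj$sex)) {
      for (tm in intersect(phn_terms, adj$term[adj$model == mv])) {
        sel <- adj$model == mv & adj$sex == sx & adj$term == tm
        if (!any(sel)) next
        q <- bh_qvalues(adj$p[sel])
        qrows[[length(qrows) + 1L]] <- data.frame(
          model = mv, sex = sx, cause = adj$cause[sel], term = tm,
          p = adj$p[sel], q = q, reportable = q < config$q_report)
      }
    }
    bundle$qvalues <- do.call(rbind, qrows)
  }

  if ("stratified" %in% variants) {
    out <- list()
    specs <- list(
      list(field = "baseline_pop", threshold = config$pop_threshold),
      list(field = "baseline_ebsmr", threshold = config$ebsmr_threshold))
    for (sp in specs) for (sx in sexes) for (cs in causes) {
      r <- rows[rows$sex == sx & rows$cause == cs, ]
      fits <- tryCatch(
        stratified_fits(r, adjusted_covariates$all_phn,
                        baseline_field = sp$field,
                        threshold = sp$threshold),
        error = function(e) NULL)
      if (is.null(fits)) {
        partial <- c(partial, paste("stratified", sp$field, sx, cs))
        next
      }
      for (f in fits) {
        cr <- coef_rows(f, paste0("stratified_", sp$field), sx, cs,
                        stratum = paste0(f$stratum, "_", sp$threshold))
        cr$stratum_n <- f$stratum_n
        out[[length(out) + 1L]] <- cr
      }
    }
    bundle$stratified <- do.call(rbind, out)
  }

  bym_variants <- intersect(c("bym", "bym_split"), variants)
  if (length(bym_variants) > 0) {
    graph <- adjacency_graph(data$adjacency,
                             n = max(panel$municipality_id))
    out <- list()
    fit_i <- 0L
    for (sx in sexes) for (cs in causes) {
      obs <- build_bym_data(ebsmr, data$resources, sx, cs)
      for (bv in bym_variants) {
        fit_i <- fit_i + 1L
        spec <- bym_model_spec(
          obs, chains = config$bym$chains, iter = config$bym$iter,
          warmup = config$bym$warmup,
          prior_sd_beta = config$bym$prior_sd_beta,
          seed = (config$seed * 1000L + fit_i) %% .Machine$integer.max)
        if (bv == "bym_split") spec <- split_phn_covariate(spec)
        fit <- tryCatch(fit_bym(spec, graph), error = function(e) e)
        if (inherits(fit, "error")) {
          partial <- c(partial, paste("bym", bv, sx, cs))
          next
        }
        s <- fit$summary
        s$model <- bv; s$sex <- sx; s$cause <- cs
        s$converged <- fit$converged
        s$seed <- spec$seed
        out[[length(out) + 1L]] <- s
      }
    }
    bundle$bym <- do.call(rbind, out)
  }

  bundle$manifest <- data.frame(
    key = c("seed", "n_municipalities", "sexes", "causes", "variants",
            "pop_threshold", "ebsmr_threshold", "significance", "q_report",
            "min_group", "bym_chains", "bym_iter", "bym_warmup", "partial"),
    value = c(config$seed,
              length(unique(panel$municipality_id)),
              paste(sexes, collapse = ","), paste(causes, collapse = ","),
              paste(variants, collapse = ","),
              config$pop_threshold, config$ebsmr_threshold,
              config$significance, config$q_report, config$min_group,
              config$bym$chains, config$bym$iter, config$bym$warmup,
              if (length(partial)) paste(partial, collapse = ";") else "none")
  )
  bundle$partial <- partial
  class(bundle) <- "phn_report_bundle"
  bundle
}

#' Write a report bundle as delimited text
#'
#' Writes every table of the bundle as a tab-separated file under \code{dir}
#' (created if needed). Deterministic given a deterministic bundle: the same
#' seed and configuration reproduce every file byte for byte.
#'
#' @param bundle a \code{phn_report_bundle}.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "phn_report_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- c("ebsmr", "first_difference", "descriptive", "changes",
              "bivariate", "adjusted", "vif", "stratified", "qvalues",
              "bym", "manifest")
  paths <- character(0)
  for (nm in tables) {
    tb <- bundle[[nm]]
    if (is.null(tb)) next
    path <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(format(tb, digits = 15, scientific = FALSE,
                              trim = TRUE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
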