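# Small generated fixtures shared across test files.

small_config <- function(n = 120, pref = 6, seed = 42, ...) {
  generator_config(n_municipalities = n, n_prefectures = pref, seed = seed,
                   ...)
}

# a null configuration: every source of risk variation switched off
null_config <- function(n = 400, seed = 99) {
  generator_config(n_municipalities = n, n_prefectures = 8,
                   true_beta = numeric(0), prior_shape = 1e8,
                   prior_rate = 1e8, pref_sd = 0, spatial_sd = 0,
                   hetero_sd = 0, time_effect = 0, seed = seed)
}

# dense-matrix ICAR quadratic form: -(tau/2) * phi' (D - W) phi
icar_quadratic_oracle <- function(phi, edges, n, tau) {
  W <- matrix(0, n, n)
  for (k in seq_len(nrow(edges))) {
    W[edges$from[k], edges$to[k]] <- 1
    W[edges$to[k], edges$from[k]] <- 1
  }
  D <- diag(rowSums(W))
  -(tau / 2) * drop(t(phi) %*% (D - W) %*% phi)
}

# posterior mean of theta under Poisson(o | e*theta) x Gamma(alpha, nu),
# by numerical integration (independent of the conjugate closed form)
eb_quadrature_oracle <- function(o, e, alpha, nu) {
  f <- function(th) stats::dpois(o, e * th) * stats::dgamma(th, alpha, nu)
  upper <- stats::qgamma(1 - 1e-14, shape = o + alpha, rate = e + nu) * 2
  num <- stats::integrate(function(th) th * f(th), 0, upper,
                          rel.tol = 1e-12, abs.tol = 0)$value
  den <- stats::integrate(f, 0, upper, rel.tol = 1e-12, abs.tol = 0)$value
  num / den
}

# step-up BH by direct evaluation of the definition
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    j <- seq(i, n)
    q[ord[i]] <- min(1, min(p[ord[j]] * n / j))
  }
  q
}
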