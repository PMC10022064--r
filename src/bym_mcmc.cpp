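// Adaptive Metropolis-within-Gibbs sampler for the Besag-York-Mollie model:
//   o_k ~ Poisson(mu_k),  log(mu_k) = log(e_k) + x_k beta + phi_{m(k)} + eps_k
// with an intrinsic CAR prior on phi (per-component soft sum-to-zero),
// iid normal heterogeneity eps, independent normal priors on beta and
// half-normal(0,1) priors on the two scale parameters.
//
// Municipality-level covariates are confounded with the free spatial field:
// beta_j and phi can trade off along a direction the likelihood barely
// constrains. Besides single-site updates, each iteration therefore makes
// (a) a joint multivariate beta proposal whose covariance is adapted from
// the warmup history, and (b) per-covariate "ridge" moves that shift beta_j
// and simultaneously translate phi by the municipality means of x_j, so the
// chain travels along the weakly identified direction.
//
// Single chain; the R wrapper loops over chains. Uses R's RNG so runs are
// reproducible under set.seed(). Proposal scales adapt towards standard
// acceptance targets during warmup with diminishing adaptation.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double pois_term(double o, double eta) {
  if (eta > 700.0) return R_NegInf;  // exp would overflow: reject
  return o * eta - std::exp(eta);
}

// [[Rcpp::export(name = ".bym_mcmc_chain")]]
List bym_mcmc_chain(NumericVector o, NumericVector log_e, NumericMatrix X,
                    IntegerVector muni, IntegerMatrix edges,
                    IntegerVector comp, NumericVector prior_sd_beta,
                    double soft_sum_sd_factor,
                    bool include_spatial, bool include_hetero,
                    bool use_likelihood, int n_iter, int n_warmup,
                    bool store_phi) {
  const int N = o.size();
  const int p = X.ncol();
  const int E = edges.nrow();
  int M = 0;
  for (int k = 0; k < N; ++k) if (muni[k] + 1 > M) M = muni[k] + 1;

  // observation lists and neighbour lists per municipality
  std::vector< std::vector<int> > obs_of(M), nb_of(M);
  for (int k = 0; k < N; ++k) obs_of[muni[k]].push_back(k);
  for (int e = 0; e < E; ++e) {
    nb_of[edges(e, 0)].push_back(edges(e, 1));
    nb_of[edges(e, 1)].push_back(edges(e, 0));
  }
  int C = 0;
  for (int i = 0; i < M; ++i) if (comp[i] + 1 > C) C = comp[i] + 1;
  std::vector<int> comp_size(C, 0);
  for (int i = 0; i < M; ++i) comp_size[comp[i]]++;

  // municipality means of each covariate (a) and within deviations (b)
  NumericMatrix a(M, p), b(N, p);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < M; ++i) {
      double s = 0.0;
      for (size_t t = 0; t < obs_of[i].size(); ++t) s += X(obs_of[i][t], j);
      a(i, j) = obs_of[i].empty() ? 0.0 : s / obs_of[i].size();
    }
    for (int k = 0; k < N; ++k) b(k, j) = X(k, j) - a(muni[k], j);
  }
  // per-edge differences of a, and per-component sums of a
  NumericMatrix a_edge(E, p), a_comp(C, p);
  for (int j = 0; j < p; ++j) {
    for (int e = 0; e < E; ++e)
      a_edge(e, j) = a(edges(e, 0), j) - a(edges(e, 1), j);
    for (int i = 0; i < M; ++i) a_comp(comp[i], j) += a(i, j);
  }

  // state
  std::vector<double> beta(p, 0.0), phi(M, 0.0), eps(N, 0.0);
  double sigma_phi = 0.5, sigma_eps = 0.5;
  std::vector<double> comp_sum(C, 0.0);
  std::vector<double> eta(N);
  for (int k = 0; k < N; ++k) eta[k] = log_e[k];
  double icar_Q = 0.0;  // sum over edges of (phi_i - phi_j)^2, kept current

  // adaptive proposal scales (beta scales track the prior sd so the
  // sampler is exactly equivariant under joint covariate/prior rescaling)
  std::vector<double> ps_beta(p), ps_ridge(p), ps_phi(M, 0.3), ps_eps(N, 0.5);
  double ps_lsphi = 0.4, ps_lseps = 0.4, ps_joint = 0.1;
  double ps_scphi = 0.2, ps_sceps = 0.2;
  for (int j = 0; j < p; ++j) {
    ps_beta[j] = 0.02 * prior_sd_beta[j];
    ps_ridge[j] = 0.02 * prior_sd_beta[j];
  }
  std::vector<int> acc_beta(p, 0), acc_ridge(p, 0), acc_phi(M, 0),
    acc_eps(N, 0);
  int acc_lsphi = 0, acc_lseps = 0, acc_joint = 0, batch = 0;
  int acc_scphi = 0, acc_sceps = 0;
  const int batch_len = 50;

  // warmup history of beta for the joint proposal covariance
  std::vector< std::vector<double> > hist;
  std::vector< std::vector<double> > chol(p, std::vector<double>(p, 0.0));
  bool have_chol = false;

  int n_keep = n_iter - n_warmup;
  NumericMatrix beta_draws(n_keep, p);
  NumericVector sphi_draws(n_keep), seps_draws(n_keep), lp_draws(n_keep);
  NumericMatrix phi_draws(store_phi && include_spatial ? n_keep : 0,
                          store_phi && include_spatial ? M : 0);
  std::vector<double> phi_mean(M, 0.0), eps_mean(N, 0.0);

  for (int it = 0; it < n_iter; ++it) {
    if (it % 256 == 0) Rcpp::checkUserInterrupt();

    // --- beta, one coordinate at a time with cached eta ---
    for (int j = 0; j < p; ++j) {
      double cur = beta[j];
      double prop = cur + ps_beta[j] * R::norm_rand();
      double d = prop - cur;
      double dll = 0.0;
      if (use_likelihood) {
        for (int k = 0; k < N; ++k) {
          double e1 = eta[k] + X(k, j) * d;
          dll += pois_term(o[k], e1) - pois_term(o[k], eta[k]);
          if (!R_FINITE(dll)) break;
        }
      }
      double dpr = -(prop * prop - cur * cur) /
        (2.0 * prior_sd_beta[j] * prior_sd_beta[j]);
      if (R_FINITE(dll) && std::log(R::unif_rand()) < dll + dpr) {
        beta[j] = prop;
        for (int k = 0; k < N; ++k) eta[k] += X(k, j) * d;
        acc_beta[j]++;
      }
    }

    // --- joint beta proposal with adapted covariance; when the spatial
    //     field is present it is translated along with beta (multivariate
    //     ridge move), so correlated weakly identified combinations of
    //     covariates can move together ---
    if (have_chol) {
      std::vector<double> z(p), d(p, 0.0);
      for (int j = 0; j < p; ++j) z[j] = R::norm_rand();
      for (int j = 0; j < p; ++j)
        for (int l = 0; l <= j; ++l) d[j] += chol[j][l] * z[l];
      for (int j = 0; j < p; ++j) d[j] *= ps_joint;
      double dll = 0.0, dpr = 0.0, dic = 0.0, dsoft = 0.0, dq = 0.0;
      if (use_likelihood) {
        for (int k = 0; k < N; ++k) {
          double de = 0.0;
          if (include_spatial) {
            for (int j = 0; j < p; ++j) de += b(k, j) * d[j];
          } else {
            for (int j = 0; j < p; ++j) de += X(k, j) * d[j];
          }
          dll += pois_term(o[k], eta[k] + de) - pois_term(o[k], eta[k]);
          if (!R_FINITE(dll)) break;
        }
      }
      for (int j = 0; j < p; ++j) {
        double cur = beta[j], prop = beta[j] + d[j];
        dpr += -(prop * prop - cur * cur) /
          (2.0 * prior_sd_beta[j] * prior_sd_beta[j]);
      }
      if (include_spatial) {
        double tau = 1.0 / (sigma_phi * sigma_phi);
        for (int e = 0; e < E; ++e) {
          double g = 0.0;
          for (int j = 0; j < p; ++j) g += a_edge(e, j) * d[j];
          double dphi = phi[edges(e, 0)] - phi[edges(e, 1)];
          dq += -2.0 * g * dphi + g * g;
        }
        dic = -0.5 * tau * dq;
        for (int c = 0; c < C; ++c) {
          double sh = 0.0;
          for (int j = 0; j < p; ++j) sh += a_comp(c, j) * d[j];
          double ssd = soft_sum_sd_factor * comp_size[c];
          double s_new = comp_sum[c] - sh;
          dsoft += -(s_new * s_new - comp_sum[c] * comp_sum[c]) /
            (2.0 * ssd * ssd);
        }
      }
      if (R_FINITE(dll) &&
          std::log(R::unif_rand()) < dll + dpr + dic + dsoft) {
        for (int k = 0; k < N; ++k) {
          double de = 0.0;
          if (include_spatial) {
            for (int j = 0; j < p; ++j) de += b(k, j) * d[j];
          } else {
            for (int j = 0; j < p; ++j) de += X(k, j) * d[j];
          }
          eta[k] += de;
        }
        for (int j = 0; j < p; ++j) beta[j] += d[j];
        if (include_spatial) {
          for (int i = 0; i < M; ++i) {
            double sh = 0.0;
            for (int j = 0; j < p; ++j) sh += a(i, j) * d[j];
            phi[i] -= sh;
          }
          for (int c = 0; c < C; ++c) {
            double sh = 0.0;
            for (int j = 0; j < p; ++j) sh += a_comp(c, j) * d[j];
            comp_sum[c] -= sh;
          }
          icar_Q += dq;
        }
        acc_joint++;
      }
    }

    // --- ridge moves: beta_j up, phi down by the municipality means of x_j;
    //     eta changes only through within-municipality deviations ---
    if (include_spatial) {
      double tau = 1.0 / (sigma_phi * sigma_phi);
      for (int j = 0; j < p; ++j) {
        double d = ps_ridge[j] * R::norm_rand();
        double dll = 0.0;
        if (use_likelihood) {
          for (int k = 0; k < N; ++k) {
            if (b(k, j) == 0.0) continue;
            dll += pois_term(o[k], eta[k] + d * b(k, j)) -
              pois_term(o[k], eta[k]);
            if (!R_FINITE(dll)) break;
          }
        }
        double cur = beta[j], prop = beta[j] + d;
        double dpr = -(prop * prop - cur * cur) /
          (2.0 * prior_sd_beta[j] * prior_sd_beta[j]);
        // ICAR quadratic form change for phi_i -> phi_i - d * a(i, j)
        double s1 = 0.0, s2 = 0.0;
        for (int e = 0; e < E; ++e) {
          double dphi = phi[edges(e, 0)] - phi[edges(e, 1)];
          s1 += a_edge(e, j) * dphi;
          s2 += a_edge(e, j) * a_edge(e, j);
        }
        double dq = -2.0 * d * s1 + d * d * s2;
        double dic = -0.5 * tau * dq;
        double dsoft = 0.0;
        for (int c = 0; c < C; ++c) {
          double ssd = soft_sum_sd_factor * comp_size[c];
          double s_new = comp_sum[c] - d * a_comp(c, j);
          dsoft += -(s_new * s_new - comp_sum[c] * comp_sum[c]) /
            (2.0 * ssd * ssd);
        }
        if (R_FINITE(dll) &&
            std::log(R::unif_rand()) < dll + dpr + dic + dsoft) {
          beta[j] = prop;
          for (int i = 0; i < M; ++i) phi[i] -= d * a(i, j);
          for (int c = 0; c < C; ++c) comp_sum[c] -= d * a_comp(c, j);
          for (int k = 0; k < N; ++k) eta[k] += d * b(k, j);
          icar_Q += dq;
          acc_ridge[j]++;
        }
      }
    }

    // --- phi, single site ---
    if (include_spatial) {
      double tau = 1.0 / (sigma_phi * sigma_phi);
      for (int i = 0; i < M; ++i) {
        double cur = phi[i];
        double prop = cur + ps_phi[i] * R::norm_rand();
        double d = prop - cur;
        double dll = 0.0;
        if (use_likelihood) {
          for (size_t t = 0; t < obs_of[i].size(); ++t) {
            int k = obs_of[i][t];
            dll += pois_term(o[k], eta[k] + d) - pois_term(o[k], eta[k]);
          }
        }
        double dq = 0.0;
        for (size_t t = 0; t < nb_of[i].size(); ++t) {
          double nbv = phi[nb_of[i][t]];
          dq += (prop - nbv) * (prop - nbv) - (cur - nbv) * (cur - nbv);
        }
        double dic = -0.5 * tau * dq;
        int c = comp[i];
        double ssd = soft_sum_sd_factor * comp_size[c];
        double s_new = comp_sum[c] + d;
        double dsoft = -(s_new * s_new - comp_sum[c] * comp_sum[c]) /
          (2.0 * ssd * ssd);
        if (R_FINITE(dll) &&
            std::log(R::unif_rand()) < dll + dic + dsoft) {
          phi[i] = prop;
          comp_sum[c] = s_new;
          icar_Q += dq;
          for (size_t t = 0; t < obs_of[i].size(); ++t)
            eta[obs_of[i][t]] += d;
          acc_phi[i]++;
        }
      }

      // --- sigma_phi via MH on log scale (half-normal(1) prior) ---
      {
        double curl = std::log(sigma_phi);
        double propl = curl + ps_lsphi * R::norm_rand();
        double s0 = sigma_phi, s1 = std::exp(propl);
        double rank = (double)(M - C);
        double lp0 = -rank * std::log(s0) - icar_Q / (2.0 * s0 * s0)
          - 0.5 * s0 * s0 + std::log(s0);
        double lp1 = -rank * std::log(s1) - icar_Q / (2.0 * s1 * s1)
          - 0.5 * s1 * s1 + std::log(s1);
        if (std::log(R::unif_rand()) < lp1 - lp0) {
          sigma_phi = s1;
          acc_lsphi++;
        }
      }

      // --- joint rescale of (sigma_phi, phi): a funnel move; the ICAR
      //     quadratic form is invariant, so acceptance involves only the
      //     likelihood, the soft constraint, the half-normal prior and the
      //     Jacobian ---
      {
        double lr = ps_scphi * R::norm_rand();
        double r = std::exp(lr);
        double dll = 0.0;
        if (use_likelihood) {
          for (int k = 0; k < N; ++k) {
            double de = (r - 1.0) * phi[muni[k]];
            dll += pois_term(o[k], eta[k] + de) - pois_term(o[k], eta[k]);
            if (!R_FINITE(dll)) break;
          }
        }
        double dsoft = 0.0;
        for (int c = 0; c < C; ++c) {
          double ssd = soft_sum_sd_factor * comp_size[c];
          dsoft += -(r * r - 1.0) * comp_sum[c] * comp_sum[c] /
            (2.0 * ssd * ssd);
        }
        double s0 = sigma_phi;
        double lacc = dll + dsoft + (C + 1.0) * lr -
          0.5 * s0 * s0 * (r * r - 1.0);
        if (R_FINITE(dll) && std::log(R::unif_rand()) < lacc) {
          for (int k = 0; k < N; ++k) eta[k] += (r - 1.0) * phi[muni[k]];
          for (int i = 0; i < M; ++i) phi[i] *= r;
          for (int c = 0; c < C; ++c) comp_sum[c] *= r;
          icar_Q *= r * r;
          sigma_phi *= r;
          acc_scphi++;
        }
      }
    }

    // --- eps, single site ---
    if (include_hetero) {
      double t2 = 2.0 * sigma_eps * sigma_eps;
      for (int k = 0; k < N; ++k) {
        double cur = eps[k];
        double prop = cur + ps_eps[k] * R::norm_rand();
        double dll = 0.0;
        if (use_likelihood) {
          dll = pois_term(o[k], eta[k] + prop - cur) -
            pois_term(o[k], eta[k]);
        }
        double dpr = -(prop * prop - cur * cur) / t2;
        if (R_FINITE(dll) && std::log(R::unif_rand()) < dll + dpr) {
          eps[k] = prop;
          eta[k] += prop - cur;
          acc_eps[k]++;
        }
      }

      // --- sigma_eps via MH on log scale (half-normal(1) prior) ---
      {
        double curl = std::log(sigma_eps);
        double propl = curl + ps_lseps * R::norm_rand();
        double s0 = sigma_eps, s1 = std::exp(propl);
        double se = 0.0;
        for (int k = 0; k < N; ++k) se += eps[k] * eps[k];
        double lp0 = -N * std::log(s0) - se / (2.0 * s0 * s0)
          - 0.5 * s0 * s0 + std::log(s0);
        double lp1 = -N * std::log(s1) - se / (2.0 * s1 * s1)
          - 0.5 * s1 * s1 + std::log(s1);
        if (std::log(R::unif_rand()) < lp1 - lp0) {
          sigma_eps = s1;
          acc_lseps++;
        }
      }

      // --- joint rescale of (sigma_eps, eps), same funnel move ---
      {
        double lr = ps_sceps * R::norm_rand();
        double r = std::exp(lr);
        double dll = 0.0;
        if (use_likelihood) {
          for (int k = 0; k < N; ++k) {
            double de = (r - 1.0) * eps[k];
            dll += pois_term(o[k], eta[k] + de) - pois_term(o[k], eta[k]);
            if (!R_FINITE(dll)) break;
          }
        }
        double s0 = sigma_eps;
        double lacc = dll + lr - 0.5 * s0 * s0 * (r * r - 1.0);
        if (R_FINITE(dll) && std::log(R::unif_rand()) < lacc) {
          for (int k = 0; k < N; ++k) {
            eta[k] += (r - 1.0) * eps[k];
            eps[k] *= r;
          }
          sigma_eps *= r;
          acc_sceps++;
        }
      }
    }

    // --- adaptation during warmup ---
    if (it < n_warmup) {
      hist.push_back(beta);
      if ((it + 1) % batch_len == 0) {
        batch++;
        double delta = std::min(0.1, 1.0 / std::sqrt((double)batch));
        const double t1 = 0.44, tj = 0.24;
        for (int j = 0; j < p; ++j) {
          ps_beta[j] *= std::exp(((double)acc_beta[j] / batch_len - t1) *
                                 delta * 5.0);
          ps_ridge[j] *= std::exp(((double)acc_ridge[j] / batch_len - t1) *
                                  delta * 5.0);
          acc_beta[j] = acc_ridge[j] = 0;
        }
        for (int i = 0; i < M; ++i) {
          ps_phi[i] *= std::exp(((double)acc_phi[i] / batch_len - t1) *
                                delta * 5.0);
          acc_phi[i] = 0;
        }
        for (int k = 0; k < N; ++k) {
          ps_eps[k] *= std::exp(((double)acc_eps[k] / batch_len - t1) *
                                delta * 5.0);
          acc_eps[k] = 0;
        }
        ps_lsphi *= std::exp(((double)acc_lsphi / batch_len - t1) *
                             delta * 5.0);
        ps_lseps *= std::exp(((double)acc_lseps / batch_len - t1) *
                             delta * 5.0);
        ps_scphi *= std::exp(((double)acc_scphi / batch_len - t1) *
                             delta * 5.0);
        ps_sceps *= std::exp(((double)acc_sceps / batch_len - t1) *
                             delta * 5.0);
        acc_scphi = acc_sceps = 0;
        if (have_chol)
          ps_joint *= std::exp(((double)acc_joint / batch_len - tj) *
                               delta * 5.0);
        acc_lsphi = acc_lseps = acc_joint = 0;

        // refresh the joint-proposal covariance from the second half of
        // the warmup history
        int H = (int)hist.size();
        if (H >= 200) {
          int lo = H / 2, n_h = H - lo;
          std::vector<double> mu(p, 0.0);
          for (int h = lo; h < H; ++h)
            for (int j = 0; j < p; ++j) mu[j] += hist[h][j] / n_h;
          std::vector< std::vector<double> > S(p,
            std::vector<double>(p, 0.0));
          for (int h = lo; h < H; ++h)
            for (int j = 0; j < p; ++j)
              for (int l = 0; l <= j; ++l)
                S[j][l] += (hist[h][j] - mu[j]) * (hist[h][l] - mu[l]) /
                  (n_h - 1);
          double scale = 2.38 * 2.38 / p;
          for (int j = 0; j < p; ++j) {
            for (int l = 0; l <= j; ++l) S[j][l] *= scale;
            S[j][j] += 1e-12 * prior_sd_beta[j] * prior_sd_beta[j];
          }
          // Cholesky (lower)
          bool ok = true;
          for (int j = 0; j < p && ok; ++j) {
            for (int l = 0; l <= j; ++l) {
              double s = S[j][l];
              for (int t = 0; t < l; ++t) s -= chol[j][t] * chol[l][t];
              if (l == j) {
                if (s <= 0) { ok = false; break; }
                chol[j][j] = std::sqrt(s);
              } else {
                chol[j][l] = s / chol[l][l];
              }
            }
          }
          if (ok && !have_chol) { have_chol = true; ps_joint = 1.0; }
          if (!ok) have_chol = have_chol && true;
        }
      }
    }

    // --- store ---
    if (it >= n_warmup) {
      int s = it - n_warmup;
      for (int j = 0; j < p; ++j) beta_draws(s, j) = beta[j];
      sphi_draws[s] = sigma_phi;
      seps_draws[s] = sigma_eps;
      double lp = 0.0;
      if (use_likelihood)
        for (int k = 0; k < N; ++k) lp += pois_term(o[k], eta[k]);
      lp_draws[s] = lp;
      if (store_phi && include_spatial)
        for (int i = 0; i < M; ++i) phi_draws(s, i) = phi[i];
      for (int i = 0; i < M; ++i) phi_mean[i] += phi[i] / n_keep;
      for (int k = 0; k < N; ++k) eps_mean[k] += eps[k] / n_keep;
    }
  }

  return List::create(
    _["beta"] = beta_draws,
    _["sigma_phi"] = sphi_draws,
    _["sigma_eps"] = seps_draws,
    _["lp"] = lp_draws,
    _["phi"] = phi_draws,
    _["phi_mean"] = NumericVector(phi_mean.begin(), phi_mean.end()),
    _["eps_mean"] = NumericVector(eps_mean.begin(), eps_mean.end()));
}
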