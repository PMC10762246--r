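// Slice-within-Gibbs samplers for the hierarchical evidence-accumulation
// model and the ordinal / binary probit regressions.
//
// All samplers draw from R's RNG stream (seed them with set.seed() before the
// call), use univariate slice sampling (Neal 2003, stepping-out) for
// non-conjugate updates and a conjugate Gibbs draw for population means.
// The latent evidence scale is fixed (sigma = 1) in all models.

#include <Rcpp.h>
#include <functional>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline double Phi(double x) { return 0.5 * erfc(-x * M_SQRT1_2); }

// observed-category probabilities are floored at 1e-300 so that pathological
// parameter values degrade the posterior instead of crashing the sampler
static const double LOG_FLOOR = -690.77552789821368; // log(1e-300)

// log P(category j | mu, sd) for K ordered categories cut by c[0..K-2]
static inline double cat_logp(int j, double mu, double sd, const double* c, int K) {
  double lo = (j == 1) ? 0.0 : Phi((c[j - 2] - mu) / sd);
  double hi = (j == K) ? 1.0 : Phi((c[j - 1] - mu) / sd);
  double p = hi - lo;
  return (p > 1e-300) ? std::log(p) : LOG_FLOOR;
}

// univariate slice sampler with stepping out, bounded support [lower, upper]
static double slice1(double x0, const std::function<double(double)>& logf,
                     double w, double lower, double upper) {
  double f0 = logf(x0);
  if (!std::isfinite(f0)) return x0;
  double logy = f0 + std::log(unif_rand());
  double u = unif_rand() * w;
  double L = std::max(lower, x0 - u);
  double R = std::min(upper, x0 + (w - u));
  for (int m = 0; m < 30 && L > lower && logf(L) > logy; ++m)
    L = std::max(lower, L - w);
  for (int m = 0; m < 30 && R < upper && logf(R) > logy; ++m)
    R = std::min(upper, R + w);
  for (int it = 0; it < 100; ++it) {
    double x1 = L + unif_rand() * (R - L);
    if (logf(x1) >= logy) return x1;
    if (x1 < x0) L = x1; else R = x1;
  }
  return x0;
}

static inline double half_normal_lp(double x, double sd) {
  if (x < 0) return R_NegInf;
  return -0.5 * x * x / (sd * sd);
}

// ---------------------------------------------------------------------------
// Evidence-accumulation model, hierarchical over subjects.
//
// Color-axis latent mean for trial i of subject u:
//   mu_i = tau_u + (de_u*(1-hard_i) + dh_u*hard_i) * DT_i * col_i
//          + (ds_u * ST_i + g_u) * ssign_i
// with ssign_i = col_i * lambda_i * si_present_i (the color indicated by the
// social information; 0 when absent) and Var = DT_i (sigma = 1).
//
// Parameter slots: 0 = delta_easy, 1 = delta_hard, 2 = delta_s, 3 = gamma,
// 4 = tau.  `use` switches slots 0/1 (personal drift), 2 (social drift) and
// 3 (social shift); tau and the criteria are always estimated.
// Criteria: c6..c10 = cumsum(inc[0..4]) with mirror-symmetric negatives.
//
// fixed_scale >= 0 pins every population SD at that value; fixed_scale == 0
// degenerates the hierarchy (all subjects share the population mean).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List ea_mcmc_cpp(IntegerVector y, IntegerVector subj, NumericVector col,
                 IntegerVector hard, NumericVector DT, NumericVector ST,
                 NumericVector ssign, int n_subj, LogicalVector use,
                 int iter, int warmup, int thin,
                 double prior_loc_sd, double prior_scale_sd, double prior_inc_sd,
                 double fixed_scale, bool save_loglik) {
  RNGScope scope;
  const int N = y.size();
  std::vector<std::vector<int> > tix(n_subj);
  for (int i = 0; i < N; ++i) tix[subj[i]].push_back(i);
  std::vector<double> sdt(N);
  for (int i = 0; i < N; ++i) sdt[i] = std::sqrt(DT[i]);

  bool inc_par[5] = {use[0] != 0, use[1] != 0, use[2] != 0, use[3] != 0, true};
  bool scale_fixed = fixed_scale >= 0.0;

  std::vector<double> theta(n_subj * 5, 0.0);
  double m[5] = {0, 0, 0, 0, 0};
  double s[5];
  for (int k = 0; k < 5; ++k) s[k] = scale_fixed ? fixed_scale : 0.5;
  double inc[5] = {1, 1, 1, 1, 1};
  double c[10];
  auto build_c = [&](const double* ic, double* cc) {
    double acc = 0;
    for (int j = 0; j < 5; ++j) { acc += ic[j]; cc[5 + j] = acc; }
    for (int j = 0; j < 5; ++j) cc[4 - j] = -cc[5 + j];
  };
  build_c(inc, c);

  // mean social-influence time per subject and overall, for the
  // drift-shift exchange moves (the two parameters trade off along
  // gamma + delta_s * ST, so single-site updates mix slowly there)
  std::vector<double> st_bar(n_subj, 0.0);
  double st_bar_all = 0.0;
  {
    std::vector<int> n_si(n_subj, 0);
    int n_si_all = 0;
    for (int i = 0; i < N; ++i) {
      if (ssign[i] != 0.0) {
        st_bar[subj[i]] += ST[i];
        n_si[subj[i]]++;
        st_bar_all += ST[i];
        n_si_all++;
      }
    }
    for (int u = 0; u < n_subj; ++u)
      st_bar[u] = n_si[u] > 0 ? st_bar[u] / n_si[u] : 0.0;
    st_bar_all = n_si_all > 0 ? st_bar_all / n_si_all : 0.0;
  }

  auto trial_mu = [&](int i, const double* th) -> double {
    double dp = th[0] * (1.0 - hard[i]) + th[1] * hard[i];
    return th[4] + dp * DT[i] * col[i] + (th[2] * ST[i] + th[3]) * ssign[i];
  };
  auto subj_ll = [&](int u, const double* th, const double* cc) -> double {
    double ll = 0;
    for (size_t q = 0; q < tix[u].size(); ++q) {
      int i = tix[u][q];
      ll += cat_logp(y[i], trial_mu(i, th), sdt[i], cc, 11);
    }
    return ll;
  };
  auto full_ll = [&](const double* cc) -> double {
    double ll = 0;
    for (int i = 0; i < N; ++i)
      ll += cat_logp(y[i], trial_mu(i, &theta[subj[i] * 5]), sdt[i], cc, 11);
    return ll;
  };

  const int n_save = (iter - warmup + thin - 1) / thin;
  NumericMatrix out_m(n_save, 5), out_s(n_save, 5), out_inc(n_save, 5);
  NumericMatrix out_theta(n_save, n_subj * 5);
  NumericMatrix out_ll(save_loglik ? n_save : 0, save_loglik ? N : 0);

  int row = 0;
  for (int it = 0; it < iter; ++it) {
    // subject-level parameters
    for (int k = 0; k < 5; ++k) {
      if (!inc_par[k]) continue;
      if (scale_fixed && fixed_scale == 0.0) {
        // degenerate hierarchy: one shared value, updated through the full data
        double cur = m[k];
        double th[5];
        auto logf = [&](double x) -> double {
          double ll = 0;
          for (int u = 0; u < n_subj; ++u) {
            for (int kk = 0; kk < 5; ++kk) th[kk] = theta[u * 5 + kk];
            th[k] = x;
            ll += subj_ll(u, th, c);
          }
          return ll + R::dnorm(x, 0.0, prior_loc_sd, 1);
        };
        double nx = slice1(cur, logf, 0.5, -50, 50);
        m[k] = nx;
        for (int u = 0; u < n_subj; ++u) theta[u * 5 + k] = nx;
        continue;
      }
      for (int u = 0; u < n_subj; ++u) {
        double th[5];
        for (int kk = 0; kk < 5; ++kk) th[kk] = theta[u * 5 + kk];
        auto logf = [&](double x) -> double {
          th[k] = x;
          return subj_ll(u, th, c) + R::dnorm(x, m[k], s[k], 1);
        };
        theta[u * 5 + k] = slice1(theta[u * 5 + k], logf, 0.5, -50, 50);
      }
      // population mean: conjugate normal draw
      double sum = 0;
      for (int u = 0; u < n_subj; ++u) sum += theta[u * 5 + k];
      double prec = n_subj / (s[k] * s[k]) + 1.0 / (prior_loc_sd * prior_loc_sd);
      double mean = (sum / (s[k] * s[k])) / prec;
      m[k] = mean + norm_rand() / std::sqrt(prec);
      // population SD: slice with half-normal prior
      if (!scale_fixed) {
        auto logf = [&](double x) -> double {
          if (x <= 0) return R_NegInf;
          double lp = half_normal_lp(x, prior_scale_sd);
          for (int u = 0; u < n_subj; ++u)
            lp += R::dnorm(theta[u * 5 + k], m[k], x, 1);
          return lp;
        };
        s[k] = slice1(s[k], logf, 0.3, 1e-6, 50);
      }
    }
    // drift-shift exchange moves along gamma + delta_s * ST
    if (inc_par[2] && inc_par[3] && !(scale_fixed && fixed_scale == 0.0)) {
      for (int u = 0; u < n_subj; ++u) {
        if (st_bar[u] <= 0) continue;
        double eps = norm_rand() * 0.15;
        double th_old[5], th_new[5];
        for (int kk = 0; kk < 5; ++kk)
          th_old[kk] = th_new[kk] = theta[u * 5 + kk];
        th_new[2] += eps;
        th_new[3] -= eps * st_bar[u];
        double delta = subj_ll(u, th_new, c) - subj_ll(u, th_old, c) +
          R::dnorm(th_new[2], m[2], s[2], 1) -
          R::dnorm(th_old[2], m[2], s[2], 1) +
          R::dnorm(th_new[3], m[3], s[3], 1) -
          R::dnorm(th_old[3], m[3], s[3], 1);
        if (std::log(unif_rand()) < delta) {
          theta[u * 5 + 2] = th_new[2];
          theta[u * 5 + 3] = th_new[3];
        }
      }
      if (st_bar_all > 0) {
        // population-level exchange: shift every subject (deviations from
        // the population means are unchanged, so only the mean priors and
        // the likelihood enter the ratio)
        double eps = norm_rand() * 0.05;
        double ll_old = full_ll(c);
        std::vector<double> backup(theta);
        for (int u = 0; u < n_subj; ++u) {
          theta[u * 5 + 2] += eps;
          theta[u * 5 + 3] -= eps * st_bar_all;
        }
        double m2_new = m[2] + eps, m3_new = m[3] - eps * st_bar_all;
        double delta = full_ll(c) - ll_old +
          R::dnorm(m2_new, 0.0, prior_loc_sd, 1) -
          R::dnorm(m[2], 0.0, prior_loc_sd, 1) +
          R::dnorm(m3_new, 0.0, prior_loc_sd, 1) -
          R::dnorm(m[3], 0.0, prior_loc_sd, 1);
        if (std::log(unif_rand()) < delta) {
          m[2] = m2_new;
          m[3] = m3_new;
        } else {
          theta = backup;
        }
      }
    }
    // confidence criteria increments (shared across subjects)
    for (int j = 0; j < 5; ++j) {
      auto logf = [&](double x) -> double {
        if (x <= 0) return R_NegInf;
        double ic[5], cc[10];
        for (int q = 0; q < 5; ++q) ic[q] = inc[q];
        ic[j] = x;
        build_c(ic, cc);
        return full_ll(cc) + half_normal_lp(x, prior_inc_sd);
      };
      inc[j] = slice1(inc[j], logf, 0.3, 1e-6, 50);
      build_c(inc, c);
    }

    if (it >= warmup && (it - warmup) % thin == 0) {
      for (int k = 0; k < 5; ++k) {
        out_m(row, k) = m[k];
        out_s(row, k) = s[k];
        out_inc(row, k) = inc[k];
      }
      for (int q = 0; q < n_subj * 5; ++q) out_theta(row, q) = theta[q];
      if (save_loglik)
        for (int i = 0; i < N; ++i)
          out_ll(row, i) = cat_logp(y[i], trial_mu(i, &theta[subj[i] * 5]),
                                    sdt[i], c, 11);
      ++row;
    }
  }

  return List::create(_["pop_mean"] = out_m, _["pop_sd"] = out_s,
                      _["inc"] = out_inc, _["theta"] = out_theta,
                      _["loglik"] = out_ll);
}

// ---------------------------------------------------------------------------
// Ordinal probit regression with a subject random intercept.
// Latent mean mu_i = X_i . beta + a[subj_i], unit latent noise; K categories
// cut by thresholds t[0] (free) and positive increments e[1..K-2].
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List op_mcmc_cpp(IntegerVector y, NumericMatrix X, IntegerVector subj,
                 int n_subj, int K, int iter, int warmup, int thin,
                 double prior_beta_sd, double prior_t_sd, double prior_inc_sd,
                 double prior_ranef_sd, bool save_loglik) {
  RNGScope scope;
  const int N = y.size(), P = X.ncol();
  std::vector<std::vector<int> > tix(n_subj);
  for (int i = 0; i < N; ++i) tix[subj[i]].push_back(i);

  std::vector<double> beta(P, 0.0), a(n_subj, 0.0), eta(N, 0.0);
  double sd_a = 0.5;
  double t1 = -2.0;
  std::vector<double> e(K - 2, 4.0 / (K - 2));
  std::vector<double> t(K - 1);
  auto build_t = [&](double tt1, const std::vector<double>& ee,
                     std::vector<double>& out) {
    out[0] = tt1;
    for (int k = 1; k < K - 1; ++k) out[k] = out[k - 1] + ee[k - 1];
  };
  build_t(t1, e, t);

  auto full_ll_t = [&](const std::vector<double>& tt) -> double {
    double ll = 0;
    for (int i = 0; i < N; ++i)
      ll += cat_logp(y[i], eta[i] + a[subj[i]], 1.0, tt.data(), K);
    return ll;
  };

  const int n_save = (iter - warmup + thin - 1) / thin;
  NumericMatrix out_beta(n_save, P), out_t(n_save, K - 1), out_a(n_save, n_subj);
  NumericVector out_sda(n_save);
  NumericMatrix out_ll(save_loglik ? n_save : 0, save_loglik ? N : 0);

  int row = 0;
  for (int it = 0; it < iter; ++it) {
    for (int p = 0; p < P; ++p) {
      double b0 = beta[p];
      auto logf = [&](double x) -> double {
        double ll = 0, d = x - b0;
        for (int i = 0; i < N; ++i)
          ll += cat_logp(y[i], eta[i] + d * X(i, p) + a[subj[i]], 1.0,
                         t.data(), K);
        return ll + R::dnorm(x, 0.0, prior_beta_sd, 1);
      };
      double nb = slice1(b0, logf, 0.5, -50, 50);
      if (nb != b0) {
        double d = nb - b0;
        for (int i = 0; i < N; ++i) eta[i] += d * X(i, p);
        beta[p] = nb;
      }
    }
    for (int u = 0; u < n_subj; ++u) {
      auto logf = [&](double x) -> double {
        double ll = 0;
        for (size_t q = 0; q < tix[u].size(); ++q) {
          int i = tix[u][q];
          ll += cat_logp(y[i], eta[i] + x, 1.0, t.data(), K);
        }
        return ll + R::dnorm(x, 0.0, sd_a, 1);
      };
      a[u] = slice1(a[u], logf, 0.5, -50, 50);
    }
    {
      auto logf = [&](double x) -> double {
        if (x <= 0) return R_NegInf;
        double lp = half_normal_lp(x, prior_ranef_sd);
        for (int u = 0; u < n_subj; ++u) lp += R::dnorm(a[u], 0.0, x, 1);
        return lp;
      };
      sd_a = slice1(sd_a, logf, 0.3, 1e-6, 50);
    }
    {
      auto logf = [&](double x) -> double {
        std::vector<double> tt(K - 1);
        build_t(x, e, tt);
        return full_ll_t(tt) + R::dnorm(x, 0.0, prior_t_sd, 1);
      };
      t1 = slice1(t1, logf, 0.5, -50, 50);
      build_t(t1, e, t);
    }
    for (int k = 0; k < K - 2; ++k) {
      auto logf = [&](double x) -> double {
        if (x <= 0) return R_NegInf;
        std::vector<double> ee(e), tt(K - 1);
        ee[k] = x;
        build_t(t1, ee, tt);
        return full_ll_t(tt) + half_normal_lp(x, prior_inc_sd);
      };
      e[k] = slice1(e[k], logf, 0.3, 1e-6, 50);
      build_t(t1, e, t);
    }

    if (it >= warmup && (it - warmup) % thin == 0) {
      for (int p = 0; p < P; ++p) out_beta(row, p) = beta[p];
      for (int k = 0; k < K - 1; ++k) out_t(row, k) = t[k];
      for (int u = 0; u < n_subj; ++u) out_a(row, u) = a[u];
      out_sda[row] = sd_a;
      if (save_loglik)
        for (int i = 0; i < N; ++i)
          out_ll(row, i) = cat_logp(y[i], eta[i] + a[subj[i]], 1.0,
                                    t.data(), K);
      ++row;
    }
  }
  return List::create(_["beta"] = out_beta, _["thresholds"] = out_t,
                      _["ranef"] = out_a, _["sd_ranef"] = out_sda,
                      _["loglik"] = out_ll);
}

// ---------------------------------------------------------------------------
// Binary probit regression with a subject random intercept.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List bp_mcmc_cpp(IntegerVector y, NumericMatrix X, IntegerVector subj,
                 int n_subj, int iter, int warmup, int thin,
                 double prior_beta_sd, double prior_ranef_sd,
                 bool save_loglik) {
  RNGScope scope;
  const int N = y.size(), P = X.ncol();
  std::vector<std::vector<int> > tix(n_subj);
  for (int i = 0; i < N; ++i) tix[subj[i]].push_back(i);

  std::vector<double> beta(P, 0.0), a(n_subj, 0.0), eta(N, 0.0);
  double sd_a = 0.5;

  auto bern_lp = [&](int yi, double mu) -> double {
    double p = Phi(mu);
    if (p < 1e-300) p = 1e-300;
    if (p > 1.0 - 1e-16) p = 1.0 - 1e-16;
    return yi ? std::log(p) : std::log1p(-p);
  };

  const int n_save = (iter - warmup + thin - 1) / thin;
  NumericMatrix out_beta(n_save, P), out_a(n_save, n_subj);
  NumericVector out_sda(n_save);
  NumericMatrix out_ll(save_loglik ? n_save : 0, save_loglik ? N : 0);

  int row = 0;
  for (int it = 0; it < iter; ++it) {
    for (int p = 0; p < P; ++p) {
      double b0 = beta[p];
      auto logf = [&](double x) -> double {
        double ll = 0, d = x - b0;
        for (int i = 0; i < N; ++i)
          ll += bern_lp(y[i], eta[i] + d * X(i, p) + a[subj[i]]);
        return ll + R::dnorm(x, 0.0, prior_beta_sd, 1);
      };
      double nb = slice1(b0, logf, 0.5, -50, 50);
      if (nb != b0) {
        double d = nb - b0;
        for (int i = 0; i < N; ++i) eta[i] += d * X(i, p);
        beta[p] = nb;
      }
    }
    for (int u = 0; u < n_subj; ++u) {
      auto logf = [&](double x) -> double {
        double ll = 0;
        for (size_t q = 0; q < tix[u].size(); ++q) {
          int i = tix[u][q];
          ll += bern_lp(y[i], eta[i] + x);
        }
        return ll + R::dnorm(x, 0.0, sd_a, 1);
      };
      a[u] = slice1(a[u], logf, 0.5, -50, 50);
    }
    {
      auto logf = [&](double x) -> double {
        if (x <= 0) return R_NegInf;
        double lp = half_normal_lp(x, prior_ranef_sd);
        for (int u = 0; u < n_subj; ++u) lp += R::dnorm(a[u], 0.0, x, 1);
        return lp;
      };
      sd_a = slice1(sd_a, logf, 0.3, 1e-6, 50);
    }
    if (it >= warmup && (it - warmup) % thin == 0) {
      for (int p = 0; p < P; ++p) out_beta(row, p) = beta[p];
      for (int u = 0; u < n_subj; ++u) out_a(row, u) = a[u];
      out_sda[row] = sd_a;
      if (save_loglik)
        for (int i = 0; i < N; ++i)
          out_ll(row, i) = bern_lp(y[i], eta[i] + a[subj[i]]);
      ++row;
    }
  }
  return List::create(_["beta"] = out_beta, _["ranef"] = out_a,
                      _["sd_ranef"] = out_sda, _["loglik"] = out_ll);
}
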