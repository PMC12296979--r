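#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// GPCM in intercept form: score x in 0..c-1 has linear predictor
//   eta_x = x * alpha * theta + d_x,   d_0 = 0, dfree = (d_1 .. d_{c-1})
// Probabilities are softmax(eta_0..eta_{c-1}); evaluated with the running
// max subtracted so |alpha*theta| up to +-40 stays finite.

static inline void cat_probs(double ath, const double* dfree, int c, double* p) {
  double terms[16];
  terms[0] = 0.0;
  double m = 0.0;
  for (int k = 1; k < c; k++) {
    terms[k] = k * ath + dfree[k - 1];
    if (terms[k] > m) m = terms[k];
  }
  double s = 0.0;
  for (int k = 0; k < c; k++) { p[k] = std::exp(terms[k] - m); s += p[k]; }
  for (int k = 0; k < c; k++) p[k] /= s;
}

static inline double cell_loglik(double ath, const double* dfree, int c, int x) {
  double terms[16];
  terms[0] = 0.0;
  double m = 0.0;
  for (int k = 1; k < c; k++) {
    terms[k] = k * ath + dfree[k - 1];
    if (terms[k] > m) m = terms[k];
  }
  double s = 0.0;
  for (int k = 0; k < c; k++) s += std::exp(terms[k] - m);
  return terms[x] - (m + std::log(s));
}

// Cholesky of a small V x V correlation matrix (row-major). Returns false
// when the matrix is not positive definite (proposal outside the space).
static bool chol_small(const std::vector<double>& A, int V, std::vector<double>& L) {
  L.assign(V * V, 0.0);
  for (int i = 0; i < V; i++) {
    for (int j = 0; j <= i; j++) {
      double s = A[i * V + j];
      for (int k = 0; k < j; k++) s -= L[i * V + k] * L[j * V + k];
      if (i == j) {
        if (s <= 1e-12) return false;
        L[i * V + i] = std::sqrt(s);
      } else {
        L[i * V + j] = s / L[j * V + j];
      }
    }
  }
  return true;
}

// log N(x; 0, R) up to the constant, using the Cholesky factor L of R.
static double mvn_logpdf(const double* x, const std::vector<double>& L, int V) {
  double y[16];
  double quad = 0.0, logdet = 0.0;
  for (int i = 0; i < V; i++) {
    double s = x[i];
    for (int k = 0; k < i; k++) s -= L[i * V + k] * y[k];
    y[i] = s / L[i * V + i];
    quad += y[i] * y[i];
    logdet += std::log(L[i * V + i]);
  }
  return -0.5 * quad - logdet;
}

// Random-walk Metropolis-within-blocks sampler for the Bayesian GPCM.
// Blocks: theta_n | items, alpha_i | rest, d_ij | rest, correlation | theta.
// resp holds internal scores 0..c-1 with NA_INTEGER for missing cells;
// item_dim is 0-based. Proposal scales adapt during burn-in only, so the
// retained chains are draws from a fixed-kernel Markov chain.
// [[Rcpp::export]]
List cpp_fit_gpcm(IntegerMatrix resp, IntegerVector item_dim, int V, int c,
                  int n_chains, int n_burn, int n_iter,
                  double slope_m, double slope_sd, double int_sd,
                  bool est_items, NumericVector alpha_fix, NumericMatrix d_fix,
                  bool est_corr, bool use_joint = true, bool use_ridge = true) {
  const int N = resp.nrow(), K = resp.ncol(), cf = c - 1;
  const int T = n_chains * n_iter;
  NumericMatrix theta_st(T, N * V), alpha_st(T, K), d_st(T, K * cf),
      corr_st(T, V * V);
  IntegerVector chain_id(T);
  NumericVector acc_summary(4);

  // observed items per person (indices), persons per item
  std::vector<std::vector<int> > obs_items(N), obs_persons(K);
  for (int n = 0; n < N; n++)
    for (int i = 0; i < K; i++)
      if (resp(n, i) != NA_INTEGER) {
        obs_items[n].push_back(i);
        obs_persons[i].push_back(n);
      }

  const double theta_target = (V > 1) ? 0.25 : 0.44;
  long acc_theta = 0, try_theta = 0, acc_item = 0, try_item = 0,
       acc_corr = 0, try_corr = 0, acc_ridge = 0, try_ridge = 0;
  int row = 0;

  for (int ch = 0; ch < n_chains; ch++) {
    // state
    std::vector<double> theta(N * V), alpha(K), d(K * cf);
    for (int n = 0; n < N * V; n++) theta[n] = norm_rand();
    for (int i = 0; i < K; i++)
      alpha[i] = est_items ? 1.0 + 0.1 * norm_rand() : alpha_fix[i];
    for (int i = 0; i < K; i++)
      for (int j = 0; j < cf; j++)
        d[i * cf + j] = est_items ? 0.1 * norm_rand() : d_fix(i, j);
    std::vector<double> Rcor(V * V, 0.0), Lchol;
    for (int v = 0; v < V; v++) Rcor[v * V + v] = 1.0;
    chol_small(Rcor, V, Lchol);

    // adaptive proposal scales
    std::vector<double> s_theta(N, 0.5), s_alpha(K, 0.3), s_d(K * cf, 0.3);
    std::vector<double> s_corr(V * V, 0.1);
    std::vector<int> a_theta(N, 0), a_alpha(K, 0), a_d(K * cf, 0),
        a_corr(V * V, 0);

    // per-item joint (alpha, d) proposal with covariance learned during
    // burn-in (the free intercepts are strongly correlated a posteriori, so
    // scalar walks alone mix slowly)
    const int pj = 1 + cf;
    std::vector<double> jm(K * pj, 0.0), jc(K * pj * pj, 0.0),
        jl(K * pj * pj, 0.0), s_joint(K, 0.6);
    std::vector<int> a_joint(K, 0);
    std::vector<long> jn(K, 0);
    std::vector<bool> jl_ok(K, false);

    // global ridge-move scales (per dimension)
    std::vector<double> s_scale(V, 0.05), s_loc(V, 0.1);
    std::vector<int> a_scale(V, 0), a_loc(V, 0);

    for (int it = 0; it < n_burn + n_iter; it++) {
      const bool burn = it < n_burn;

      // --- theta block ---
      for (int n = 0; n < N; n++) {
        double prop[16], cur[16];
        for (int v = 0; v < V; v++) {
          cur[v] = theta[n + N * v];
          prop[v] = cur[v] + s_theta[n] * norm_rand();
        }
        double lr = mvn_logpdf(prop, Lchol, V) - mvn_logpdf(cur, Lchol, V);
        for (size_t q = 0; q < obs_items[n].size(); q++) {
          int i = obs_items[n][q], v = item_dim[i], x = resp(n, i);
          lr += cell_loglik(alpha[i] * prop[v], &d[i * cf], c, x) -
                cell_loglik(alpha[i] * cur[v], &d[i * cf], c, x);
        }
        try_theta++;
        if (std::log(unif_rand()) < lr) {
          for (int v = 0; v < V; v++) theta[n + N * v] = prop[v];
          a_theta[n]++;
          acc_theta++;
        }
      }

      // --- item block ---
      if (est_items) {
        for (int i = 0; i < K; i++) {
          int v = item_dim[i];
          // slope
          {
            double ap = alpha[i] + s_alpha[i] * norm_rand();
            double lr = (-0.5 * std::pow((ap - slope_m) / slope_sd, 2)) -
                        (-0.5 * std::pow((alpha[i] - slope_m) / slope_sd, 2));
            for (size_t q = 0; q < obs_persons[i].size(); q++) {
              int n = obs_persons[i][q], x = resp(n, i);
              double th = theta[n + N * v];
              lr += cell_loglik(ap * th, &d[i * cf], c, x) -
                    cell_loglik(alpha[i] * th, &d[i * cf], c, x);
            }
            try_item++;
            if (std::log(unif_rand()) < lr) { alpha[i] = ap; a_alpha[i]++; acc_item++; }
          }
          // free intercepts
          for (int j = 0; j < cf; j++) {
            double dp[16];
            for (int k = 0; k < cf; k++) dp[k] = d[i * cf + k];
            dp[j] += s_d[i * cf + j] * norm_rand();
            double lr = (-0.5 * std::pow(dp[j] / int_sd, 2)) -
                        (-0.5 * std::pow(d[i * cf + j] / int_sd, 2));
            for (size_t q = 0; q < obs_persons[i].size(); q++) {
              int n = obs_persons[i][q], x = resp(n, i);
              double ath = alpha[i] * theta[n + N * v];
              lr += cell_loglik(ath, dp, c, x) - cell_loglik(ath, &d[i * cf], c, x);
            }
            try_item++;
            if (std::log(unif_rand()) < lr) { d[i * cf + j] = dp[j]; a_d[i * cf + j]++; acc_item++; }
          }

          // joint (alpha, d) move along the learned covariance
          if (use_joint && jl_ok[i]) {
            double z[16], delta[16];
            for (int q = 0; q < pj; q++) z[q] = norm_rand();
            for (int q = 0; q < pj; q++) {
              double s = 0.0;
              for (int k = 0; k <= q; k++) s += jl[i * pj * pj + q * pj + k] * z[k];
              delta[q] = s_joint[i] * s;
            }
            double ap = alpha[i] + delta[0], dp[16];
            for (int k = 0; k < cf; k++) dp[k] = d[i * cf + k] + delta[1 + k];
            double lr = (-0.5 * std::pow((ap - slope_m) / slope_sd, 2)) -
                        (-0.5 * std::pow((alpha[i] - slope_m) / slope_sd, 2));
            for (int k = 0; k < cf; k++)
              lr += (-0.5 * std::pow(dp[k] / int_sd, 2)) -
                    (-0.5 * std::pow(d[i * cf + k] / int_sd, 2));
            for (size_t q = 0; q < obs_persons[i].size(); q++) {
              int n = obs_persons[i][q], x = resp(n, i);
              double th = theta[n + N * v];
              lr += cell_loglik(ap * th, dp, c, x) -
                    cell_loglik(alpha[i] * th, &d[i * cf], c, x);
            }
            try_item++;
            if (std::log(unif_rand()) < lr) {
              alpha[i] = ap;
              for (int k = 0; k < cf; k++) d[i * cf + k] = dp[k];
              a_joint[i]++;
              acc_item++;
            }
          }

          // running mean/covariance of (alpha, d) over burn-in draws
          if (burn) {
            double xv[16];
            xv[0] = alpha[i];
            for (int k = 0; k < cf; k++) xv[1 + k] = d[i * cf + k];
            jn[i]++;
            double w = 1.0 / jn[i];
            double dm[16];
            for (int q = 0; q < pj; q++) {
              dm[q] = xv[q] - jm[i * pj + q];
              jm[i * pj + q] += w * dm[q];
            }
            for (int q = 0; q < pj; q++)
              for (int k = 0; k < pj; k++)
                jc[i * pj * pj + q * pj + k] +=
                    dm[q] * (xv[k] - jm[i * pj + k]);
          }
        }
      }

      // --- global ridge moves (likelihood-invariant, prior-driven) ---
      // scale: (alpha_i, theta_v) -> (s*alpha_i, theta_v/s) for one
      // dimension; location: theta_v -> theta_v + m with intercepts
      // sheared by -x*alpha_i*m. Both leave every cell probability
      // unchanged, so acceptance depends on priors (and the Jacobian for
      // the scale move); they traverse the soft identification ridges that
      // coordinate-wise walks cross slowly.
      if (est_items && use_ridge) {
        for (int v = 0; v < V; v++) {
          int Kv = 0;
          for (int i = 0; i < K; i++) if (item_dim[i] == v) Kv++;
          // scale move
          {
            double ls = s_scale[v] * norm_rand();
            double s = std::exp(ls);
            double lr = (Kv - N) * ls;
            for (int i = 0; i < K; i++) if (item_dim[i] == v)
              lr += (-0.5 * std::pow((s * alpha[i] - slope_m) / slope_sd, 2)) -
                    (-0.5 * std::pow((alpha[i] - slope_m) / slope_sd, 2));
            double cur[16], prop[16];
            for (int n = 0; n < N; n++) {
              for (int u = 0; u < V; u++) {
                cur[u] = theta[n + N * u];
                prop[u] = (u == v) ? cur[u] / s : cur[u];
              }
              lr += mvn_logpdf(prop, Lchol, V) - mvn_logpdf(cur, Lchol, V);
            }
            try_ridge++;
            if (std::log(unif_rand()) < lr) {
              for (int i = 0; i < K; i++) if (item_dim[i] == v) alpha[i] *= s;
              for (int n = 0; n < N; n++) theta[n + N * v] /= s;
              a_scale[v]++;
              acc_ridge++;
            }
          }
          // location move
          {
            double m = s_loc[v] * norm_rand();
            double lr = 0.0;
            for (int i = 0; i < K; i++) if (item_dim[i] == v)
              for (int k = 0; k < cf; k++) {
                double dn = d[i * cf + k] - (k + 1) * alpha[i] * m;
                lr += (-0.5 * std::pow(dn / int_sd, 2)) -
                      (-0.5 * std::pow(d[i * cf + k] / int_sd, 2));
              }
            double cur[16], prop[16];
            for (int n = 0; n < N; n++) {
              for (int u = 0; u < V; u++) {
                cur[u] = theta[n + N * u];
                prop[u] = (u == v) ? cur[u] + m : cur[u];
              }
              lr += mvn_logpdf(prop, Lchol, V) - mvn_logpdf(cur, Lchol, V);
            }
            try_ridge++;
            if (std::log(unif_rand()) < lr) {
              for (int i = 0; i < K; i++) if (item_dim[i] == v)
                for (int k = 0; k < cf; k++)
                  d[i * cf + k] -= (k + 1) * alpha[i] * m;
              for (int n = 0; n < N; n++) theta[n + N * v] += m;
              a_loc[v]++;
              acc_ridge++;
            }
          }
        }
      }

      // --- correlation block (uniform prior over PD correlation matrices) ---
      if (est_corr && V > 1) {
        for (int a = 0; a < V; a++) for (int b = a + 1; b < V; b++) {
          std::vector<double> Rp(Rcor), Lp;
          double rp = Rcor[a * V + b] + s_corr[a * V + b] * norm_rand();
          Rp[a * V + b] = rp; Rp[b * V + a] = rp;
          try_corr++;
          if (std::fabs(rp) < 1.0 && chol_small(Rp, V, Lp)) {
            double lr = 0.0, cur[16];
            for (int n = 0; n < N; n++) {
              for (int v = 0; v < V; v++) cur[v] = theta[n + N * v];
              lr += mvn_logpdf(cur, Lp, V) - mvn_logpdf(cur, Lchol, V);
            }
            if (std::log(unif_rand()) < lr) {
              Rcor = Rp; Lchol = Lp; a_corr[a * V + b]++; acc_corr++;
            }
          }
        }
      }

      // --- adapt during burn-in ---
      if (burn && (it + 1) % 50 == 0) {
        for (int n = 0; n < N; n++) {
          double r = a_theta[n] / 50.0;
          s_theta[n] = std::min(10.0, std::max(1e-3, s_theta[n] * std::exp(r - theta_target)));
          a_theta[n] = 0;
        }
        if (est_items) {
          for (int i = 0; i < K; i++) {
            double r = a_alpha[i] / 50.0;
            s_alpha[i] = std::min(10.0, std::max(1e-3, s_alpha[i] * std::exp(r - 0.44)));
            a_alpha[i] = 0;
            for (int j = 0; j < cf; j++) {
              double rj = a_d[i * cf + j] / 50.0;
              s_d[i * cf + j] = std::min(10.0, std::max(1e-3, s_d[i * cf + j] * std::exp(rj - 0.44)));
              a_d[i * cf + j] = 0;
            }
            // refresh the joint-proposal Cholesky from the running covariance
            if (jn[i] >= 200) {
              std::vector<double> C(pj * pj), L;
              for (int q = 0; q < pj; q++)
                for (int k = 0; k < pj; k++) {
                  C[q * pj + k] = jc[i * pj * pj + q * pj + k] / (jn[i] - 1);
                  if (q == k) C[q * pj + k] += 1e-6;
                }
              if (chol_small(C, pj, L)) {
                for (int q = 0; q < pj * pj; q++) jl[i * pj * pj + q] = L[q];
                if (!jl_ok[i]) s_joint[i] = 2.38 / std::sqrt((double)pj);
                jl_ok[i] = true;
              }
            }
            if (jl_ok[i]) {
              double rj = a_joint[i] / 50.0;
              s_joint[i] = std::min(10.0, std::max(1e-3, s_joint[i] * std::exp(rj - 0.25)));
              a_joint[i] = 0;
            }
          }
        }
        if (est_items)
          for (int v = 0; v < V; v++) {
            double rs = a_scale[v] / 50.0, rl = a_loc[v] / 50.0;
            s_scale[v] = std::min(2.0, std::max(1e-4, s_scale[v] * std::exp(rs - 0.44)));
            s_loc[v] = std::min(5.0, std::max(1e-4, s_loc[v] * std::exp(rl - 0.44)));
            a_scale[v] = 0; a_loc[v] = 0;
          }
        if (est_corr && V > 1)
          for (int a = 0; a < V; a++) for (int b = a + 1; b < V; b++) {
            double r = a_corr[a * V + b] / 50.0;
            s_corr[a * V + b] = std::min(2.0, std::max(1e-3, s_corr[a * V + b] * std::exp(r - 0.44)));
            a_corr[a * V + b] = 0;
          }
      }

      // --- store ---
      if (!burn) {
        for (int q = 0; q < N * V; q++) theta_st(row, q) = theta[q];
        for (int i = 0; i < K; i++) alpha_st(row, i) = alpha[i];
        for (int q = 0; q < K * cf; q++) d_st(row, q) = d[q];
        for (int q = 0; q < V * V; q++) corr_st(row, q) = Rcor[q];
        chain_id[row] = ch + 1;
        row++;
      }
    }
  }

  acc_summary[0] = try_theta ? (double)acc_theta / try_theta : NA_REAL;
  acc_summary[1] = try_item ? (double)acc_item / try_item : NA_REAL;
  acc_summary[2] = try_corr ? (double)acc_corr / try_corr : NA_REAL;
  acc_summary[3] = try_ridge ? (double)acc_ridge / try_ridge : NA_REAL;

  return List::create(_["theta"] = theta_st, _["alpha"] = alpha_st,
                      _["d"] = d_st, _["corr"] = corr_st,
                      _["chain"] = chain_id, _["accept"] = acc_summary);
}

// One posterior-predictive replicate for a single joint draw. Missing cells
// of the template stay missing; for every observed cell a category is drawn
// from the GPCM probabilities at that draw. Also returns, per person, the
// expected number of extreme responses E(NE) over that person's observed
// items and the replicated extreme count.
// [[Rcpp::export]]
List cpp_replicate_one(NumericVector theta, NumericVector alpha, NumericMatrix d,
                       IntegerVector item_dim, IntegerMatrix resp, int c, int V) {
  const int N = resp.nrow(), K = resp.ncol(), cf = c - 1;
  IntegerMatrix rep(N, K);
  NumericVector E(N);
  IntegerVector ne_rep(N);
  double p[16];
  std::vector<double> dfree(cf);
  for (int n = 0; n < N; n++) {
    for (int i = 0; i < K; i++) {
      if (resp(n, i) == NA_INTEGER) { rep(n, i) = NA_INTEGER; continue; }
      int v = item_dim[i];
      for (int j = 0; j < cf; j++) dfree[j] = d(i, j);
      cat_probs(alpha[i] * theta[n + N * v], dfree.data(), c, p);
      E[n] += p[0] + p[c - 1];
      double u = unif_rand(), cum = 0.0;
      int x = c - 1;
      for (int k = 0; k < c; k++) { cum += p[k]; if (u < cum) { x = k; break; } }
      rep(n, i) = x + 1;  // external 1..c coding
      if (x == 0 || x == c - 1) ne_rep[n]++;
    }
  }
  return List::create(_["rep"] = rep, _["E"] = E, _["ne_rep"] = ne_rep);
}
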