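// Hierarchical Dirichlet process mixture over channel-categorical mutations:
// top node -> patient nodes -> branch nodes, uniform Dirichlet base over
// channels, one concentration parameter per level with vague Gamma(1,1)
// hyperpriors resampled by the auxiliary-variable method. Posterior sampling
// uses the direct-assignment (Chinese restaurant franchise) scheme with
// explicit stick weights at the top and patient levels.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Chinese restaurant table count: number of tables when n customers sit with
// concentration mass a.
static int crt(int n, double a) {
  if (n <= 0) return 0;
  int t = 1;
  for (int i = 1; i < n; ++i) {
    if (unif_rand() < a / (a + i)) ++t;
  }
  return t;
}

static double rgamma1(double shape, double rate) {
  if (shape <= 0.0) shape = 1e-3;
  return R::rgamma(shape, 1.0 / rate);
}

// [[Rcpp::export]]
List hdp_gibbs_cpp(IntegerVector x, IntegerVector branch,
                   IntegerVector patient_of_branch, int n_channels,
                   int burnin, int n_samples, int spacing,
                   double eta, double prior_shape, double prior_rate,
                   int init_k = 10) {
  RNGScope scope;
  const int N = x.size();
  const int J = patient_of_branch.size();
  int P = 0;
  for (int j = 0; j < J; ++j) P = std::max(P, patient_of_branch[j] + 1);
  const int C = n_channels;

  // state: start from a random partition into init_k dishes so the sampler
  // does not have to escape the K=1 mode through rare new-dish moves
  int K = std::max(1, init_k);
  std::vector<int> z(N, 0);
  std::vector<std::vector<int>> njk(J, std::vector<int>(K, 0));
  std::vector<std::vector<int>> nkc(K, std::vector<int>(C, 0));
  std::vector<int> nk(K, 0);
  for (int i = 0; i < N; ++i) {
    int k0 = (int)(unif_rand() * K);
    if (k0 >= K) k0 = K - 1;
    z[i] = k0;
    njk[branch[i]][k0]++;
    nkc[k0][x[i]]++;
    nk[k0]++;
  }
  std::vector<double> beta(K + 1, 1.0 / (K + 1));  // K weights + remainder
  std::vector<std::vector<double>> pi(P, std::vector<double>(K + 1, 1.0 / (K + 1)));
  double conc_b = 1.0, conc_p = 1.0, conc_g = 1.0;

  std::vector<int> n_j(J, 0);
  for (int i = 0; i < N; ++i) n_j[branch[i]]++;

  List out_spectra, out_exposures;
  std::vector<double> prob;

  int total_iter = burnin + n_samples * spacing;
  for (int iter = 1; iter <= total_iter; ++iter) {
    // 1. resample cluster assignments
    for (int i = 0; i < N; ++i) {
      int j = branch[i], p = patient_of_branch[j], c = x[i];
      int k_old = z[i];
      njk[j][k_old]--; nkc[k_old][c]--; nk[k_old]--;

      prob.assign(K + 1, 0.0);
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        double lik = (nkc[k][c] + eta) / (nk[k] + C * eta);
        prob[k] = (njk[j][k] + conc_b * pi[p][k]) * lik;
        tot += prob[k];
      }
      prob[K] = conc_b * pi[p][K] / C;
      tot += prob[K];

      double u = unif_rand() * tot;
      int k_new = 0;
      double acc = 0.0;
      for (int k = 0; k <= K; ++k) {
        acc += prob[k];
        if (u <= acc) { k_new = k; break; }
        k_new = k;
      }

      if (k_new == K) {
        // open a new dish: split the remainder sticks at both levels
        for (int j2 = 0; j2 < J; ++j2) njk[j2].push_back(0);
        nkc.push_back(std::vector<int>(C, 0));
        nk.push_back(0);
        double nu = R::rbeta(1.0, conc_g);
        double beta_u_old = beta[K];
        beta[K] = nu * beta_u_old;
        beta.push_back((1.0 - nu) * beta_u_old);
        for (int pp = 0; pp < P; ++pp) {
          double bsplit = R::rbeta(std::max(conc_p * beta[K], 1e-3),
                                   std::max(conc_p * beta[K + 1], 1e-3));
          double pi_u_old = pi[pp][K];
          pi[pp][K] = bsplit * pi_u_old;
          pi[pp].push_back((1.0 - bsplit) * pi_u_old);
        }
        K++;
      }
      z[i] = k_new;
      njk[j][k_new]++; nkc[k_new][c]++; nk[k_new]++;
    }

    // 2. table counts: branch level then patient level
    std::vector<std::vector<int>> m_pk(P, std::vector<int>(K, 0));
    std::vector<int> t_k(K, 0);
    std::vector<int> tables_j(J, 0);
    std::vector<int> M_p(P, 0), T_p(P, 0);
    for (int j = 0; j < J; ++j) {
      int p = patient_of_branch[j];
      for (int k = 0; k < K; ++k) {
        if (njk[j][k] > 0) {
          int m = crt(njk[j][k], conc_b * std::max(pi[p][k], 1e-12));
          m_pk[p][k] += m;
          tables_j[j] += m;
        }
      }
    }
    for (int p = 0; p < P; ++p) {
      for (int k = 0; k < K; ++k) {
        M_p[p] += m_pk[p][k];
        if (m_pk[p][k] > 0) {
          int t = crt(m_pk[p][k], conc_p * std::max(beta[k], 1e-12));
          t_k[k] += t;
          T_p[p] += t;
        }
      }
    }

    // 3. global sticks and patient weights
    {
      double s = 0.0;
      std::vector<double> g(K + 1);
      for (int k = 0; k < K; ++k) { g[k] = rgamma1(t_k[k], 1.0); s += g[k]; }
      g[K] = rgamma1(conc_g, 1.0); s += g[K];
      for (int k = 0; k <= K; ++k) beta[k] = g[k] / s;
      for (int p = 0; p < P; ++p) {
        double sp = 0.0;
        for (int k = 0; k < K; ++k) {
          pi[p][k] = rgamma1(conc_p * beta[k] + m_pk[p][k], 1.0);
          sp += pi[p][k];
        }
        pi[p][K] = rgamma1(std::max(conc_p * beta[K], 1e-6), 1.0);
        sp += pi[p][K];
        for (int k = 0; k <= K; ++k) pi[p][k] /= sp;
      }
    }

    // 4. concentration parameters (auxiliary-variable resampling)
    {
      // branch level: customers n_j, tables tables_j
      double sum_log_w = 0.0; int sum_s = 0, T = 0;
      for (int j = 0; j < J; ++j) {
        if (n_j[j] == 0) continue;
        double w = R::rbeta(conc_b + 1.0, (double)n_j[j]);
        sum_log_w += std::log(std::max(w, 1e-300));
        if (unif_rand() < n_j[j] / (n_j[j] + conc_b)) sum_s++;
        T += tables_j[j];
      }
      conc_b = rgamma1(prior_shape + T - sum_s, prior_rate - sum_log_w);

      // patient level: customers M_p, tables T_p
      sum_log_w = 0.0; sum_s = 0; T = 0;
      for (int p = 0; p < P; ++p) {
        if (M_p[p] == 0) continue;
        double w = R::rbeta(conc_p + 1.0, (double)M_p[p]);
        sum_log_w += std::log(std::max(w, 1e-300));
        if (unif_rand() < M_p[p] / (M_p[p] + conc_p)) sum_s++;
        T += T_p[p];
      }
      conc_p = rgamma1(prior_shape + T - sum_s, prior_rate - sum_log_w);

      // top level: customers = total patient tables, tables = K active
      int M = 0;
      for (int k = 0; k < K; ++k) M += t_k[k];
      if (M > 0) {
        double w = R::rbeta(conc_g + 1.0, (double)M);
        int s = unif_rand() < M / (M + conc_g) ? 1 : 0;
        conc_g = rgamma1(prior_shape + K - s, prior_rate - std::log(std::max(w, 1e-300)));
      }
    }

    // 5. drop empty dishes
    {
      std::vector<int> map(K, -1);
      int K2 = 0;
      for (int k = 0; k < K; ++k) {
        if (nk[k] > 0) map[k] = K2++;
      }
      if (K2 < K) {
        double freed = 0.0;
        std::vector<double> beta2(K2 + 1);
        std::vector<std::vector<double>> pi2(P, std::vector<double>(K2 + 1));
        std::vector<std::vector<int>> nkc2;
        std::vector<int> nk2;
        for (int k = 0; k < K; ++k) {
          if (map[k] >= 0) {
            beta2[map[k]] = beta[k];
            nkc2.push_back(nkc[k]);
            nk2.push_back(nk[k]);
            for (int p = 0; p < P; ++p) pi2[p][map[k]] = pi[p][k];
          } else {
            freed += beta[k];
          }
        }
        beta2[K2] = beta[K] + freed;
        for (int p = 0; p < P; ++p) {
          double freed_p = 0.0;
          for (int k = 0; k < K; ++k) if (map[k] < 0) freed_p += pi[p][k];
          pi2[p][K2] = pi[p][K] + freed_p;
        }
        for (int j = 0; j < J; ++j) {
          std::vector<int> nj2(K2, 0);
          for (int k = 0; k < K; ++k) if (map[k] >= 0) nj2[map[k]] = njk[j][k];
          njk[j] = nj2;
        }
        for (int i = 0; i < N; ++i) z[i] = map[z[i]];
        beta = beta2; pi = pi2; nkc = nkc2; nk = nk2; K = K2;
      }
    }

    // record
    if (iter > burnin && (iter - burnin) % spacing == 0) {
      IntegerMatrix sp(K, C);
      for (int k = 0; k < K; ++k)
        for (int c = 0; c < C; ++c) sp(k, c) = nkc[k][c];
      IntegerMatrix ex(J, K);
      for (int j = 0; j < J; ++j)
        for (int k = 0; k < K; ++k) ex(j, k) = njk[j][k];
      out_spectra.push_back(sp);
      out_exposures.push_back(ex);
    }
  }

  return List::create(_["spectra"] = out_spectra,
                      _["exposures"] = out_exposures,
                      _["conc"] = NumericVector::create(conc_g, conc_p, conc_b));
}
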