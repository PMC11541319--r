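// Metropolis-within-Gibbs sampler for the heteroskedastic Tobit model
// with demographic scale parameters.
//
// The likelihood is evaluated on unique (state, cell) groups using the
// Gaussian sufficient statistics of each group's observations (count,
// sum and sum of squares of the uncensored values, count of censored
// values).  Each parameter block only touches the groups whose (mu,
// sigma) it can change, with a per-group log-likelihood cache, so one
// full Gibbs scan costs a few thousand scalar evaluations regardless of
// the number of respondents.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

constexpr double LOG_SQRT_2PI = 0.9189385332046727417803297364;

// deterministic RNG: mt19937_64 + Box-Muller (std::normal_distribution
// is implementation-defined, so normals are generated explicitly)
struct Rng {
  std::mt19937_64 gen;
  bool have_spare = false;
  double spare = 0.0;
  explicit Rng(uint64_t seed) : gen(seed) {}
  double unif() {  // (0, 1)
    return (static_cast<double>(gen() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 6.283185307179586476925287 * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

// log of the standard normal CDF, accurate into the far lower tail
double log_norm_cdf(double z) {
  if (z > -37.0) {
    return std::log(0.5 * std::erfc(-z * M_SQRT1_2));
  }
  double z2 = z * z;
  return -0.5 * z2 - std::log(-z) - LOG_SQRT_2PI +
         std::log1p(-1.0 / z2 + 3.0 / (z2 * z2));
}

struct Model {
  int K = 0, G = 8;
  std::vector<std::array<int, 10>> X;  // group dummies
  std::vector<int> cell;               // 0-based
  std::vector<double> n_unc, sum_v, sum_v2, n_cens;
  double censor = -1.0;
  // parameter vector: 0 beta0, 1..10 beta, 11..15 gamma, 16+d*G+c phi
  std::vector<double> p;
  std::vector<double> ll;  // per-group cached log-likelihood
  double total_ll = 0.0;
  // affected group indices per block
  std::vector<int> all_groups;
  std::array<std::vector<int>, 10> beta_groups;
  std::vector<std::vector<int>> phi_groups;  // 5*G entries, d*G+c

  int phi_idx(int d, int c) const { return 16 + d * G + c; }

  double group_ll(int k) const {
    double mu = p[0];
    int c = cell[k];
    for (int d = 0; d < 5; ++d) {
      double contrib = 0.0;
      if (X[k][2 * d]) contrib += p[1 + 2 * d];
      if (X[k][2 * d + 1]) contrib += p[2 + 2 * d];
      if (contrib != 0.0) mu += contrib * p[phi_idx(d, c)];
    }
    double lg = p[11] + mu * (p[12] + mu * (p[13] + mu * (p[14] + mu * p[15])));
    if (lg > 350.0 || !std::isfinite(lg)) return -std::numeric_limits<double>::infinity();
    double sg = std::exp(lg);
    double out = 0.0;
    if (n_unc[k] > 0) {
      double ss = sum_v2[k] - 2.0 * mu * sum_v[k] + n_unc[k] * mu * mu;
      out += -n_unc[k] * (lg + LOG_SQRT_2PI) - ss / (2.0 * sg * sg);
    }
    if (n_cens[k] > 0) {
      out += n_cens[k] * log_norm_cdf((censor - mu) / sg);
    }
    return out;
  }

  // sum of fresh group log-likelihoods over a set, written to scratch
  double eval_set(const std::vector<int>& idx, std::vector<double>& scratch) {
    scratch.resize(idx.size());
    double s = 0.0;
    for (size_t i = 0; i < idx.size(); ++i) {
      scratch[i] = group_ll(idx[i]);
      s += scratch[i];
    }
    return s;
  }
  double cached_sum(const std::vector<int>& idx) const {
    double s = 0.0;
    for (int k : idx) s += ll[k];
    return s;
  }
  void commit(const std::vector<int>& idx, const std::vector<double>& scratch) {
    for (size_t i = 0; i < idx.size(); ++i) {
      total_ll += scratch[i] - ll[idx[i]];
      ll[idx[i]] = scratch[i];
    }
  }
  void init_cache() {
    ll.assign(K, 0.0);
    total_ll = 0.0;
    for (int k = 0; k < K; ++k) { ll[k] = group_ll(k); total_ll += ll[k]; }
  }
};

double lnorm_logpdf(double x, double m, double s) {
  if (x <= 0) return -std::numeric_limits<double>::infinity();
  double z = (std::log(x) - m) / s;
  return -std::log(x) - std::log(s) - LOG_SQRT_2PI - 0.5 * z * z;
}

}  // namespace

// [[Rcpp::export(name = ".tobit_group_loglik_cpp")]]
double tobit_group_loglik_cpp(IntegerMatrix X, IntegerVector cell,
                              NumericVector n_unc, NumericVector sum_v,
                              NumericVector sum_v2, NumericVector n_cens,
                              int G, NumericVector params, double censor) {
  Model m;
  m.K = X.nrow(); m.G = G; m.censor = censor;
  m.X.resize(m.K); m.cell.resize(m.K);
  for (int k = 0; k < m.K; ++k) {
    for (int j = 0; j < 10; ++j) m.X[k][j] = X(k, j);
    m.cell[k] = cell[k] - 1;
  }
  m.n_unc = as<std::vector<double>>(n_unc);
  m.sum_v = as<std::vector<double>>(sum_v);
  m.sum_v2 = as<std::vector<double>>(sum_v2);
  m.n_cens = as<std::vector<double>>(n_cens);
  m.p = as<std::vector<double>>(params);
  double s = 0.0;
  for (int k = 0; k < m.K; ++k) s += m.group_ll(k);
  return s;
}

// [[Rcpp::export(name = ".run_tobit_chain_cpp")]]
List run_tobit_chain_cpp(IntegerMatrix X, IntegerVector cell,
                         NumericVector n_unc, NumericVector sum_v,
                         NumericVector sum_v2, NumericVector n_cens,
                         int G, NumericVector init, double censor,
                         int n_burnin, int n_total, int thin,
                         double seed, bool antithetic, bool adapt,
                         NumericVector step_init, double slice_w,
                         double prior_sd, double phi_log_mean,
                         double phi_log_sd) {
  Model m;
  m.K = X.nrow(); m.G = G; m.censor = censor;
  m.X.resize(m.K); m.cell.resize(m.K);
  for (int k = 0; k < m.K; ++k) {
    for (int j = 0; j < 10; ++j) m.X[k][j] = X(k, j);
    m.cell[k] = cell[k] - 1;
  }
  m.n_unc = as<std::vector<double>>(n_unc);
  m.sum_v = as<std::vector<double>>(sum_v);
  m.sum_v2 = as<std::vector<double>>(sum_v2);
  m.n_cens = as<std::vector<double>>(n_cens);
  m.p = as<std::vector<double>>(init);
  const int P = 16 + 5 * G;
  if ((int)m.p.size() != P) stop("init has wrong length");

  // affected-group index lists
  m.all_groups.resize(m.K);
  for (int k = 0; k < m.K; ++k) m.all_groups[k] = k;
  for (int j = 0; j < 10; ++j)
    for (int k = 0; k < m.K; ++k)
      if (m.X[k][j]) m.beta_groups[j].push_back(k);
  m.phi_groups.assign(5 * G, {});
  for (int k = 0; k < m.K; ++k)
    for (int d = 0; d < 5; ++d)
      if (m.X[k][2 * d] || m.X[k][2 * d + 1])
        m.phi_groups[d * G + m.cell[k]].push_back(k);

  m.init_cache();
  if (!std::isfinite(m.total_ll))
    stop("non-finite log-likelihood at the initial parameter values");

  Rng rng(static_cast<uint64_t>(seed));
  std::vector<double> step(16), ls(16);
  for (int j = 0; j < 16; ++j) {
    step[j] = step_init[j];
    ls[j] = std::log(step[j]);
  }
  std::vector<double> z_store(16, 0.0);
  std::vector<int> acc_count(16, 0), prop_count(16, 0);
  std::vector<double> scratch;

  const int n_ret = (n_total - n_burnin) / thin;
  NumericMatrix draws(n_ret, P + 1);
  int row = 0;

  for (int scan = 0; scan < n_total; ++scan) {
    bool burn = scan < n_burnin;
    bool mirror = antithetic && (scan % 2 == 1);
    // --- Metropolis updates: beta0, beta1..10, gamma0..4 ---
    for (int j = 0; j < 16; ++j) {
      double z;
      if (mirror) z = -z_store[j];
      else { z = rng.norm(); z_store[j] = z; }
      const std::vector<int>& A =
          (j >= 1 && j <= 10) ? m.beta_groups[j - 1] : m.all_groups;
      double cur = m.p[j];
      double prop = cur + step[j] * z;
      double dprior = -(prop * prop - cur * cur) / (2.0 * prior_sd * prior_sd);
      m.p[j] = prop;
      double new_sum = m.eval_set(A, scratch);
      double delta = dprior + new_sum - m.cached_sum(A);
      bool ok = std::isfinite(new_sum) &&
                std::log(rng.unif()) < delta;
      if (ok) {
        m.commit(A, scratch);
        ++acc_count[j];
      } else {
        m.p[j] = cur;
      }
      ++prop_count[j];
      if (burn && adapt) {
        double eta = std::pow(scan + 1.0, -0.6);
        ls[j] += eta * ((ok ? 1.0 : 0.0) - 0.44);
        if (ls[j] < -12.0) ls[j] = -12.0;
        if (ls[j] > 5.0) ls[j] = 5.0;
        step[j] = std::exp(ls[j]);
      }
    }
    // --- slice updates for the free phi coordinates ---
    for (int d = 0; d < 5; ++d) {
      int der = m.phi_idx(d, G - 1);
      for (int c = 0; c < G - 1; ++c) {
        int pj = m.phi_idx(d, c);
        double x0 = m.p[pj];
        double derived0 = m.p[der];
        double total0 = x0 + derived0;  // conserved by the update
        // affected groups: this cell and the derived cell, dimension d
        std::vector<int>& A1 = m.phi_groups[d * G + c];
        std::vector<int>& A2 = m.phi_groups[d * G + (G - 1)];
        auto g = [&](double x) -> double {
          if (x <= 0.0 || x >= total0) return -std::numeric_limits<double>::infinity();
          m.p[pj] = x;
          m.p[der] = total0 - x;
          double s = lnorm_logpdf(x, phi_log_mean, phi_log_sd);
          for (int k : A1) s += m.group_ll(k);
          for (int k : A2) s += m.group_ll(k);
          return s;
        };
        double g0 = g(x0);
        double y = g0 + std::log(rng.unif());  // slice level
        // stepping out within (0, total0)
        double w = slice_w;
        double L = x0 - w * rng.unif();
        double R = L + w;
        int expand = 0;
        while (L > 0.0 && g(L) > y && expand < 100) { L -= w; ++expand; }
        if (L < 0.0) L = 0.0;
        while (R < total0 && g(R) > y && expand < 200) { R += w; ++expand; }
        if (R > total0) R = total0;
        if (expand >= 200) stop("slice sampler failed to bracket the slice");
        // shrinkage
        double x1 = x0;
        for (int it = 0; it < 200; ++it) {
          x1 = L + rng.unif() * (R - L);
          if (g(x1) > y) break;
          if (x1 < x0) L = x1; else R = x1;
          if (it == 199) x1 = x0;  // degenerate slice: stay put
        }
        // leave state at x1 and refresh the cache for affected groups
        m.p[pj] = x1;
        m.p[der] = total0 - x1;
        for (int k : A1) { double v = m.group_ll(k); m.total_ll += v - m.ll[k]; m.ll[k] = v; }
        for (int k : A2) { double v = m.group_ll(k); m.total_ll += v - m.ll[k]; m.ll[k] = v; }
      }
    }
    if (!burn && ((scan - n_burnin) % thin == thin - 1)) {
      for (int j = 0; j < P; ++j) draws(row, j) = m.p[j];
      draws(row, P) = m.total_ll;
      ++row;
    }
    if (scan % 512 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector acc(16), fstep(16);
  for (int j = 0; j < 16; ++j) {
    acc[j] = prop_count[j] ? (double)acc_count[j] / prop_count[j] : NA_REAL;
    fstep[j] = step[j];
  }
  return List::create(_["draws"] = draws, _["accept_rate"] = acc,
                      _["final_step"] = fstep);
}
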