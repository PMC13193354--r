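// Compute-heavy kernels: Monte-Carlo exact HWE pairing, permutation G-test
// for genotypic LD, simulated-annealing mixture clustering, admixture EM,
// and the pairwise squared genotype-distance matrix.
//
// RNG: self-contained mt19937_64 with hand-rolled uniform mappings so that
// streams are identical across compilers and standard libraries.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Rng {
  std::mt19937_64 gen;
  explicit Rng(uint64_t seed) : gen(seed) {}
  // uniform double in [0,1)
  double unif() { return (gen() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  int below(int n) { return (int)(unif() * n) % n; }
  template <typename T> void shuffle(std::vector<T>& v) {
    for (int i = (int)v.size() - 1; i > 0; --i) {
      int j = below(i + 1);
      std::swap(v[i], v[j]);
    }
  }
};

}  // namespace

// Monte-Carlo exact HWE probability test: random pairings of the 2n gene
// copies sample genotype arrays from the conditional null. Returns the
// number of resampled arrays with conditional probability <= observed
// (compared via the array score s = h*log2 - sum(log n_ab!), the only
// non-constant part given fixed allele counts).
// copies: 1-based allele indices of all 2n gene copies; s_obs: observed score.
// [[Rcpp::export]]
int cpp_hwe_mc(IntegerVector copies, int n_alleles, double s_obs,
               int B, int seed) {
  const int m = copies.size();
  const int n = m / 2;
  const int k = n_alleles;
  std::vector<int> cp(copies.begin(), copies.end());
  std::vector<double> lfact(m + 1, 0.0);
  for (int i = 0; i <= m; ++i) lfact[i] = std::lgamma(i + 1.0);
  const double ln2 = std::log(2.0);
  Rng rng((uint64_t)seed);
  std::vector<int> cnt(k * k, 0);
  std::vector<int> used;
  used.reserve(n);
  int hits = 0;
  for (int b = 0; b < B; ++b) {
    rng.shuffle(cp);
    used.clear();
    int h = 0;
    for (int i = 0; i < n; ++i) {
      int a = cp[2 * i] - 1, c = cp[2 * i + 1] - 1;
      if (a != c) ++h;
      int lo = a < c ? a : c, hi = a < c ? c : a;
      int idx = lo * k + hi;
      if (cnt[idx] == 0) used.push_back(idx);
      cnt[idx]++;
    }
    double s = h * ln2;
    for (size_t u = 0; u < used.size(); ++u) {
      s -= lfact[cnt[used[u]]];
      cnt[used[u]] = 0;
    }
    if (s <= s_obs + 1e-9) ++hits;
  }
  return hits;
}

static double g_stat(const std::vector<int>& x, const std::vector<int>& y,
                     int r, int c, std::vector<int>& tab,
                     std::vector<int>& rs, std::vector<int>& cs) {
  const int n = (int)x.size();
  std::fill(tab.begin(), tab.end(), 0);
  std::fill(rs.begin(), rs.end(), 0);
  std::fill(cs.begin(), cs.end(), 0);
  for (int i = 0; i < n; ++i) {
    tab[(x[i] - 1) * c + (y[i] - 1)]++;
    rs[x[i] - 1]++;
    cs[y[i] - 1]++;
  }
  double G = 0.0;
  for (int i = 0; i < r; ++i)
    for (int j = 0; j < c; ++j) {
      int o = tab[i * c + j];
      if (o > 0) {
        double e = (double)rs[i] * cs[j] / n;
        G += 2.0 * o * std::log(o / e);
      }
    }
  return G;
}

// Permutation G-test of independence between two genotype-class columns.
// Returns c(G_obs, hits) where hits = #permutations with G >= G_obs.
// [[Rcpp::export]]
NumericVector cpp_ld_perm(IntegerVector xi, IntegerVector yi, int n_x,
                          int n_y, int B, int seed) {
  std::vector<int> x(xi.begin(), xi.end()), y(yi.begin(), yi.end());
  std::vector<int> tab(n_x * n_y), rs(n_x), cs(n_y);
  double g_obs = g_stat(x, y, n_x, n_y, tab, rs, cs);
  Rng rng((uint64_t)seed);
  int hits = 0;
  for (int b = 0; b < B; ++b) {
    rng.shuffle(y);
    if (g_stat(x, y, n_x, n_y, tab, rs, cs) >= g_obs - 1e-9) ++hits;
  }
  return NumericVector::create(g_obs, (double)hits);
}

namespace {

// shared state for mixture profile likelihood
struct MixState {
  int n, L, K, totA;
  const int* G;          // n x 2L column-major, 0 = missing
  std::vector<int> A, off;
  std::vector<double> beta_term;  // unused
  double beta;
  std::vector<int> cnt;       // K x totA: cnt[k*totA + off[l]+a]
  std::vector<int> ncop;      // K x L gene copies
  std::vector<double> term;   // K x L cluster-locus log-lik term
  std::vector<double> lg_cnt; // log(c + beta), c = 0..2n
  std::vector<double> lg_den; // log(nc + beta*A[l]), per locus x nc

  void build_tables() {
    lg_cnt.resize(2 * n + 1);
    for (int c = 0; c <= 2 * n; ++c) lg_cnt[c] = std::log(c + beta);
    lg_den.resize((size_t)L * (2 * n + 1));
    for (int l = 0; l < L; ++l)
      for (int nc = 0; nc <= 2 * n; ++nc)
        lg_den[(size_t)l * (2 * n + 1) + nc] = std::log(nc + beta * A[l]);
  }
  double locus_term(int k, int l) const {
    int nc = ncop[k * L + l];
    if (nc == 0) return 0.0;
    double denom = lg_den[(size_t)l * (2 * n + 1) + nc];
    double t = 0.0;
    const int* c = &cnt[k * totA + off[l]];
    for (int a = 0; a < A[l]; ++a)
      if (c[a] > 0) t += c[a] * (lg_cnt[c[a]] - denom);
    return t;
  }
  void add_ind(int i, int k, int sign) {
    for (int l = 0; l < L; ++l) {
      int a1 = G[i + (size_t)n * (2 * l)];
      if (a1 == 0) continue;
      int a2 = G[i + (size_t)n * (2 * l + 1)];
      cnt[k * totA + off[l] + a1 - 1] += sign;
      cnt[k * totA + off[l] + a2 - 1] += sign;
      ncop[k * L + l] += 2 * sign;
    }
  }
  double total() const {
    double s = 0.0;
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l) s += term[k * L + l];
    return s;
  }
};

}  // namespace

// Profile-likelihood mixture clustering by Metropolis annealing over
// single-individual reassignments. Cluster allele frequencies are profiled
// out with a beta pseudo-count per allele. Returns the best state visited
// (never worse than the initial state).
// [[Rcpp::export]]
List cpp_mix_anneal(IntegerMatrix Gm, IntegerVector Av, int K,
                    IntegerVector z0, int n_sweeps, double cool,
                    double beta, int stop_sweeps, int seed) {
  MixState st;
  st.n = Gm.nrow();
  st.L = Av.size();
  st.K = K;
  st.G = INTEGER(Gm);
  st.A.assign(Av.begin(), Av.end());
  st.off.resize(st.L);
  st.totA = 0;
  for (int l = 0; l < st.L; ++l) { st.off[l] = st.totA; st.totA += st.A[l]; }
  st.beta = beta;
  st.cnt.assign((size_t)K * st.totA, 0);
  st.ncop.assign((size_t)K * st.L, 0);
  st.term.assign((size_t)K * st.L, 0.0);
  st.build_tables();

  std::vector<int> z(z0.begin(), z0.end());
  for (int i = 0; i < st.n; ++i) st.add_ind(i, z[i] - 1, +1);
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < st.L; ++l) st.term[k * st.L + l] = st.locus_term(k, l);
  double cur = st.total();
  std::vector<int> best_z = z;
  double best = cur;
  if (K > 1) {
    // initial temperature: spread of per-individual log-lik contributions
    std::vector<double> contrib(st.n, 0.0);
    for (int i = 0; i < st.n; ++i) {
      int k = z[i] - 1;
      double s = 0.0;
      for (int l = 0; l < st.L; ++l) {
        int a1 = st.G[i + (size_t)st.n * (2 * l)];
        if (a1 == 0) continue;
        int a2 = st.G[i + (size_t)st.n * (2 * l + 1)];
        double denom = std::log(st.ncop[k * st.L + l] + beta * st.A[l]);
        s += std::log(st.cnt[k * st.totA + st.off[l] + a1 - 1] + beta) - denom;
        s += std::log(st.cnt[k * st.totA + st.off[l] + a2 - 1] + beta) - denom;
      }
      contrib[i] = s;
    }
    double mu = 0.0, ss = 0.0;
    for (int i = 0; i < st.n; ++i) mu += contrib[i];
    mu /= st.n;
    for (int i = 0; i < st.n; ++i) ss += (contrib[i] - mu) * (contrib[i] - mu);
    double T = st.n > 1 ? std::sqrt(ss / (st.n - 1)) : 1.0;
    if (T <= 0) T = 1.0;

    Rng rng((uint64_t)seed);
    std::vector<int> order(st.n);
    for (int i = 0; i < st.n; ++i) order[i] = i;
    std::vector<double> old_terms(2 * st.L), new_terms(2 * st.L);
    int quiet = 0;
    for (int sweep = 0; sweep < n_sweeps; ++sweep) {
      rng.shuffle(order);
      int accepted = 0;
      for (int oi = 0; oi < st.n; ++oi) {
        int i = order[oi];
        int k = z[i] - 1;
        int k2 = rng.below(K - 1);
        if (k2 >= k) ++k2;
        double delta = 0.0;
        for (int l = 0; l < st.L; ++l) {
          old_terms[l] = st.term[k * st.L + l];
          old_terms[st.L + l] = st.term[k2 * st.L + l];
        }
        st.add_ind(i, k, -1);
        st.add_ind(i, k2, +1);
        for (int l = 0; l < st.L; ++l) {
          if (st.G[i + (size_t)st.n * (2 * l)] == 0) {
            new_terms[l] = old_terms[l];
            new_terms[st.L + l] = old_terms[st.L + l];
            continue;
          }
          new_terms[l] = st.locus_term(k, l);
          new_terms[st.L + l] = st.locus_term(k2, l);
          delta += new_terms[l] - old_terms[l] +
                   new_terms[st.L + l] - old_terms[st.L + l];
        }
        bool accept = delta >= 0 || rng.unif() < std::exp(delta / T);
        if (accept) {
          z[i] = k2 + 1;
          cur += delta;
          for (int l = 0; l < st.L; ++l) {
            st.term[k * st.L + l] = new_terms[l];
            st.term[k2 * st.L + l] = new_terms[st.L + l];
          }
          ++accepted;
          if (cur > best) { best = cur; best_z = z; }
        } else {
          st.add_ind(i, k2, -1);
          st.add_ind(i, k, +1);
        }
      }
      T *= cool;
      quiet = accepted == 0 ? quiet + 1 : 0;
      if (quiet >= stop_sweeps) break;
    }
  }
  return List::create(_["z"] = IntegerVector(best_z.begin(), best_z.end()),
                      _["logL"] = best);
}

// Log-likelihood of genotypes under admixture proportions Q (n x K) and
// cluster allele frequencies P (totA x K, per-locus blocks each summing
// to 1 columnwise).
// [[Rcpp::export]]
double cpp_admix_loglik(IntegerMatrix Gm, IntegerVector Av,
                        NumericMatrix Q, NumericMatrix P) {
  const int n = Gm.nrow(), L = Av.size(), K = Q.ncol();
  std::vector<int> off(L);
  int totA = 0;
  for (int l = 0; l < L; ++l) { off[l] = totA; totA += Av[l]; }
  double logL = 0.0;
  for (int i = 0; i < n; ++i)
    for (int l = 0; l < L; ++l) {
      int a1 = Gm(i, 2 * l);
      if (a1 == 0) continue;
      int a2 = Gm(i, 2 * l + 1);
      int c1 = off[l] + a1 - 1, c2 = off[l] + a2 - 1;
      double d1 = 0.0, d2 = 0.0;
      for (int k = 0; k < K; ++k) {
        d1 += Q(i, k) * P(c1, k);
        d2 += Q(i, k) * P(c2, k);
      }
      logL += std::log(d1) + std::log(d2);
    }
  return logL;
}

// EM for the admixture model. Missing calls are skipped. Returns the
// final Q, P, the per-iteration log-likelihood trace, and convergence info.
// [[Rcpp::export]]
List cpp_admix_em(IntegerMatrix Gm, IntegerVector Av, NumericMatrix Q0,
                  NumericMatrix P0, double tol, int max_iter) {
  const int n = Gm.nrow(), L = Av.size(), K = Q0.ncol();
  std::vector<int> off(L);
  int totA = 0;
  for (int l = 0; l < L; ++l) { off[l] = totA; totA += Av[l]; }
  NumericMatrix Q = clone(Q0), P = clone(P0);
  NumericMatrix Qn(n, K), Pn(totA, K);
  std::vector<double> trace;
  trace.reserve(max_iter);
  bool converged = false;
  int it = 0;
  double prev = R_NegInf;
  for (it = 0; it < max_iter; ++it) {
    std::fill(Qn.begin(), Qn.end(), 0.0);
    std::fill(Pn.begin(), Pn.end(), 0.0);
    double logL = 0.0;
    std::vector<double> r(K);
    for (int i = 0; i < n; ++i) {
      double tot_i = 0.0;
      for (int l = 0; l < L; ++l) {
        int a1 = Gm(i, 2 * l);
        if (a1 == 0) continue;
        int a2 = Gm(i, 2 * l + 1);
        int cc[2] = {off[l] + a1 - 1, off[l] + a2 - 1};
        for (int c = 0; c < 2; ++c) {
          double denom = 0.0;
          for (int k = 0; k < K; ++k) {
            r[k] = Q(i, k) * P(cc[c], k);
            denom += r[k];
          }
          if (denom <= 0) return List::create(_["failed"] = true);
          logL += std::log(denom);
          for (int k = 0; k < K; ++k) {
            double rk = r[k] / denom;
            Qn(i, k) += rk;
            Pn(cc[c], k) += rk;
          }
          tot_i += 1.0;
        }
      }
      if (tot_i > 0)
        for (int k = 0; k < K; ++k) Q(i, k) = Qn(i, k) / tot_i;
    }
    trace.push_back(logL);
    // M-step for P: normalise per (cluster, locus) block
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l) {
        double s = 0.0;
        for (int a = 0; a < Av[l]; ++a) s += Pn(off[l] + a, k);
        if (s > 0)
          for (int a = 0; a < Av[l]; ++a) P(off[l] + a, k) = Pn(off[l] + a, k) / s;
        // s == 0: cluster has no mass at this locus; keep previous P
      }
    if (it > 0 && trace[it] - prev < tol && trace[it] >= prev - 1e-8) {
      converged = true;
      prev = trace[it];
      ++it;
      break;
    }
    prev = trace[it];
  }
  return List::create(_["Q"] = Q, _["P"] = P,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["iterations"] = it, _["converged"] = converged,
                      _["failed"] = false);
}

// Pairwise multi-locus squared genotype distances (codominant
// allele-count metric, 0/1/2/3/4 per locus), rescaled by L / L_observed
// for pairwise-complete loci. A pair sharing no scored locus gets -1.
// [[Rcpp::export]]
NumericMatrix cpp_pair_dist(IntegerMatrix Gm, IntegerVector Av) {
  const int n = Gm.nrow(), L = Av.size();
  NumericMatrix D(n, n);
  const int* G = INTEGER(Gm);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      int lobs = 0;
      for (int l = 0; l < L; ++l) {
        int a1 = G[i + (size_t)n * (2 * l)];
        int b1 = G[j + (size_t)n * (2 * l)];
        if (a1 == 0 || b1 == 0) continue;
        int a2 = G[i + (size_t)n * (2 * l + 1)];
        int b2 = G[j + (size_t)n * (2 * l + 1)];
        ++lobs;
        if (a1 == b1 && a2 == b2) continue;
        // allele-count differences over the <=4 alleles involved
        int al[4] = {a1, a2, b1, b2};
        double d2 = 0.0;
        for (int u = 0; u < 4; ++u) {
          bool seen = false;
          for (int v = 0; v < u; ++v)
            if (al[v] == al[u]) { seen = true; break; }
          if (seen) continue;
          int c1 = (a1 == al[u]) + (a2 == al[u]);
          int c2 = (b1 == al[u]) + (b2 == al[u]);
          d2 += (double)(c1 - c2) * (c1 - c2);
        }
        s += 0.5 * d2;
      }
      double val = lobs == 0 ? -1.0 : s * ((double)L / lobs);
      D(i, j) = val;
      D(j, i) = val;
    }
  return D;
}
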